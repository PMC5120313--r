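#' Modulation frequency band
#'
#' A band of envelope-modulation frequencies, named after the neural
#' oscillation band whose timescale it matches.
#'
#' @param name Band label (character scalar).
#' @param f_lo,f_hi Lower and upper edge in Hz; `0 < f_lo < f_hi`.
#' @return An object of class `"band"`: a list with `name`, `f_lo`, `f_hi`.
#' @examples
#' band("theta", 4, 10)
#' @export
band <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(f_lo), is.numeric(f_hi), length(f_lo) == 1L,
            length(f_hi) == 1L, is.finite(f_lo), is.finite(f_hi))
  if (!(f_lo > 0 && f_lo < f_hi)) stop("band requires 0 < f_lo < f_hi")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "band")
}

#' @export
print.band <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' Canonical envelope-modulation bands
#'
#' The six sub-50 Hz modulation bands examined as candidate primary and
#' secondary segmentation references: delta 0.4-4, theta 4-10, alpha 11-16,
#' beta 16-25, low gamma 25-35 and mid gamma 35-50 Hz.
#'
#' @return Named list of [band] objects.
#' @examples
#' speech_bands()$theta
#' @export
speech_bands <- function() {
  list(
    delta     = band("delta", 0.4, 4),
    theta     = band("theta", 4, 10),
    alpha     = band("alpha", 11, 16),
    beta      = band("beta", 16, 25),
    low_gamma = band("low_gamma", 25, 35),
    mid_gamma = band("mid_gamma", 35, 50)
  )
}

as_band <- function(x) {
  if (inherits(x, "band")) return(x)
  if (is.character(x) && length(x) == 1L) {
    b <- speech_bands()[[x]]
    if (is.null(b)) stop("unknown band name: ", x)
    return(b)
  }
  if (is.numeric(x) && length(x) == 2L) return(band("custom", x[1], x[2]))
  stop("cannot interpret band specification")
}
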