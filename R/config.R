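#' Pipeline configuration
#'
#' Collects every tunable parameter of the segmentation, entropy, feature
#' and recognition pipeline with its default. Defaults are the method's
#' published operating point: theta (4-10 Hz) primary and low-gamma
#' (25-35 Hz) secondary bands, energy-threshold factors 0.32 and 0.8,
#' 25 ms / 10 ms fixed-frame baseline, 33 ERB channels, 13 cepstra (39
#' dimensions with derivatives) and 4-state, 5-mixture HMMs.
#'
#' @param ... Named overrides of any default.
#' @return Object of class `"nvfs_config"` (a named list).
#' @examples
#' cfg <- nvfs_config(alpha = 0.25)
#' cfg$alpha
#' @export
nvfs_config <- function(...) {
  cfg <- list(
    fs = 16000,
    primary_band = "theta",
    secondary_band = "low_gamma",
    alpha = 0.32,
    beta = 0.8,
    min_frame_ms = 2,
    ffsr_frame_ms = 25,
    ffsr_shift_ms = 10,
    cse_channels = 33L,
    mfcc_n_filters = 26L,
    mfcc_n_cep = 13L,
    hmm_states = 4L,
    hmm_mixtures = 5L,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$fs > 0, cfg$alpha < cfg$beta, cfg$alpha > 0,
            cfg$min_frame_ms > 0, cfg$cse_channels >= 1,
            cfg$hmm_states >= 1, cfg$hmm_mixtures >= 1)
  as_band(cfg$primary_band); as_band(cfg$secondary_band)
  structure(cfg, class = c("nvfs_config", "list"))
}

#' @export
print.nvfs_config <- function(x, ...) {
  cat("<nvfs_config>\n")
  for (nm in names(x)) cat(sprintf("  %-15s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
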