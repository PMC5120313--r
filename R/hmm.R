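#' Mix signal and noise at a prescribed SNR
#'
#' Scales the noise so that `10*log10(P_signal / P_noise) = snr_db`, with
#' powers measured as mean square over the full utterance, and adds it to
#' the signal. Noise shorter than the signal is tiled; a seeded random
#' offset selects the noise excerpt.
#'
#' @param x Clean [waveform] (or numeric vector with `fs`).
#' @param noise Noise [waveform] or numeric vector at the same rate.
#' @param snr_db Target signal-to-noise ratio in dB.
#' @param seed Integer seed for the noise offset; `NULL` starts at 0.
#' @param fs Sampling rate if `x` is a bare vector.
#' @return A [waveform] of the noisy mixture. The scaled noise component is
#'   attached as attribute `"noise"` for SNR verification.
#' @examples
#' syl <- synth_cv(syllable_spec("p", "ih", seed = 6))
#' nz <- synth_noise("stationary", 8000, seed = 2)
#' noisy <- mix_at_snr(syl$wave, nz, 10, seed = 3)
#' @export
mix_at_snr <- function(x, noise, snr_db, seed = NULL, fs = NULL) {
  w <- .wave_parts(x, fs)
  nv <- if (inherits(noise, "waveform")) noise$samples else as.numeric(noise)
  n <- length(w$samples)
  if (length(nv) < n) nv <- rep_len(nv, n + length(nv))
  max_off <- length(nv) - n
  off <- if (is.null(seed) || max_off == 0L) 0L
         else with_seed(seed, sample.int(max_off + 1L, 1L) - 1L)
  nv <- nv[(off + 1L):(off + n)]
  ps <- mean(w$samples^2)
  pn <- mean(nv^2)
  if (ps == 0 || pn == 0) stop("zero-power signal or noise")
  g <- sqrt(ps / (pn * 10^(snr_db / 10)))
  out <- waveform(w$samples + g * nv, w$fs)
  attr(out, "noise") <- g * nv
  out
}

## ---- left-to-right diagonal-covariance GMM-HMM ----

# Model representation: list(trans KxK, init K, w KxM, mu  K x M x D,
# vr K x M x D). Left-to-right without skips: trans has only the diagonal
# and first superdiagonal; sequences start in state 1.

VAR_FLOOR <- 1e-4 # absolute lower bound; training adds a fractional floor

# log [w_m N(x | mu_m, diag(vr_m))] for all frames against every
# state-mixture component. X: T x D; mu, vr: (K*M) x D; lw: log weights.
log_gmm_dens2 <- function(X, mu, vr, lw) {
  D <- ncol(X)
  const <- -0.5 * D * log(2 * pi) - 0.5 * rowSums(log(vr))
  A <- X^2 %*% t(1 / (2 * vr))
  B <- X %*% t(mu / vr)
  Cc <- rowSums(mu^2 / (2 * vr))
  t(t(B - A) - Cc + const + lw)
}

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# per-state log emission and per-mixture responsibilities for one sequence
state_log_lik <- function(X, model) {
  K <- model$K; M <- model$M
  ld <- log_gmm_dens2(X, model$mu, model$vr, model$lw) # T x (K*M)
  TT <- nrow(X)
  B <- matrix(0, TT, K)
  for (k in seq_len(K)) {
    cols <- ((k - 1L) * M + 1L):(k * M)
    sub <- ld[, cols, drop = FALSE]
    mx <- apply(sub, 1L, max)
    B[, k] <- mx + log(rowSums(exp(sub - mx)))
  }
  list(B = B, ld = ld)
}

# scaled forward-backward; returns log-likelihood, state posteriors gamma
# (T x K) and transition expectations xi_sum (K x K)
forward_backward <- function(B, trans, init) {
  TT <- nrow(B); K <- ncol(B)
  b <- exp(B - apply(B, 1L, max)) # rescaled emissions
  bshift <- apply(B, 1L, max)
  alpha <- matrix(0, TT, K); beta <- matrix(0, TT, K)
  cvec <- numeric(TT)
  a <- init * b[1L, ]
  cvec[1L] <- sum(a)
  if (!is.finite(cvec[1L]) || cvec[1L] == 0) # emission underflow dead end
    return(list(loglik = -Inf))
  alpha[1L, ] <- a / cvec[1L]
  if (TT > 1L) for (t in 2:TT) {
    a <- as.numeric(crossprod(alpha[t - 1L, ], trans)) * b[t, ]
    cvec[t] <- sum(a)
    if (!is.finite(cvec[t]) || cvec[t] == 0)
      return(list(loglik = -Inf))
    alpha[t, ] <- a / cvec[t]
  }
  beta[TT, ] <- 1
  for (t in (TT - 1L):1L) {
    beta[t, ] <- as.numeric(trans %*% (b[t + 1L, ] * beta[t + 1L, ])) / cvec[t + 1L]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, K, K)
  for (t in 1:(TT - 1L)) {
    xi <- (alpha[t, ] %o% (b[t + 1L, ] * beta[t + 1L, ])) * trans / cvec[t + 1L]
    xi_sum <- xi_sum + xi
  }
  list(loglik = sum(log(cvec)) + sum(bshift), gamma = gamma, xi_sum = xi_sum)
}

hmm_loglik <- function(X, model) {
  if (nrow(X) < 1L) return(-Inf)
  sl <- state_log_lik(X, model)
  fb <- forward_backward(sl$B, model$trans, model$init)
  fb$loglik
}

init_hmm <- function(seqs, K, D, var_floor = VAR_FLOOR) {
  # uniform-segmentation initialization, single mixture per state
  mu <- matrix(0, K, D); vr <- matrix(0, K, D); cnt <- numeric(K)
  acc <- vector("list", K)
  for (k in seq_len(K)) acc[[k]] <- list(s = numeric(D), s2 = numeric(D), n = 0)
  for (X in seqs) {
    TT <- nrow(X)
    cuts <- floor(seq(0, TT, length.out = K + 1L))
    for (k in seq_len(K)) {
      idx <- (cuts[k] + 1L):cuts[k + 1L]
      if (cuts[k + 1L] <= cuts[k]) next
      sub <- X[idx, , drop = FALSE]
      acc[[k]]$s <- acc[[k]]$s + colSums(sub)
      acc[[k]]$s2 <- acc[[k]]$s2 + colSums(sub^2)
      acc[[k]]$n <- acc[[k]]$n + nrow(sub)
    }
  }
  for (k in seq_len(K)) {
    nk <- max(acc[[k]]$n, 1)
    mu[k, ] <- acc[[k]]$s / nk
    vr[k, ] <- pmax(acc[[k]]$s2 / nk - mu[k, ]^2, var_floor)
  }
  mean_T <- mean(vapply(seqs, nrow, numeric(1)))
  stay <- max(0.5, 1 - K / mean_T)
  trans <- matrix(0, K, K)
  for (k in seq_len(K - 1L)) {
    trans[k, k] <- stay; trans[k, k + 1L] <- 1 - stay
  }
  trans[K, K] <- 1
  list(K = K, M = 1L, D = D, trans = trans, init = c(1, numeric(K - 1L)),
       mu = mu, vr = vr, lw = rep(0, K)) # lw = log mixture weights, (K*M)
}

# split mixtures of every state until each has `target` components:
# repeatedly split the heaviest component, perturbing means by +-0.2 sd
split_mixtures <- function(model, target) {
  K <- model$K; D <- model$D
  mu_l <- vector("list", K); vr_l <- vector("list", K); lw_l <- vector("list", K)
  for (k in seq_len(K)) {
    cols <- ((k - 1L) * model$M + 1L):(k * model$M)
    mu <- model$mu[cols, , drop = FALSE]
    vr <- model$vr[cols, , drop = FALSE]
    w <- exp(model$lw[cols])
    while (nrow(mu) < target) {
      j <- which.max(w)
      sdj <- sqrt(vr[j, ])
      mu <- rbind(mu, mu[j, ] + 0.2 * sdj)
      mu[j, ] <- mu[j, ] - 0.2 * sdj
      vr <- rbind(vr, vr[j, ])
      w <- c(w, w[j] / 2); w[j] <- w[j] / 2
    }
    mu_l[[k]] <- mu; vr_l[[k]] <- vr; lw_l[[k]] <- log(w / sum(w))
  }
  model$M <- as.integer(target)
  model$mu <- do.call(rbind, mu_l)
  model$vr <- do.call(rbind, vr_l)
  model$lw <- unlist(lw_l)
  model
}

# Baum-Welch EM on a list of sequences; returns model with loglik trace.
train_hmm_em <- function(seqs, model, tol = 1e-3, max_iter = 100L,
                         var_floor = VAR_FLOOR) {
  K <- model$K; M <- model$M; D <- model$D
  trace <- numeric(0)
  prev <- -Inf
  for (iter in seq_len(max_iter)) {
    trans_num <- matrix(0, K, K)
    g_sum <- numeric(K * M)
    mu_num <- matrix(0, K * M, D)
    vr_num <- matrix(0, K * M, D)
    state_occ <- numeric(K)
    total_ll <- 0
    for (X in seqs) {
      sl <- state_log_lik(X, model)
      fb <- forward_backward(sl$B, model$trans, model$init)
      if (!is.finite(fb$loglik)) next
      total_ll <- total_ll + fb$loglik
      trans_num <- trans_num + fb$xi_sum
      # mixture responsibilities: gamma_k(t) * p(m | k, x_t)
      for (k in seq_len(K)) {
        cols <- ((k - 1L) * M + 1L):(k * M)
        sub <- sl$ld[, cols, drop = FALSE]
        mx <- apply(sub, 1L, max)
        pr <- exp(sub - mx)
        pr <- pr / rowSums(pr)
        r <- pr * fb$gamma[, k] # T x M
        g_sum[cols] <- g_sum[cols] + colSums(r)
        mu_num[cols, ] <- mu_num[cols, ] + t(r) %*% X
        vr_num[cols, ] <- vr_num[cols, ] + t(r) %*% (X^2)
        state_occ[k] <- state_occ[k] + sum(fb$gamma[, k])
      }
    }
    # M step
    rs <- rowSums(trans_num)
    for (k in seq_len(K)) {
      if (rs[k] > 0) model$trans[k, ] <- trans_num[k, ] / rs[k]
    }
    model$trans[K, K] <- 1; if (K > 1L) model$trans[K, -K] <- 0
    for (j in seq_len(K * M)) {
      if (g_sum[j] > 1e-8) {
        model$mu[j, ] <- mu_num[j, ] / g_sum[j]
        model$vr[j, ] <- pmax(vr_num[j, ] / g_sum[j] - model$mu[j, ]^2,
                              var_floor)
      }
    }
    for (k in seq_len(K)) {
      cols <- ((k - 1L) * M + 1L):(k * M)
      wk <- g_sum[cols]
      if (sum(wk) > 0) model$lw[cols] <- log(pmax(wk, 1e-12) / sum(pmax(wk, 1e-12)))
    }
    trace <- c(trace, total_ll)
    if (is.finite(prev) && abs(total_ll - prev) < tol) break
    prev <- total_ll
  }
  model$loglik_trace <- trace
  model
}

#' Train per-class syllable HMMs
#'
#' Fits one left-to-right hidden Markov model with diagonal-covariance
#' Gaussian-mixture emissions per class by Baum-Welch EM (log-likelihood
#' tolerance 1e-3, at most 100 iterations per stage). Mixtures are grown by
#' successive splitting 1 -> 2 -> `n_mix`, retraining after each split.
#' Variances are floored HTK-style at `var_floor_frac` (default 1%) of the
#' global per-dimension variance of the training features, with an absolute
#' lower bound of 1e-4. Initialization is deterministic (uniform
#' state segmentation), so training is reproducible; `seed` is accepted for
#' interface stability.
#'
#' @param features List of feature matrices (one per utterance, rows =
#'   frames), e.g. from [mfcc_for_frames()].
#' @param labels Class label per utterance.
#' @param n_states Number of HMM states (default 4).
#' @param n_mix Gaussian mixtures per state (default 5).
#' @param seed Unused placeholder for API stability (training is
#'   deterministic).
#' @param var_floor_frac Fraction of the global per-dimension variance used
#'   as the variance floor.
#' @param tol,max_iter EM stopping rule per mixture stage.
#' @return Object of class `"hmm_classifier"`: per-class models plus the EM
#'   log-likelihood traces.
#' @examples
#' \donttest{
#' corp <- build_corpus(6, classes = c("p", "t"), seed = 1)
#' feats <- lapply(corp, function(it) mfcc_for_frames(it$wave, nvfs(it$wave)))
#' mod <- train_models(feats, vapply(corp, `[[`, "", "label"))
#' }
#' @export
train_models <- function(features, labels, n_states = 4L, n_mix = 5L,
                         seed = NULL, var_floor_frac = 0.01, tol = 1e-3,
                         max_iter = 100L) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes")
  if (any(table(labels) < 5L)) stop("need at least 5 sequences per class")
  D <- ncol(features[[1L]])
  all_frames <- do.call(rbind, features)
  var_floor <- pmax(var_floor_frac * apply(all_frames, 2L, stats::var),
                    VAR_FLOOR)
  models <- list()
  schedule <- unique(pmin(c(1L, 2L, n_mix), n_mix))
  for (cls in classes) {
    seqs <- features[labels == cls]
    m <- init_hmm(seqs, n_states, D, var_floor = var_floor)
    trace <- numeric(0)
    for (M in schedule) {
      if (M > m$M) m <- split_mixtures(m, M)
      m <- train_hmm_em(seqs, m, tol = tol, max_iter = max_iter,
                        var_floor = var_floor)
      trace <- c(trace, m$loglik_trace)
    }
    m$loglik_trace <- trace
    models[[cls]] <- m
  }
  structure(list(models = models, classes = classes,
                 n_states = n_states, n_mix = n_mix,
                 var_floor = var_floor),
            class = "hmm_classifier")
}

#' @export
print.hmm_classifier <- function(x, ...) {
  cat(sprintf("<hmm_classifier> %d classes (%s), %d states, %d mixtures/state\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              x$n_states, x$n_mix))
  invisible(x)
}

#' @param object An `hmm_classifier`.
#' @param newdata List of feature matrices.
#' @param ... Unused.
#' @describeIn train_models Classify utterances by maximum class
#'   log-likelihood; returns a character vector of predicted classes with
#'   the per-class log-likelihood matrix as attribute `"loglik"`.
#' @export
predict.hmm_classifier <- function(object, newdata, ...) {
  L <- vapply(object$classes, function(cls)
    vapply(newdata, hmm_loglik, numeric(1), model = object$models[[cls]]),
    numeric(length(newdata)))
  L <- matrix(L, nrow = length(newdata),
              dimnames = list(NULL, object$classes))
  pred <- object$classes[max.col(L, ties.method = "first")]
  attr(pred, "loglik") <- L
  pred
}

#' Recognition accuracy of a trained classifier
#'
#' @param models An `hmm_classifier`.
#' @param features List of feature matrices (test set).
#' @param labels True class label per utterance.
#' @return Percent of utterances classified correctly (0-100).
#' @export
evaluate_models <- function(models, features, labels) {
  pred <- predict(models, features)
  100 * mean(as.character(pred) == as.character(labels))
}
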