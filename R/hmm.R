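# Seven-state Gaussian hidden Markov model with frozen emissions: the state
# photon levels are fixed a priori (low occupancy of the higher oligomers
# makes free emission fitting unidentifiable); only the transition matrix and
# initial distribution are estimated per trace.

#' Frozen emission specification for the seven-state HMM
#'
#' Defaults are the frozen state photon levels used throughout: background
#' S0 and the six oligomeric states S1..S6 at 20, 50, 100, 150, 200, 250,
#' 300 photons with SDs 25, 25, 35, 35, 35, 35, 35.
#'
#' @param state_means Photon means, strictly increasing.
#' @param state_sds Photon SDs (> 0), same length.
#' @param labels State labels (default `S0..S6`).
#' @param frozen Kept for provenance; emissions are always treated as frozen
#'   by [fit_hmm()] unless `freeze_sds = FALSE` there.
#' @return An object of class `hmm_spec`.
#' @export
hmm_spec <- function(state_means = c(20, 50, 100, 150, 200, 250, 300),
                     state_sds = c(25, 25, 35, 35, 35, 35, 35),
                     labels = paste0("S", seq_along(state_means) - 1L),
                     frozen = TRUE) {
  stopifnot(length(state_means) == length(state_sds),
            all(diff(state_means) > 0), all(state_sds > 0))
  structure(list(state_means = state_means, state_sds = state_sds,
                 labels = labels, frozen = frozen),
            class = "hmm_spec")
}

#' Write / read an HMM spec as JSON
#' @param spec An [hmm_spec()].
#' @param path File path.
#' @export
write_hmm_spec_json <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hmm_spec_json
#' @export
read_hmm_spec_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  hmm_spec(x$state_means, x$state_sds, x$labels)
}

# Scaled forward-backward pass, pure-R reference implementation. The
# compiled kernel (.hx_forward_backward) is used by fit_hmm(); this version
# is retained as an independent cross-check of the recursion.
.hmm_forward_backward <- function(logB, A, pi0) {
  Tn <- nrow(logB); K <- ncol(logB)
  mx <- apply(logB, 1L, max)
  B <- exp(logB - mx)
  alpha <- matrix(0, Tn, K)
  cvec <- numeric(Tn)
  a <- pi0 * B[1L, ]
  cvec[1L] <- sum(a)
  alpha[1L, ] <- a / cvec[1L]
  for (t in 2:Tn) {
    a <- drop(alpha[t - 1L, ] %*% A) * B[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(0, Tn, K)
  beta[Tn, ] <- 1
  for (t in (Tn - 1L):1L) {
    beta[t, ] <- drop(A %*% (B[t + 1L, ] * beta[t + 1L, ])) / cvec[t + 1L]
  }
  g <- alpha * beta
  g <- g / rowSums(g)
  list(alpha = alpha, beta = beta, B = B, cvec = cvec,
       gamma = g, loglik = sum(log(cvec)) + sum(mx))
}

.hmm_viterbi <- function(logB, A, pi0) {
  Tn <- nrow(logB); K <- ncol(logB)
  logA <- log(pmax(A, 1e-300))
  delta <- log(pmax(pi0, 1e-300)) + logB[1L, ]
  psi <- matrix(0L, Tn, K)
  for (t in 2:Tn) {
    m <- delta + logA              # K x K: prev state rows
    best <- max.col(t(m), ties.method = "first")
    psi[t, ] <- best
    delta <- m[cbind(best, seq_len(K))] + logB[t, ]
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  for (t in (Tn - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  path
}

#' Idealize a photon trace with the frozen-emission HMM
#'
#' Fits a Gaussian-emission HMM whose emission means and SDs are frozen to
#' the spec; the transition matrix and initial distribution are estimated per
#' trace by expectation-maximization (uniform initialization, at most
#' `max_iter` iterations, absolute log-likelihood tolerance `tol`). The state
#' path is obtained by Viterbi decoding, which yields a self-consistent path
#' for dwell-time analysis (per-frame posterior argmax does not). No minimum
#' dwell is imposed; single-frame states are retained and their prevalence is
#' reported as a diagnostic.
#'
#' @param trace A [photon_trace] or numeric photon vector (>= 10 frames).
#' @param spec An [hmm_spec()] (default [hmm_spec()]).
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Absolute log-likelihood convergence tolerance (default 1e-6).
#' @param freeze_sds Keep emission SDs frozen (default TRUE). When FALSE the
#'   SDs are re-estimated per state from the posterior weights.
#' @return An object of class `idealized_trace`: `states` (per-frame state
#'   index 0..6, i.e. the S-number), `idealized` (state mean photons),
#'   `residuals`, `loglik`, `trans_mat`, `initial`, `converged`,
#'   `single_frame_fraction`, `spec`.
#' @export
fit_hmm <- function(trace, spec = hmm_spec(), max_iter = 500L, tol = 1e-6,
                    freeze_sds = TRUE) {
  x <- if (inherits(trace, "photon_trace")) trace$photons else trace
  if (length(x) < 10L) stop("trace shorter than 10 frames")
  K <- length(spec$state_means)
  mu <- spec$state_means
  sdv <- spec$state_sds
  logB <- vapply(seq_len(K), function(k) dnorm(x, mu[k], sdv[k], log = TRUE),
                 numeric(length(x)))
  A <- matrix(1 / K, K, K)
  pi0 <- rep(1 / K, K)
  if (freeze_sds) {
    em <- .hx_em(logB, A, pi0, as.integer(max_iter), tol)
    A <- em$A
    pi0 <- em$pi
    ll_old <- em$loglik
    converged <- em$converged
  } else {
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      fb <- .hx_forward_backward(logB, A, pi0)
      if (it > 1L && abs(fb$loglik - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- fb$loglik
      A <- fb$Anum / pmax(rowSums(fb$Anum), 1e-300)
      pi0 <- fb$gamma[1L, ]
      for (k in seq_len(K)) {
        wk <- fb$gamma[, k]
        if (sum(wk) > 1e-8)
          sdv[k] <- sqrt(sum(wk * (x - mu[k])^2) / sum(wk))
      }
      sdv <- pmax(sdv, 1e-3)
      logB <- vapply(seq_len(K), function(k) dnorm(x, mu[k], sdv[k], log = TRUE),
                     numeric(length(x)))
    }
  }
  if (!converged)
    warning("EM did not converge within max_iter; returning best iterate")
  path <- .hx_viterbi(logB, log(pmax(A, 1e-300)), log(pmax(pi0, 1e-300)))
  ideal <- mu[path]
  rl <- rle(path)
  structure(list(states = path - 1L,
                 idealized = ideal,
                 residuals = x - ideal,
                 loglik = ll_old,
                 trans_mat = A, initial = pi0,
                 converged = converged,
                 single_frame_fraction = mean(rl$lengths == 1L),
                 spec = spec),
            class = "idealized_trace")
}

#' @export
print.idealized_trace <- function(x, ...) {
  cat(sprintf("idealized_trace: %d frames, %d transitions, loglik %.1f%s\n",
              length(x$states), sum(diff(x$states) != 0), x$loglik,
              if (!x$converged) " [EM not converged]" else ""))
  invisible(x)
}

#' Joint log-probability of a given state path under a fitted model
#'
#' Used to verify Viterbi optimality: the decoded path must score at least as
#' high as any other path, including the generating ground truth.
#'
#' @param trace Photon vector or [photon_trace].
#' @param states Per-frame state indices (0-based S-numbers).
#' @param fit An [fit_hmm()] result supplying the transition matrix, initial
#'   distribution and emission spec.
#' @return Scalar log-probability.
#' @export
path_logprob <- function(trace, states, fit) {
  x <- if (inherits(trace, "photon_trace")) trace$photons else trace
  k <- states + 1L
  mu <- fit$spec$state_means
  sdv <- fit$spec$state_sds
  em <- sum(dnorm(x, mu[k], sdv[k], log = TRUE))
  trans <- sum(log(pmax(fit$trans_mat[cbind(k[-length(k)], k[-1L])], 1e-300)))
  em + trans + log(pmax(fit$initial[k[1L]], 1e-300))
}

#' Pooled residual QC for idealized traces
#'
#' Pools residuals across traces, fits a single Gaussian (mean, SD) and
#' reports an Anderson-Darling normality p-value. Residuals centered on zero
#' with no heavy structure indicate the frozen seven-state levels describe
#' the data without systematic error.
#'
#' @param idealized List of [idealized_trace] objects (or one).
#' @param max_n Residuals are subsampled to this many values for the
#'   normality statistic (default 5000; the moments use all residuals).
#' @param seed Seed for the subsample.
#' @return List with `mu`, `sigma`, `n`, `normality_p`, `degenerate`.
#' @export
residual_qc <- function(idealized, max_n = 5000L, seed = 1L) {
  if (inherits(idealized, "idealized_trace")) idealized <- list(idealized)
  res <- unlist(lapply(idealized, `[[`, "residuals"))
  mu <- mean(res); sigma <- sd(res)
  degenerate <- !is.finite(sigma) || sigma < .Machine$double.eps^0.5
  pval <- if (degenerate) NA_real_ else {
    sub <- if (length(res) > max_n) with_seed(seed, sample(res, max_n)) else res
    tryCatch(nortest::ad.test(sub)$p.value, error = function(e) NA_real_)
  }
  list(mu = mu, sigma = sigma, n = length(res),
       normality_p = pval, degenerate = degenerate)
}

#' Calibrate photons per monomer from a monomeric control
#'
#' Pools the per-frame photon values of monomeric (anchored) control traces
#' (optionally restricted to pre-bleach frames via a [bleach_blink_qc()]
#' report) and fits a single Gaussian. A two-component mixture screen flags
#' aggregate contamination (multimodality); in that case the dominant mode is
#' reported with a warning.
#'
#' @param traces List of [photon_trace] objects or numeric vectors.
#' @param qc Optional [bleach_blink_qc()] report for the same traces;
#'   frames from the first bleached block onward are dropped.
#' @param seed Seed for the mixture-screen subsample.
#' @return An object of class `monomer_calibration`: `mu`, `sigma`,
#'   `n_particles`, `n_frames`, `multimodal`.
#' @export
calibrate_photons_per_monomer <- function(traces, qc = NULL, seed = 1L) {
  get_photons <- function(tr) if (inherits(tr, "photon_trace")) tr$photons else tr
  vals <- lapply(seq_along(traces), function(i) {
    p <- get_photons(traces[[i]])
    if (!is.null(qc) && !is.na(qc$first_bleached_block[i])) {
      cut <- (qc$first_bleached_block[i] - 1L) * 400L
      p <- p[seq_len(min(length(p), max(cut, 0L)))]
    }
    p
  })
  x <- unlist(vals)
  if (!length(x)) stop("no frames left after bleach filtering")
  mu <- mean(x); sigma <- sd(x)
  multimodal <- FALSE
  sub <- if (length(x) > 20000L) with_seed(seed, sample(x, 20000L)) else x
  gm <- .gmm2(sub)
  sep <- abs(diff(gm$means)) / max(gm$sds)
  if (gm$bic2 < gm$bic1 - 10 && min(gm$weights) > 0.1 && sep > 3) {
    multimodal <- TRUE
    major <- which.max(gm$weights)
    mu <- gm$means[major]
    sigma <- gm$sds[major]
    warning("monomer photon distribution is multimodal (aggregate contamination?); reporting the dominant mode")
  }
  structure(list(mu = mu, sigma = sigma,
                 n_particles = length(traces), n_frames = length(x),
                 multimodal = multimodal),
            class = "monomer_calibration")
}

#' @export
print.monomer_calibration <- function(x, ...) {
  cat(sprintf("monomer_calibration: %.1f photons/monomer (sigma = %.1f; %d particles, %d frames)%s\n",
              x$mu, x$sigma, x$n_particles, x$n_frames,
              if (x$multimodal) " [multimodal]" else ""))
  invisible(x)
}

#' State occupancies from the pooled photon histogram
#'
#' Fits the pooled (idealized or raw) photon values with a mixture of seven
#' Gaussians whose means and SDs are frozen to the spec; the mixture weights
#' are the state occupancies. The uncertainty is estimated by parametric
#' bootstrap: the fitted mixture is resampled and refitted `n_boot` times
#' (10 by default) and the mean and SD over refits are reported.
#'
#' @param values Pooled photon values (numeric), e.g. concatenated
#'   `idealized` fields (optionally jittered by the residual width) or raw
#'   photons.
#' @param spec An [hmm_spec()].
#' @param n_boot Number of parametric-bootstrap refits (default 10).
#' @param seed Seed for the bootstrap.
#' @return List with `weights` (named, sums to 1), `boot_mean`, `boot_sd`.
#' @export
state_occupancy <- function(values, spec = hmm_spec(), n_boot = 10L, seed = NULL) {
  w <- .frozen_mixture_weights(values, spec$state_means, spec$state_sds)
  names(w) <- spec$labels
  boot <- with_seed(seed, {
    replicate(n_boot, {
      comp <- sample.int(length(w), length(values), replace = TRUE, prob = pmax(w, 1e-12))
      xb <- rnorm(length(values), spec$state_means[comp], spec$state_sds[comp])
      .frozen_mixture_weights(xb, spec$state_means, spec$state_sds)
    })
  })
  list(weights = w,
       boot_mean = setNames(rowMeans(boot), spec$labels),
       boot_sd = setNames(apply(boot, 1L, sd), spec$labels))
}

#' Write idealized traces as a long-format CSV table
#'
#' Columns: particle, frame, raw_photons, state, idealized_photons, residual.
#'
#' @param idealized List of [idealized_trace] objects.
#' @param raw Matching list of raw traces (optional; reconstructed from
#'   idealized + residuals when omitted).
#' @param path File path.
#' @return `path` invisibly.
#' @export
write_idealized_csv <- function(idealized, path, raw = NULL) {
  rows <- lapply(seq_along(idealized), function(i) {
    it <- idealized[[i]]
    rp <- if (is.null(raw)) it$idealized + it$residuals else
      (if (inherits(raw[[i]], "photon_trace")) raw[[i]]$photons else raw[[i]])
    data.frame(particle = i, frame = seq_along(it$states),
               raw_photons = rp, state = it$states,
               idealized_photons = it$idealized, residual = it$residuals)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
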