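# EMCCD noise model: Poisson (shot noise) convolved with Erlang (EM gain
# register), fitted per pixel on a particle-free control stack, then used to
# convert camera counts to photons.

#' Poisson-Erlang pixel-intensity density (continuous part)
#'
#' Density of the EMCCD count `s` given offset `s0`, inverse gain `gamma`
#' (photons per count) and expected photons `E`:
#' a point mass `exp(-E)` at `s = s0` (zero detected photons; see
#' [emccd_zero_mass()]) plus, for `s > s0`, the continuous part
#' `sqrt(gamma*E/(s - s0)) * exp(-gamma*(s - s0) - E) * I1(2*sqrt(gamma*E*(s - s0)))`
#' with `I1` the modified Bessel function of the first kind. The continuous
#' part is evaluated on the offset-corrected argument `s - s0`: this is the
#' only convention under which the density integrates to one and has mean
#' `s0 + E/gamma`, i.e. it is the true generative compound Poisson-Gamma
#' model.
#'
#' @param s Counts (vectorized).
#' @param s0 Count offset (>= 0).
#' @param gamma Inverse gain, photons per count (> 0).
#' @param E Expected photons (>= 0).
#' @return Continuous density at `s` (0 for `s <= s0`).
#' @export
emccd_pdf <- function(s, s0, gamma, E) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (E < 0) stop("E must be >= 0")
  ds <- s - s0
  out <- numeric(length(s))
  pos <- ds > 0
  if (E > 0 && any(pos)) {
    x <- 2 * sqrt(gamma * E * ds[pos])
    # scaled Bessel keeps the product finite for large arguments
    out[pos] <- sqrt(gamma * E / ds[pos]) *
      besselI(x, nu = 1, expon.scaled = TRUE) *
      exp(x - gamma * ds[pos] - E)
  }
  out
}

#' Point mass of the EMCCD density at `s = s0`
#'
#' Probability that zero photons are detected, `exp(-E)`.
#'
#' @inheritParams emccd_pdf
#' @return `exp(-E)`.
#' @export
emccd_zero_mass <- function(E) {
  if (any(E < 0)) stop("E must be >= 0")
  exp(-E)
}

# Bin probabilities of the compound Poisson-Gamma count model over bins
# defined by `edges` (left-closed). The CDF of the continuous part is
# F(s) = sum_n Pois(n | E) * pgamma(s - s0, shape = n, rate = gamma); for
# integer shapes the incomplete gamma obeys
# P_{n+1}(x) = P_n(x) - e^{-x} x^n / n!, so the whole sum is a cheap
# vectorized recurrence. The zero-photon spike exp(-E) lands in the bin
# containing s0.
.emccd_bin_probs <- function(edges, s0, gamma, E) {
  nb <- length(edges) - 1L
  x <- pmax(gamma * (edges - s0), 0)
  nmax <- max(5L, ceiling(E + 10 * sqrt(E) + 10))
  ex <- exp(-x)
  P <- 1 - ex            # pgamma(x, 1, 1)
  tn <- x * ex           # e^-x x^n / n! at n = 1
  pn <- dpois(seq_len(nmax), E)
  F <- pn[1L] * P
  for (n in 2:nmax) {
    P <- P - tn
    F <- F + pn[n] * P
    tn <- tn * x / n
  }
  probs <- pmax(diff(F), 0)
  spike_bin <- findInterval(s0, edges, rightmost.closed = TRUE)
  if (spike_bin >= 1L && spike_bin <= nb)
    probs[spike_bin] <- probs[spike_bin] + exp(-E)
  probs
}

# Merge adjacent integer-count bins until each expected count is >= 5 under
# the provided parameter guess (chi-square validity).
.merge_bins <- function(counts_tab, edges, s0, gamma, E, n_obs, min_expected = 5) {
  p <- .emccd_bin_probs(edges, s0, gamma, E) * n_obs
  new_edges <- edges[1L]
  new_obs <- numeric(0)
  acc_o <- 0; acc_e <- 0
  for (i in seq_along(counts_tab)) {
    acc_o <- acc_o + counts_tab[i]
    acc_e <- acc_e + p[i]
    if (acc_e >= min_expected) {
      new_edges <- c(new_edges, edges[i + 1L])
      new_obs <- c(new_obs, acc_o)
      acc_o <- 0; acc_e <- 0
    }
  }
  if (acc_o > 0 || acc_e > 0) {
    # fold the remainder into the last bin
    if (length(new_obs)) {
      new_obs[length(new_obs)] <- new_obs[length(new_obs)] + acc_o
      new_edges[length(new_edges)] <- edges[length(edges)]
    } else {
      new_obs <- acc_o
      new_edges <- c(new_edges, edges[length(edges)])
    }
  }
  list(obs = new_obs, edges = new_edges)
}

# Moment-based initial estimate from the compound model cumulants:
# mean = s0 + E/gamma, var = 2E/gamma^2, third central moment = 6E/gamma^3.
.emccd_moments_init <- function(x) {
  m <- mean(x); v <- var(x)
  k3 <- mean((x - m)^3)
  gamma0 <- if (is.finite(k3) && k3 > 0) 3 * v / k3 else NA_real_
  if (!is.finite(gamma0) || gamma0 <= 0) gamma0 <- 2 / sqrt(max(v, 1e-6))
  E0 <- gamma0^2 * v / 2
  if (!is.finite(E0) || E0 <= 0) E0 <- 1
  s00 <- m - E0 / gamma0
  if (!is.finite(s00)) s00 <- min(x)
  c(s0 = s00, gamma = gamma0, E = E0)
}

#' Fit the Poisson-Erlang model to one pixel's count histogram
#'
#' Minimum chi-square fit of `(s0, gamma, E)` to the integer-binned counts of
#' a single pixel across frames. Integer bins are merged until the expected
#' count per bin is at least 5 (evaluated at a moment-based initial
#' estimate); the zero-photon spike is kept as the bin containing `s0`, not
#' approximated by a narrow Gaussian. The goodness-of-fit p-value uses the
#' chi-square statistic with `bins - 3 - 1` degrees of freedom.
#'
#' @param counts Numeric vector of camera counts for one pixel (>= 100
#'   observations).
#' @param init Optional named vector `c(s0=, gamma=, E=)` overriding the
#'   moment-based starting point.
#' @return List with `s0`, `gamma`, `E`, `chisq`, `df`, `p_value`, `ok`
#'   (FALSE for degenerate histograms that cannot be fitted).
#' @export
fit_emccd_pixel <- function(counts, init = NULL) {
  if (length(counts) < 100L) stop("need >= 100 observations per pixel")
  n_obs <- length(counts)
  lo <- floor(min(counts)); hi <- ceiling(max(counts)) + 1L
  if (hi - lo < 3L) {
    return(list(s0 = mean(counts), gamma = NA_real_, E = NA_real_,
                chisq = NA_real_, df = NA_integer_, p_value = NA_real_, ok = FALSE))
  }
  edges <- seq(lo - 0.5, hi + 0.5, by = 1)
  tab <- tabulate(findInterval(counts, edges), nbins = length(edges) - 1L)
  p0 <- if (is.null(init)) .emccd_moments_init(counts) else init
  merged <- .merge_bins(tab, edges, p0[["s0"]], p0[["gamma"]], p0[["E"]], n_obs)
  nb <- length(merged$obs)
  if (nb < 5L) {
    return(list(s0 = mean(counts), gamma = NA_real_, E = NA_real_,
                chisq = NA_real_, df = NA_integer_, p_value = NA_real_, ok = FALSE))
  }
  obj <- function(theta) {
    s0 <- theta[1L]; g <- exp(theta[2L]); E <- exp(theta[3L])
    if (!is.finite(s0) || !is.finite(g) || !is.finite(E) || E > 1e4) return(1e12)
    expd <- .emccd_bin_probs(merged$edges, s0, g, E) * n_obs
    sum((merged$obs - expd)^2 / pmax(expd, 1e-9))
  }
  # two starting points: compound-model cumulants, and (when visible) the
  # zero-photon spike at the modal count with moments conditioned on it
  starts <- list(c(p0[["s0"]], log(p0[["gamma"]]), log(p0[["E"]])))
  tabmax <- which.max(tab)
  mode_count <- (edges[tabmax] + edges[tabmax + 1L]) / 2
  if (mode_count < mean(counts)) {
    m <- mean(counts); v <- var(counts)
    g1 <- 2 * (m - mode_count) / v
    if (is.finite(g1) && g1 > 0) {
      E1 <- g1 * (m - mode_count)
      if (is.finite(E1) && E1 > 0)
        starts <- c(starts, list(c(mode_count, log(g1), log(E1))))
    }
  }
  fit <- NULL
  for (th0 in starts) {
    cand <- optim(th0, obj, method = "Nelder-Mead",
                  control = list(maxit = 1000, reltol = 1e-9))
    if (is.null(fit) || cand$value < fit$value) fit <- cand
  }
  chisq <- fit$value
  df <- nb - 3L - 1L
  pval <- pchisq(chisq, df, lower.tail = FALSE)
  list(s0 = fit$par[1L], gamma = exp(fit$par[2L]), E = exp(fit$par[3L]),
       chisq = chisq, df = df, p_value = pval, ok = TRUE)
}

#' Calibrate an EMCCD from a particle-free control stack
#'
#' Selects `n_pixels` random pixels from the control movie (without
#' replacement, capped at the pixel count), fits each pixel's intensity
#' histogram with the Poisson-Erlang model, and averages `s0` and `gamma`
#' over fits whose goodness-of-fit p-value exceeds `p_threshold` (1% by
#' default). Per-pixel `E` is retained as a diagnostic only; the count ->
#' photon conversion uses only the averaged `s0` and `gamma`.
#'
#' @param control_movie A particle-free [tirf_movie()] in counts.
#' @param n_pixels Number of random pixels to fit (default 400).
#' @param seed Integer seed for the pixel selection.
#' @param p_threshold Acceptance threshold on the fit p-value (default 0.01).
#' @param min_accepted Minimum accepted fits below which calibration fails
#'   (default 10).
#' @return An object of class `camera_model` with `s0`, `gamma`,
#'   `n_pixels_fit`, `n_pixels_accepted` and the per-pixel fit table.
#' @export
calibrate_camera <- function(control_movie, n_pixels = 400L, seed = NULL,
                             p_threshold = 0.01, min_accepted = 10L) {
  stopifnot(inherits(control_movie, "tirf_movie"))
  d <- dim(control_movie$data)
  npx <- d[2L] * d[3L]
  n_pixels <- min(as.integer(n_pixels), npx)
  mat <- matrix(control_movie$data, d[1L], npx)
  idx <- with_seed(seed, sample.int(npx, n_pixels))
  fits <- lapply(idx, function(i) fit_emccd_pixel(mat[, i]))
  tab <- data.frame(pixel = idx,
                    s0 = vapply(fits, `[[`, numeric(1L), "s0"),
                    gamma = vapply(fits, `[[`, numeric(1L), "gamma"),
                    E = vapply(fits, `[[`, numeric(1L), "E"),
                    p_value = vapply(fits, `[[`, numeric(1L), "p_value"),
                    ok = vapply(fits, `[[`, logical(1L), "ok"))
  acc <- tab$ok & !is.na(tab$p_value) & tab$p_value > p_threshold
  if (sum(acc) < min_accepted)
    stop(sprintf("camera calibration unusable: only %d of %d pixel fits accepted",
                 sum(acc), n_pixels))
  structure(list(s0 = mean(tab$s0[acc]), gamma = mean(tab$gamma[acc]),
                 n_pixels_fit = n_pixels, n_pixels_accepted = sum(acc),
                 fits = tab),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("camera_model: s0 = %.2f counts, gamma = %.4g photons/count (%d/%d pixel fits accepted)\n",
              x$s0, x$gamma, x$n_pixels_accepted, x$n_pixels_fit))
  invisible(x)
}

#' Write / read a camera model as JSON
#' @param model A `camera_model`.
#' @param path File path.
#' @return `path` invisibly (write); a `camera_model` (read).
#' @export
write_camera_json <- function(model, path) {
  jsonlite::write_json(list(s0 = model$s0, gamma = model$gamma,
                            n_pixels_fit = model$n_pixels_fit,
                            n_pixels_accepted = model$n_pixels_accepted),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_camera_json
#' @export
read_camera_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(s0 = x$s0, gamma = x$gamma,
                 n_pixels_fit = x$n_pixels_fit,
                 n_pixels_accepted = x$n_pixels_accepted, fits = NULL),
            class = "camera_model")
}

#' Convert camera counts to photons
#'
#' `n = (s - <s0>) * <gamma>`, applied elementwise. Negative photon values are
#' permitted: they are noise around zero and carry information for
#' downstream averaging.
#'
#' @param x Counts: numeric vector/array or a [tirf_movie()].
#' @param model A `camera_model`.
#' @return Same shape as `x` (a movie keeps its class, with units flipped).
#' @export
to_photons <- function(x, model) {
  stopifnot(inherits(model, "camera_model"))
  if (inherits(x, "tirf_movie")) {
    x$data <- (x$data - model$s0) * model$gamma
    x$units <- "photons"
    return(x)
  }
  (x - model$s0) * model$gamma
}
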