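# Small numerical helpers shared across the pipeline.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the previous RNG state so
#' that seeded operations leave no global trace. A `NULL` seed evaluates `code`
#' with the ambient RNG stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Reflect an (possibly out-of-range) index into 1..n (mirror boundary,
# repeated folding so kernels wider than the image remain valid).
.reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n
  j <- (i - 1L) %% p
  j <- ifelse(j >= n, p - 1L - j, j)
  as.integer(j + 1L)
}

# Separable Gaussian convolution of a matrix with reflective boundaries.
.gaussian_blur2d <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  n <- nrow(mat); m <- ncol(mat)
  tmp <- matrix(0, n, m)
  for (d in seq(-r, r)) {
    tmp <- tmp + k[d + r + 1L] * mat[.reflect_index(seq_len(n) + d, n), , drop = FALSE]
  }
  out <- matrix(0, n, m)
  for (d in seq(-r, r)) {
    out <- out + k[d + r + 1L] * tmp[, .reflect_index(seq_len(m) + d, m), drop = FALSE]
  }
  out
}

# Gaussian smoothing along the rows of a matrix (used for the time axis,
# rows = frames), reflective boundaries.
.gaussian_blur_rows <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  n <- nrow(mat)
  out <- matrix(0, n, ncol(mat))
  for (d in seq(-r, r)) {
    out <- out + k[d + r + 1L] * mat[.reflect_index(seq_len(n) + d, n), , drop = FALSE]
  }
  out
}

# Boxcar (uniform) mean filter of a matrix, window `width`, reflective.
.boxcar2d <- function(mat, width) {
  r <- max(1L, floor(width / 2))
  n <- nrow(mat); m <- ncol(mat)
  tmp <- matrix(0, n, m)
  for (d in seq(-r, r)) {
    tmp <- tmp + mat[.reflect_index(seq_len(n) + d, n), , drop = FALSE]
  }
  tmp <- tmp / (2 * r + 1)
  out <- matrix(0, n, m)
  for (d in seq(-r, r)) {
    out <- out + tmp[, .reflect_index(seq_len(m) + d, m), drop = FALSE]
  }
  out / (2 * r + 1)
}

# Gaussian smoothing of a numeric vector, reflective boundaries.
.gaussian_smooth_vec <- function(x, sigma) {
  if (sigma <= 0) return(x)
  drop(.gaussian_blur_rows(matrix(x, ncol = 1L), sigma))
}

# EM fit of mixture weights with all component means/sds frozen.
# Returns the weight vector; components can collapse to weight 0.
.frozen_mixture_weights <- function(x, means, sds, max_iter = 1000L, tol = 1e-10) {
  stopifnot(length(means) == length(sds))
  k <- length(means)
  logd <- vapply(seq_len(k), function(j) dnorm(x, means[j], sds[j], log = TRUE),
                 numeric(length(x)))
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    lp <- sweep(logd, 2L, log(pmax(w, 1e-300)), "+")
    mx <- apply(lp, 1L, max)
    p <- exp(lp - mx)
    rs <- rowSums(p)
    ll <- sum(log(rs) + mx)
    w <- colSums(p / rs) / length(x)
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  w
}

# Two-component 1-D Gaussian mixture by EM (free means, variances, weights),
# used as a bimodality screen. Returns parameters plus the BIC of the 1- and
# 2-component fits.
.gmm2 <- function(x, max_iter = 300L, tol = 1e-8) {
  n <- length(x)
  mu <- unname(quantile(x, c(0.25, 0.75)))
  sdv <- rep(sd(x) / 2, 2L) + 1e-9
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    lp <- cbind(log(w[1L]) + dnorm(x, mu[1L], sdv[1L], log = TRUE),
                log(w[2L]) + dnorm(x, mu[2L], sdv[2L], log = TRUE))
    m <- pmax(lp[, 1L], lp[, 2L])
    p1 <- exp(lp[, 1L] - m); p2 <- exp(lp[, 2L] - m)
    tot <- p1 + p2
    ll <- sum(log(tot) + m)
    r <- p1 / tot
    w <- c(mean(r), 1 - mean(r))
    if (any(w < 1e-8)) break
    mu <- c(sum(r * x) / sum(r), sum((1 - r) * x) / sum(1 - r))
    sdv <- sqrt(c(sum(r * (x - mu[1L])^2) / sum(r),
                  sum((1 - r) * (x - mu[2L])^2) / sum(1 - r)))
    sdv <- pmax(sdv, 1e-9)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  bic2 <- -2 * ll + 5 * log(n)
  bic1 <- -2 * sum(dnorm(x, mean(x), sd(x), log = TRUE)) + 2 * log(n)
  list(means = mu, sds = sdv, weights = w, bic1 = bic1, bic2 = bic2)
}

.stars_from_p <- function(p) {
  if (!is.finite(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}
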