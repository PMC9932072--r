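# Image pipeline: illumination correction, particle localization and ROI
# photometry turning a photon-calibrated movie into single-particle traces.

#' Estimate the background illumination profile
#'
#' The time-average image of the movie is convolved with a wide spatial
#' Gaussian (sigma = 30 px by default, reflective boundaries). The smoothing
#' removes particle-scale structure, leaving the slowly varying excitation
#' profile.
#'
#' @param movie A [tirf_movie()] (photons or counts).
#' @param smoothing_sigma Spatial Gaussian width in pixels (default 30).
#' @return An `illumination_profile`: strictly positive H x W matrix with the
#'   smoothing sigma attached.
#' @export
estimate_illumination <- function(movie, smoothing_sigma = 30) {
  stopifnot(inherits(movie, "tirf_movie"))
  avg <- time_average(movie)
  prof <- .gaussian_blur2d(avg, smoothing_sigma)
  if (any(prof <= 0))
    stop("estimated illumination profile is not strictly positive; check input")
  structure(prof, class = c("illumination_profile", "matrix"),
            smoothing_sigma = smoothing_sigma)
}

#' Correct a movie for the illumination profile
#'
#' Each frame is divided pixelwise by the profile normalized to its maximum;
#' max-normalization keeps the photon scale of a particle under peak
#' illumination (a plain division by the raw profile would destroy the photon
#' units). A temporally smoothed copy (Gaussian, sigma = 3 frames) is kept
#' for particle detection only; photometry always uses the unsmoothed
#' corrected frames, because temporal smoothing would distort dwell kinetics
#' at the 0.15 s frame interval.
#'
#' @param movie A [tirf_movie()] (photon units recommended).
#' @param profile An [estimate_illumination()] result (or any positive
#'   matrix of matching size).
#' @param temporal_sigma Temporal Gaussian width in frames for the detection
#'   copy (default 3; 0 disables).
#' @return A `corrected_movie`: list with `photometry` (corrected movie),
#'   `detection` (corrected + temporally smoothed movie) and `profile`
#'   (the normalized profile used).
#' @export
correct_movie <- function(movie, profile, temporal_sigma = 3) {
  stopifnot(inherits(movie, "tirf_movie"))
  prof <- unclass(profile)
  d <- dim(movie$data)
  if (!all(dim(prof) == d[2:3])) stop("profile shape does not match movie")
  if (any(prof <= 0)) stop("cannot divide by a non-positive illumination profile")
  prof <- prof / max(prof)
  mat <- matrix(movie$data, d[1L], d[2L] * d[3L])
  mat <- sweep(mat, 2L, as.vector(prof), "/")
  phot <- tirf_movie(array(mat, dim = d), movie$frame_interval, movie$units)
  det <- if (temporal_sigma > 0) {
    tirf_movie(array(.gaussian_blur_rows(mat, temporal_sigma), dim = d),
               movie$frame_interval, movie$units)
  } else phot
  structure(list(photometry = phot, detection = det, profile = prof),
            class = "corrected_movie")
}

#' @export
print.corrected_movie <- function(x, ...) {
  cat("corrected_movie:\n  ")
  print(x$photometry)
  invisible(x)
}

# Greedy enforcement of a minimum separation between candidate maxima,
# keeping the brighter one.
.enforce_separation <- function(cand, separation) {
  if (nrow(cand) <= 1L) return(cand)
  ord <- order(cand$strength, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    d2 <- (prev$x - cand$x[i])^2 + (prev$y - cand$y[i])^2
    keep[i] <- all(d2 >= separation^2)
  }
  cand[keep, , drop = FALSE]
}

# Least-squares 2-D Gaussian refinement around a candidate (0-based coords).
.fit_gaussian2d <- function(img, x0, y0, win) {
  h <- nrow(img); w <- ncol(img)
  cols <- max(0L, round(x0) - win):min(w - 1L, round(x0) + win)
  rows <- max(0L, round(y0) - win):min(h - 1L, round(y0) + win)
  z <- img[rows + 1L, cols + 1L, drop = FALSE]
  xs <- matrix(rep(cols, each = length(rows)), length(rows))
  ys <- matrix(rep(rows, length(cols)), length(rows))
  b0 <- median(z)
  a0 <- max(z) - b0
  if (a0 <= 0) a0 <- max(abs(z - b0), 1e-6)
  obj <- function(p) {
    mu_x <- p[1L]; mu_y <- p[2L]
    amp <- exp(p[3L]); sx <- exp(p[4L]); sy <- exp(p[5L]); b <- p[6L]
    model <- b + amp * exp(-((xs - mu_x)^2 / (2 * sx^2) + (ys - mu_y)^2 / (2 * sy^2)))
    sum((model - z)^2)
  }
  fit <- optim(c(x0, y0, log(a0), log(1.5), log(1.5), b0), obj,
               method = "Nelder-Mead", control = list(maxit = 2000, reltol = 1e-12))
  p <- fit$par
  list(x = p[1L], y = p[2L], amplitude = exp(p[3L]),
       sigma_x = exp(p[4L]), sigma_y = exp(p[5L]), baseline = p[6L],
       sse = fit$value)
}

#' Locate particles on the time-average image
#'
#' Candidate spots are found on the time-average of the (temporally smoothed)
#' detection movie by band-pass filtering (Gaussian smoothing minus a boxcar
#' background over the spot diameter) followed by local-maximum detection
#' with the stated minimum separation. Candidates whose integrated,
#' background-subtracted mass falls below `minmass_factor` times the mean of
#' the averaged movie are discarded. Each survivor is refined by a
#' least-squares 2-D Gaussian fit (x, y, amplitude, sigma_x, sigma_y,
#' baseline); roundness = max(sigma)/min(sigma) and spots outside
#' `roundness_range` (which excludes merged spots) are dropped.
#'
#' @param corrected A [correct_movie()] result.
#' @param diameter Spot diameter in pixels (default 11).
#' @param separation Minimum spot separation in pixels (default 6).
#' @param minmass_factor Mass threshold as a fraction of the averaged-movie
#'   mean (default 0.4).
#' @param snr_threshold Minimum band-passed peak height in robust noise units
#'   (MAD of the band-passed average, default 5); suppresses spurious
#'   detections on near-empty backgrounds.
#' @param roundness_range Acceptance window for roundness (default
#'   `c(1, 1.6)`); `NULL` disables the filter.
#' @return data.frame with columns x, y (0-based sub-pixel), amplitude,
#'   sigma_x, sigma_y, baseline, roundness, mass. Empty when nothing is
#'   found.
#' @export
locate_particles <- function(corrected, diameter = 11, separation = 6,
                             minmass_factor = 0.4, snr_threshold = 5,
                             roundness_range = c(1, 1.6)) {
  stopifnot(inherits(corrected, "corrected_movie"))
  avg_det <- time_average(corrected$detection)
  avg_phot <- time_average(corrected$photometry)
  h <- nrow(avg_det); w <- ncol(avg_det)
  empty <- data.frame(x = numeric(0), y = numeric(0), amplitude = numeric(0),
                      sigma_x = numeric(0), sigma_y = numeric(0),
                      baseline = numeric(0), roundness = numeric(0),
                      mass = numeric(0))
  bpu <- .gaussian_blur2d(avg_det, 1) - .boxcar2d(avg_det, diameter)
  bp <- pmax(bpu, 0)
  noise <- mad(bpu)
  # local maxima within the separation neighborhood
  r <- max(1L, floor(separation / 2))
  dil <- bp
  for (dy in seq(-r, r)) for (dx in seq(-r, r)) {
    if (dx == 0L && dy == 0L) next
    dil <- pmax(dil, bp[.reflect_index(seq_len(h) + dy, h),
                        .reflect_index(seq_len(w) + dx, w)])
  }
  is_max <- bp >= dil & bp > 0
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  cand <- data.frame(x = idx[, 2L] - 1, y = idx[, 1L] - 1,
                     strength = bp[idx])
  cand <- cand[cand$strength >= snr_threshold * noise, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand <- .enforce_separation(cand, separation)
  # integrated background-subtracted mass within the spot diameter
  rad <- diameter / 2
  off <- expand.grid(dx = seq(-floor(rad), floor(rad)),
                     dy = seq(-floor(rad), floor(rad)))
  off <- off[off$dx^2 + off$dy^2 <= rad^2, ]
  med <- median(avg_phot)
  minmass <- minmass_factor * mean(avg_phot)
  win <- (diameter - 1) / 2
  out <- list()
  for (i in seq_len(nrow(cand))) {
    cx <- round(cand$x[i]); cy <- round(cand$y[i])
    px <- cx + off$dx; py <- cy + off$dy
    inside <- px >= 0 & px < w & py >= 0 & py < h
    mass <- sum(avg_phot[cbind(py[inside] + 1L, px[inside] + 1L)] - med)
    if (mass < minmass) next
    if (cx < win || cx > w - 1 - win || cy < win || cy > h - 1 - win) next
    g <- .fit_gaussian2d(avg_phot, cand$x[i], cand$y[i], win)
    roundness <- max(g$sigma_x, g$sigma_y) / min(g$sigma_x, g$sigma_y)
    if (!is.null(roundness_range) &&
        (roundness < roundness_range[1L] || roundness > roundness_range[2L])) next
    out[[length(out) + 1L]] <- data.frame(
      x = g$x, y = g$y, amplitude = g$amplitude,
      sigma_x = g$sigma_x, sigma_y = g$sigma_y, baseline = g$baseline,
      roundness = roundness, mass = mass)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# Circular ROI pixel offsets for a given diameter (69 px for diameter 9).
.roi_offsets <- function(roi_diameter) {
  r <- roi_diameter / 2
  off <- expand.grid(dx = seq(-floor(r), floor(r)), dy = seq(-floor(r), floor(r)))
  off[off$dx^2 + off$dy^2 <= r^2, ]
}

#' Extract a background-corrected photon trace for one particle
#'
#' Per frame, `f = sum(ROI counts) - b * N_pixels`, where the ROI is the
#' discrete circular mask of the stated diameter (69 pixels at the default 9)
#' centered on the rounded centroid, and `b` is the particle's Gaussian-fit
#' baseline from the time-average image, reused for all frames. Photometry is
#' performed on the unsmoothed corrected frames.
#'
#' @param corrected A [correct_movie()] result.
#' @param particle One row of [locate_particles()] output (or a list with
#'   `x`, `y`, `baseline`).
#' @param roi_diameter ROI diameter in pixels (default 9).
#' @return An object of class `photon_trace`: list with `photons` (per-frame
#'   series), `particle`, `n_pixels`, and `edge_clipped` (TRUE means the ROI
#'   fell off the image; such traces carry no photometry and are excluded by
#'   [qc_traces()]).
#' @export
extract_trace <- function(corrected, particle, roi_diameter = 9) {
  stopifnot(inherits(corrected, "corrected_movie"))
  mov <- corrected$photometry
  d <- dim(mov$data)
  off <- .roi_offsets(roi_diameter)
  cx <- round(particle$x); cy <- round(particle$y)
  px <- cx + off$dx; py <- cy + off$dy
  if (any(px < 0 | px >= d[3L] | py < 0 | py >= d[2L])) {
    return(structure(list(photons = rep(NA_real_, d[1L]), particle = particle,
                          n_pixels = nrow(off), edge_clipped = TRUE),
                     class = "photon_trace"))
  }
  mat <- matrix(mov$data, d[1L], d[2L] * d[3L])
  lin <- (px) * d[2L] + py + 1L   # column-major: row y+1, col x+1
  f <- rowSums(mat[, lin, drop = FALSE]) - particle$baseline * nrow(off)
  structure(list(photons = f, particle = particle,
                 n_pixels = nrow(off), edge_clipped = FALSE),
            class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf("photon_trace: %d frames, mean %.1f photons%s\n",
              length(x$photons), mean(x$photons),
              if (x$edge_clipped) " [edge-clipped, excluded]" else ""))
  invisible(x)
}

#' Extract traces for all located particles
#'
#' @inheritParams extract_trace
#' @param particles [locate_particles()] output.
#' @return List of [photon_trace] objects.
#' @export
extract_traces <- function(corrected, particles, roi_diameter = 9) {
  lapply(seq_len(nrow(particles)),
         function(i) extract_trace(corrected, particles[i, ], roi_diameter))
}

#' Quality-control photon traces
#'
#' Discards edge-clipped traces and traces whose photon count exceeds the
#' aggregate threshold in any frame (500 photons by default: such particles
#' are higher-order aggregates, not assembly intermediates). Optionally
#' applies temporal Gaussian smoothing (sigma = 5 frames is the low-SNR
#' variant) to the surviving traces.
#'
#' @param traces List of [photon_trace] objects (or numeric vectors).
#' @param aggregate_threshold Photons; traces with any frame strictly above
#'   this are discarded (default 500).
#' @param smoothing_sigma Optional temporal smoothing width in frames
#'   (`NULL` = off).
#' @return Filtered (possibly smoothed) list of traces, with attributes
#'   `n_discarded_aggregate` and `n_discarded_clipped`.
#' @export
qc_traces <- function(traces, aggregate_threshold = 500, smoothing_sigma = NULL) {
  get_photons <- function(tr) if (inherits(tr, "photon_trace")) tr$photons else tr
  clipped <- vapply(traces, function(tr)
    inherits(tr, "photon_trace") && isTRUE(tr$edge_clipped), logical(1L))
  aggregate <- vapply(traces, function(tr) {
    p <- get_photons(tr)
    !all(is.na(p)) && max(p, na.rm = TRUE) > aggregate_threshold
  }, logical(1L))
  keep <- !clipped & !aggregate
  out <- traces[keep]
  if (!is.null(smoothing_sigma) && smoothing_sigma > 0) {
    out <- lapply(out, function(tr) {
      if (inherits(tr, "photon_trace")) {
        tr$photons <- .gaussian_smooth_vec(tr$photons, smoothing_sigma)
        tr
      } else .gaussian_smooth_vec(tr, smoothing_sigma)
    })
  }
  attr(out, "n_discarded_aggregate") <- sum(aggregate & !clipped)
  attr(out, "n_discarded_clipped") <- sum(clipped)
  out
}

#' Bleaching and blinking QC for monomeric control traces
#'
#' Bleaching: the trace is cut into blocks (400 frames by default); a block
#' whose mean photon count is at or below `bleach_mean` (30 photons) is
#' flagged bleached. Blinking: within the analysis window (frames 100..1000,
#' chosen to avoid bleaching bias), a frame whose deviation from the trace
#' mean is at least `blink_k` trace standard deviations is flagged. Both the
#' sign-free count (deviation of either sign, the literal reading) and the
#' dark-state count (negative deviations only, the photophysical reading) are
#' reported.
#'
#' @param traces List of [photon_trace] objects or numeric vectors.
#' @param block_size Frames per bleaching block (default 400).
#' @param bleach_mean Photon threshold for a bleached block (default 30).
#' @param blink_window Frame range (1-based, inclusive) for blink analysis
#'   (default `c(100, 1000)`).
#' @param blink_k SD multiplier (default 3).
#' @return data.frame with one row per trace: `n_blocks`,
#'   `first_bleached_block` (NA if never), `bleached`, `n_blink_frames_abs`,
#'   `n_blink_frames_dark`, `short_trace` (shorter than one block). The
#'   per-trace flagged frame indices are attached as attribute
#'   `blink_frames`.
#' @export
bleach_blink_qc <- function(traces, block_size = 400L, bleach_mean = 30,
                            blink_window = c(100L, 1000L), blink_k = 3) {
  get_photons <- function(tr) if (inherits(tr, "photon_trace")) tr$photons else tr
  blink_list <- vector("list", length(traces))
  rows <- lapply(seq_along(traces), function(i) {
    p <- get_photons(traces[[i]])
    n <- length(p)
    short <- n < block_size
    nb <- max(1L, as.integer(ceiling(n / block_size)))
    block_means <- vapply(seq_len(nb), function(b) {
      j <- ((b - 1L) * block_size + 1L):min(b * block_size, n)
      mean(p[j])
    }, numeric(1L))
    bleached_blocks <- which(block_means <= bleach_mean)
    w <- seq(max(1L, blink_window[1L]), min(n, blink_window[2L]))
    m <- mean(p); s <- sd(p)
    dev <- p[w] - m
    abs_idx <- w[s > 0 & abs(dev) >= blink_k * s]
    dark_idx <- w[s > 0 & -dev >= blink_k * s]
    blink_list[[i]] <<- dark_idx
    data.frame(trace = i, n_blocks = nb,
               first_bleached_block = if (length(bleached_blocks)) bleached_blocks[1L] else NA_integer_,
               bleached = length(bleached_blocks) > 0L,
               n_blink_frames_abs = length(abs_idx),
               n_blink_frames_dark = length(dark_idx),
               short_trace = short)
  })
  out <- do.call(rbind, rows)
  attr(out, "blink_frames") <- blink_list
  out
}

#' Write particle localizations as CSV
#' @param particles [locate_particles()] output.
#' @param path File path.
#' @return `path` invisibly.
#' @export
write_localizations_csv <- function(particles, path) {
  utils::write.csv(particles, path, row.names = FALSE)
  invisible(path)
}

#' Write photon traces as a long-format CSV keyed by particle id
#' @param traces List of [photon_trace] objects.
#' @param path File path.
#' @return `path` invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  get_photons <- function(tr) if (inherits(tr, "photon_trace")) tr$photons else tr
  rows <- lapply(seq_along(traces), function(i) {
    p <- get_photons(traces[[i]])
    data.frame(particle = i, frame = seq_along(p), photons = p)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
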