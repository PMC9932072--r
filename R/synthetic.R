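# Synthetic-data module: ground-truth surface assembly paths, photon traces
# and camera-realistic TIRF movies. Everything downstream is validated by
# parameter recovery against these generators.

#' Surface kinetic model for a single immobilized particle
#'
#' Continuous-time Markov model of one surface-bound insulin particle cycling
#' through oligomeric states S1 (monomer) to S6 (hexamer). Assembly channels
#' i -> j (j > i) fire with propensity `assoc[i, j] * solution_conc[j - i]`
#' (bimolecular constant times the molar concentration of the free species
#' being added); disassembly channels i -> j (j < i) fire with the
#' unimolecular constant `dissoc[i, j]`. Free-solution concentrations are held
#' constant (open system): the surface particle does not deplete the solution.
#'
#' Rates can be supplied as full `n_states x n_states` matrices or as named
#' vectors like `c("1->2" = 1e7)`.
#'
#' @param assoc Association rate constants, 1/(M s). Matrix or named vector.
#' @param dissoc Dissociation rate constants, 1/s. Matrix or named vector.
#' @param solution_conc Molar concentrations of the free species sizes 1..5
#'   (monomer .. pentamer). A named or positional numeric vector; sizes not
#'   supplied default to 0.
#' @param n_states Number of surface states (default 6, monomer..hexamer).
#' @param allowed_steps Permitted assembly step sizes (default monomer, dimer
#'   and tetramer addition: `c(1, 2, 4)`). Concerted double-dimer addition is
#'   deliberately not generated.
#' @return An object of class `surface_kinetic_model`.
#' @export
surface_kinetic_model <- function(assoc = NULL, dissoc = NULL,
                                  solution_conc = numeric(),
                                  n_states = 6L, allowed_steps = c(1L, 2L, 4L)) {
  n <- as.integer(n_states)
  stopifnot(n >= 2L)
  A <- .rates_to_matrix(assoc, n, "assoc")
  D <- .rates_to_matrix(dissoc, n, "dissoc")
  if (any(A < 0) || any(D < 0)) stop("rate constants must be >= 0")
  conc <- rep(0, n - 1L)
  if (length(solution_conc)) {
    if (!is.null(names(solution_conc))) {
      idx <- as.integer(names(solution_conc))
    } else {
      idx <- seq_along(solution_conc)
    }
    stopifnot(all(idx >= 1L), all(idx <= n - 1L))
    conc[idx] <- as.numeric(solution_conc)
  }
  if (any(conc < 0)) stop("solution concentrations must be >= 0")
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (A[i, j] > 0) {
      if (j <= i) stop("assoc rates require j > i")
      if (!( (j - i) %in% allowed_steps))
        stop(sprintf("assembly step %d->%d not in allowed_steps", i, j))
    }
    if (D[i, j] > 0 && j >= i) stop("dissoc rates require j < i")
  }
  structure(list(n_states = n, assoc = A, dissoc = D, solution_conc = conc,
                 allowed_steps = as.integer(allowed_steps)),
            class = "surface_kinetic_model")
}

.rates_to_matrix <- function(x, n, what) {
  if (is.null(x)) return(matrix(0, n, n))
  if (is.matrix(x)) {
    stopifnot(nrow(x) == n, ncol(x) == n)
    return(unname(x))
  }
  m <- matrix(0, n, n)
  if (!length(x)) return(m)
  if (is.null(names(x))) stop(what, " rates must be a matrix or a named vector like c('1->2' = k)")
  for (nm in names(x)) {
    ij <- as.integer(strsplit(nm, "->", fixed = TRUE)[[1L]])
    if (length(ij) != 2L || anyNA(ij)) stop("bad rate name: ", nm)
    m[ij[1L], ij[2L]] <- as.numeric(x[[nm]])
  }
  m
}

# Exit channels (target states and propensities) from state i.
.exit_channels <- function(model, i) {
  n <- model$n_states
  to <- integer(0); a <- numeric(0)
  up <- which(model$assoc[i, ] > 0)
  if (length(up)) {
    to <- c(to, up)
    a <- c(a, model$assoc[i, up] * model$solution_conc[up - i])
  }
  down <- which(model$dissoc[i, ] > 0)
  if (length(down)) {
    to <- c(to, down)
    a <- c(a, model$dissoc[i, down])
  }
  keep <- a > 0
  list(to = to[keep], a = a[keep])
}

#' Simulate a ground-truth state path (exact stochastic simulation)
#'
#' Gillespie simulation of the surface particle's oligomeric state: from state
#' i each exit channel fires after an exponential waiting time with its
#' propensity; the realized channel is chosen proportionally. A state with no
#' positive exit propensity is absorbing and the path simply remains there
#' until `duration`.
#'
#' @param model A [surface_kinetic_model()].
#' @param initial_state Starting state in 1..n_states.
#' @param duration Total simulated time, seconds (> 0).
#' @param seed Integer seed for reproducibility (or `NULL`).
#' @return An object of class `ground_truth_path`: list with `jump_times`
#'   (strictly increasing, seconds), `states` (length `length(jump_times)+1`,
#'   consecutive entries differ), `duration`, `seed`.
#' @export
simulate_state_path <- function(model, initial_state, duration, seed = NULL) {
  stopifnot(inherits(model, "surface_kinetic_model"),
            initial_state >= 1L, initial_state <= model$n_states,
            duration > 0)
  with_seed(seed, {
    cap <- 256L
    jt <- numeric(cap); st <- integer(cap + 1L)
    st[1L] <- as.integer(initial_state)
    nj <- 0L
    t_now <- 0
    s <- as.integer(initial_state)
    channels <- lapply(seq_len(model$n_states), function(i) .exit_channels(model, i))
    repeat {
      ch <- channels[[s]]
      a0 <- sum(ch$a)
      if (a0 <= 0) break
      t_now <- t_now + rexp(1L, a0)
      if (t_now >= duration) break
      s <- if (length(ch$to) == 1L) ch$to else
        ch$to[sample.int(length(ch$to), 1L, prob = ch$a)]
      nj <- nj + 1L
      if (nj > cap) {
        cap <- cap * 2L
        jt <- c(jt, numeric(cap - length(jt)))
        st <- c(st, integer(cap + 1L - length(st)))
      }
      jt[nj] <- t_now
      st[nj + 1L] <- s
    }
    structure(list(jump_times = jt[seq_len(nj)],
                   states = st[seq_len(nj + 1L)],
                   duration = duration,
                   seed = seed),
              class = "ground_truth_path")
  })
}

#' @export
print.ground_truth_path <- function(x, ...) {
  cat(sprintf("ground_truth_path: %d jumps over %.3g s, states %s...\n",
              length(x$jump_times), x$duration,
              paste(utils::head(x$states, 8L), collapse = "-")))
  invisible(x)
}

# Time-weighted mean state size over windows [a, b] (vectorized over windows).
.path_window_mean <- function(path, a, b) {
  brk <- c(0, path$jump_times, path$duration)
  st <- path$states
  ia <- findInterval(a, brk, rightmost.closed = FALSE)
  ib <- findInterval(pmin(b, path$duration), brk, rightmost.closed = TRUE)
  ia <- pmin(pmax(ia, 1L), length(st))
  ib <- pmin(pmax(ib, 1L), length(st))
  out <- numeric(length(a))
  same <- ia == ib
  out[same] <- st[ia[same]]
  for (f in which(!same)) {
    segs <- ia[f]:ib[f]
    lo <- pmax(brk[segs], a[f])
    hi <- pmin(brk[segs + 1L], b[f])
    wt <- pmax(hi - lo, 0)
    out[f] <- sum(st[segs] * wt) / sum(wt)
  }
  out
}

#' Movie / trace rendering configuration
#'
#' Acquisition and emission parameters shared by the trace and movie
#' renderers. Defaults follow the acquisition used throughout: 50 ms exposure
#' followed by 100 ms dead time (0.15 s/frame), 46 photons per labeled
#' monomer with per-fluorophore width 16 photons.
#'
#' @param frames,height,width Movie geometry (frames x H x W pixels).
#' @param frame_interval Seconds per frame (default 0.15).
#' @param exposure Exposure window per frame, seconds (default 0.05). Must not
#'   exceed `frame_interval`; only the exposure window is observed.
#' @param psf_sigma Gaussian PSF width in pixels (default 1.5).
#' @param photons_per_monomer_mean Mean photons emitted per labeled monomer
#'   per exposure (default 46).
#' @param photons_per_monomer_sd Per-fluorophore emission width in photons
#'   (default 16).
#' @param noise_scaling `"sqrt"` (default): trace noise SD scales with the
#'   square root of the state size (independent fluorophores add in
#'   variance); `"constant"`: fixed SD regardless of state.
#' @param illumination List with `sigma` (pixels; `Inf` = flat field) and
#'   optional `center` (`c(x, y)`, 0-based; default image center). The 2-D
#'   Gaussian profile has peak 1.
#' @param camera List with EMCCD parameters `s0` (count offset) and `gamma`
#'   (inverse gain, photons per count).
#' @param dark_photons Illumination-scaled background fluorescence photons per
#'   pixel per exposure (default 2).
#' @param bleach_rate Per-particle photobleach rate, 1/s (0 = off).
#' @param blink_off_rate,blink_on_rate Telegraph blinking rates, 1/s:
#'   on->off and off->on (0 = off).
#' @return An object of class `movie_config`.
#' @export
movie_config <- function(frames = 400L, height = 64L, width = 64L,
                         frame_interval = 0.15, exposure = 0.05,
                         psf_sigma = 1.5,
                         photons_per_monomer_mean = 46,
                         photons_per_monomer_sd = 16,
                         noise_scaling = c("sqrt", "constant"),
                         illumination = list(sigma = Inf, center = NULL),
                         camera = list(s0 = 100, gamma = 0.02),
                         dark_photons = 2,
                         bleach_rate = 0, blink_off_rate = 0, blink_on_rate = 0) {
  noise_scaling <- match.arg(noise_scaling)
  stopifnot(frame_interval >= exposure, exposure > 0, psf_sigma > 0,
            photons_per_monomer_mean > 0, photons_per_monomer_sd >= 0,
            camera$gamma > 0, camera$s0 >= 0, dark_photons >= 0)
  structure(list(shape = c(frames = as.integer(frames), height = as.integer(height),
                           width = as.integer(width)),
                 frame_interval = frame_interval, exposure = exposure,
                 psf_sigma = psf_sigma,
                 photons_per_monomer_mean = photons_per_monomer_mean,
                 photons_per_monomer_sd = photons_per_monomer_sd,
                 noise_scaling = noise_scaling,
                 illumination = illumination, camera = camera,
                 dark_photons = dark_photons,
                 bleach_rate = bleach_rate,
                 blink_off_rate = blink_off_rate,
                 blink_on_rate = blink_on_rate),
            class = "movie_config")
}

# Fraction of each frame's exposure window spent emitting, given optional
# per-particle bleaching (single exponential time) and telegraph blinking.
.emission_modulation <- function(cfg, n_frames) {
  if (cfg$bleach_rate <= 0 && cfg$blink_off_rate <= 0) return(rep(1, n_frames))
  t_total <- n_frames * cfg$frame_interval
  bleach_t <- if (cfg$bleach_rate > 0) rexp(1L, cfg$bleach_rate) else Inf
  # telegraph: alternating on/off sojourns starting "on"
  jumps <- numeric(0)
  if (cfg$blink_off_rate > 0 && cfg$blink_on_rate > 0) {
    t <- 0; on <- TRUE
    while (t < t_total) {
      t <- t + rexp(1L, if (on) cfg$blink_off_rate else cfg$blink_on_rate)
      if (t < t_total) jumps <- c(jumps, t)
      on <- !on
    }
  }
  tele <- list(jump_times = jumps,
               states = rep_len(c(1L, 0L), length(jumps) + 1L),
               duration = t_total)
  class(tele) <- "ground_truth_path"
  a <- (seq_len(n_frames) - 1L) * cfg$frame_interval
  b <- a + cfg$exposure
  frac_on <- .path_window_mean(tele, a, b)
  # bleach truncates the emitting part of each window
  lit <- pmax(pmin(bleach_t, b) - a, 0) / cfg$exposure
  frac_on * pmin(lit, 1)
}

#' Render a photon time series from a ground-truth path
#'
#' Frame f reports the particle's state size averaged over the exposure window
#' only (the dead time between exposures is unobserved), scaled by
#' `photons_per_monomer_mean`, plus Gaussian emission noise whose SD is
#' `photons_per_monomer_sd * sqrt(size)` by default (or constant, see
#' [movie_config()]). Optional per-particle bleaching/blinking modulates the
#' emission.
#'
#' @param path A [simulate_state_path()] result.
#' @param cfg A [movie_config()].
#' @param seed Integer seed for the emission noise, or `NULL`.
#' @param n_frames Number of frames (default `cfg$shape["frames"]`). Requires
#'   `path$duration >= n_frames * cfg$frame_interval`.
#' @return Numeric vector of per-frame photon counts.
#' @export
render_photon_trace <- function(path, cfg, seed = NULL, n_frames = NULL) {
  stopifnot(inherits(path, "ground_truth_path"), inherits(cfg, "movie_config"))
  n_frames <- if (is.null(n_frames)) cfg$shape[["frames"]] else as.integer(n_frames)
  if (path$duration < n_frames * cfg$frame_interval)
    stop("path shorter than requested movie duration")
  a <- (seq_len(n_frames) - 1L) * cfg$frame_interval
  b <- a + cfg$exposure
  size <- .path_window_mean(path, a, b)
  with_seed(seed, {
    mod <- .emission_modulation(cfg, n_frames)
    mu <- size * cfg$photons_per_monomer_mean * mod
    sdv <- if (cfg$photons_per_monomer_sd == 0) rep(0, n_frames)
           else if (cfg$noise_scaling == "sqrt")
             cfg$photons_per_monomer_sd * sqrt(pmax(size * mod, 0))
           else rep(cfg$photons_per_monomer_sd, n_frames)
    mu + rnorm(n_frames, 0, sdv)
  })
}

# H x W illumination profile (peak 1) for a config.
.illumination_matrix <- function(cfg) {
  h <- cfg$shape[["height"]]; w <- cfg$shape[["width"]]
  sig <- cfg$illumination$sigma
  if (is.null(sig) || !is.finite(sig)) return(matrix(1, h, w))
  ctr <- cfg$illumination$center
  if (is.null(ctr)) ctr <- c((w - 1) / 2, (h - 1) / 2)
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), w), h, w)
  exp(-((x - ctr[1L])^2 + (y - ctr[2L])^2) / (2 * sig^2))
}

# Pixel-integrated Gaussian PSF weights for a spot at (x, y) (0-based pixel
# centers at integers). Returns list(rows, cols, w) restricted to +-5 sigma.
.psf_weights <- function(x, y, sigma, h, w) {
  r <- ceiling(5 * sigma)
  cols <- max(0L, floor(x) - r):min(w - 1L, ceiling(x) + r)
  rows <- max(0L, floor(y) - r):min(h - 1L, ceiling(y) + r)
  wx <- pnorm(cols + 0.5, x, sigma) - pnorm(cols - 0.5, x, sigma)
  wy <- pnorm(rows + 0.5, y, sigma) - pnorm(rows - 0.5, y, sigma)
  list(rows = rows + 1L, cols = cols + 1L, w = outer(wy, wx))
}

#' Render a camera-realistic TIRF movie
#'
#' Builds the expected-photon image per frame (pixel-integrated Gaussian PSF
#' per particle, times the illumination profile, plus illumination-scaled
#' background fluorescence) and samples EMCCD counts from the generative
#' Poisson-Erlang model: `s = s0 + Gamma(shape = Poisson(E), rate = gamma)`,
#' with a zero Poisson draw collapsing to exactly `s0`. Counts are rounded to
#' integers and clipped to the 16-bit range. Overlapping particles are allowed
#' and produce merged spots.
#'
#' @param particles List of particles, each a list with `x`, `y` (0-based
#'   pixel coordinates) and `path` (a [ground_truth_path] or `NULL` for an
#'   empty calibration movie). Use `list()` for a particle-free control stack.
#' @param cfg A [movie_config()].
#' @param seed Integer seed, or `NULL`.
#' @return A [tirf_movie()] in raw camera counts.
#' @export
render_movie <- function(particles, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "movie_config"))
  fr <- cfg$shape[["frames"]]; h <- cfg$shape[["height"]]; w <- cfg$shape[["width"]]
  illum <- .illumination_matrix(cfg)
  margin <- 2 * cfg$psf_sigma
  for (p in particles) {
    if (p$x < margin || p$x > w - 1 - margin || p$y < margin || p$y > h - 1 - margin)
      stop("particle too close to the frame edge (needs a PSF margin)")
  }
  with_seed(seed, {
    E <- array(rep(cfg$dark_photons * illum, fr), dim = c(h, w, fr))
    a <- (seq_len(fr) - 1L) * cfg$frame_interval
    b <- a + cfg$exposure
    for (p in particles) {
      if (is.null(p$path)) next
      size <- .path_window_mean(p$path, a, b)
      mod <- .emission_modulation(cfg, fr)
      photons <- size * cfg$photons_per_monomer_mean * mod
      pw <- .psf_weights(p$x, p$y, cfg$psf_sigma, h, w)
      gain <- illum[pw$rows, pw$cols, drop = FALSE] * pw$w
      for (f in seq_len(fr)) {
        if (photons[f] <= 0) next
        E[pw$rows, pw$cols, f] <- E[pw$rows, pw$cols, f] + photons[f] * gain
      }
    }
    n_phot <- rpois(length(E), as.vector(E))
    counts <- rep(cfg$camera$s0, length(E))
    pos <- n_phot > 0L
    if (any(pos)) counts[pos] <- counts[pos] + rgamma(sum(pos), shape = n_phot[pos],
                                                      rate = cfg$camera$gamma)
    counts <- pmin(pmax(round(counts), 0), 65535)
    data <- aperm(array(counts, dim = c(h, w, fr)), c(3L, 1L, 2L))
    tirf_movie(data, frame_interval = cfg$frame_interval, units = "counts")
  })
}

#' Write / read a movie configuration as JSON
#'
#' @param cfg A [movie_config()].
#' @param path File path.
#' @return `path` invisibly (write); a `movie_config` (read).
#' @export
write_movie_config_json <- function(cfg, path) {
  stopifnot(inherits(cfg, "movie_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_movie_config_json
#' @export
read_movie_config_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  illum <- x$illumination
  # JSON has no Inf: a flat field round-trips as the string "Inf"
  illum$sigma <- if (is.null(illum$sigma)) Inf else as.numeric(illum$sigma)
  if (!is.null(illum$center)) illum$center <- as.numeric(illum$center)
  # shape serializes as a plain [frames, height, width] array
  movie_config(frames = x$shape[[1L]], height = x$shape[[2L]],
               width = x$shape[[3L]],
               frame_interval = x$frame_interval, exposure = x$exposure,
               psf_sigma = x$psf_sigma,
               photons_per_monomer_mean = x$photons_per_monomer_mean,
               photons_per_monomer_sd = x$photons_per_monomer_sd,
               noise_scaling = x$noise_scaling,
               illumination = illum, camera = as.list(x$camera),
               dark_photons = x$dark_photons,
               bleach_rate = x$bleach_rate,
               blink_off_rate = x$blink_off_rate,
               blink_on_rate = x$blink_on_rate)
}

#' Write a ground-truth sidecar (path and particle positions) as JSON
#'
#' @param particles As in [render_movie()].
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(particles, path) {
  payload <- lapply(particles, function(p) {
    list(x = p$x, y = p$y,
         jump_times = if (is.null(p$path)) numeric(0) else p$path$jump_times,
         states = if (is.null(p$path)) integer(0) else p$path$states)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
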