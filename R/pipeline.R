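# End-to-end orchestration in the published stage order:
# calibrate -> correct -> locate -> trace -> QC -> HMM -> kinetics -> thermo -> ODE.
# Every intermediate artifact is written to disk and every report entry names
# the file it came from (provenance).

#' Pipeline configuration
#'
#' Collects the stage parameters, seeds and paths for [run_pipeline()]. When
#' `input_movie`/`control_movie` are `NULL` a synthetic demonstration data
#' set is generated (a calibration stack plus a movie of immobilized
#' particles switching states under `demo_model`).
#'
#' @param out_dir Output directory for intermediate artifacts and the report.
#' @param seed Master integer seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @param condition Condition label carried into the report (e.g. `"HI"`,
#'   `"HI+Zn"`, `"HI+phenol"`, `"HI+Zn+phenol"`).
#' @param total_monomer_equiv Total monomer-equivalent concentration, molar
#'   (default 10e-9).
#' @param input_movie,control_movie Paths to multi-page TIFFs, or `NULL` to
#'   generate synthetic inputs.
#' @param demo_model [surface_kinetic_model()] used for synthetic input
#'   generation (default: monomer exchange S1<->S2 at 10 nM).
#' @param demo_particles,demo_frames,demo_size Synthetic movie geometry.
#' @param scheme [solution_scheme()] for the extrapolation stage (default
#'   [example_scheme()]).
#' @param hmm [hmm_spec()] for idealization.
#' @param frame_interval Seconds per frame (default 0.15).
#' @param aggregate_threshold Photon QC threshold (default 500).
#' @param smoothing_sigma Optional low-SNR trace smoothing (default `NULL`).
#' @param sweep_concs Initial concentrations for the extrapolation sweep.
#' @param n_calib_pixels Pixels fitted during camera calibration (default 400).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, condition = "HI",
                            total_monomer_equiv = 10e-9,
                            input_movie = NULL, control_movie = NULL,
                            demo_model = NULL,
                            demo_particles = 12L, demo_frames = 600L,
                            demo_size = 64L,
                            scheme = example_scheme("HI"),
                            hmm = hmm_spec(),
                            frame_interval = 0.15,
                            aggregate_threshold = 500,
                            smoothing_sigma = NULL,
                            sweep_concs = 10^seq(-9, -3, length.out = 13L),
                            n_calib_pixels = 400L) {
  if (is.null(demo_model)) {
    demo_model <- surface_kinetic_model(
      assoc = c("1->2" = 1e7), dissoc = c("2->1" = 0.1),
      solution_conc = c("1" = total_monomer_equiv))
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 condition = condition,
                 total_monomer_equiv = total_monomer_equiv,
                 input_movie = input_movie, control_movie = control_movie,
                 demo_model = demo_model, demo_particles = demo_particles,
                 demo_frames = demo_frames, demo_size = demo_size,
                 scheme = scheme, hmm = hmm,
                 frame_interval = frame_interval,
                 aggregate_threshold = aggregate_threshold,
                 smoothing_sigma = smoothing_sigma,
                 sweep_concs = sweep_concs,
                 n_calib_pixels = as.integer(n_calib_pixels)),
            class = "pipeline_config")
}

.stage_fail <- function(stage, msg) {
  stop(sprintf("[stage: %s] %s", stage, msg), call. = FALSE)
}

# per-stage stderr log line with elapsed time
.stage_log <- function(stage, t0) {
  message(sprintf("[%s] done in %.1f s", stage,
                  as.numeric(Sys.time() - t0, units = "secs")))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in the published order, writes every intermediate
#' artifact under `config$out_dir`, and returns (and writes) a
#' machine-readable report of rate constants, occupancies and equilibrium
#' constants. Each report entry carries a `provenance` field naming the
#' artifact it was computed from. Reruns with the same config and seed are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return The report list, invisibly; also written to
#'   `file.path(out_dir, "report.json")`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  f <- function(...) file.path(config$out_dir, ...)
  report <- list(condition = config$condition, seed = seed)
  t0 <- Sys.time()

  # --- inputs -----------------------------------------------------------
  if (is.null(config$input_movie)) {
    cfg <- movie_config(frames = config$demo_frames,
                        height = config$demo_size, width = config$demo_size,
                        frame_interval = config$frame_interval,
                        illumination = list(sigma = 300, center = NULL))
    grid <- .demo_positions(config$demo_particles, config$demo_size)
    particles <- lapply(seq_len(config$demo_particles), function(i) {
      path <- simulate_state_path(config$demo_model, initial_state = 1L,
                                  duration = config$demo_frames * config$frame_interval + 1,
                                  seed = seed + 100L + i)
      list(x = grid$x[i], y = grid$y[i], path = path)
    })
    movie <- render_movie(particles, cfg, seed = seed + 1L)
    ctrl_cfg <- movie_config(frames = 1000L, height = 24L, width = 24L,
                             frame_interval = config$frame_interval,
                             dark_photons = cfg$dark_photons,
                             camera = cfg$camera)
    control <- render_movie(list(), ctrl_cfg, seed = seed + 2L)
    write_movie_tiff(movie, f("movie.tif"))
    write_movie_tiff(control, f("control.tif"))
    write_ground_truth_json(particles, f("ground_truth.json"))
  } else {
    if (is.null(config$control_movie))
      .stage_fail("calibrate", "no calibration stack configured (control_movie is NULL)")
    if (!file.exists(config$control_movie))
      .stage_fail("calibrate", paste("calibration stack not found:", config$control_movie))
    if (!file.exists(config$input_movie))
      .stage_fail("input", paste("input movie not found:", config$input_movie))
    movie <- read_movie_tiff(config$input_movie, config$frame_interval)
    control <- read_movie_tiff(config$control_movie, config$frame_interval)
  }

  .stage_log("inputs", t0); t0 <- Sys.time()

  # --- calibrate --------------------------------------------------------
  cam <- tryCatch(calibrate_camera(control, n_pixels = config$n_calib_pixels, seed = seed + 3L),
                  error = function(e) .stage_fail("calibrate", conditionMessage(e)))
  write_camera_json(cam, f("camera.json"))
  report$camera <- list(s0 = cam$s0, gamma = cam$gamma,
                        n_accepted = cam$n_pixels_accepted,
                        provenance = "camera.json")

  .stage_log("calibrate", t0); t0 <- Sys.time()

  # --- correct ----------------------------------------------------------
  phot <- to_photons(movie, cam)
  illum <- estimate_illumination(phot)
  corrected <- correct_movie(phot, illum)

  .stage_log("correct", t0); t0 <- Sys.time()

  # --- locate -----------------------------------------------------------
  parts <- locate_particles(corrected)
  if (!nrow(parts)) .stage_fail("locate", "no particles found")
  write_localizations_csv(parts, f("localizations.csv"))
  report$n_particles <- list(value = nrow(parts), provenance = "localizations.csv")

  .stage_log("locate", t0); t0 <- Sys.time()

  # --- trace + QC -------------------------------------------------------
  traces <- extract_traces(corrected, parts)
  traces <- qc_traces(traces, aggregate_threshold = config$aggregate_threshold,
                      smoothing_sigma = config$smoothing_sigma)
  if (!length(traces)) .stage_fail("qc", "no traces survived QC")
  write_traces_csv(traces, f("traces.csv"))
  report$n_traces <- list(value = length(traces), provenance = "traces.csv")

  .stage_log("trace+qc", t0); t0 <- Sys.time()

  # --- HMM --------------------------------------------------------------
  ideal <- lapply(traces, fit_hmm, spec = config$hmm)
  write_idealized_csv(ideal, f("idealized.csv"))
  rq <- residual_qc(ideal)
  report$residuals <- list(mu = rq$mu, sigma = rq$sigma,
                           provenance = "idealized.csv")
  occ <- state_occupancy(unlist(lapply(ideal, `[[`, "idealized")),
                         spec = config$hmm, seed = seed + 4L)
  report$occupancy <- list(weights = as.list(occ$weights),
                           sd = as.list(occ$boot_sd),
                           provenance = "idealized.csv")

  .stage_log("hmm", t0); t0 <- Sys.time()

  # --- kinetics ---------------------------------------------------------
  trans <- extract_transitions(ideal, frame_interval = config$frame_interval)
  if (!nrow(trans)) .stage_fail("kinetics", "no transitions observed")
  write_transitions_csv(trans, f("transitions.csv"))
  steps <- trans$photon_after[trans$to > trans$from] -
    trans$photon_before[trans$to > trans$from]
  calib <- structure(list(mu = 46, sigma = 16), class = "monomer_calibration")
  comp <- if (length(steps) >= 2L)
    suppressWarnings(estimate_solution_composition(steps, calib,
                                                   config$total_monomer_equiv))
  else NULL
  chess <- build_chess(trans, comp, seed = seed + 5L)
  write_chess_json(chess, f("chess.json"))
  rate_entries <- list()
  for (i in 1:6) for (j in 1:6) {
    if (!is.na(chess$rate[i, j])) {
      rate_entries[[sprintf("k%d%d", i, j)]] <-
        list(value = chess$rate[i, j], error = chess$error[i, j],
             n = chess$density[i, j], low_n = chess$low_n[i, j],
             units = if (j > i) "1/(M s)" else "1/s",
             provenance = "chess.json")
    }
  }
  report$rate_constants <- rate_entries

  .stage_log("kinetics", t0); t0 <- Sys.time()

  # --- thermodynamics ---------------------------------------------------
  eq <- list()
  for (i in 1:5) {
    j <- i + 1L
    if (!is.na(chess$rate[i, j]) && !is.na(chess$rate[j, i]) &&
        chess$rate[i, j] > 0 && chess$rate[j, i] > 0 &&
        !chess$unconvertible[i, j]) {
      K <- equilibrium_constant(chess$rate[i, j], chess$rate[j, i])
      eq[[sprintf("K%d%d", i, j)]] <- list(
        K_eq = K, dG_kJ_mol = free_energy(K) / 1000,
        provenance = "chess.json")
    }
  }
  report$equilibria <- eq

  .stage_log("thermo", t0); t0 <- Sys.time()

  # --- ODE extrapolation ------------------------------------------------
  ft <- endpoint_fractions(config$scheme, config$sweep_concs)
  write_fractions_csv(ft, f("fractions.csv"))
  hf <- hill_fit(ft, species = 6L)
  report$extrapolation <- list(
    hill_K = hf$K, hill_n_h = hf$n_h, hill_B_max = hf$B_max,
    mu_at_10nM = ft$mu[which.min(abs(ft$initial_monomer - 1e-8))],
    provenance = "fractions.csv")

  .stage_log("ode", t0)
  jsonlite::write_json(report, f("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}

# Evenly spread particle positions with an edge margin.
.demo_positions <- function(n, size) {
  margin <- 8
  per_row <- ceiling(sqrt(n))
  pitch <- (size - 2 * margin) / max(per_row - 1, 1)
  idx <- seq_len(n) - 1L
  list(x = margin + (idx %% per_row) * pitch,
       y = margin + (idx %/% per_row) * pitch)
}
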