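# Illumination correction, localization, ROI photometry and trace QC.

make_flat_movie <- function(value, frames = 10, h = 32, w = 32) {
  tirf_movie(array(value, dim = c(frames, h, w)), units = "photons")
}

test_that("illumination profile of a flat movie is the flat value", {
  prof <- estimate_illumination(make_flat_movie(7))
  expect_equal(max(abs(prof - 7)), 0, tolerance = 1e-10)
})

test_that("illumination estimate tracks a synthetic Gaussian profile", {
  cfg <- movie_config(frames = 30, height = 320, width = 320, dark_photons = 10,
                      illumination = list(sigma = 100, center = NULL))
  mv <- render_movie(list(), cfg, seed = 51)
  phot <- to_photons(mv, true_camera())
  prof <- estimate_illumination(phot)
  truth <- hexakin:::.illumination_matrix(cfg)
  expect_gt(cor(as.vector(unclass(prof)), as.vector(truth)), 0.99)
  # smoothing removes pixel-scale structure
  expect_lte(var(as.vector(unclass(prof))), var(as.vector(time_average(phot))))
})

test_that("a non-positive profile is an error", {
  mv <- make_flat_movie(0)
  expect_error(estimate_illumination(mv), "positive")
})

test_that("correction by a flat profile is the identity", {
  mv <- make_flat_movie(5)
  prof <- estimate_illumination(mv)
  corr <- correct_movie(mv, prof, temporal_sigma = 0)
  expect_equal(corr$photometry$data, mv$data)
})

test_that("a movie equal to its profile corrects to a spatially flat movie", {
  cfg <- movie_config(frames = 1, height = 48, width = 48,
                      illumination = list(sigma = 30, center = NULL))
  prof_true <- hexakin:::.illumination_matrix(cfg) * 20
  mv <- tirf_movie(array(rep(prof_true, 5), dim = c(48, 48, 5)) |>
                     aperm(c(3, 1, 2)), units = "photons")
  corr <- correct_movie(mv, structure(prof_true, class = c("illumination_profile", "matrix")),
                        temporal_sigma = 0)
  # max-normalized division leaves a constant (= profile peak) everywhere
  expect_lt(diff(range(corr$photometry$data)), 1e-9)
  expect_equal(max(corr$photometry$data), max(prof_true), tolerance = 1e-9)
})

test_that("corner and center particles photometer equally after correction", {
  # field large relative to the 30 px smoothing scale; bright spots beat
  # shot noise, and a substantial fluorescent background keeps the spots'
  # own smoothed contribution out of the profile estimate
  cfg <- movie_config(frames = 500, height = 96, width = 96, psf_sigma = 1.5,
                      dark_photons = 200, photons_per_monomer_mean = 2000,
                      illumination = list(sigma = 300, center = NULL))
  parts <- list(list(x = 47.5, y = 47.5, path = const_path(1L, 500 * 0.15 + 1)),
                list(x = 16, y = 16, path = const_path(1L, 500 * 0.15 + 1)))
  mv <- render_movie(parts, cfg, seed = 52)
  phot <- to_photons(mv, true_camera())
  corr <- correct_movie(phot, estimate_illumination(phot))
  loc <- locate_particles(corr)
  expect_identical(nrow(loc), 2L)
  tr <- extract_traces(corr, loc, roi_diameter = 9)
  means <- vapply(tr, function(t) mean(t$photons), numeric(1L))
  expect_lt(abs(diff(means)) / mean(means), 0.02)
})

test_that("localization refines a bright spot to sub-0.1 px accuracy", {
  cfg <- movie_config(frames = 60, height = 40, width = 40, psf_sigma = 1.5,
                      photons_per_monomer_mean = 2000, dark_photons = 2)
  mv <- render_movie(list(list(x = 20.3, y = 14.7, path = const_path(1L, 10))),
                     cfg, seed = 53)
  phot <- to_photons(mv, true_camera())
  corr <- correct_movie(phot, estimate_illumination(phot))
  loc <- locate_particles(corr)
  expect_identical(nrow(loc), 1L)
  expect_lt(abs(loc$x - 20.3), 0.1)
  expect_lt(abs(loc$y - 14.7), 0.1)
})

test_that("spots closer than the separation merge into one detection", {
  cfg <- movie_config(frames = 40, height = 40, width = 40, psf_sigma = 1.5,
                      photons_per_monomer_mean = 500, dark_photons = 2)
  parts <- list(list(x = 18, y = 20, path = const_path(1L, 10)),
                list(x = 22, y = 20, path = const_path(1L, 10)))
  mv <- render_movie(parts, cfg, seed = 54)
  phot <- to_photons(mv, true_camera())
  corr <- correct_movie(phot, estimate_illumination(phot))
  loc <- locate_particles(corr, roundness_range = NULL)
  expect_identical(nrow(loc), 1L)
})

test_that("spots below the integrated-mass threshold are dropped", {
  cfg <- movie_config(frames = 40, height = 40, width = 40, psf_sigma = 1.5,
                      photons_per_monomer_mean = 2, dark_photons = 10)
  mv <- render_movie(list(list(x = 20, y = 20, path = const_path(1L, 10))),
                     cfg, seed = 55)
  phot <- to_photons(mv, true_camera())
  corr <- correct_movie(phot, estimate_illumination(phot))
  expect_identical(nrow(locate_particles(corr)), 0L)
})

test_that("localization bias is small and precision improves with brightness", {
  locate_one <- function(amp, seed) {
    cfg <- movie_config(frames = 30, height = 36, width = 36, psf_sigma = 1.5,
                        photons_per_monomer_mean = amp, dark_photons = 2)
    mv <- render_movie(list(list(x = 17.6, y = 18.4, path = const_path(1L, 10))),
                       cfg, seed = seed)
    phot <- to_photons(mv, true_camera())
    corr <- correct_movie(phot, estimate_illumination(phot))
    loc <- locate_particles(corr)
    if (nrow(loc) != 1L) return(c(NA_real_, NA_real_))
    c(loc$x - 17.6, loc$y - 18.4)
  }
  bright <- t(vapply(1:6, function(i) locate_one(3000, 500 + i), numeric(2L)))
  dim_ <- t(vapply(1:6, function(i) locate_one(120, 600 + i), numeric(2L)))
  expect_lt(max(abs(colMeans(bright))), 0.05)                # bias, high SNR
  expect_lt(mean(abs(bright)), mean(abs(dim_), na.rm = TRUE)) # CRLB trend
})

test_that("the circular ROI of diameter 9 holds 69 pixels", {
  expect_identical(nrow(hexakin:::.roi_offsets(9)), 69L)
})

test_that("ROI photometry matches the Gaussian mass-in-disk oracle", {
  # noiseless spot: 1000 photons, PSF sigma 1.5 px; disk of radius 4.5 px
  # captures 1 - exp(-r^2 / (2 sigma^2)) ~ 0.9889 of the mass
  h <- 41; w <- 41
  pw <- hexakin:::.psf_weights(20, 20, 1.5, h, w)
  img <- matrix(0, h, w)
  img[pw$rows, pw$cols] <- 1000 * pw$w
  mv <- tirf_movie(array(rep(img, 2), dim = c(h, w, 2)) |> aperm(c(3, 1, 2)),
                   units = "photons")
  corr <- correct_movie(mv, structure(matrix(1, h, w), class = c("illumination_profile", "matrix")),
                        temporal_sigma = 0)
  tr <- extract_trace(corr, list(x = 20, y = 20, baseline = 0))
  oracle <- 1000 * (1 - exp(-4.5^2 / (2 * 1.5^2)))
  expect_lt(abs(tr$photons[1L] - oracle) / 1000, 0.015)
  # linearity: doubling the spot doubles f (baseline fixed)
  mv2 <- tirf_movie(2 * mv$data, units = "photons")
  corr2 <- correct_movie(mv2, structure(matrix(1, h, w), class = c("illumination_profile", "matrix")),
                         temporal_sigma = 0)
  tr2 <- extract_trace(corr2, list(x = 20, y = 20, baseline = 0))
  expect_equal(tr2$photons[1L], 2 * tr$photons[1L], tolerance = 1e-12)
})

test_that("background-only photometry with the fitted baseline averages to zero", {
  cfg <- movie_config(frames = 300, height = 30, width = 30, dark_photons = 4)
  mv <- render_movie(list(), cfg, seed = 56)
  phot <- to_photons(mv, true_camera())
  corr <- correct_movie(phot, estimate_illumination(phot))
  tr <- extract_trace(corr, list(x = 15, y = 15, baseline = 4))
  se <- sd(tr$photons) / sqrt(length(tr$photons))
  expect_lt(abs(mean(tr$photons)), 3 * se)
})

test_that("an ROI clipped by the image edge is flagged and excluded", {
  mv <- make_flat_movie(1, frames = 5, h = 20, w = 20)
  corr <- correct_movie(mv, estimate_illumination(mv), temporal_sigma = 0)
  tr <- extract_trace(corr, list(x = 2, y = 10, baseline = 0))
  expect_true(tr$edge_clipped)
  kept <- qc_traces(list(tr))
  expect_length(kept, 0L)
  expect_identical(attr(kept, "n_discarded_clipped"), 1L)
})

test_that("the 500-photon aggregate threshold is a strict boundary", {
  peak520 <- c(rep(100, 50), 520, rep(100, 49))
  peak499 <- c(rep(100, 50), 499, rep(100, 49))
  peak500 <- c(rep(100, 50), 500, rep(100, 49))
  kept <- qc_traces(list(peak520, peak499, peak500))
  expect_length(kept, 2L)
  expect_identical(attr(kept, "n_discarded_aggregate"), 1L)
})

test_that("the stated filters keep 7 of 10 traces with 3 planted aggregates", {
  traces <- c(
    lapply(1:7, function(i) with_seed(i, rnorm(200, 46 * (i %% 3 + 1), 14))),
    lapply(8:10, function(i) with_seed(i, rnorm(200, 700, 30))))
  kept <- qc_traces(traces)
  expect_length(kept, 7L)
})

test_that("optional low-SNR smoothing reduces noise without changing the mean", {
  x <- with_seed(3, rnorm(500, 46, 16))
  sm <- qc_traces(list(x), smoothing_sigma = 5)[[1L]]
  expect_lt(sd(sm), sd(x) / 2)
  expect_equal(mean(sm), mean(x), tolerance = 0.02)
})

test_that("bleach QC flags blocks at or below the 30-photon mean", {
  qc <- bleach_blink_qc(list(rep(20, 800)))
  expect_true(qc$bleached)
  expect_identical(qc$first_bleached_block, 1L)
  qc2 <- bleach_blink_qc(list(with_seed(4, rnorm(1200, 46, 2))))
  expect_false(qc2$bleached)
  expect_identical(qc2$n_blink_frames_dark, 0L)
  # boundary: block mean exactly 30 counts as bleached
  qc3 <- bleach_blink_qc(list(rep(30, 400)))
  expect_true(qc3$bleached)
})

test_that("a planted dark excursion is flagged frame-exactly", {
  x <- with_seed(7, rnorm(1200, 46, 1))
  x[301:310] <- x[301:310] - 12
  qc <- bleach_blink_qc(list(x))
  expect_identical(attr(qc, "blink_frames")[[1L]], 301:310)
  expect_identical(qc$n_blink_frames_dark, 10L)
  expect_gte(qc$n_blink_frames_abs, 10L)
})

test_that("traces shorter than one block are reported with a flag", {
  qc <- bleach_blink_qc(list(rep(40, 150)))
  expect_true(qc$short_trace)
  expect_identical(qc$n_blocks, 1L)
})
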