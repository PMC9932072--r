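# Transition enumeration, dwell MLE, solution composition, CHESS assembly,
# thermodynamics and condition statistics.

test_that("transition enumeration matches brute-force expectation", {
  # S1 x10, S2 x20, S4 x5, S2 x7 frames
  it <- ideal_from_states(rep(c(1L, 2L, 4L, 2L), times = c(10, 20, 5, 7)))
  tr <- extract_transitions(it)
  expect_identical(nrow(tr), 3L)
  expect_identical(tr$from, c(1L, 2L, 4L))
  expect_identical(tr$to, c(2L, 4L, 2L))
  # first segment censored: S1 dwell density-only; S2 and S4 interior
  expect_identical(tr$interior, c(FALSE, TRUE, TRUE))
  expect_equal(tr$dwell, c(10, 20, 5) * 0.15)
  cl <- dwell_clusters(tr)
  expect_equal(cl[["2->4"]], 3.0)
  expect_equal(cl[["4->2"]], 0.75)
  expect_equal(tr$photon_before, c(50, 100, 200))
})

test_that("a constant trace yields no transitions", {
  expect_identical(nrow(extract_transitions(ideal_from_states(rep(3L, 50)))), 0L)
})

test_that("transitions touching the background state are excluded", {
  it <- ideal_from_states(rep(c(0L, 1L, 2L, 0L, 2L), times = c(10, 10, 10, 10, 10)))
  tr <- extract_transitions(it)
  expect_identical(nrow(tr), 1L)   # only 1 -> 2 survives
  expect_identical(tr$from, 1L)
  expect_identical(tr$to, 2L)
})

test_that("the dwell MLE is 1/mean with the 75 s exclusion rule", {
  f <- fit_dwell(c(1, 1, 1), seed = 1)
  expect_equal(f$rate, 1.0)
  expect_true(f$low_n)
  # exclusion: a 100 s dwell is dropped, leaving n = 1 -> undefined
  f2 <- fit_dwell(c(2, 100), seed = 1)
  expect_true(is.na(f2$rate))
  expect_identical(f2$n_excluded, 1L)
  # boundary: exactly 75 s is retained
  expect_identical(fit_dwell(c(1, 75), seed = 1)$n, 2L)
})

test_that("the dwell MLE is consistent against a large exponential sample", {
  d <- with_seed(70, rexp(1e4, 0.2))
  f <- fit_dwell(d, seed = 71)
  expect_false(f$low_n)
  expect_lt(abs(f$rate - 0.2), 3 * f$se)
  expect_lt(f$se, 0.01)
})

test_that("pure monomeric steps give a pure monomer composition", {
  steps <- with_seed(72, rnorm(500, 46, 10))
  comp <- estimate_solution_composition(steps, list(mu = 46, sigma = 16), 10e-9)
  expect_gt(comp$weights[["m1"]], 0.99)
  expect_equal(unname(comp$concentrations[["m1"]]), 10e-9, tolerance = 0.01)
})

test_that("composition concentrations conserve monomer equivalents", {
  # equal monomer/dimer steps: C_N = total / 1.5, c1 = c2 = total / 1.5
  steps <- with_seed(73, c(rnorm(400, 46, 5), rnorm(400, 92, 7)))
  comp <- estimate_solution_composition(steps, list(mu = 46, sigma = 16), 10e-9)
  expect_lt(abs(comp$weights[["m1"]] - 0.5), 0.05)
  expect_equal(sum(seq_len(5) * comp$concentrations), 10e-9, tolerance = 1e-12)
  expect_equal(unname(comp$concentrations[["m1"]]), 10e-9 / 1.5, tolerance = 0.1)
})

test_that("mixture weights of planted step sizes are recovered", {
  w_true <- c(0.8, 0.15, 0.03, 0.015, 0.005)
  n <- 5000
  comp <- with_seed(74, {
    m <- sample(1:5, n, replace = TRUE, prob = w_true)
    steps <- rnorm(n, 46 * m, 16 * sqrt(m))
    estimate_solution_composition(steps, list(mu = 46, sigma = 16), 10e-9)
  })
  # ~3x the binomial SE at n = 5000, inflated for component overlap
  expect_lt(max(abs(comp$weights - w_true)), 0.03)
})

test_that("CHESS converts assembly decay rates by the added-species concentration", {
  # hand-built transitions: 12 interior dwells of 100 s-scale decay 0.01/s
  dw <- rep(100, 12)   # mean 100 s > cutoff... use explicit dwells below 75
  it <- NULL
  tr <- data.frame(trace_id = 1L, video_id = 1L, from = 1L, to = 2L,
                   dwell = rep(c(60, 70, 50, 40, 30, 50), 2),
                   interior = TRUE, photon_before = 50, photon_after = 100)
  class(tr) <- c("transition_table", "data.frame")
  comp <- structure(list(weights = c(m1 = 1, m2 = 0, m3 = 0, m4 = 0, m5 = 0),
                         concentrations = c(m1 = 1e-9, m2 = 0, m3 = 0, m4 = 0, m5 = 0),
                         total_monomer_equiv = 1e-9, n_steps = 12L),
                    class = "solution_composition")
  chess <- build_chess(tr, comp, seed = 75)
  expect_equal(chess$rate[1, 2], (1 / 50) / 1e-9)
  expect_identical(unname(chess$density[1, 2]), 12)
  expect_false(chess$low_n[1, 2])
})

test_that("CHESS flags low-n clusters and unconvertible assemblies", {
  tr <- data.frame(trace_id = 1L, video_id = 1L,
                   from = c(rep(2L, 6), 3L), to = c(rep(4L, 6), 1L),
                   dwell = c(5, 6, 7, 8, 9, 10, 4),
                   interior = c(rep(TRUE, 6), TRUE),
                   photon_before = 0, photon_after = 0)
  class(tr) <- c("transition_table", "data.frame")
  chess <- build_chess(tr, composition = NULL, seed = 76)
  expect_true(chess$low_n[2, 4])          # n = 6 < 10: triangle semantics
  expect_true(chess$unconvertible[2, 4])  # no composition supplied
  expect_true(is.na(chess$rate[3, 1]))    # single dwell: density-only entry
  expect_identical(unname(chess$density[3, 1]), 1)
})

test_that("CHESS densities sum to the number of enumerated transitions", {
  ideal <- with_seed(77, lapply(1:5, function(i)
    ideal_from_states(sample(1:3, 200, replace = TRUE))))
  tr <- extract_transitions(ideal)
  chess <- build_chess(tr, n_boot = 50, seed = 78)
  expect_identical(sum(chess$density), as.numeric(nrow(tr)))
})

test_that("per-cluster fits report the total exit rate; corrected rates sum to it", {
  # S2 with two exit channels: 2->1 at 0.3/s and 2->3 at 0.2/s
  m <- surface_kinetic_model(assoc = c("1->2" = 1e8, "2->3" = 2e7),
                             dissoc = c("2->1" = 0.3, "3->2" = 1),
                             solution_conc = c("1" = 1e-8))
  p <- simulate_state_path(m, 2L, 4e4, seed = 79)
  states <- p$states
  segs <- rle(states)
  dwell <- diff(c(0, p$jump_times, p$duration))
  tr <- data.frame(trace_id = 1L, video_id = 1L,
                   from = segs$values[-length(segs$values)],
                   to = segs$values[-1L],
                   dwell = dwell[-length(dwell)],
                   interior = c(FALSE, rep(TRUE, length(segs$values) - 2L)),
                   photon_before = 0, photon_after = 0)
  class(tr) <- c("transition_table", "data.frame")
  cl <- dwell_clusters(tr)
  expect_gt(length(cl[["2->1"]]) + length(cl[["2->3"]]), 5000)
  chess <- build_chess(tr, n_boot = 50, seed = 80)
  # published convention: each per-cluster rate estimates the TOTAL exit rate
  expect_lt(abs(chess$rate[2, 1] - 0.5) / 0.5, 0.1)
  total_from_clusters <- chess$fits[["2->3"]]$rate
  expect_lt(abs(total_from_clusters - 0.5) / 0.5, 0.1)
  # competing-risks corrected channel rates sum to the total exit rate
  s <- sum(chess$rate_corrected[2, ], na.rm = TRUE)
  expect_lt(abs(s - 0.5) / 0.5, 0.1)
  # and split it by the observed channel shares (0.3 : 0.2)
  expect_lt(abs(chess$rate_corrected[2, 1] - 0.3) / 0.3, 0.15)
  expect_lt(abs(chess$rate_corrected[2, 3] - 0.2) / 0.2, 0.15)
})

test_that("per-video errors report the spread over acquisitions", {
  ideal <- with_seed(81, lapply(1:8, function(i) {
    st <- rep(rep(c(1L, 2L), 25), times = 1)
    lens <- pmax(1L, rpois(length(st), 20))
    ideal_from_states(rep(st, times = lens))
  }))
  tr <- extract_transitions(ideal, video_ids = rep(1:4, each = 2))
  chess <- build_chess(tr, n_boot = 50, seed = 82)
  expect_false(is.na(chess$error_video[1, 2]))
  expect_gt(chess$error_video[1, 2], 0)
})

test_that("equilibrium constants and free energies follow transition-state theory", {
  expect_equal(free_energy(1), 0)
  expect_error(free_energy(-2))
  expect_error(equilibrium_constant(0, 1))
  # K56 = 0.96e8 1/M at 298 K -> about -45.5 kJ/mol
  K <- equilibrium_constant(0.96e8, 1)
  expect_lt(abs(free_energy(K) / 1000 - (-45.54)), 0.1)
  # direct-evaluation oracle for the printed pentamer->hexamer constants
  K56 <- equilibrium_constant(1.3e7, 0.13)
  expect_equal(K56, 1e8)
})

test_that("activation energies vanish at the transition-state prefactor", {
  cc <- thermo_constants()
  expect_equal(activation_energy(cc$k_B * cc$T / cc$h), 0, tolerance = 1e-10)
  expect_lt(abs(activation_energy(1) / 1000 - 72.99), 0.1)
  expect_error(activation_energy(0))
})

test_that("Welch's t from summary statistics matches stats::t.test", {
  w <- compare_conditions(10, 2, 5, 10, 2, 5)
  expect_equal(w$t, 0)
  expect_equal(w$p_value, 1)
  expect_identical(w$stars, "")
  # textbook case vs a reference implementation on exact-moment samples
  make <- function(m, s, n) {
    v <- seq_len(n)
    m + s * (v - mean(v)) / sd(v)
  }
  x <- make(10, 2, 5); y <- make(12, 3, 5)
  ref <- t.test(x, y)
  w2 <- compare_conditions(10, 2, 5, 12, 3, 5)
  expect_lt(abs(w2$p_value - ref$p.value), 1e-6)
  expect_lt(abs(w2$t - unname(ref$statistic)), 1e-6)
  expect_lt(abs(w2$df - unname(ref$parameter)), 1e-6)
})

test_that("significance stars follow the published mapping", {
  expect_identical(hexakin:::.stars_from_p(0.03), "*")
  expect_identical(hexakin:::.stars_from_p(0.004), "**")
  expect_identical(hexakin:::.stars_from_p(2e-4), "***")
  expect_identical(hexakin:::.stars_from_p(0.2), "")
  expect_true(is.na(compare_conditions(1, 1, 1, 2, 1, 5)$p_value))
})

test_that("fold ratios reproduce the printed rate-constant arithmetic", {
  # dimer->tetramer vs dimer->trimer under both additives: 45-fold
  fr <- fold_ratio(4.0e8, 8.9e6, e_num = 0.4e8, e_den = 0.07e6, sig_figs = 2)
  expect_equal(fr$ratio, 45)
  expect_gt(fr$error, 0)
  # apparent-affinity shift on zinc addition: ~3-fold
  expect_equal(round(fold_ratio(2.6, 0.87)$raw), 3)
})

test_that("transition tables round trip through CSV", {
  it <- ideal_from_states(rep(c(1L, 2L), times = c(10, 10)))
  tr <- extract_transitions(it)
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_transitions_csv(tr, tmp)
  rt <- utils::read.csv(tmp)
  expect_identical(nrow(rt), 1L)
  expect_identical(rt$from, 1L)
})
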