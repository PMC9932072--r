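# Mass-action extrapolation: integration, endpoint fractions, Hill fits and
# the stochastic cross-check.

test_that("with all rates zero the concentrations are constant", {
  sc <- solution_scheme(k64 = 0)
  tc <- integrate_scheme(sc, 1e-6, t_end = 50, n_steps = 20)
  expect_true(all(tc$S1 == 1e-6))
  expect_true(all(as.matrix(tc[, paste0("S", 2:6)]) == 0))
})

test_that("negative rate constants are rejected", {
  expect_error(solution_scheme(k12 = -1))
})

test_that("dimerization-only equilibrium matches the quadratic closed form", {
  # K = k12/k21 = 1e6 1/M, C0 = 1e-6 M:
  # [S1] = (-1 + sqrt(1 + 8 K C0)) / (4 K) = 5.0e-7, [S2] = 2.5e-7
  sc <- solution_scheme(k12 = 1e6, k21 = 1, k64 = 0)
  tc <- integrate_scheme(sc, 1e-6)
  end <- tc[nrow(tc), ]
  expect_equal(end$S1, 5.0e-7, tolerance = 1e-6)
  expect_equal(end$S2, 2.5e-7, tolerance = 1e-6)
})

test_that("monomer equivalents are conserved at every step", {
  for (cond in c("HI", "zn_phenol")) {
    tc <- integrate_scheme(example_scheme(cond), 1e-5)
    mass <- monomer_equivalents(tc)
    expect_lt(max(abs(mass - 1e-5)) / 1e-5, 1e-9)
  }
})

test_that("equilibrium is effectively reached within the 300 s window", {
  for (cond in c("HI", "zn_phenol")) {
    sc <- example_scheme(cond)
    for (c0 in c(1e-8, 1e-6, 1e-3)) {
      tc <- integrate_scheme(sc, c0)
      y <- as.numeric(tc[nrow(tc), paste0("S", 1:6)])
      dy <- unlist(hexakin:::.oligomer_derivs(0, y, unclass(sc)))
      expect_lt(max(abs(dy)) / c0, 1e-6)
    }
  }
})

test_that("detailed balance holds for a cycle-free monomer ladder", {
  sc <- solution_scheme(k12 = 1e6, k21 = 2, k23 = 5e6, k32 = 0.5, k64 = 0)
  tc <- integrate_scheme(sc, 1e-6, t_end = 2000)
  end <- tc[nrow(tc), ]
  expect_equal(end$S2 / end$S1^2, 1e6 / 2, tolerance = 1e-5)
  expect_equal(end$S3 / (end$S2 * end$S1), 5e6 / 0.5, tolerance = 1e-5)
})

test_that("endpoint fractions are normalized and track the mean oligomeric state", {
  ft <- endpoint_fractions(example_scheme("HI"),
                           initial_concs = 10^seq(-9, -3, length.out = 9))
  f <- as.matrix(ft[, paste0("f", 1:6)])
  expect_true(all(abs(rowSums(f) - 1) < 1e-9))
  expect_equal(ft$mu, as.numeric(f %*% (1:6)), tolerance = 1e-12)
  # assembly-favored scheme: mean oligomeric state non-decreasing in C0
  expect_true(all(diff(ft$mu) > -1e-9))
  # dilute limit is monomeric, concentrated limit oligomeric
  expect_gt(ft$f1[1L], 0.9)
  expect_gt(ft$mu[nrow(ft)], 4)
})

test_that("a pure-monomer endpoint has mu = 1; a hexamer-driven one approaches 6", {
  none <- solution_scheme(k64 = 0)
  ft1 <- endpoint_fractions(none, initial_concs = c(1e-8, 1e-7, 1e-6, 1e-5, 1e-4))
  expect_true(all(ft1$f1 == 1))
  expect_true(all(ft1$mu == 1))
  # reversible ladder with an absorbing hexamer funnels all mass into S6
  hex <- solution_scheme(k12 = 1e9, k21 = 1, k23 = 1e9, k32 = 1,
                         k34 = 1e9, k43 = 1, k45 = 1e9, k54 = 1,
                         k56 = 1e9, k65 = 0, k64 = 0)
  ft6 <- endpoint_fractions(hex, initial_concs = 1e-4, t_end = 1000)
  expect_gt(ft6$f6, 0.95)
  expect_gt(ft6$mu, 5.8)
})

test_that("the Hill fit exactly recovers noiseless Hill-generated data", {
  K <- 1e-6; nh <- 0.8; bmax <- 0.9
  x <- 10^seq(-9, -3, length.out = 15)
  y <- bmax * x^nh / (K^nh + x^nh)
  hf <- hill_fit(x, f = y)
  expect_true(hf$converged)
  expect_equal(hf$K, K, tolerance = 1e-6)
  expect_equal(hf$n_h, nh, tolerance = 1e-6)
  expect_equal(hf$B_max, bmax, tolerance = 1e-6)
  # half-max identity f(K) = B_max / 2
  expect_equal(bmax * K^nh / (K^nh + K^nh), bmax / 2)
})

test_that("hexamer curves from the default schemes have Hill coefficients below 1", {
  for (cond in c("HI", "zn_phenol")) {
    ft <- endpoint_fractions(example_scheme(cond),
                             initial_concs = 10^seq(-9, -3, length.out = 13))
    hf <- hill_fit(ft, species = 6)
    expect_true(hf$converged)
    expect_lt(hf$n_h, 1)
    expect_gt(hf$K, 0)
  }
})

test_that("the tetramer-side dimer-addition switch and mass weighting behave", {
  # with s2s4_forward = "max", k46 can carry the S2+S4 flux
  base <- solution_scheme(k12 = 1e7, k21 = 1, k24 = 1e8, k42 = 0.1,
                          k26 = 0, k46 = 2e9, k64 = 0)
  alt <- solution_scheme(k12 = 1e7, k21 = 1, k24 = 1e8, k42 = 0.1,
                         k26 = 0, k46 = 2e9, k64 = 0, s2s4_forward = "max")
  e_base <- tail(integrate_scheme(base, 1e-6), 1L)
  e_alt <- tail(integrate_scheme(alt, 1e-6), 1L)
  expect_equal(e_base$S6, 0)          # k26 = 0: no hexamer route
  expect_gt(e_alt$S6, 0)              # k46 routed in
  # monomer-equivalent weighting reweights fractions by size
  ft_p <- endpoint_fractions(base, initial_concs = 1e-6)
  ft_m <- endpoint_fractions(base, initial_concs = 1e-6,
                             normalization = "monomer_equivalent")
  expect_lt(abs(sum(ft_m[, paste0("f", 1:6)]) - 1), 1e-9)
  expect_gt(ft_m$f4, ft_p$f4)         # heavier species gain weight by mass
  expect_identical(ft_m$mu, ft_p$mu)  # mu stays particle-based
})

test_that("non-sigmoidal data yields a flagged failure, not a crash", {
  x <- 10^seq(-9, -5, length.out = 6)
  expect_error(hill_fit(x, f = rep(0, 6)), "non-sigmoidal")
})

test_that("the stochastic simulator is frozen, seeded and mass-conserving", {
  sc <- solution_scheme(k12 = 1e6, k21 = 1, k64 = 0)
  g1 <- gillespie_scheme(sc, 1e-6, volume = 2e-15, t_end = 3, seed = 90)
  g2 <- gillespie_scheme(sc, 1e-6, volume = 2e-15, t_end = 3, seed = 90)
  expect_identical(g1, g2)
  mass <- g1[, -1L] %*% (1:6)
  expect_true(all(mass == mass[1L]))
  # zero-rate network: constant counts
  g0 <- gillespie_scheme(solution_scheme(k64 = 0), 1e-6, volume = 2e-15,
                         t_end = 3, seed = 91)
  expect_true(all(g0[, "S1"] == g0[1L, "S1"]))
})

test_that("the stochastic mean matches the dimerization closed form", {
  # ~1.2e4 particles: endpoint fractions within a few percent of equilibrium
  sc <- solution_scheme(k12 = 1e6, k21 = 1, k64 = 0)
  vol <- 2e-14
  g <- gillespie_scheme(sc, 1e-6, volume = vol, t_end = 6, seed = 92)
  n_end <- g[nrow(g), c("S1", "S2")]
  n_av <- 6.02214076e23
  expect_lt(abs(n_end[["S1"]] / (n_av * vol) - 5e-7) / 5e-7, 0.05)
  expect_error(gillespie_scheme(sc, 1e-12, volume = 1e-18, t_end = 1, seed = 1),
               "fewer than one")
})

test_that("scheme and fraction tables round trip through files", {
  sc <- example_scheme("HI")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  write_scheme_json(sc, tmp)
  rt <- read_scheme_json(tmp)
  expect_equal(unclass(rt), unclass(sc))
  ft <- endpoint_fractions(sc, initial_concs = c(1e-8, 1e-6))
  csv <- tempfile(fileext = ".csv")
  on.exit(unlink(csv), add = TRUE)
  write_fractions_csv(ft, csv)
  expect_identical(nrow(utils::read.csv(csv)), 2L)
})
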