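# Shared builders for synthetic fixtures. Everything is generated in code
# under fixed seeds; no data files.

# A path that never leaves `state`.
const_path <- function(state, duration) {
  structure(list(jump_times = numeric(0), states = as.integer(state),
                 duration = duration, seed = NULL),
            class = "ground_truth_path")
}

# A path from explicit jump times / states.
manual_path <- function(jump_times, states, duration) {
  structure(list(jump_times = jump_times, states = as.integer(states),
                 duration = duration, seed = NULL),
            class = "ground_truth_path")
}

# Symmetric two-state monomer-exchange model: S1 <-> S2, both decay rates in
# 1/s (association expressed through a 10 nM free monomer pool).
two_state_model <- function(k_on = 1, k_off = 1, conc = 10e-9) {
  surface_kinetic_model(assoc = setNames(k_on / conc, "1->2"),
                        dissoc = setNames(k_off, "2->1"),
                        solution_conc = setNames(conc, "1"))
}

# Minimal idealized_trace wrapper around a per-frame state vector (S-numbers
# 0..6), for tests that exercise the kinetics layer directly.
ideal_from_states <- function(states, spec = hmm_spec()) {
  states <- as.integer(states)
  structure(list(states = states,
                 idealized = spec$state_means[states + 1L],
                 residuals = rep(0, length(states)),
                 loglik = 0, trans_mat = NULL, initial = NULL,
                 converged = TRUE, single_frame_fraction = 0,
                 spec = spec),
            class = "idealized_trace")
}

# Camera model with known truth (bypasses calibration where the test is not
# about calibration).
true_camera <- function(s0 = 100, gamma = 0.02) {
  structure(list(s0 = s0, gamma = gamma, n_pixels_fit = NA_integer_,
                 n_pixels_accepted = NA_integer_, fits = NULL),
            class = "camera_model")
}

# Sample one pixel's EMCCD counts from the generative model.
sim_pixel_counts <- function(n, s0, gamma, E) {
  nph <- rpois(n, E)
  s <- rep(s0, n)
  pos <- nph > 0
  s[pos] <- s[pos] + rgamma(sum(pos), shape = nph[pos], rate = gamma)
  round(s)
}

# State path whose dwells are exponential but truncated below at `min_dwell`
# seconds (memorylessness: min_dwell + Exp(rate)); random +-1 ladder walk
# over states 1..6. Used for decode-fidelity tests where dwells must be
# resolvable.
truncated_dwell_path <- function(duration, rate = 0.2, min_dwell = 0.75,
                                 start = 2L) {
  t_now <- 0
  st <- start
  states <- integer(0)
  jumps <- numeric(0)
  repeat {
    states <- c(states, st)
    dwell <- min_dwell + rexp(1L, rate)
    t_now <- t_now + dwell
    if (t_now >= duration) break
    jumps <- c(jumps, t_now)
    st <- if (st == 1L) 2L else if (st == 6L) 5L else st + sample(c(-1L, 1L), 1L)
  }
  manual_path(jumps, states, duration)
}

# Ground-truth per-frame state (rounded exposure-window occupancy).
true_frame_states <- function(path, n_frames, frame_interval = 0.15,
                              exposure = 0.05) {
  a <- (seq_len(n_frames) - 1L) * frame_interval
  b <- a + exposure
  round(hexakin:::.path_window_mean(path, a, b))
}
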