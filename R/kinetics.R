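# Kinetics: from idealized traces to the CHESS table. Transition
# enumeration, per-cluster dwell-time maximum-likelihood, solution
# composition from assembly step sizes, bimolecular conversion, and the
# thermodynamic and statistical helpers downstream.

#' Enumerate transitions and dwell times from idealized traces
#'
#' Every state change between non-background states becomes a transition
#' record; the cluster key is (state before, state after), equivalent to a
#' transition-density-plot grid aligned with the frozen HMM levels.
#' Transitions involving the background state S0 are excluded from the 6x6
#' table. Dwell times used for rate fitting are restricted to interior
#' segments, i.e. those whose entry AND exit are both observed; the first
#' segment of a trace (censored entry) contributes to transition densities
#' only.
#'
#' @param idealized List of [idealized_trace] objects (or one).
#' @param frame_interval Seconds per frame (default 0.15).
#' @param video_ids Optional vector (one entry per trace) assigning traces to
#'   acquisition videos; enables the per-video error variant in
#'   [build_chess()]. Default: all traces in one video.
#' @return data.frame of class `transition_table` with columns `trace_id`,
#'   `video_id`, `from`, `to` (1..6), `dwell` (seconds in `from` before the
#'   jump), `interior` (logical: dwell usable for rate fitting),
#'   `photon_before`, `photon_after`.
#' @export
extract_transitions <- function(idealized, frame_interval = 0.15,
                                video_ids = NULL) {
  if (inherits(idealized, "idealized_trace")) idealized <- list(idealized)
  if (is.null(video_ids)) video_ids <- rep(1L, length(idealized))
  stopifnot(length(video_ids) == length(idealized))
  rows <- lapply(seq_along(idealized), function(i) {
    st <- idealized[[i]]$states
    mu <- idealized[[i]]$spec$state_means
    r <- rle(st)
    ns <- length(r$values)
    if (ns < 2L) return(NULL)
    k <- seq_len(ns - 1L)
    from <- r$values[k]; to <- r$values[k + 1L]
    keep <- from > 0L & to > 0L
    if (!any(keep)) return(NULL)
    data.frame(trace_id = i, video_id = video_ids[i],
               from = from[keep], to = to[keep],
               dwell = r$lengths[k][keep] * frame_interval,
               interior = (k[keep] > 1L),
               photon_before = mu[from[keep] + 1L],
               photon_after = mu[to[keep] + 1L])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(trace_id = integer(0),
                                      video_id = integer(0),
                                      from = integer(0),
                                      to = integer(0), dwell = numeric(0),
                                      interior = logical(0),
                                      photon_before = numeric(0),
                                      photon_after = numeric(0))
  class(out) <- c("transition_table", "data.frame")
  attr(out, "frame_interval") <- frame_interval
  out
}

#' Dwell-time clusters from a transition table
#'
#' @param transitions An [extract_transitions()] table.
#' @param interior_only Use only interior dwells (default TRUE, the rate
#'   fitting convention).
#' @return Named list (key `"i->j"`) of dwell-time vectors in seconds.
#' @export
dwell_clusters <- function(transitions, interior_only = TRUE) {
  tt <- transitions
  if (interior_only) tt <- tt[tt$interior, , drop = FALSE]
  if (!nrow(tt)) return(list())
  split(tt$dwell, paste0(tt$from, "->", tt$to))
}

#' Single-exponential dwell-time fit (maximum likelihood)
#'
#' Dwells above the cutoff (75 s by default) are excluded: long-lived
#' outliers do not follow the single-exponential decay. The MLE of the decay
#' rate is 1/mean of the retained dwells; the error is a nonparametric
#' bootstrap SE (1000 resamples by default). Clusters with fewer than 10
#' retained dwells are flagged low-n.
#'
#' @param dwells Dwell times in seconds.
#' @param cutoff Exclusion threshold in seconds (default 75).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @return An object of class `dwell_fit`: `rate` (1/s; NA when fewer than 2
#'   retained dwells), `se`, `n`, `n_excluded`, `low_n`.
#' @export
fit_dwell <- function(dwells, cutoff = 75, n_boot = 1000L, seed = NULL) {
  kept <- dwells[dwells <= cutoff]
  n <- length(kept)
  if (n < 2L) {
    return(structure(list(rate = NA_real_, se = NA_real_, n = n,
                          n_excluded = length(dwells) - n, low_n = TRUE),
                     class = "dwell_fit"))
  }
  rate <- 1 / mean(kept)
  se <- with_seed(seed, {
    boots <- replicate(n_boot, 1 / mean(sample(kept, n, replace = TRUE)))
    sd(boots)
  })
  structure(list(rate = rate, se = se, n = n,
                 n_excluded = length(dwells) - n, low_n = n < 10L),
            class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("dwell_fit: rate %.4g 1/s (se %.2g), n = %d%s%s\n",
              x$rate, x$se, x$n,
              if (x$n_excluded) sprintf(", %d above cutoff", x$n_excluded) else "",
              if (x$low_n) " [low n]" else ""))
  invisible(x)
}

#' Estimate the solution oligomer composition from assembly step sizes
#'
#' The photon increments of all assembly transitions are fitted with a
#' five-Gaussian mixture whose component means are anchored at m * mu
#' (m = 1..5 monomers, mu from the monomer calibration; means frozen, SDs
#' sqrt(m) * sigma, weights free). The weights are the number fractions of
#' the free soluble species. Molar concentrations follow from
#' monomer-equivalent conservation: `c_m = w_m * C_N` with
#' `C_N = total_monomer_equiv / sum(m * w_m)`, so that
#' `sum(m * c_m) = total_monomer_equiv`.
#'
#' @param assembly_steps Photon increments at assembly transitions
#'   (`photon_after - photon_before`, positive).
#' @param calibration A [calibrate_photons_per_monomer()] result (or a list
#'   with `mu`, `sigma`).
#' @param total_monomer_equiv Total protein as monomer-equivalent molar
#'   concentration (e.g. `10e-9` for 10 nM).
#' @param max_species Largest added species (default 5, pentamer).
#' @return An object of class `solution_composition`: `weights` (sum 1),
#'   `concentrations` (molar, per species size), `total_monomer_equiv`,
#'   `n_steps`.
#' @export
estimate_solution_composition <- function(assembly_steps, calibration,
                                          total_monomer_equiv,
                                          max_species = 5L) {
  steps <- assembly_steps[is.finite(assembly_steps) & assembly_steps > 0]
  if (length(steps) < 2L) stop("need at least 2 assembly steps")
  if (length(steps) < 100L)
    warning("fewer than 100 assembly steps; composition weights will be noisy")
  m <- seq_len(max_species)
  w <- .frozen_mixture_weights(steps, m * calibration$mu,
                               sqrt(m) * calibration$sigma)
  cn <- total_monomer_equiv / sum(m * w)
  conc <- w * cn
  structure(list(weights = setNames(w, paste0("m", m)),
                 concentrations = setNames(conc, paste0("m", m)),
                 total_monomer_equiv = total_monomer_equiv,
                 n_steps = length(steps)),
            class = "solution_composition")
}

#' @export
print.solution_composition <- function(x, ...) {
  cat("solution_composition (number fractions -> molar):\n")
  for (m in seq_along(x$weights)) {
    cat(sprintf("  %d-mer: w = %.3f, c = %.3g M\n",
                m, x$weights[m], x$concentrations[m]))
  }
  invisible(x)
}

#' Build the CHESS table (Complete HEatmap of State transitionS)
#'
#' Aggregates the transition table into per-(i -> j) densities and rate
#' constants. Disassembly (j < i) rate constants are the fitted decay rates
#' (1/s). Assembly (j > i) decay rates are converted to bimolecular rate
#' constants by dividing by the solution concentration of the species being
#' added, `c_(j-i)` (1/(M s)); entries whose added-species concentration is
#' missing or zero are flagged unconvertible. Clusters fitted from fewer
#' than 10 transitions carry the low-n flag (the "triangle" annotation).
#'
#' @param transitions An [extract_transitions()] table.
#' @param composition A [estimate_solution_composition()] result, or `NULL`
#'   (assembly entries then stay as decay rates and are flagged
#'   unconvertible).
#' @param cutoff Dwell cutoff in seconds (default 75).
#' @param n_boot Bootstrap resamples per cluster (default 200).
#' @param seed Seed for the bootstraps.
#' @param n_states Table size (default 6).
#' @return An object of class `chess_table`: 6x6 matrices `density`, `rate`,
#'   `error`, `low_n`, `unconvertible`, the per-cluster `fits`, and
#'   `rate_corrected` - the competing-risks corrected channel decay rates
#'   (1/s, diagnostic): the published per-cluster convention reports the
#'   total exit rate of the source state in every cluster; the corrected
#'   rates (channel share times pooled total exit rate) sum to the total
#'   exit rate per state.
#' @export
build_chess <- function(transitions, composition = NULL, cutoff = 75,
                        n_boot = 200L, seed = NULL, n_states = 6L) {
  dens <- matrix(0, n_states, n_states)
  rate <- matrix(NA_real_, n_states, n_states)
  err <- matrix(NA_real_, n_states, n_states)
  lown <- matrix(FALSE, n_states, n_states)
  unconv <- matrix(FALSE, n_states, n_states)
  dimnames(dens) <- dimnames(rate) <- dimnames(err) <-
    dimnames(lown) <- dimnames(unconv) <-
    list(from = paste0("S", 1:n_states), to = paste0("S", 1:n_states))
  tab <- table(factor(transitions$from, levels = 1:n_states),
               factor(transitions$to, levels = 1:n_states))
  dens[] <- as.numeric(tab)
  clusters <- dwell_clusters(transitions, interior_only = TRUE)
  fits <- list()
  for (key in names(clusters)) {
    ij <- as.integer(strsplit(key, "->", fixed = TRUE)[[1L]])
    i <- ij[1L]; j <- ij[2L]
    f <- fit_dwell(clusters[[key]], cutoff = cutoff, n_boot = n_boot, seed = seed)
    fits[[key]] <- f
    lown[i, j] <- f$low_n
    if (is.na(f$rate)) next
    if (j > i) {
      csp <- if (is.null(composition)) NA_real_ else
        unname(composition$concentrations[j - i])
      if (is.na(csp) || csp <= 0) {
        unconv[i, j] <- TRUE
        rate[i, j] <- f$rate      # decay rate, 1/s, not converted
        err[i, j] <- f$se
      } else {
        rate[i, j] <- f$rate / csp
        err[i, j] <- f$se / csp
      }
    } else {
      rate[i, j] <- f$rate
      err[i, j] <- f$se
    }
  }
  # competing-risks corrected channel decay rates (diagnostic): the
  # per-cluster single-exponential fit reports the TOTAL exit rate of the
  # source state for every exit channel; the corrected channel rate is the
  # channel's share of events times the pooled total exit rate, so the
  # corrected rates from one state sum to its total exit rate.
  corr <- matrix(NA_real_, n_states, n_states, dimnames = dimnames(rate))
  ti <- transitions[transitions$interior & transitions$dwell <= cutoff, , drop = FALSE]
  for (i in seq_len(n_states)) {
    di <- ti[ti$from == i, , drop = FALSE]
    if (nrow(di) < 2L) next
    total_rate <- 1 / mean(di$dwell)
    share <- table(factor(di$to, levels = seq_len(n_states))) / nrow(di)
    corr[i, ] <- as.numeric(share) * total_rate
    corr[i, share == 0] <- NA_real_
  }
  # per-video error variant: SD of per-video decay-rate refits (the
  # spread over independent acquisitions), on the same scale as `rate`
  errv <- matrix(NA_real_, n_states, n_states, dimnames = dimnames(rate))
  if (length(unique(transitions$video_id)) > 1L) {
    for (key in names(clusters)) {
      ij <- as.integer(strsplit(key, "->", fixed = TRUE)[[1L]])
      sel <- transitions$interior & transitions$dwell <= cutoff &
        transitions$from == ij[1L] & transitions$to == ij[2L]
      dsub <- transitions[sel, , drop = FALSE]
      pv <- vapply(split(dsub$dwell, dsub$video_id),
                   function(d) if (length(d) >= 2L) 1 / mean(d) else NA_real_,
                   numeric(1L))
      pv <- pv[!is.na(pv)]
      if (length(pv) >= 2L) {
        e <- sd(pv)
        if (ij[2L] > ij[1L] && !is.null(composition)) {
          csp <- unname(composition$concentrations[ij[2L] - ij[1L]])
          if (!is.na(csp) && csp > 0) e <- e / csp
        }
        errv[ij[1L], ij[2L]] <- e
      }
    }
  }
  structure(list(density = dens, rate = rate, error = err,
                 low_n = lown, unconvertible = unconv,
                 rate_corrected = corr, error_video = errv,
                 fits = fits, composition = composition),
            class = "chess_table")
}

#' @export
print.chess_table <- function(x, ...) {
  cat("chess_table: transition densities (rows = from, cols = to)\n")
  print(x$density)
  cat("rate constants (assembly 1/(M s), disassembly 1/s; low-n flagged *)\n")
  r <- signif(x$rate, 3)
  flag <- ifelse(x$low_n & !is.na(x$rate), "*", "")
  out <- matrix(paste0(ifelse(is.na(r), ".", format(r)), flag),
                nrow(r), dimnames = dimnames(r))
  print(out, quote = FALSE)
  invisible(x)
}

#' Heatmap of a CHESS table
#'
#' @param x A `chess_table`.
#' @param layer `"density"` or `"rate"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.chess_table <- function(x, layer = c("density", "rate"), ...) {
  layer <- match.arg(layer)
  m <- x[[layer]]
  n <- nrow(m)
  z <- log10(pmax(t(m)[, n:1, drop = FALSE], 1e-12))
  z[!is.finite(z)] <- NA
  image(1:n, 1:n, z, axes = FALSE, xlab = "state before", ylab = "state after",
        col = hcl.colors(64, "YlOrRd", rev = TRUE),
        main = paste("CHESS:", layer), ...)
  axis(1, at = 1:n, labels = paste0("S", 1:n))
  axis(2, at = 1:n, labels = paste0("S", n:1))
  for (i in 1:n) for (j in 1:n) {
    v <- m[i, j]
    if (!is.na(v) && v > 0) {
      lab <- format(signif(v, 2))
      if (x$low_n[i, j]) lab <- paste0(lab, "△")
      text(i, n + 1 - j, lab, cex = 0.6)
    }
  }
  invisible(x)
}

#' Write a CHESS table as JSON
#' @param chess A `chess_table`.
#' @param path File path.
#' @return `path` invisibly.
#' @export
write_chess_json <- function(chess, path) {
  jsonlite::write_json(list(density = chess$density, rate = chess$rate,
                            error = chess$error, low_n = chess$low_n,
                            unconvertible = chess$unconvertible),
                       path, digits = NA)
  invisible(path)
}

# ---- transition-state thermodynamics ----------------------------------------

#' Physical constants used for the free-energy calculations
#'
#' @return List with `R` (8.314 J/(mol K)), `T` (298 K), `k_B`, `h` (SI).
#' @export
thermo_constants <- function() {
  list(R = 8.314, T = 298, k_B = 1.380649e-23, h = 6.62607015e-34)
}

#' Equilibrium constant from forward and reverse rate constants
#'
#' `K_eq = k_ij / k_ji`.
#'
#' @param k_ij Forward (association) rate constant (> 0).
#' @param k_ji Reverse (dissociation) rate constant (> 0).
#' @return `K_eq` (units of `k_ij`/`k_ji`, typically 1/M).
#' @export
equilibrium_constant <- function(k_ij, k_ji) {
  if (any(k_ij <= 0) || any(k_ji <= 0)) stop("rate constants must be > 0")
  k_ij / k_ji
}

#' Gibbs free-energy difference from an equilibrium constant
#'
#' `dG = -R T ln(K_eq)`, J/mol.
#'
#' @param K_eq Equilibrium constant (> 0).
#' @param T Temperature in K (default 298).
#' @return Free-energy difference in J/mol.
#' @export
free_energy <- function(K_eq, T = 298) {
  if (any(K_eq <= 0)) stop("K_eq must be > 0")
  -thermo_constants()$R * T * log(K_eq)
}

#' Gibbs energy of activation from a rate constant
#'
#' Transition-state theory: `dG_act = -R T ln(h k / (k_B T))`, J/mol.
#'
#' @param k Rate constant (> 0, 1/s).
#' @param T Temperature in K (default 298).
#' @return Activation energy in J/mol.
#' @export
activation_energy <- function(k, T = 298) {
  if (any(k <= 0)) stop("rate constant must be > 0")
  cc <- thermo_constants()
  -cc$R * T * log(cc$h * k / (cc$k_B * T))
}

# ---- condition comparisons ---------------------------------------------------

#' Welch's unequal-variance t-test from summary statistics
#'
#' Means, SDs and group sizes (typically n = number of videos, 4..7) give the
#' Welch t statistic with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value; significance stars follow the mapping * p < 0.05,
#' ** p < 0.01, *** p < 0.001.
#'
#' @param mean1,sd1,n1 Summary statistics of condition 1.
#' @param mean2,sd2,n2 Summary statistics of condition 2.
#' @return List with `t`, `df`, `p_value`, `stars`.
#' @export
compare_conditions <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2L || n2 < 2L) {
    return(list(t = NA_real_, df = NA_real_, p_value = NA_real_,
                stars = NA_character_))
  }
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  se2 <- v1 + v2
  if (se2 == 0) {
    t <- 0; df <- n1 + n2 - 2; p <- 1
  } else {
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    p <- 2 * pt(-abs(t), df)
  }
  list(t = t, df = df, p_value = p, stars = .stars_from_p(p))
}

#' Ratio of two rate constants with first-order error propagation
#'
#' @param k_num,k_den Rate constants (> 0).
#' @param e_num,e_den Their errors (default 0).
#' @param sig_figs Significant figures for the reported ratio (default 2).
#' @return List with `ratio` (rounded to `sig_figs`), `error`, `raw`.
#' @export
fold_ratio <- function(k_num, k_den, e_num = 0, e_den = 0, sig_figs = 2L) {
  if (k_num <= 0 || k_den <= 0) stop("rate constants must be > 0")
  raw <- k_num / k_den
  err <- raw * sqrt((e_num / k_num)^2 + (e_den / k_den)^2)
  list(ratio = signif(raw, sig_figs), error = err, raw = raw)
}

#' Write a transition table as CSV
#' @param transitions An [extract_transitions()] table.
#' @param path File path.
#' @return `path` invisibly.
#' @export
write_transitions_csv <- function(transitions, path) {
  utils::write.csv(as.data.frame(transitions), path, row.names = FALSE)
  invisible(path)
}
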