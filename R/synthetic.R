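# Per-state emission parameters (normal family). Means are separated so the
# SIRS thresholds are informative: SIRS-like states exceed the HR/RR/temp/WBC
# criteria with high probability, shock states sit below the SBP/MAP
# thresholds. The "probable" states (PS/BPS/PSS) carry total missingness on
# the four SIRS vitals, which is what produces their labels.
default_emissions <- function() {
  base <- list(
    NO_SIRS      = list(temperature = c(37, 0.3), heart_rate = c(75, 5),
                        respiratory_rate = c(14, 2), wbc = c(8000, 1000),
                        map = c(90, 5), sbp = c(120, 8)),
    SIRS         = list(temperature = c(39, 0.4), heart_rate = c(110, 8),
                        respiratory_rate = c(26, 3), wbc = c(16000, 1500),
                        map = c(92, 6), sbp = c(125, 8)),
    SEPSIS       = list(temperature = c(39.2, 0.4), heart_rate = c(115, 8),
                        respiratory_rate = c(28, 3), wbc = c(17000, 1500),
                        map = c(92, 6), sbp = c(125, 8)),
    SEPTIC_SHOCK = list(temperature = c(39.5, 0.4), heart_rate = c(125, 8),
                        respiratory_rate = c(30, 3), wbc = c(18000, 1500),
                        map = c(55, 5), sbp = c(75, 6)),
    BACTEREMIA   = list(temperature = c(37.2, 0.3), heart_rate = c(80, 5),
                        respiratory_rate = c(15, 2), wbc = c(9000, 1000),
                        map = c(88, 5), sbp = c(118, 8)),
    PS           = list(temperature = c(37, 0.3), heart_rate = c(78, 5),
                        respiratory_rate = c(15, 2), wbc = c(8500, 1000),
                        map = c(89, 5), sbp = c(119, 8)),
    BPS          = list(temperature = c(37.5, 0.4), heart_rate = c(90, 6),
                        respiratory_rate = c(17, 2), wbc = c(10000, 1200),
                        map = c(86, 5), sbp = c(112, 8)),
    PSS          = list(temperature = c(38, 0.5), heart_rate = c(100, 8),
                        respiratory_rate = c(18, 3), wbc = c(11000, 1500),
                        map = c(56, 5), sbp = c(78, 6))
  )
  base
}

sirs_vitals <- function() c("temperature", "heart_rate", "respiratory_rate", "wbc")

default_missingness <- function() {
  sts <- transient_states()
  vit <- c(sirs_vitals(), "map", "sbp")
  m <- matrix(0.05, length(sts), length(vit), dimnames = list(sts, vit))
  # total SIRS-vital missingness generates the probable states
  m[c("PS", "BPS", "PSS"), sirs_vitals()] <- 1
  m[c("PS", "BPS", "PSS"), c("map", "sbp")] <- 0.1
  m["PSS", c("map", "sbp")] <- 0.02
  m
}

default_blood_rates <- function() {
  c(NO_SIRS = 0.02, PS = 0.02, SIRS = 0.02, BACTEREMIA = 0.98,
    BPS = 0.98, PSS = 0.98, SEPSIS = 0.98, SEPTIC_SHOCK = 0.98)
}

# Distribute transition mass for one transient state as a birth-death walk on
# the severity ladder: improvement moves to the adjacent better state (from
# NO_SIRS that is discharge), deterioration to the adjacent worse state (from
# SEPTIC_SHOCK that is death), the remainder stays put.
severity_row <- function(state, p_better, p_same, p_worse,
                         states = sepsis_states()) {
  stopifnot(abs(p_better + p_same + p_worse - 1) < 1e-12)
  i <- match(state, states)
  row <- stats::setNames(numeric(length(states)), states)
  row[states[i - 1]] <- p_better   # adjacent better (toward DISMISSAL)
  row[states[i + 1]] <- p_worse    # adjacent worse (toward DEATH)
  row[state] <- row[state] + p_same
  row
}

#' Construct a ground-truth scenario for the synthetic EHR generator
#'
#' Three stated worlds: `strong_signal` gives one designated drug combination
#' (vancomycin + ceftriaxone, action 9) a probability of improvement higher
#' by `margin` than any other action in every treatable state; `null_signal`
#' makes transitions independent of the action; `paper_like` shapes the state
#' mix loosely towards the source cohort (majority NO_SIRS/PS, rare septic
#' shock) with a modest treatment effect.
#'
#' @param name Scenario name.
#' @param seed Seed stored with the truth (construction is deterministic).
#' @param margin Improvement-probability margin of the beneficial action in
#'   the strong-signal scenario (default 0.5).
#' @return An object of class `ground_truth` holding the transition tensor,
#'   emission parameters, blood-culture rates, behavior policy, missingness
#'   rates, initial state distribution and the beneficial action index.
#' @export
make_scenario <- function(name = c("strong_signal", "null_signal", "paper_like"),
                          seed = 1L, margin = 0.5) {
  name <- match.arg(name)
  states <- sepsis_states()
  S <- length(states)
  A <- n_actions()
  a_star <- encode_action(c("VANCOMYCIN", "CEFTRIAXONE"))$index  # = 9
  T <- array(0, c(S, A, S), dimnames = list(states, NULL, states))
  for (st in absorbing_states()) T[st, , st] <- 1
  for (st in transient_states()) {
    for (a in seq_len(A)) {
      probs <- switch(name,
        strong_signal = if (a - 1L == a_star) {
          pb <- min(0.3 + margin, 0.9)
          c(pb, 0.6 * (1 - pb), 0.4 * (1 - pb))
        } else c(0.3, 0.3, 0.4),
        null_signal = c(0.35, 0.35, 0.30),
        paper_like = if (a - 1L == a_star) c(0.45, 0.35, 0.20)
                     else c(0.30, 0.40, 0.30))
      T[st, a, ] <- severity_row(st, probs[1], probs[2], probs[3], states)
    }
  }
  init <- switch(name,
    paper_like = c(NO_SIRS = 0.31, PS = 0.45, SIRS = 0.07, BACTEREMIA = 0.04,
                   BPS = 0.07, PSS = 0.03, SEPSIS = 0.02, SEPTIC_SHOCK = 0.01),
    c(NO_SIRS = 0.20, PS = 0.20, SIRS = 0.15, BACTEREMIA = 0.10,
      BPS = 0.10, PSS = 0.08, SEPSIS = 0.10, SEPTIC_SHOCK = 0.07))
  init <- init / sum(init)
  eps <- 0.5
  behavior <- matrix(0, length(transient_states()), A,
                     dimnames = list(transient_states(), NULL))
  if (name == "null_signal") {
    behavior[] <- 1 / A
  } else {
    behavior[] <- eps / A
    behavior[, a_star + 1L] <- behavior[, a_star + 1L] + (1 - eps)
  }
  structure(list(name = name, seed = as.integer(seed), states = states,
                 T = T, emissions = default_emissions(),
                 blood_rates = default_blood_rates(),
                 behavior = behavior, missingness = default_missingness(),
                 init = init, beneficial_action = a_star, margin = margin,
                 ranges = plausible_ranges()),
            class = "ground_truth")
}

clamp <- function(x, r) pmin(pmax(x, r[1]), r[2])

emit_snapshot <- function(truth, state) {
  em <- truth$emissions[[state]]
  miss <- truth$missingness[state, ]
  vit <- c(sirs_vitals(), "map", "sbp")
  out <- stats::setNames(rep(NA_real_, length(vit)), vit)
  for (v in vit) {
    if (stats::runif(1) < miss[[v]]) next
    out[[v]] <- clamp(stats::rnorm(1, em[[v]][1], em[[v]][2]), truth$ranges[[v]])
  }
  culture <- if (stats::runif(1) < truth$blood_rates[[state]]) "pos" else "neg"
  list(vitals = out, culture = culture)
}

action_string <- function(index) {
  if (index == 0) "AMOXICILLIN" else paste(action_drugs(index), collapse = ";")
}

#' Simulate a synthetic cohort
#'
#' Per patient: draw the initial state, then at each step draw an action from
#' the behavior policy, the next state from the true transition tensor, and a
#' vitals snapshot (with missingness and clamping to plausible clinical
#' ranges) from the state's emission parameters. Trajectories stop at an
#' absorbing state, written as a terminal outcome record, or at `max_length`
#' transitions.
#'
#' Trajectory lengths are geometric with mean `mean_length` transitions
#' (loosely matching the ~2.8 transitions per patient of the source cohort),
#' truncated at `max_length`; a censored trajectory has no outcome record.
#'
#' @param truth A [make_scenario()] ground truth.
#' @param n_patients Number of patients (>= 1).
#' @param max_length Hard cap on transitions per patient (default 20).
#' @param mean_length Mean of the geometric length distribution (default 4).
#' @param seed RNG seed.
#' @return An object of class `synthetic_cohort`: the cohort table (`cohort`,
#'   in the [read_cohort()] layout) and the aligned latent state sequences
#'   (`latent`).
#' @export
simulate_cohort <- function(truth, n_patients, max_length = 20L,
                            mean_length = 4, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_patients < 1) stop("n_patients must be >= 1")
  set.seed(seed)
  states <- truth$states
  rows <- list(); lat <- list(); ri <- 0L
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%04d", p)
    s <- sample(names(truth$init), 1, prob = truth$init)
    len <- min(1L + stats::rgeom(1, 1 / mean_length), max_length)
    t <- 0L
    repeat {
      snap <- emit_snapshot(truth, s)
      a <- sample.int(n_actions(), 1, prob = truth$behavior[s, ]) - 1L
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        patient_id = pid, timestamp = t,
        temperature = snap$vitals[["temperature"]],
        heart_rate = snap$vitals[["heart_rate"]],
        respiratory_rate = snap$vitals[["respiratory_rate"]],
        wbc = snap$vitals[["wbc"]], map = snap$vitals[["map"]],
        sbp = snap$vitals[["sbp"]], blood_culture = snap$culture,
        antibiotics = action_string(a), outcome = "none",
        stringsAsFactors = FALSE)
      lat[[ri]] <- data.frame(patient_id = pid, timestamp = t, state = s,
                              action = a, stringsAsFactors = FALSE)
      s2 <- sample(states, 1, prob = truth$T[s, a + 1L, ])
      t <- t + 1L
      if (s2 %in% absorbing_states()) {
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          patient_id = pid, timestamp = t, temperature = NA_real_,
          heart_rate = NA_real_, respiratory_rate = NA_real_, wbc = NA_real_,
          map = NA_real_, sbp = NA_real_, blood_culture = "",
          antibiotics = "",
          outcome = ifelse(s2 == "DEATH", "death", "dismissal"),
          stringsAsFactors = FALSE)
        lat[[ri]] <- data.frame(patient_id = pid, timestamp = t, state = s2,
                                action = NA_integer_, stringsAsFactors = FALSE)
        break
      }
      s <- s2
      if (t >= len) break
    }
  }
  structure(list(cohort = validate_cohort(do.call(rbind, rows)),
                 latent = do.call(rbind, lat),
                 truth_name = truth$name, seed = as.integer(seed)),
            class = "synthetic_cohort")
}

# Latent (state, action, next_state) triples of a synthetic cohort.
latent_transitions <- function(sc) {
  stopifnot(inherits(sc, "synthetic_cohort"))
  lt <- sc$latent[order(sc$latent$patient_id, sc$latent$timestamp), ]
  by <- split(lt, lt$patient_id)
  out <- lapply(by, function(d) {
    n <- nrow(d)
    if (n < 2) return(NULL)
    data.frame(state = d$state[-n], action = d$action[-n],
               next_state = d$state[-1], stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# True per-vital observation factors of a scenario over given pooled edges:
# the emission normal's mass in each bin, renormalized over the edge span.
true_observation_factors <- function(truth, global) {
  vitals <- obs_vitals()
  sts <- transient_states()
  factors <- array(NA_real_, c(length(sts), length(vitals), 5),
                   dimnames = list(sts, vitals, NULL))
  for (i in seq_along(sts)) {
    for (k in seq_along(vitals)) {
      em <- truth$emissions[[sts[i]]][[vitals[k]]]
      cd <- stats::pnorm(global[[vitals[k]]]$edges, em[1], em[2])
      mass <- diff(cd)
      factors[i, k, ] <- mass / sum(mass)
    }
  }
  factors
}

row_tv <- function(p, q) 0.5 * sum(abs(p - q))

#' Parameter-recovery experiment
#'
#' For each cohort size in `n_grid`, simulates a cohort from the ground
#' truth, estimates the transition and observation models from the latent
#' state sequences, and reports the mean per-row total-variation distance of
#' observed transition rows from truth and the mean L1 distance of the
#' observation factors estimated from states with data.
#'
#' @param truth A [make_scenario()] ground truth.
#' @param n_grid Vector of patient counts.
#' @param seed Base seed; cohort `i` uses `seed + i`.
#' @return Data frame with columns `n`, `n_transitions`, `tv_transition`,
#'   `l1_observation`.
#' @export
recovery_experiment <- function(truth, n_grid, seed = 1L) {
  out <- lapply(seq_along(n_grid), function(i) {
    sc <- simulate_cohort(truth, n_grid[i], seed = seed + i)
    tr <- latent_transitions(sc)
    tm <- estimate_transitions(tr)
    tvs <- c()
    for (st in transient_states()) {
      for (a in seq_len(n_actions())) {
        if (sum(tm$counts[st, a, ]) > 0) {
          tvs <- c(tvs, row_tv(tm$probs[st, a, ], truth$T[st, a, ]))
        }
      }
    }
    snaps <- sc$cohort
    snaps$state <- sc$latent$state[match(
      paste(snaps$patient_id, snaps$timestamp),
      paste(sc$latent$patient_id, sc$latent$timestamp))]
    snaps <- snaps[!(snaps$state %in% absorbing_states()), ]
    samples <- collect_vital_samples(snaps)
    binning <- suppressWarnings(build_binning(samples))
    om <- suppressWarnings(estimate_observation_model(snaps, binning))
    tf <- true_observation_factors(truth, binning$global)
    l1 <- c()
    for (st in transient_states()) {
      for (k in seq_along(obs_vitals())) {
        x <- snaps[[obs_vitals()[k]]][snaps$state == st]
        if (sum(is.finite(x)) >= 10) {
          l1 <- c(l1, sum(abs(om$factors[st, k, ] - tf[st, k, ])))
        }
      }
    }
    data.frame(n = n_grid[i], n_transitions = nrow(tr),
               tv_transition = mean(tvs), l1_observation = mean(l1))
  })
  do.call(rbind, out)
}
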