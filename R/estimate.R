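#' Estimate the transition model from state-action-next-state triples
#'
#' `P(s' | s, a)` is the empirical frequency of `(s, a, s')` among all
#' transitions leaving `(s, a)`. Unobserved `(state, action)` pairs back off
#' to the action-marginalized row for that state; states never observed at
#' all back off to the uniform distribution over non-absorbing states.
#' DISMISSAL and DEATH rows are forced unit self-loops under every action.
#'
#' @param transitions Data frame with columns `state`, `action` (0-based
#'   index in `[0, n_actions)`) and `next_state`.
#' @param states State label order (default [sepsis_states()]).
#' @param n_actions Number of actions (default 32).
#' @param smoothing Optional additive (Laplace) count, default 0 (pure
#'   frequencies).
#' @param min_support Minimum number of transitions a (state, action) pair
#'   needs before its own frequencies are trusted; pairs at or below the
#'   threshold are flagged and backed off like unobserved pairs. Default 0
#'   (any observation counts); the estimation pipeline uses 10, mirroring
#'   the sufficient-data rule applied to observation bins.
#' @return An object of class `transition_model` with `probs` (array
#'   `[state, action, next_state]`), integer `counts`, and a logical
#'   `backoff` matrix flagging unobserved pairs.
#' @export
estimate_transitions <- function(transitions, states = sepsis_states(),
                                 n_actions = 32L, smoothing = 0,
                                 min_support = 0L) {
  if (is.null(transitions) || nrow(transitions) == 0) {
    stop(structure(class = c("sepsisCDSS_no_data", "error", "condition"),
                   list(message = "no transitions: cannot estimate", call = NULL)))
  }
  S <- length(states)
  s <- state_index(transitions$state, states)
  sn <- state_index(transitions$next_state, states)
  a <- as.integer(transitions$action) + 1L
  if (any(is.na(a)) || any(a < 1) || any(a > n_actions)) {
    stop("action indices must lie in [0, ", n_actions, ")")
  }
  flat <- (s - 1L) + (a - 1L) * S + (sn - 1L) * S * n_actions
  counts <- array(tabulate(flat + 1L, S * n_actions * S),
                  dim = c(S, n_actions, S),
                  dimnames = list(states, NULL, states))
  work <- counts + smoothing
  probs <- array(0, dim(counts), dimnames = dimnames(counts))
  backoff <- matrix(FALSE, S, n_actions, dimnames = list(states, NULL))
  absorbing <- states %in% absorbing_states()
  transient <- !absorbing
  marg <- apply(counts, c(1, 3), sum)  # action-marginalized counts per state
  for (i in seq_len(S)) {
    if (absorbing[i]) {
      probs[i, , i] <- 1
      next
    }
    for (j in seq_len(n_actions)) {
      if (sum(counts[i, j, ]) > max(0L, min_support)) {
        probs[i, j, ] <- work[i, j, ] / sum(work[i, j, ])
      } else {
        backoff[i, j] <- TRUE
        if (sum(marg[i, ]) > 0) {
          probs[i, j, ] <- marg[i, ] / sum(marg[i, ])
        } else {
          probs[i, j, transient] <- 1 / sum(transient)
        }
      }
    }
  }
  structure(list(probs = probs, counts = counts, backoff = backoff,
                 states = states, n_actions = as.integer(n_actions),
                 smoothing = smoothing),
            class = "transition_model")
}

#' Estimate the factored observation model
#'
#' For each state, five per-vital bin distributions over the scheme's pooled
#' edges plus a Bernoulli blood-culture positivity rate. The default `fitted`
#' mode takes each factor as the fitted per-(state, vital) distribution's
#' mass over the pooled bins; `empirical` mode uses raw bin counts. The joint
#' probability of a code is the product of its six factors (conditional
#' independence given the state).
#'
#' @param snapshots Data frame of labeled snapshots: a `state` column plus
#'   the vitals columns of [obs_vitals()] and `blood_culture`.
#' @param binning A [build_binning()] scheme.
#' @param states State label order.
#' @param mode `"fitted"` or `"empirical"`.
#' @return An object of class `observation_model` with `factors` (array
#'   `[state, vital, bin]`), `blood_rate`, and the pooled edges/modal bins
#'   used for encoding.
#' @export
estimate_observation_model <- function(snapshots, binning,
                                       states = sepsis_states(),
                                       mode = c("fitted", "empirical")) {
  mode <- match.arg(mode)
  stopifnot(inherits(binning, "binning_scheme"))
  vitals <- obs_vitals()
  S <- length(states)
  nb <- binning$n_bins
  factors <- array(1 / nb, dim = c(S, length(vitals), nb),
                   dimnames = list(states, vitals, NULL))
  blood_rate <- stats::setNames(rep(0.5, S), states)
  st_col <- as.character(snapshots$state)
  culture <- normalize_culture(snapshots$blood_culture)
  for (i in seq_len(S)) {
    st <- states[i]
    rows <- which(st_col == st)
    if (length(rows) == 0) {
      warning("state ", st, " has no snapshots: uniform observation factors")
      next
    }
    blood_rate[i] <- mean(culture[rows] == "positive")
    for (k in seq_along(vitals)) {
      vt <- vitals[k]
      g <- binning$global[[vt]]
      x <- as.numeric(snapshots[[vt]][rows])
      x <- x[is.finite(x)]
      if (mode == "empirical") {
        if (length(x) == 0) next  # keep uniform factor
        counts <- tabulate(assign_bin(x, g$edges) + 1L, nb)
        factors[i, k, ] <- counts / sum(counts)
      } else {
        entry <- binning$entries[[st]][[vt]]
        if (is.null(entry)) {
          if (length(x) == 0) next
          counts <- tabulate(assign_bin(x, g$edges) + 1L, nb)
          factors[i, k, ] <- counts / sum(counts)
        } else {
          factors[i, k, ] <- bin_probabilities(g$edges, entry$fit)
        }
      }
    }
  }
  structure(list(factors = factors, blood_rate = blood_rate, states = states,
                 vitals = vitals, n_bins = nb,
                 global = binning$global[vitals], mode = mode),
            class = "observation_model")
}

#' Probability of one observation code given a state
#'
#' @param om An `observation_model`.
#' @param state State label or index.
#' @param code Observation code(s) in `[0, 6250)`.
#' @return Numeric vector of probabilities.
#' @export
observation_prob <- function(om, state, code) {
  i <- if (is.character(state)) state_index(state, om$states) else as.integer(state)
  dec <- decode_observation(code)
  p <- rep(1, length(code))
  for (k in seq_along(om$vitals)) {
    p <- p * om$factors[i, k, dec$vital_bins[, k] + 1L]
  }
  rate <- om$blood_rate[i]
  p * ifelse(dec$blood_flag == 1, rate, 1 - rate)
}

#' Dense observation matrix
#'
#' Expands the factored model into the full `states x 6250` matrix; each row
#' sums to 1 by construction.
#'
#' @param om An `observation_model`.
#' @return Numeric matrix `[state, code]`.
#' @export
observation_matrix <- function(om) {
  S <- length(om$states)
  Z <- om$n_bins^length(om$vitals) * 2L
  z <- 0:(Z - 1L)
  dec <- decode_observation(z)
  M <- matrix(0, S, Z, dimnames = list(om$states, NULL))
  for (i in seq_len(S)) {
    p <- rep(1, Z)
    for (k in seq_along(om$vitals)) {
      p <- p * om$factors[i, k, dec$vital_bins[, k] + 1L]
    }
    rate <- om$blood_rate[i]
    M[i, ] <- p * ifelse(dec$blood_flag == 1, rate, 1 - rate)
  }
  M
}
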