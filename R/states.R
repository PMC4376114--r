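#' The ten-state clinical state space
#'
#' The model distinguishes eight clinical states derived from vitals and blood
#' cultures plus two absorbing outcome states. States are returned in severity
#' order, best to worst, which is also the canonical index order used by every
#' matrix and tensor in the package: DISMISSAL, NO_SIRS, PS (probable SIRS),
#' SIRS, BACTEREMIA, BPS (bacteremia probable sepsis), PSS (probable septic
#' shock), SEPSIS, SEPTIC_SHOCK, DEATH.
#'
#' @return Character vector of the ten state labels, best to worst.
#' @export
sepsis_states <- function() {
  c("DISMISSAL", "NO_SIRS", "PS", "SIRS", "BACTEREMIA",
    "BPS", "PSS", "SEPSIS", "SEPTIC_SHOCK", "DEATH")
}

#' Absorbing outcome states
#'
#' DISMISSAL and DEATH terminate a trajectory: their transition rows are unit
#' self-loops under every action.
#'
#' @return Character vector of the two absorbing labels.
#' @export
absorbing_states <- function() c("DISMISSAL", "DEATH")

#' Non-absorbing (treatable) states
#'
#' @return Character vector of the eight clinical states that admit treatment.
#' @export
transient_states <- function() setdiff(sepsis_states(), absorbing_states())

#' Default per-state reward table
#'
#' Physician-elicited rewards, attached to the state reached: DISMISSAL
#' 100000 ("healthy" outcome), NO_SIRS 50000, PS 5000, SIRS -50, BACTEREMIA
#' -10000, BPS -12500, PSS -15000, SEPSIS -40000, SEPTIC_SHOCK -60000,
#' DEATH -100000. The ranking of these rewards defines the severity order.
#'
#' @return Named numeric vector over [sepsis_states()].
#' @export
default_rewards <- function() {
  c(DISMISSAL = 100000, NO_SIRS = 50000, PS = 5000, SIRS = -50,
    BACTEREMIA = -10000, BPS = -12500, PSS = -15000, SEPSIS = -40000,
    SEPTIC_SHOCK = -60000, DEATH = -100000)
}

#' Severity ranking of states
#'
#' @param states Character vector giving the order, best to worst.
#' @return Named integer vector: rank 1 is best (DISMISSAL), rank 10 worst
#'   (DEATH).
#' @export
severity_rank <- function(states = sepsis_states()) {
  stats::setNames(seq_along(states), states)
}

state_index <- function(labels, states = sepsis_states()) {
  idx <- match(labels, states)
  if (anyNA(idx)) {
    stop("unknown state label(s): ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Compare two states under the severity order
#'
#' Classifies the move `from -> to` relative to the best-to-worst severity
#' ranking. Vectorized over both arguments.
#'
#' @param from,to State labels (see [sepsis_states()]).
#' @param states Severity order, best to worst.
#' @return Character vector with elements `"better"`, `"same"` or `"worse"`.
#' @export
compare_states <- function(from, to, states = sepsis_states()) {
  rf <- state_index(from, states)
  rt <- state_index(to, states)
  ifelse(rt < rf, "better", ifelse(rt > rf, "worse", "same"))
}
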