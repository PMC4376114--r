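#' The five named antibiotics
#'
#' The most frequently administered antibiotics in the source cohort, in the
#' canonical bit order used by the action index.
#'
#' @return Character vector of length 5.
#' @export
antibiotic_names <- function() {
  c("VANCOMYCIN", "CEFEPIME", "METRONIDAZOLE", "CEFTRIAXONE", "MEROPENEM")
}

#' Number of antibiotic actions
#' @return 32: the 31 non-empty subsets of the five named drugs plus one
#'   catch-all action for any other antibiotic.
#' @export
n_actions <- function() 32L

new_action <- function(index, drug_set, other_flag) {
  structure(list(index = as.integer(index),
                 drug_set = drug_set,
                 other_flag = other_flag),
            class = "antibiotic_action")
}

#' Enumerate the 32-action antibiotic space
#'
#' Action 0 is the catch-all "other antibiotics" action; actions 1-31 are the
#' non-empty subsets of the five named drugs, indexed by bitmask (bit k set
#' means drug `antibiotic_names()[k+1]` is in the combination).
#'
#' @return Data frame with columns `index`, `drugs` (semicolon-joined) and
#'   `other_flag`.
#' @export
antibiotic_actions <- function() {
  drugs <- vapply(0:31, function(i) {
    if (i == 0) "" else paste(action_drugs(i), collapse = ";")
  }, character(1))
  data.frame(index = 0:31, drugs = drugs,
             other_flag = c(TRUE, rep(FALSE, 31)))
}

#' Drug set of an action index
#'
#' @param index Integer action index in `[0, 32)`.
#' @return Character vector of drug names; empty for the catch-all action 0.
#' @export
action_drugs <- function(index) {
  stopifnot(length(index) == 1, index >= 0, index < 32)
  if (index == 0) return(character(0))
  antibiotic_names()[bitwAnd(index, 2^(0:4)) > 0]
}

#' Decode an action index
#'
#' @param index Integer in `[0, 32)`.
#' @return An `antibiotic_action` with its drug set and catch-all flag.
#' @export
decode_action <- function(index) {
  new_action(index, action_drugs(index), index == 0)
}

#' Encode an administered drug set as an action
#'
#' The intersection of `drugs` with the five named antibiotics determines the
#' subset action; if the intersection is empty but other antibiotics were
#' given, the catch-all action (index 0) fires. An empty input is not an
#' action and raises a condition of class `sepsisCDSS_no_action`.
#'
#' @param drugs Character vector of administered antibiotic names.
#' @return An `antibiotic_action`.
#' @export
encode_action <- function(drugs) {
  drugs <- drugs[!is.na(drugs) & nzchar(drugs)]
  if (length(drugs) == 0) {
    stop(structure(class = c("sepsisCDSS_no_action", "error", "condition"),
                   list(message = "no antibiotics administered: not an action",
                        call = sys.call(-1))))
  }
  named <- match(toupper(drugs), antibiotic_names())
  named <- named[!is.na(named)]
  if (length(named) == 0) return(decode_action(0L))
  mask <- sum(2^(unique(named) - 1L))
  decode_action(as.integer(mask))
}

# Vectorized: semicolon-joined antibiotics strings -> action index, NA for
# empty administrations (no action).
action_index_from_string <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_integer_)
    encode_action(strsplit(s, ";", fixed = TRUE)[[1]])$index
  }, integer(1), USE.NAMES = FALSE)
}

#' @export
print.antibiotic_action <- function(x, ...) {
  lab <- if (x$other_flag) "<other antibiotics>" else paste(x$drug_set, collapse = "+")
  cat(sprintf("antibiotic action %d: %s\n", x$index, lab))
  invisible(x)
}
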