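#' Vitals entering the observation model
#'
#' Heart rate is used for SIRS labeling but is not part of the observation
#' space; the five observation vitals, in code order (least-significant digit
#' first), are temperature, respiratory rate, WBC, MAP and SBP.
#'
#' @return Character vector of length 5.
#' @export
obs_vitals <- function() c("temperature", "respiratory_rate", "wbc", "map", "sbp")

#' Number of observation codes
#' @return 6250 = 2 * 5^5 (five vitals in five bins each, one binary
#'   blood-culture flag).
#' @export
n_observation_codes <- function() 6250L

#' Compose an observation index from bins and blood flag
#'
#' `index = blood_flag * 5^5 + sum_k vital_bins[k] * 5^k`, a bijection onto
#' `[0, 6250)`.
#'
#' @param vital_bins Integer vector of 5 bin indices in `[0, 5)`, in
#'   [obs_vitals()] order, or a matrix with 5 columns for many codes at once.
#' @param blood_flag 0/1 blood-culture positivity flag(s).
#' @return Integer index (vector) in `[0, 6250)`.
#' @export
observation_index <- function(vital_bins, blood_flag) {
  if (is.matrix(vital_bins)) {
    stopifnot(ncol(vital_bins) == 5)
    as.integer(vital_bins %*% 5^(0:4) + as.integer(blood_flag) * 3125L)
  } else {
    stopifnot(length(vital_bins) == 5)
    as.integer(sum(vital_bins * 5^(0:4)) + as.integer(blood_flag) * 3125L)
  }
}

#' Decompose an observation index
#'
#' @param index Integer (vector) in `[0, 6250)`.
#' @return A list with `vital_bins` (matrix, columns named by [obs_vitals()])
#'   and `blood_flag`.
#' @export
decode_observation <- function(index) {
  stopifnot(all(index >= 0), all(index < 6250))
  blood <- index %/% 3125L
  rest <- index %% 3125L
  bins <- sapply(0:4, function(k) (rest %/% 5L^k) %% 5L)
  if (is.null(dim(bins))) bins <- matrix(bins, nrow = 1)
  colnames(bins) <- obs_vitals()
  list(vital_bins = bins, blood_flag = as.integer(blood))
}

# Bin assignment over 6 edges: half-open [e_k, e_{k+1}) with the top bin
# closed; out-of-range values clamp to the extreme bins.
assign_bin <- function(x, edges) {
  findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE) - 1L
}

#' Encode a vitals snapshot as an observation code
#'
#' Each present vital is mapped to its bin under the scheme's pooled
#' (state-unconditional) edges; a missing vital is imputed with the pooled
#' modal bin and flagged. The blood flag is 1 iff the culture is positive
#' (a missing culture counts as no observed bacteria).
#'
#' @param v A [vitals_snapshot()].
#' @param binning A [build_binning()] scheme.
#' @return A list with `index`, `vital_bins`, `blood_flag` and `imputed`
#'   (logical vector flagging imputed vitals).
#' @export
encode_observation <- function(v, binning) {
  v <- as_snapshot(v)
  stopifnot(inherits(binning, "binning_scheme"))
  vitals <- obs_vitals()
  bins <- integer(5)
  imputed <- logical(5)
  for (k in seq_along(vitals)) {
    g <- binning$global[[vitals[k]]]
    x <- v[[vitals[k]]]
    if (is.na(x)) {
      bins[k] <- g$modal_bin
      imputed[k] <- TRUE
    } else {
      bins[k] <- assign_bin(x, g$edges)
    }
  }
  blood <- as.integer(identical(v$blood_culture, "positive"))
  list(index = observation_index(bins, blood),
       vital_bins = bins, blood_flag = blood, imputed = imputed)
}

# Vectorized over a cohort table; returns 0-based codes.
encode_observations <- function(df, binning) {
  n <- nrow(df)
  bins <- matrix(0L, n, 5)
  vitals <- obs_vitals()
  for (k in seq_along(vitals)) {
    g <- binning$global[[vitals[k]]]
    x <- as.numeric(df[[vitals[k]]])
    b <- rep(g$modal_bin, n)
    ok <- !is.na(x)
    b[ok] <- assign_bin(x[ok], g$edges)
    bins[, k] <- b
  }
  blood <- as.integer(normalize_culture(df$blood_culture) == "positive")
  observation_index(bins, blood)
}
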