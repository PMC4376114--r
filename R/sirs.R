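#' A single timestamped vitals snapshot
#'
#' Container for one measurement record. Any numeric field may be missing
#' (`NA`); present values must be finite and strictly positive. Units:
#' temperature in degrees Celsius, heart rate in beats/min, respiratory rate
#' in breaths/min, WBC in cells/mm^3, MAP and SBP in mm Hg.
#'
#' @param temperature,heart_rate,respiratory_rate,wbc,map,sbp Numeric scalars
#'   or `NA`.
#' @param blood_culture One of `"missing"`, `"positive"`, `"negative"`.
#' @param timestamp Non-negative time of the measurement.
#' @return An object of class `vitals_snapshot`.
#' @export
vitals_snapshot <- function(temperature = NA_real_, heart_rate = NA_real_,
                            respiratory_rate = NA_real_, wbc = NA_real_,
                            map = NA_real_, sbp = NA_real_,
                            blood_culture = c("missing", "positive", "negative"),
                            timestamp = 0) {
  blood_culture <- match.arg(blood_culture)
  fields <- list(temperature = temperature, heart_rate = heart_rate,
                 respiratory_rate = respiratory_rate, wbc = wbc,
                 map = map, sbp = sbp)
  for (nm in names(fields)) {
    x <- fields[[nm]]
    if (length(x) != 1) stop(nm, " must be a scalar")
    if (!is.na(x) && (!is.finite(x) || x <= 0)) {
      stop(nm, " must be finite and strictly positive (got ", x, ")")
    }
  }
  if (!is.finite(timestamp) || timestamp < 0) stop("timestamp must be >= 0")
  structure(c(lapply(fields, as.numeric),
              list(blood_culture = blood_culture,
                   timestamp = as.numeric(timestamp))),
            class = "vitals_snapshot")
}

as_snapshot <- function(v) {
  if (inherits(v, "vitals_snapshot")) return(v)
  do.call(vitals_snapshot, v)
}

#' Count satisfied SIRS criteria
#'
#' The four SIRS criteria are evaluated only on the fields that are present:
#' HR > 90 beats/min, RR > 20 breaths/min, temperature > 38 or < 36 degrees C,
#' WBC > 12000 or < 4000 cells/mm^3. All comparisons are strict.
#'
#' @param v A [vitals_snapshot()] (or a named list coercible to one).
#' @return A list with `met` (criteria satisfied, 0-4) and `evaluable`
#'   (criteria with a present measurement, 0-4).
#' @export
count_sirs_criteria <- function(v) {
  v <- as_snapshot(v)
  crit <- c(
    hr   = if (is.na(v$heart_rate)) NA else v$heart_rate > 90,
    rr   = if (is.na(v$respiratory_rate)) NA else v$respiratory_rate > 20,
    temp = if (is.na(v$temperature)) NA else (v$temperature > 38 || v$temperature < 36),
    wbc  = if (is.na(v$wbc)) NA else (v$wbc > 12000 || v$wbc < 4000)
  )
  list(met = sum(crit, na.rm = TRUE), evaluable = sum(!is.na(crit)))
}

#' Hypotension predicate
#'
#' Hypotension holds when SBP < 90 mm Hg or MAP < 70 mm Hg on the present
#' fields. With both pressures missing the predicate is undeterminable (`NA`);
#' a single present, non-low pressure yields `FALSE`.
#'
#' @param v A [vitals_snapshot()].
#' @return `TRUE`, `FALSE` or `NA` (undeterminable).
#' @export
is_hypotensive <- function(v) {
  v <- as_snapshot(v)
  if (is.na(v$sbp) && is.na(v$map)) return(NA)
  isTRUE(v$sbp < 90) || isTRUE(v$map < 70)
}

# SIRS status is undeterminable when fewer than 2 criteria are evaluable and
# fewer than 2 are already met; 2 met criteria settle it regardless of
# missingness.
sirs_undeterminable <- function(met, evaluable) evaluable < 2 & met < 2

#' Label the clinical state of a snapshot
#'
#' Applies the state-definition rules in strict most-severe-first priority:
#' SEPTIC_SHOCK (>=2 SIRS criteria, positive culture, hypotensive), SEPSIS
#' (>=2 SIRS criteria, positive culture), PSS (positive culture, hypotensive,
#' SIRS undeterminable), BPS (positive culture, SIRS undeterminable),
#' BACTEREMIA (positive culture, SIRS determinable and not met), SIRS (>=2
#' criteria, no infection evidence), PS (no infection evidence, SIRS
#' undeterminable), NO_SIRS otherwise. A supplied outcome event short-circuits
#' to DEATH or DISMISSAL.
#'
#' @param v A [vitals_snapshot()].
#' @param outcome Optional `"death"` or `"dismissal"` (or `"none"`/`NULL`).
#' @return A single state label from [sepsis_states()].
#' @export
label_state <- function(v, outcome = NULL) {
  if (!is.null(outcome) && !is.na(outcome) && outcome != "none") {
    return(switch(outcome, death = "DEATH", dismissal = "DISMISSAL",
                  stop("unknown outcome event: ", outcome)))
  }
  v <- as_snapshot(v)
  s <- count_sirs_criteria(v)
  pos <- identical(v$blood_culture, "positive")
  sirs <- s$met >= 2
  undet <- sirs_undeterminable(s$met, s$evaluable)
  hypo <- isTRUE(is_hypotensive(v))
  if (sirs && pos && hypo) return("SEPTIC_SHOCK")
  if (sirs && pos) return("SEPSIS")
  if (pos && undet && hypo) return("PSS")
  if (pos && undet) return("BPS")
  if (pos) return("BACTEREMIA")
  if (sirs) return("SIRS")
  if (undet) return("PS")
  "NO_SIRS"
}

normalize_culture <- function(x) {
  x <- tolower(as.character(x))
  out <- rep("missing", length(x))
  out[x %in% c("pos", "positive", "1", "true")] <- "positive"
  out[x %in% c("neg", "negative", "0", "false")] <- "negative"
  out
}

#' Label every row of a cohort table
#'
#' Vectorized equivalent of [label_state()] over the cohort layout described
#' in [read_cohort()].
#'
#' @param df Data frame with the cohort columns (`temperature`, `heart_rate`,
#'   `respiratory_rate`, `wbc`, `map`, `sbp`, `blood_culture`, and optionally
#'   `outcome`).
#' @return Character vector of state labels, one per row.
#' @export
label_states <- function(df) {
  n <- nrow(df)
  num <- function(col) if (col %in% names(df)) as.numeric(df[[col]]) else rep(NA_real_, n)
  temp <- num("temperature"); hr <- num("heart_rate")
  rr <- num("respiratory_rate"); wbc <- num("wbc")
  map <- num("map"); sbp <- num("sbp")
  c_hr   <- ifelse(is.na(hr), NA, hr > 90)
  c_rr   <- ifelse(is.na(rr), NA, rr > 20)
  c_temp <- ifelse(is.na(temp), NA, temp > 38 | temp < 36)
  c_wbc  <- ifelse(is.na(wbc), NA, wbc > 12000 | wbc < 4000)
  crit <- cbind(c_hr, c_rr, c_temp, c_wbc)
  met <- rowSums(crit, na.rm = TRUE)
  evaluable <- rowSums(!is.na(crit))
  pos <- normalize_culture(df$blood_culture) == "positive"
  undet <- sirs_undeterminable(met, evaluable)
  sirs <- met >= 2
  hypo <- (!is.na(sbp) & sbp < 90) | (!is.na(map) & map < 70)

  out <- rep("NO_SIRS", n)
  out[undet & !pos] <- "PS"
  out[sirs & !pos] <- "SIRS"
  out[pos & !undet & !sirs] <- "BACTEREMIA"
  out[pos & undet] <- "BPS"
  out[pos & undet & hypo] <- "PSS"
  out[pos & sirs] <- "SEPSIS"
  out[pos & sirs & hypo] <- "SEPTIC_SHOCK"
  if ("outcome" %in% names(df)) {
    oc <- as.character(df$outcome)
    out[!is.na(oc) & oc == "death"] <- "DEATH"
    out[!is.na(oc) & oc == "dismissal"] <- "DISMISSAL"
  }
  out
}
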