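#' Cohort file column layout
#'
#' @return Character vector of the canonical cohort CSV columns.
#' @export
cohort_columns <- function() {
  c("patient_id", "timestamp", "temperature", "heart_rate",
    "respiratory_rate", "wbc", "map", "sbp", "blood_culture",
    "antibiotics", "outcome")
}

#' Validate a cohort table
#'
#' Checks the column set, numeric positivity of present vitals, the
#' blood-culture coding (`pos`/`neg`/empty) and the outcome coding
#' (`none`/`death`/`dismissal`).
#'
#' @param df Cohort data frame.
#' @return The validated data frame, invisibly coerced to canonical types.
#' @export
validate_cohort <- function(df) {
  miss <- setdiff(cohort_columns(), names(df))
  if (length(miss)) stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  for (col in c("timestamp", "temperature", "heart_rate", "respiratory_rate",
                "wbc", "map", "sbp")) {
    df[[col]] <- as.numeric(df[[col]])
    x <- df[[col]]
    bad <- !is.na(x) & (!is.finite(x) | (col != "timestamp" & x <= 0))
    if (any(bad)) stop("column ", col, " has non-positive or non-finite values")
  }
  bc <- as.character(df$blood_culture)
  bc[is.na(bc)] <- ""
  if (!all(bc %in% c("pos", "neg", "", "positive", "negative", "missing"))) {
    stop("blood_culture must be one of pos/neg/empty")
  }
  df$blood_culture <- bc
  oc <- as.character(df$outcome)
  oc[is.na(oc) | oc == ""] <- "none"
  if (!all(oc %in% c("none", "death", "dismissal"))) {
    stop("outcome must be none/death/dismissal")
  }
  df$outcome <- oc
  ab <- as.character(df$antibiotics)
  ab[is.na(ab)] <- ""
  df$antibiotics <- ab
  df$patient_id <- as.character(df$patient_id)
  df[order(df$patient_id, df$timestamp), cohort_columns(), drop = FALSE]
}

#' Read a cohort CSV
#'
#' Expects the layout of [cohort_columns()]: one row per timestamped record,
#' missing numeric values as empty cells, `blood_culture` coded `pos`/`neg`/
#' empty, `antibiotics` as a semicolon-joined drug list and `outcome` as
#' `none`/`death`/`dismissal`.
#'
#' @param path Path to the CSV file.
#' @return A validated cohort data frame ordered by patient and timestamp.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character",
                                       blood_culture = "character",
                                       antibiotics = "character",
                                       outcome = "character"))
  validate_cohort(df)
}

#' Write a cohort CSV
#'
#' @param df Cohort data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(df, path) {
  df <- validate_cohort(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Export the state/action/observation code books
#'
#' Writes a JSON file describing the state labels and severity order, the
#' 32-action encoding and the observation index layout, for reproducibility
#' of any serialized model or policy.
#'
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
export_codebooks <- function(path) {
  book <- list(
    states = list(order_best_to_worst = sepsis_states(),
                  absorbing = absorbing_states(),
                  rewards = as.list(default_rewards())),
    actions = antibiotic_actions(),
    observations = list(vitals = obs_vitals(), bins_per_vital = 5,
                        blood_flag_weight = 3125,
                        index_formula = "blood*5^5 + sum_k bin_k*5^k",
                        n_codes = n_observation_codes())
  )
  jsonlite::write_json(book, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
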