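#' Was the policy followed?
#'
#' A recorded treatment follows a policy action when at least one of the
#' policy's antibiotics was administered. A catch-all policy action is
#' followed when any non-named antibiotic was administered.
#'
#' @param action Policy action: an `antibiotic_action` or a 0-based index.
#' @param administered Character vector of administered drug names (possibly
#'   empty).
#' @return Logical.
#' @export
policy_followed <- function(action, administered) {
  act <- if (inherits(action, "antibiotic_action")) action else decode_action(action)
  administered <- toupper(administered[!is.na(administered) & nzchar(administered)])
  if (act$other_flag) {
    length(setdiff(administered, antibiotic_names())) > 0
  } else {
    length(intersect(act$drug_set, administered)) > 0
  }
}

#' One-sided hypergeometric enrichment test
#'
#' Tail probability of observing at least the given number of favorable
#' transitions in the followed arm, given the table margins. A zero margin
#' yields p = 1 by convention.
#'
#' @param tab 2x2 integer matrix: rows followed/not-followed, columns
#'   favorable/not-favorable.
#' @return The raw one-sided p-value.
#' @export
enrichment_test <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  k <- tab[1, 1]
  n <- sum(tab[1, ])
  K <- sum(tab[, 1])
  N <- sum(tab)
  if (N == 0 || K == 0 || n == 0 || K == N || n == N) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' @param p Numeric vector of raw p-values (the family is all tests emitted
#'   in one evaluation run).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Patient-level fold split
#'
#' Partitions patients into k folds of sizes within one of each other, after
#' a seeded shuffle; no patient appears in more than one test fold.
#'
#' @param patients Vector of patient identifiers.
#' @param k Number of folds (default 5).
#' @param seed Optional RNG seed.
#' @return List of `k` lists with `train` and `test` patient-id vectors.
#' @export
kfold_split <- function(patients, k = 5, seed = NULL) {
  patients <- unique(patients)
  if (length(patients) < k) stop("fewer patients (", length(patients),
                                 ") than folds (", k, ")")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample(patients)
  fold <- rep(seq_len(k), length.out = length(perm))
  lapply(seq_len(k), function(f) {
    list(train = perm[fold != f], test = perm[fold == f])
  })
}

# Walk one patient's records, tracking the belief and classifying each
# transition. Returns a per-transition data frame.
walk_patient <- function(rows, labels, policy, model, binning) {
  n <- nrow(rows)
  if (n < 2) return(NULL)
  codes <- encode_observations(rows, binning)
  b <- model$b0
  upd0 <- tryCatch({
    w <- model$O[, codes[1] + 1L] * b
    if (sum(w) > 0) w / sum(w) else b
  }, error = function(e) b)
  b <- upd0
  out <- vector("list", n - 1)
  for (t in seq_len(n - 1)) {
    drugs <- strsplit(rows$antibiotics[t], ";", fixed = TRUE)[[1]]
    rec <- extract_action(policy, b)
    followed <- policy_followed(rec$action, drugs)
    out[[t]] <- data.frame(
      patient = rows$patient_id[1], step = t,
      from_state = labels[t], to_state = labels[t + 1],
      outcome_class = compare_states(labels[t], labels[t + 1]),
      policy_action = rec$action, followed = followed,
      stringsAsFactors = FALSE)
    a_idx <- if (length(drugs) == 0 || !nzchar(rows$antibiotics[t])) 0L else
      encode_action(drugs)$index
    b <- tryCatch(belief_update(b, a_idx, codes[t + 1], model)$belief,
                  sepsisCDSS_inconsistent_observation = function(e) model$b0)
  }
  do.call(rbind, out)
}

arm_counts <- function(records) {
  classes <- c("better", "same", "worse")
  arms <- c(followed = TRUE, not_followed = FALSE)
  counts <- sapply(arms, function(f) {
    sub <- records$outcome_class[records$followed == f]
    vapply(classes, function(cl) sum(sub == cl), numeric(1))
  })
  counts <- t(counts)  # arms x classes
  pct <- counts / pmax(rowSums(counts), 1) * 100
  list(counts = counts, percentages = pct)
}

#' Retrospectively evaluate a policy on test trajectories
#'
#' Replays each patient's trajectory, maintaining the running belief with the
#' actually administered actions and observed vitals, querying the policy at
#' every step, splitting transitions into followed / not-followed arms via
#' [policy_followed()] and classifying each transition against the severity
#' order. Hypergeometric enrichment tests (BH-adjusted over the emitted
#' family) compare the arms.
#'
#' @param cohort Test cohort table (see [read_cohort()]).
#' @param policy Solved [alpha_policy()].
#' @param model The [pomdp_model()] used for belief tracking.
#' @param binning The [build_binning()] scheme used for observation encoding.
#' @return An object of class `evaluation_report`: per-arm counts and
#'   percentages, per-state breakdown, per-transition `records`, trajectory
#'   statistics and the test table.
#' @export
evaluate_transitions <- function(cohort, policy, model, binning) {
  cohort <- validate_cohort(cohort)
  cohort$state <- label_states(cohort)
  recs <- lapply(split(cohort, cohort$patient_id), function(rows) {
    rows <- rows[order(rows$timestamp), ]
    walk_patient(rows, rows$state, policy, model, binning)
  })
  records <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(records) || nrow(records) == 0) stop("no transitions to evaluate")
  rownames(records) <- NULL
  ac <- arm_counts(records)
  by_state <- table(from = records$from_state,
                    arm = ifelse(records$followed, "followed", "not_followed"),
                    class = records$outcome_class)
  tests <- evaluation_tests(records)
  structure(list(counts = ac$counts, percentages = ac$percentages,
                 by_state = by_state, records = records,
                 trajectory = trajectory_statistics(records),
                 tests = tests, n_transitions = nrow(records)),
            class = "evaluation_report")
}

evaluation_tests <- function(records) {
  f <- records$followed
  mk <- function(cl, arm_followed) {
    fav <- if (identical(cl, "better_or_same")) {
      records$outcome_class %in% c("better", "same")
    } else records$outcome_class == cl
    if (!arm_followed) f <- !f
    tab <- matrix(c(sum(f & fav), sum(f & !fav),
                    sum(!f & fav), sum(!f & !fav)), 2, 2, byrow = TRUE)
    enrichment_test(tab)
  }
  tests <- data.frame(
    test = c("better_in_followed", "better_or_same_in_followed",
             "same_in_not_followed", "worse_in_not_followed"),
    p = c(mk("better", TRUE), mk("better_or_same", TRUE),
          mk("same", FALSE), mk("worse", FALSE)),
    stringsAsFactors = FALSE)
  tests$p_adj <- bh_adjust(tests$p)
  tests
}

#' Trajectory-level 90% statistics
#'
#' Counts, per arm, the patients for whom at least 90% (inclusive) of their
#' transitions in that arm lead to strictly better states, to worse states,
#' and to better-or-same states. Patients with no transitions in an arm are
#' excluded from that arm's denominator. The comparison uses integer
#' arithmetic (`10 * favorable >= 9 * total`) so the boundary is exact.
#'
#' @param records Per-transition records as produced by
#'   [evaluate_transitions()] (columns `patient`, `followed`,
#'   `outcome_class`).
#' @return Data frame with one row per arm: patients evaluated and the
#'   counts/percentages in each >=90% bucket.
#' @export
trajectory_statistics <- function(records) {
  out <- lapply(c(TRUE, FALSE), function(arm) {
    sub <- records[records$followed == arm, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(data.frame(arm = ifelse(arm, "followed", "not_followed"),
                        n_patients = 0, better_ge90 = 0, worse_ge90 = 0,
                        better_or_same_ge90 = 0, pct_better_ge90 = NA_real_,
                        pct_worse_ge90 = NA_real_,
                        pct_better_or_same_ge90 = NA_real_))
    }
    per <- split(sub$outcome_class, sub$patient)
    tot <- lengths(per)
    nb <- vapply(per, function(x) sum(x == "better"), numeric(1))
    nw <- vapply(per, function(x) sum(x == "worse"), numeric(1))
    nbs <- vapply(per, function(x) sum(x %in% c("better", "same")), numeric(1))
    b90 <- sum(10 * nb >= 9 * tot)
    w90 <- sum(10 * nw >= 9 * tot)
    bs90 <- sum(10 * nbs >= 9 * tot)
    data.frame(arm = ifelse(arm, "followed", "not_followed"),
               n_patients = length(tot), better_ge90 = b90, worse_ge90 = w90,
               better_or_same_ge90 = bs90,
               pct_better_ge90 = 100 * b90 / length(tot),
               pct_worse_ge90 = 100 * w90 / length(tot),
               pct_better_or_same_ge90 = 100 * bs90 / length(tot))
  })
  do.call(rbind, out)
}

#' Per-state optimal drug-combination table
#'
#' Evaluates the policy at the point-mass belief of every non-absorbing state
#' (belief/probability of 1 in that state) and reports the proposed drug
#' combination.
#'
#' @param policy Solved [alpha_policy()].
#' @param model The matching [pomdp_model()].
#' @return Data frame with `state`, 0-based `action` and the `drugs` string.
#' @export
per_state_policy_table <- function(policy, model) {
  sts <- intersect(model$states, transient_states())
  rows <- lapply(sts, function(st) {
    b <- as.numeric(model$states == st)
    rec <- extract_action(policy, b)
    drugs <- if (rec$action == 0) "<other antibiotics>" else
      paste(action_drugs(rec$action), collapse = ";")
    data.frame(state = st, action = rec$action, drugs = drugs,
               runner_up_action = rec$runner_up_action,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Policy evaluation over", x$n_transitions, "transitions\n")
  cat("\nTransitions per arm (counts):\n")
  print(x$counts)
  cat("\nTransitions per arm (%):\n")
  print(round(x$percentages, 1))
  cat("\nTrajectory-level >=90% statistics:\n")
  print(x$trajectory, row.names = FALSE)
  cat("\nEnrichment tests (hypergeometric, BH-adjusted):\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}
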