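# Per-(state, vital) samples for distribution fitting; absorbing rows carry
# no vitals and are skipped.
collect_vital_samples <- function(labeled) {
  out <- list()
  for (st in transient_states()) {
    sub <- labeled[labeled$state == st, , drop = FALSE]
    out[[st]] <- lapply(stats::setNames(nm = obs_vitals()), function(vt) {
      x <- as.numeric(sub[[vt]])
      x[is.finite(x)]
    })
  }
  out
}

#' Extract labeled state-action-next-state triples from a cohort
#'
#' One transition per consecutive pair of labeled snapshots within a patient,
#' ordered by timestamp; the action is the antibiotic set recorded at the
#' earlier snapshot. Transitions with no recorded antibiotics carry no action
#' and are dropped (their count is reported in the `dropped` attribute).
#'
#' @param cohort Cohort table; a `state` column is added via [label_states()]
#'   when absent.
#' @return Data frame with `patient`, `state`, `action`, `next_state`.
#' @export
extract_transitions <- function(cohort) {
  if (!"state" %in% names(cohort)) cohort$state <- label_states(cohort)
  by <- split(cohort, cohort$patient_id)
  out <- lapply(by, function(d) {
    d <- d[order(d$timestamp), ]
    n <- nrow(d)
    if (n < 2) return(NULL)
    data.frame(patient = d$patient_id[1], state = d$state[-n],
               action = action_index_from_string(d$antibiotics[-n]),
               next_state = d$state[-1], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  dropped <- sum(is.na(res$action))
  res <- res[!is.na(res$action), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  res
}

#' Build a sepsis POMDP from a cohort
#'
#' Labels the cohort, estimates the transition tensor from the labeled
#' triples, fits per-(state, vital) distributions, builds the binning scheme
#' and the factored observation model, and assembles the [pomdp_model()] with
#' the default reward table. The initial belief is the empirical distribution
#' of first-snapshot states (uniform over treatable states as fallback).
#'
#' @param cohort Cohort table (see [read_cohort()]).
#' @param gamma Discount factor (default 0.95).
#' @param rewards Per-state rewards (default [default_rewards()]); overriding
#'   entries replicates the reward-revision hook of the interactive tool.
#' @param obs_mode `"fitted"` or `"empirical"` observation factors.
#' @param smoothing Additive (Laplace) transition smoothing, default 0
#'   (pure frequencies).
#' @param min_support Minimum transition count for a (state, action) row to
#'   be trusted (default 10). With 32 actions, raw frequency rows built from
#'   a handful of transitions are frequently degenerate (probability 1 on a
#'   single lucky next state) and planning on them chases estimation noise;
#'   rows at or below the threshold are backed off to the state's
#'   action-marginal row, the same sufficient-data principle (>10 samples)
#'   applied to observation bins. Set to 0 to trust every observed row.
#' @return List of class `cdss_model_bundle`: `model`, `binning`,
#'   `transitions`, `labeled`, `observation`, `transition`.
#' @export
build_pomdp <- function(cohort, gamma = 0.95, rewards = default_rewards(),
                        obs_mode = "fitted", smoothing = 0,
                        min_support = 10L) {
  cohort <- validate_cohort(cohort)
  cohort$state <- label_states(cohort)
  transitions <- extract_transitions(cohort)
  tm <- estimate_transitions(transitions, smoothing = smoothing,
                             min_support = min_support)
  snaps <- cohort[!(cohort$state %in% absorbing_states()), , drop = FALSE]
  samples <- collect_vital_samples(snaps)
  binning <- suppressWarnings(build_binning(samples))
  om <- suppressWarnings(estimate_observation_model(snaps, binning, mode = obs_mode))
  firsts <- vapply(split(cohort, cohort$patient_id),
                   function(d) d$state[which.min(d$timestamp)], character(1))
  b0 <- as.numeric(table(factor(firsts, levels = sepsis_states())))
  if (sum(b0) == 0 || all(b0[match(transient_states(), sepsis_states())] == 0)) {
    b0 <- as.numeric(sepsis_states() %in% transient_states())
  }
  b0 <- b0 / sum(b0)
  model <- pomdp_model(tm, om, R = rewards, b0 = b0, gamma = gamma,
                       states = sepsis_states())
  structure(list(model = model, binning = binning, transition = tm,
                 observation = om, transitions = transitions,
                 labeled = cohort),
            class = "cdss_model_bundle")
}

#' Solve a model bundle with Perseus
#'
#' @param bundle A [build_pomdp()] bundle (or a bare [pomdp_model()]).
#' @param belief_count Size of the sampled belief set (default 500).
#' @param horizon Simulation depth for belief sampling (default 30).
#' @param tolerance,max_iterations,seed Passed to [perseus_solve()].
#' @return An [alpha_policy()].
#' @export
solve_policy <- function(bundle, belief_count = 500L, horizon = 30L,
                         tolerance = NULL, max_iterations = 1000L, seed = 1L) {
  model <- if (inherits(bundle, "cdss_model_bundle")) bundle$model else bundle
  beliefs <- sample_beliefs(model, belief_count, horizon, seed = seed)
  perseus_solve(model, beliefs, tolerance = tolerance,
                max_iterations = max_iterations, seed = seed + 1L)
}

pool_records <- function(reports) {
  do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]$records
    r$fold <- i
    r
  }))
}

#' End-to-end cross-validated pipeline
#'
#' Splits patients into folds, builds and solves a POMDP on each training
#' fold, evaluates the policy on the held-out patients, pools the
#' per-transition records, and emits both pooled-percentage and
#' per-fold-averaged summaries, trajectory statistics, the BH-adjusted test
#' family (pooled tests plus each fold's better-enrichment test) and the
#' per-state policy table from a full-data solve.
#'
#' @param cohort Cohort table.
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Base seed (fold splits, belief sampling, Perseus).
#' @param gamma Discount factor.
#' @param belief_count,horizon,max_iterations,tolerance Solver settings, see
#'   [solve_policy()].
#' @param solve_full Also solve on the full cohort for the per-state policy
#'   table (default TRUE).
#' @return Object of class `cdss_evaluation`.
#' @export
run_pipeline <- function(cohort, folds = 5L, seed = 1L, gamma = 0.95,
                         belief_count = 500L, horizon = 30L,
                         max_iterations = 1000L, tolerance = NULL,
                         solve_full = TRUE) {
  cohort <- validate_cohort(cohort)
  splits <- kfold_split(unique(cohort$patient_id), k = folds, seed = seed)
  reports <- vector("list", folds)
  for (f in seq_len(folds)) {
    train <- cohort[cohort$patient_id %in% splits[[f]]$train, , drop = FALSE]
    test <- cohort[cohort$patient_id %in% splits[[f]]$test, , drop = FALSE]
    bundle <- build_pomdp(train, gamma = gamma)
    policy <- solve_policy(bundle, belief_count = belief_count,
                           horizon = horizon, tolerance = tolerance,
                           max_iterations = max_iterations,
                           seed = seed + 10L * f)
    reports[[f]] <- evaluate_transitions(test, policy, bundle$model,
                                         bundle$binning)
  }
  records <- pool_records(reports)
  pooled <- arm_counts(records)
  per_fold_pct <- t(vapply(reports, function(r) r$percentages[, "better"],
                           numeric(2)))
  tests <- evaluation_tests(records)[, c("test", "p")]
  for (f in seq_len(folds)) {
    fold_tests <- reports[[f]]$tests
    tests <- rbind(tests, data.frame(
      test = paste0("better_in_followed_fold", f),
      p = fold_tests$p[fold_tests$test == "better_in_followed"]))
  }
  tests$p_adj <- bh_adjust(tests$p)
  policy_table <- NULL
  if (solve_full) {
    full <- build_pomdp(cohort, gamma = gamma)
    full_policy <- solve_policy(full, belief_count = belief_count,
                                horizon = horizon, tolerance = tolerance,
                                max_iterations = max_iterations,
                                seed = seed + 999L)
    policy_table <- per_state_policy_table(full_policy, full$model)
  }
  structure(list(counts = pooled$counts, percentages = pooled$percentages,
                 per_fold_pct_better = per_fold_pct,
                 trajectory = trajectory_statistics(records),
                 tests = tests, records = records,
                 policy_table = policy_table, folds = folds, seed = seed),
            class = "cdss_evaluation")
}

#' @export
print.cdss_evaluation <- function(x, ...) {
  cat(sprintf("Cross-validated CDSS evaluation (%d folds, %d transitions)\n",
              x$folds, nrow(x$records)))
  cat("\nPooled transitions per arm (counts):\n"); print(x$counts)
  cat("\nPooled transitions per arm (%):\n"); print(round(x$percentages, 1))
  cat("\nPer-fold %-better (rows = folds; followed, not_followed):\n")
  print(round(x$per_fold_pct_better, 1))
  cat("\nTrajectory-level >=90% statistics:\n")
  print(x$trajectory, row.names = FALSE)
  cat("\nEnrichment tests:\n"); print(x$tests, row.names = FALSE)
  if (!is.null(x$policy_table)) {
    cat("\nPer-state optimal policy (point-mass beliefs):\n")
    print(x$policy_table, row.names = FALSE)
  }
  invisible(x)
}

#' Robustness of performance to training-set size
#'
#' Fixes a one-third test split; for each requested fraction of the
#' remaining two-thirds training pool, re-runs estimation, solving and
#' evaluation on a fresh subsample and reports the followed-arm percentage of
#' transitions to better states, repeated `repeats` times. Fraction 1.0 uses
#' the full pool once and is replicated deterministically.
#'
#' @param cohort Cohort table.
#' @param fractions Training fractions in `(0, 1]`.
#' @param repeats Repeats per fraction (default 10).
#' @param seed Base seed.
#' @param ... Passed to [solve_policy()] (e.g. `belief_count`).
#' @param gamma Discount factor.
#' @return List with per-run `runs` (fraction, repeat, pct_better_followed)
#'   and a `summary` of mean and sd per fraction.
#' @export
robustness_curve <- function(cohort, fractions, repeats = 10L, seed = 1L,
                             gamma = 0.95, ...) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  cohort <- validate_cohort(cohort)
  ids <- unique(cohort$patient_id)
  set.seed(seed)
  perm <- sample(ids)
  n_test <- max(1L, floor(length(ids) / 3))
  test_ids <- perm[seq_len(n_test)]
  pool <- setdiff(perm, test_ids)
  test <- cohort[cohort$patient_id %in% test_ids, , drop = FALSE]
  one_run <- function(train_ids, run_seed) {
    train <- cohort[cohort$patient_id %in% train_ids, , drop = FALSE]
    val <- tryCatch({
      bundle <- build_pomdp(train, gamma = gamma)
      policy <- solve_policy(bundle, seed = run_seed, ...)
      rep_ <- evaluate_transitions(test, policy, bundle$model, bundle$binning)
      rep_$percentages["followed", "better"]
    }, error = function(e) NA_real_)  # degenerate subsample: recorded, not raised
    val
  }
  runs <- list()
  full_val <- NULL
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    for (r in seq_len(repeats)) {
      if (f == 1) {
        if (is.null(full_val)) full_val <- one_run(pool, seed + 1000L)
        val <- full_val
      } else {
        set.seed(seed + 1000L * i + r)
        sub <- sample(pool, max(1L, floor(f * length(pool))))
        val <- one_run(sub, seed + 1000L * i + r)
      }
      runs[[length(runs) + 1L]] <- data.frame(
        fraction = f, rep = r, pct_better_followed = val)
    }
  }
  runs <- do.call(rbind, runs)
  summ <- do.call(rbind, lapply(split(runs, runs$fraction), function(d) {
    data.frame(fraction = d$fraction[1],
               mean = mean(d$pct_better_followed, na.rm = TRUE),
               sd = stats::sd(d$pct_better_followed, na.rm = TRUE),
               n_degenerate = sum(is.na(d$pct_better_followed)))
  }))
  rownames(summ) <- NULL
  list(runs = runs, summary = summ, test_patients = test_ids)
}
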