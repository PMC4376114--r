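---
title: "A POMDP decision-support pipeline for sepsis antibiotic policies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A POMDP decision-support pipeline for sepsis antibiotic policies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsisCDSS)
```

## The model

A hospitalized patient moves through latent clinical states; we observe only
noisy, partially missing vitals and blood-culture results, and at each step a
combination of antibiotics is administered. We model this as a POMDP
`(S, A, Z, T, O, R, b0, gamma)`:

* `S` — ten states ordered best to worst: DISMISSAL, NO_SIRS, PS, SIRS,
  BACTEREMIA, BPS, PSS, SEPSIS, SEPTIC_SHOCK, DEATH. The clinical states are
  defined by the SIRS criteria (HR > 90/min, RR > 20/min, temperature > 38 or
  < 36 °C, WBC > 12,000 or < 4,000 /mm³; two or more = SIRS), infection
  evidence (positive blood culture) and hypotension (SBP < 90 or MAP < 70 mm
  Hg). PS, BPS and PSS are "probable" states assigned when missing vitals
  leave SIRS undeterminable. DISMISSAL and DEATH are absorbing.
* `A` — 32 actions: the 31 non-empty subsets of
  {vancomycin, cefepime, metronidazole, ceftriaxone, meropenem} indexed by
  bitmask, plus a catch-all action (index 0) for any other antibiotic.
* `Z` — 6250 codes: five observation vitals (temperature, RR, WBC, MAP, SBP)
  in five bins each, plus a binary blood-culture flag
  (`2 * 5^5`). Heart rate enters the SIRS labeling rules but not the
  observation space, mirroring the variable list the state definitions and
  the observation model were built from.
* `T(s, a, s')` — frequencies of state–action–next-state patterns.
* `O(s, z)` — a factored, action-independent emission model: per state, five
  per-vital bin distributions and one Bernoulli culture rate, multiplied
  under conditional independence given the state.
* `R(s)` — per-state rewards: DISMISSAL 100,000; NO_SIRS 50,000; PS 5,000;
  SIRS −50; BACTEREMIA −10,000; BPS −12,500; PSS −15,000; SEPSIS −40,000;
  SEPTIC_SHOCK −60,000; DEATH −100,000. The ranking of rewards defines the
  severity order used everywhere (`compare_states`). The top reward is
  attached to DISMISSAL: the reward list speaks of a "healthy" outcome, and
  discharge is the healthy terminal event in this state space. `run_pipeline`
  accepts reward overrides, replicating the reward-revision hook a bedside
  tool would expose.
* `b0` — empirical distribution of first-snapshot states in the training
  cohort (uniform over treatable states as fallback).
* `gamma` — 0.95 by default. Nothing in the state definitions pins the
  discount; 0.95 is the conventional choice for indefinite-horizon clinical
  planning, and the solver takes any `gamma < 1`.

Beliefs are updated by Bayes rule,
`b'(s') ∝ O(s', z) Σ_s T(s, a, s') b(s)`, with the normalizer equal to
`P(z | b, a)`. A zero normalizer (an observation impossible under the
belief) raises a typed condition; during trajectory replay the evaluator
resets such beliefs to `b0` rather than aborting a patient.

## Labeling rules and their edge cases

State labels are assigned most-severe-first: SEPTIC_SHOCK, SEPSIS, PSS, BPS,
BACTEREMIA, SIRS, PS, NO_SIRS. The rule bodies overlap (septic shock is
sepsis plus hypotension), so a fixed priority makes them mutually exclusive
and deterministic; most-severe-first matches clinical triage.

Decisions taken where the rule table is silent:

* *SIRS determinability.* "No vitals to determine SIRS" is interpreted as
  fewer than two evaluable criteria **and** fewer than two met criteria: two
  met criteria settle SIRS regardless of what is missing.
* All threshold comparisons are strict, exactly as printed.
* The baseline-relative hypotension clause ("40 mm Hg below baseline") is
  dropped — no per-patient baseline exists in the record layout; the two
  absolute thresholds remain. The CO₂ alternative for RR and the band-count
  alternative for WBC are likewise dropped (fields absent from the data
  model).
* A single present, normal blood pressure is counted as "not hypotensive";
  only two missing pressures make hypotension undeterminable.
* A missing blood culture counts as no infection evidence.

## Estimation

**Transitions.** `P(s'|s,a)` is the frequency of `(s,a,s')` among
transitions leaving `(s,a)`; one transition per consecutive pair of labeled
snapshots within a patient, the action being the antibiotics recorded at the
earlier snapshot (intervals without a recorded administration carry no
action and are dropped from estimation). Absorbing rows are exact unit
self-loops. Unobserved `(s,a)` pairs back off to the state's
action-marginal row; a state never seen at all backs off to uniform over
non-absorbing states, so the solver always receives complete stochastic
matrices.

The estimation pipeline additionally applies a *minimum-support rule*
(`min_support = 10`): rows built from ten or fewer transitions are flagged
and backed off like unobserved ones. With 32 actions and cohorts of a few
hundred patients, most action rows rest on a handful of samples; a raw
frequency row from two transitions is frequently degenerate (probability 1
on one lucky next state), and a planner maximizing over 31 such rows chases
estimation noise rather than treatment effect — the winner's curse. Backing
off under-supported rows is the same sufficient-data principle (>10 samples)
applied to observation bins, and in our end-to-end experiments it is the
difference between recovering the beneficial action in 10/10 versus 0/10
replicates. `estimate_transitions` itself defaults to pure frequencies
(`min_support = 0`, `smoothing = 0`); Laplace smoothing is available but
off by default.

**Observations.** For each (state, vital) with data, maximum-likelihood fits
of normal, lognormal and gamma are compared by AIC — a symmetric family plus
two right-skewed ones covers the shapes vitals take; the candidate set is an
argument. Fewer than ten samples fall back to the empirical histogram
(typed sparsity warning); constant samples raise a degeneracy warning. Each
vital's range is cut into five equal-width bins (half-open, top bin closed)
and the factor is the fitted CDF mass per bin, renormalized over the binned
range; `mode = "empirical"` switches to raw bin counts. Bins holding ten or
fewer samples mark the scheme sparse.

One deliberate deviation from a literal per-state binning: the observation
*code* must be computable at runtime, when the state is latent, so encoding
uses pooled (state-unconditional) min–max edges per vital; the per-state
fitted distributions then supply each state's bin masses over those shared
edges. Per-(state, vital) edges and masses are still recorded in the scheme.
A missing vital at encoding time maps to the pooled modal bin and is
flagged; per-state imputation would leak the latent state into the code.

## The solver

`perseus_solve` implements randomized point-based value iteration. Beliefs
are sampled by forward simulation from `b0` under uniformly random actions
(default 500 beliefs, horizon 30). The value function starts at the uniform
lower bound `min(R)/(1−gamma)`, which every backup can only improve. Each
stage repeatedly picks a not-yet-improved belief at random, applies a
point-based Bellman backup against the previous stage's vector set (keeping
the previous best vector when the backup does not improve that belief), and
removes every belief whose value already rose; stages repeat until the
largest per-stage value change drops below `tolerance`
(default `1e-3 · max|R|`) or `max_iterations` (1000) is hit, in which case
the best policy is returned with a warning. Values at sampled beliefs are
non-decreasing by construction, and ties in action selection always resolve
to the lowest action index, making solves bit-reproducible under a fixed
seed.

The backup kernel is compiled (RcppArmadillo) because the observation space
is wide (6250 columns); a pure-R reference implementation is retained and
the two are tested for agreement. `exact_mdp_value_iteration` provides the
full-observability oracle: on identity-observation models, Perseus corner
values match it to 1e-4 relative tolerance (an acceptance criterion), and a
two-state model is checked against exhaustive alpha-vector iteration with
grid pruning.

## Retrospective evaluation

Policies are never replayed as interventions; the data records what actually
happened. For each test patient the belief starts at `b0`, is sharpened by
the first observation, and is then propagated with the *administered*
action and the next observation. At each step the policy is queried at the
current belief; the transition lands in the "followed" arm if at least one
policy antibiotic was administered (a catch-all policy action is followed by
any non-named antibiotic). Transitions are classified better/same/worse
against the severity order.

Reported statistics: per-arm counts and percentages (pooled across folds and
per fold — the two aggregations differ and both are emitted), per-patient
≥90% trajectory buckets (inclusive threshold, computed in integer arithmetic
so exactly 90% counts; "better" is strictly better, with a better-or-same
variant also emitted; patients without transitions in an arm leave its
denominator), and one-sided hypergeometric enrichment tests — enrichment of
better (and better-or-same) outcomes in the followed arm, of same and worse
outcomes in the other — adjusted by Benjamini–Hochberg over all tests
emitted in the run. Zero-margin tables give p = 1. `robustness_curve` fixes
a one-third test split and re-runs estimation, solving and evaluation on
subsamples of the remaining pool; degenerate subsamples are recorded as NA
points, not errors. `per_state_policy_table` evaluates the policy at
point-mass beliefs, which is a deliberately idealized query: it assumes
certainty about the state that belief tracking never provides.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
sepsis physiology. Latent dynamics form a birth–death walk on the severity
ladder: improvement moves one severity level up, deterioration one level
down; discharge occurs from NO_SIRS and death from SEPTIC_SHOCK. Three
scenarios are fixed worlds:

* `strong_signal` — vancomycin + ceftriaxone (action 9) has improvement
  probability 0.8 per step in every treatable state; every other action 0.3
  (margin 0.5).
* `null_signal` — transitions ignore the action entirely
  (better/same/worse = 0.35/0.35/0.30); used to verify the evaluation
  harness does not fabricate significance.
* `paper_like` — initial state mix shaped loosely to the source cohort's
  state table (majority NO_SIRS/PS, septic shock rare) with a modest action
  effect; it makes no claim of replication.

Emissions are state-conditional normals with means placed so the SIRS
thresholds are informative (e.g. SIRS-like states at HR ≈ 110, RR ≈ 26,
temperature ≈ 39 °C), clamped to plausible clinical ranges; culture
positivity is ≈ 0.98 in infected states and ≈ 0.02 otherwise. The probable
states carry missingness 1 on the four SIRS vitals — which is exactly what
produces their labels. The behavior policy is ε-mixed (ε = 0.5 uniform over
all 32 actions, otherwise the beneficial action) so both evaluation arms are
populated; trajectory lengths are geometric with mean 4 transitions
(≈ 2.4 observed transitions per patient after absorption, near the ~2.8 the
source cohort implies). Cohort generation is byte-reproducible under a
fixed seed.

What a green end-to-end test establishes: labeling, estimation, solving and
evaluation compose correctly, recover a strong, uniform treatment effect,
and stay quiet when no effect exists. What it does not establish: behavior
under confounding by severity (the generator's behavior policy ignores the
state, real prescribing does not), pharmacokinetics, resistance patterns,
time-varying dynamics, or realistic vitals correlation structure — the
emissions are independent given the state, matching the model's own
assumption rather than testing it.

## Numerical choices and limitations

* Simplex checks use 1e-12 (beliefs, scenario rows), 1e-6 on model
  construction after renormalization; observation rows sum to 1 by
  construction and are enumeration-tested over all 6250 codes.
* JSON round-trips serialize doubles at 17 significant digits (lossless).
* Ties everywhere (actions, greedy policies, bin assignment at edges) break
  deterministically: lowest index, top bin closed.
* The observation model is action-independent, `O(s,a,z) = O(s,z)`: vitals
  emission depends on the patient's state, not on the drug code, and no
  action-dependent estimation recipe exists for it.
* Evaluation seeds, fold splits and solver randomization all derive from one
  base seed.
* The solver is point-based and returns a lower-bound policy; exact
  Sondik-style solving at 6250 observations is out of scope, as are
  organ-failure (SOFA) states, severe sepsis, continuous observation
  filters, and any GUI.
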