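test_that("transition frequencies are count-and-divide", {
  tr <- data.frame(state = rep("SIRS", 4), action = 0L,
                   next_state = c("NO_SIRS", "NO_SIRS", "NO_SIRS", "SEPSIS"))
  tm <- estimate_transitions(tr)
  expect_equal(tm$probs["SIRS", 1, "NO_SIRS"], 0.75)
  expect_equal(tm$probs["SIRS", 1, "SEPSIS"], 0.25)
  one <- estimate_transitions(data.frame(state = "PS", action = 3L,
                                         next_state = "NO_SIRS"))
  expect_equal(one$probs["PS", 4, "NO_SIRS"], 1)
  expect_error(estimate_transitions(data.frame()), class = "sepsisCDSS_no_data")
})

test_that("transition model rows are simplices with exact absorbing self-loops", {
  sc <- strong_cohort(100, seed = 5)
  tm <- estimate_transitions(extract_transitions(sc$cohort))
  rs <- apply(tm$probs, c(1, 2), sum)
  expect_true(max(abs(rs - 1)) < 1e-12)
  for (st in absorbing_states()) {
    expect_true(all(tm$probs[st, , st] == 1))
  }
  # duplicating every triple leaves the probabilities unchanged
  tr <- extract_transitions(sc$cohort)
  tm2 <- estimate_transitions(rbind(tr, tr))
  expect_equal(tm2$probs, tm$probs)
  expect_equal(tm2$counts, 2L * tm$counts)
})

test_that("unobserved and under-supported pairs back off to the marginal row", {
  tr <- data.frame(state = rep("SIRS", 6), action = rep(c(0L, 1L), 3),
                   next_state = rep(c("NO_SIRS", "SEPSIS"), each = 3))
  tm <- estimate_transitions(tr)
  expect_true(tm$backoff["SIRS", 3])
  marg <- c(NO_SIRS = 0.5, SEPSIS = 0.5)
  expect_equal(tm$probs["SIRS", 3, c("NO_SIRS", "SEPSIS")], marg)
  # a state never observed backs off to uniform over non-absorbing states
  expect_equal(unname(tm$probs["PSS", 1, transient_states()]),
               rep(1 / 8, 8))
  expect_equal(sum(tm$probs["PSS", 1, absorbing_states()]), 0)
  # with min_support, sparse-but-observed rows are also backed off
  tm3 <- estimate_transitions(tr, min_support = 10L)
  expect_true(all(tm3$backoff["SIRS", ]))
  expect_equal(tm3$probs["SIRS", 1, c("NO_SIRS", "SEPSIS")], marg)
})

test_that("transition estimates converge to a known generic matrix", {
  set.seed(7)
  states <- c("A", "B", "C")
  truthT <- array(0, c(3, 2, 3), dimnames = list(states, NULL, states))
  for (s in 1:3) for (a in 1:2) truthT[s, a, ] <- rdirichlet1(3)
  n <- 10000
  tr <- do.call(rbind, lapply(1:3, function(s) do.call(rbind, lapply(1:2, function(a) {
    data.frame(state = states[s], action = a - 1L,
               next_state = sample(states, n, TRUE, prob = truthT[s, a, ]))
  }))))
  tm <- estimate_transitions(tr, states = states, n_actions = 2L)
  for (s in 1:3) for (a in 1:2) {
    tv <- 0.5 * sum(abs(tm$probs[s, a, ] - truthT[s, a, ]))
    expect_lt(tv, 0.05)
  }
})

test_that("distribution fitting recovers parameters and ranks by AIC", {
  set.seed(11)
  x <- rnorm(10000, 37, 0.5)
  f <- fit_vital_distribution(x)
  expect_equal(f$family, "normal")
  expect_lt(abs(f$params[["mean"]] - 37), 0.05)
  expect_lt(abs(f$params[["sd"]] - 0.5), 0.05)

  y <- rlnorm(10000, meanlog = 2, sdlog = 0.6)
  g <- fit_vital_distribution(y)
  expect_equal(g$family, "lognormal")
  expect_lt(g$aic_table[["lognormal"]], g$aic_table[["normal"]])

  expect_warning(d <- fit_vital_distribution(rep(5, 20)),
                 class = "sepsisCDSS_degenerate")
  expect_equal(d$family, "degenerate")
  expect_warning(e <- fit_vital_distribution(c(1, 2, 3)),
                 class = "sepsisCDSS_sparsity")
  expect_equal(e$family, "empirical")
})

test_that("binning edges are arithmetic and masses come from the fitted CDF", {
  expect_equal(bin_edges(c(30, 40)), c(30, 32, 34, 36, 38, 40))
  expect_error(bin_edges(rep(3, 5)), class = "sepsisCDSS_degenerate_range")

  set.seed(13)
  u <- runif(5000, 0, 10)
  fu <- sepsisCDSS:::empirical_fit(u)  # uniform-like: empirical proportions
  pu <- bin_probabilities(bin_edges(u), fu)
  expect_equal(sum(pu), 1, tolerance = 1e-9)
  expect_true(all(abs(pu - 0.2) < 0.05))

  # oracle: numeric integration of the truncated normal density
  fit <- structure(list(family = "normal", params = c(mean = 35, sd = 1)),
                   class = "vital_fit")
  edges <- seq(32, 38, length.out = 6)
  probs <- bin_probabilities(edges, fit)
  oracle <- vapply(1:5, function(k) {
    stats::integrate(dnorm, edges[k], edges[k + 1], mean = 35, sd = 1)$value
  }, numeric(1))
  oracle <- oracle / sum(oracle)
  expect_equal(probs, oracle, tolerance = 1e-6)
  expect_equal(which.max(probs), 3)
})

test_that("observation model normalizes over all 6250 codes per state", {
  sc <- strong_cohort(150, seed = 17)
  sc$cohort$state <- label_states(sc$cohort)
  snaps <- sc$cohort[!(sc$cohort$state %in% absorbing_states()), ]
  samples <- sepsisCDSS:::collect_vital_samples(snaps)
  binning <- suppressWarnings(build_binning(samples))
  om <- suppressWarnings(estimate_observation_model(snaps, binning))
  M <- observation_matrix(om)
  expect_equal(dim(M), c(10, 6250))
  expect_true(max(abs(rowSums(M) - 1)) < 1e-6)
  for (k in seq_along(obs_vitals())) {
    expect_true(max(abs(apply(om$factors[, k, ], 1, sum) - 1)) < 1e-9)
  }
  expect_true(all(om$blood_rate >= 0 & om$blood_rate <= 1))
  # uniform factors spread mass evenly: 1/6250 per code
  omu <- om
  omu$factors[] <- 1 / 5
  omu$blood_rate[] <- 0.5
  expect_equal(unname(observation_matrix(omu)[1, ]), rep(1 / 6250, 6250))
  # the factored accessor agrees with the dense matrix
  z <- c(0L, 17L, 3124L, 3125L, 6249L)
  expect_equal(observation_prob(om, "SIRS", z), unname(M["SIRS", z + 1]))
})

test_that("observation factors are recovered from known emission tables", {
  set.seed(19)
  truth <- make_scenario("strong_signal")
  n <- 10000
  snaps <- do.call(rbind, lapply(transient_states(), function(st) {
    em <- truth$emissions[[st]]
    data.frame(state = st,
               temperature = rnorm(n, em$temperature[1], em$temperature[2]),
               respiratory_rate = rnorm(n, em$respiratory_rate[1], em$respiratory_rate[2]),
               wbc = rnorm(n, em$wbc[1], em$wbc[2]),
               map = rnorm(n, em$map[1], em$map[2]),
               sbp = rnorm(n, em$sbp[1], em$sbp[2]),
               blood_culture = ifelse(runif(n) < truth$blood_rates[[st]], "pos", "neg"),
               stringsAsFactors = FALSE)
  }))
  samples <- lapply(split(snaps, snaps$state), function(d) {
    lapply(stats::setNames(nm = obs_vitals()), function(v) d[[v]])
  })
  binning <- suppressWarnings(build_binning(samples))
  om <- suppressWarnings(estimate_observation_model(snaps, binning))
  tf <- sepsisCDSS:::true_observation_factors(truth, binning$global)
  for (st in transient_states()) {
    for (k in seq_along(obs_vitals())) {
      expect_lt(sum(abs(om$factors[st, k, ] - tf[st, k, ])), 0.05)
    }
    expect_lt(abs(om$blood_rate[[st]] - truth$blood_rates[[st]]), 0.02)
  }
})

test_that("model serialization round-trips losslessly", {
  sc <- strong_cohort(80, seed = 23)
  bundle <- suppressWarnings(build_pomdp(sc$cohort))
  path <- tempfile(fileext = ".json")
  write_model_json(bundle, path)
  back <- read_model_json(path)
  expect_lt(max(abs(back$model$T - bundle$model$T)), 1e-12)
  expect_lt(max(abs(back$model$O - bundle$model$O)), 1e-12)
  expect_lt(max(abs(back$model$b0 - bundle$model$b0)), 1e-12)
  expect_equal(back$model$R, bundle$model$R)
  expect_equal(back$transition$counts, bundle$transition$counts)
  g1 <- back$binning$global$wbc$edges
  g2 <- bundle$binning$global$wbc$edges
  expect_lt(max(abs(g1 - g2)), 1e-12)
  unlink(path)
})
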