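test_that("belief update matches hand computation and degenerates correctly", {
  # identity transitions + state-independent observations: posterior = prior
  S <- 3
  Tid <- array(0, c(S, 2, S))
  for (a in 1:2) Tid[, a, ] <- diag(S)
  Oflat <- matrix(1 / 4, S, 4)
  m <- pomdp_model(Tid, Oflat, R = rep(0, S), gamma = 0.5)
  b <- c(0.2, 0.3, 0.5)
  upd <- belief_update(b, 0, 2, m)
  expect_equal(upd$belief, b)
  expect_equal(upd$prob, 1 / 4)

  # 2-state: uniform T, O(s1,z)=0.8, O(s2,z)=0.2 -> posterior (0.8, 0.2)
  T2 <- array(0.5, c(2, 1, 2))
  O2 <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2)
  m2 <- pomdp_model(T2, O2, R = c(0, 0), gamma = 0.5)
  upd2 <- belief_update(c(0.5, 0.5), 0, 0, m2)
  expect_equal(upd2$belief, c(0.8, 0.2))
  expect_equal(upd2$prob, 0.5)

  # deterministic funnel to state 2 -> point mass
  T3 <- array(0, c(2, 1, 2)); T3[, 1, 2] <- 1
  m3 <- pomdp_model(T3, O2, R = c(0, 0), gamma = 0.5)
  expect_equal(belief_update(c(0.5, 0.5), 0, 0, m3)$belief, c(0, 1))

  # impossible observation signals
  O4 <- matrix(c(1, 1, 0, 0), 2, 2)
  m4 <- pomdp_model(T3, O4, R = c(0, 0), gamma = 0.5)
  expect_error(belief_update(c(0.5, 0.5), 0, 1, m4),
               class = "sepsisCDSS_inconsistent_observation")
})

test_that("belief updates preserve the simplex on randomized instances", {
  set.seed(101)
  for (rep in 1:30) {
    m <- random_pomdp(S = sample(2:5, 1), A = sample(2:3, 1),
                      Z = sample(2:6, 1))
    b <- rdirichlet1(m$n_states)
    for (k in 1:10) {
      a <- sample(m$n_actions, 1) - 1L
      z <- sample(m$n_obs, 1) - 1L
      upd <- belief_update(b, a, z, m)
      b <- upd$belief
      expect_true(all(b >= 0))
      expect_lt(abs(sum(b) - 1), 1e-12)
      expect_gt(upd$prob, 0)
    }
  }
})

test_that("exact MDP value iteration matches closed forms and a linear solve", {
  # absorbing state: V = R / (1 - gamma)
  Tab <- array(0, c(1, 1, 1)); Tab[1, 1, 1] <- 1
  vi <- exact_mdp_value_iteration(Tab, -100000, 0.95, tolerance = 1e-6)
  expect_equal(vi$values, -100000 / 0.05, tolerance = 1e-6)

  # single-action chain: V solves (I - gamma T) V = R
  set.seed(31)
  S <- 4
  Tc <- array(0, c(S, 1, S))
  for (s in 1:S) Tc[s, 1, ] <- rdirichlet1(S)
  R <- runif(S, -10, 10)
  vi2 <- exact_mdp_value_iteration(Tc, R, 0.9, tolerance = 1e-12)
  direct <- solve(diag(S) - 0.9 * matrix(Tc[, 1, ], S, S), R)
  expect_equal(vi2$values, direct, tolerance = 1e-7)

  # gamma = 0: V = R (state rewards, no lookahead)
  m <- identity_obs_pomdp(S = 3, A = 2, seed = 32)
  vi3 <- exact_mdp_value_iteration(m$T, m$R, 0)
  expect_equal(vi3$values, m$R)
})

test_that("point-based backup reproduces the geometric series from a zero start", {
  # single-state model; seeding the backup with an explicit zero vector gives
  # value r * (1 - gamma^(k+1)) / (1 - gamma) after k backups
  r <- -7
  T1 <- array(1, c(1, 1, 1))
  m <- pomdp_model(T1, matrix(1, 1, 1), R = r, gamma = 0.5)
  pol <- alpha_policy(matrix(0, 1, 1), 0L)
  for (k in 0:6) {
    bk <- point_based_backup(1, pol, m)
    expect_equal(bk$value, r * (1 - 0.5^(k + 1)) / (1 - 0.5), tolerance = 1e-12)
    pol <- alpha_policy(matrix(bk$vector, 1, 1), bk$action)
  }
})

test_that("backup at corner beliefs equals the MDP Bellman backup and improves", {
  set.seed(41)
  for (rep in 1:5) {
    m <- identity_obs_pomdp(S = 4, A = 3, gamma = 0.9)
    lower <- min(m$R) / (1 - m$gamma)
    pol <- alpha_policy(matrix(lower, 1, m$n_states), 0L)
    V <- rep(lower, m$n_states)
    bellman <- vapply(seq_len(m$n_states), function(s) {
      max(vapply(seq_len(m$n_actions), function(a) {
        m$R[s] + m$gamma * sum(m$T[s, a, ] * V)
      }, numeric(1)))
    }, numeric(1))
    for (s in seq_len(m$n_states)) {
      b <- as.numeric(seq_len(m$n_states) == s)
      bk <- point_based_backup(b, pol, m)
      expect_equal(bk$value, bellman[s], tolerance = 1e-9)
      # Perseus improvement guarantee
      expect_gte(bk$value, policy_value(pol, b) - 1e-9)
    }
  }
})

test_that("compiled and reference backup implementations agree", {
  set.seed(43)
  for (rep in 1:10) {
    m <- random_pomdp(S = sample(2:5, 1), A = sample(2:3, 1), Z = sample(3:8, 1))
    pol <- alpha_policy(matrix(rnorm(3 * m$n_states, sd = 50), 3),
                        sample(0:(m$n_actions - 1), 3, TRUE))
    b <- rdirichlet1(m$n_states)
    r1 <- point_based_backup(b, pol, m, use_cpp = TRUE)
    r2 <- point_based_backup(b, pol, m, use_cpp = FALSE)
    expect_equal(r1$action, r2$action)
    expect_equal(r1$value, r2$value, tolerance = 1e-10)
    expect_equal(r1$vector, r2$vector, tolerance = 1e-10)
  }
})

test_that("belief sampling starts at b0, stays on the simplex, is reproducible", {
  m <- random_pomdp(S = 4, A = 2, Z = 5, seed = 51)
  expect_equal(sample_beliefs(m, 1, seed = 1), matrix(m$b0, 1))
  B1 <- sample_beliefs(m, 40, seed = 2)
  B2 <- sample_beliefs(m, 40, seed = 2)
  expect_identical(B1, B2)
  expect_equal(nrow(B1), 40)
  expect_true(all(B1 >= 0))
  expect_true(max(abs(rowSums(B1) - 1)) < 1e-9)
})

test_that("Perseus is myopic at gamma = 0 and bit-reproducible", {
  set.seed(61)
  S <- 3; A <- 3
  T <- array(0, c(S, A, S))
  for (s in 1:S) for (a in 1:A) T[s, a, ] <- rdirichlet1(S)
  m <- pomdp_model(T, diag(S), R = c(5, -2, 1), gamma = 0)
  pol <- perseus_solve(m, corner_beliefs(S), tolerance = 1e-9, seed = 7)
  for (s in 1:S) {
    b <- as.numeric(seq_len(S) == s)
    expect_equal(extract_action(pol, b)$value, m$R[s], tolerance = 1e-9)
  }
  m2 <- random_pomdp(S = 4, A = 2, Z = 5, seed = 62)
  B <- sample_beliefs(m2, 25, seed = 3)
  p1 <- perseus_solve(m2, B, seed = 9)
  p2 <- perseus_solve(m2, B, seed = 9)
  expect_identical(p1$vectors, p2$vectors)
  expect_identical(p1$actions, p2$actions)
})

test_that("Perseus value function is convex and non-decreasing in stages", {
  m <- random_pomdp(S = 4, A = 3, Z = 5, gamma = 0.85, seed = 71)
  B <- rbind(corner_beliefs(4), sample_beliefs(m, 30, seed = 4))
  pol <- perseus_solve(m, B, tolerance = 1e-6 * max(abs(m$R)), seed = 5)
  set.seed(72)
  for (k in 1:50) {
    b1 <- rdirichlet1(4); b2 <- rdirichlet1(4)
    mid <- (b1 + b2) / 2
    expect_lte(policy_value(pol, mid),
               (policy_value(pol, b1) + policy_value(pol, b2)) / 2 + 1e-9)
  }
})

test_that("identity-observation Perseus matches exact MDP value iteration", {
  for (seed in 1:5) {
    m <- identity_obs_pomdp(S = 3 + seed %% 3, A = 2 + seed %% 2,
                            gamma = 0.9, seed = 80 + seed)
    vi <- exact_mdp_value_iteration(m$T, m$R, m$gamma, tolerance = 1e-10)
    B <- rbind(corner_beliefs(m$n_states), sample_beliefs(m, 30, seed = seed))
    pol <- perseus_solve(m, B, tolerance = 1e-7 * max(abs(m$R)),
                         max_iterations = 5000, seed = seed)
    for (s in seq_len(m$n_states)) {
      b <- as.numeric(seq_len(m$n_states) == s)
      rec <- extract_action(pol, b)
      expect_equal(rec$value, vi$values[s],
                   tolerance = 1e-4 * max(abs(vi$values)))
    }
  }
})

test_that("extracted actions switch exactly at the analytic crossing point", {
  # vectors v1 = (10, 0) action 2, v2 = (0, 10) action 1 cross at b* = 0.5
  pol <- alpha_policy(rbind(c(10, 0), c(0, 10)), c(2L, 1L))
  left <- extract_action(pol, c(0.51, 0.49))
  right <- extract_action(pol, c(0.49, 0.51))
  expect_equal(left$action, 2L)
  expect_equal(left$runner_up_action, 1L)
  expect_equal(right$action, 1L)
  # exact tie at the crossing resolves to the lowest action index
  expect_equal(extract_action(pol, c(0.5, 0.5))$action, 1L)
  one <- alpha_policy(matrix(c(1, 2), 1), 5L)
  rec <- extract_action(one, c(0.5, 0.5))
  expect_equal(rec$action, 5L)
  expect_true(is.na(rec$runner_up_action))
})

test_that("point-mass policy actions agree with the exact MDP greedy policy", {
  for (seed in 1:3) {
    m <- identity_obs_pomdp(S = 4, A = 3, gamma = 0.9, seed = 90 + seed)
    vi <- exact_mdp_value_iteration(m$T, m$R, m$gamma, tolerance = 1e-10)
    B <- rbind(corner_beliefs(4), sample_beliefs(m, 20, seed = seed))
    pol <- perseus_solve(m, B, tolerance = 1e-7 * max(abs(m$R)),
                         max_iterations = 5000, seed = seed)
    for (s in 1:4) {
      b <- as.numeric(seq_len(4) == s)
      qs <- vi$Q[s, ]
      # accept any action whose Q is within numerical reach of the optimum
      near <- which(qs >= max(qs) - 1e-3 * max(abs(qs))) - 1L
      expect_true(extract_action(pol, b)$action %in% near)
    }
  }
})

test_that("a two-state model agrees with exhaustive alpha-vector iteration", {
  # two actions with opposed effects: the optimal action flips with the belief
  T <- array(0, c(2, 2, 2))
  T[1, 1, ] <- c(0.9, 0.1); T[2, 1, ] <- c(0.5, 0.5)   # action 0 favors state 1
  T[1, 2, ] <- c(0.5, 0.5); T[2, 2, ] <- c(0.1, 0.9)   # action 1 favors state 2
  O <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2)
  m <- pomdp_model(T, O, R = c(10, -10), gamma = 0.8)
  oracle <- exact_alpha_vi(m, iterations = 40)
  grid <- cbind(seq(0, 1, 0.001), 1 - seq(0, 1, 0.001))
  B <- rbind(corner_beliefs(2), grid[seq(1, 1001, by = 25), ])
  pol <- perseus_solve(m, B, tolerance = 1e-8 * max(abs(m$R)),
                       max_iterations = 5000, seed = 3)
  v_oracle <- policy_value(oracle, grid)
  v_pol <- policy_value(pol, grid)
  expect_lt(max(abs(v_oracle - v_pol)), 1e-3 * max(abs(v_oracle)))
  # actions agree except in a negligible band around the crossing
  a_oracle <- vapply(seq_len(nrow(grid)),
                     function(i) extract_action(oracle, grid[i, ])$action,
                     integer(1))
  a_pol <- vapply(seq_len(nrow(grid)),
                  function(i) extract_action(pol, grid[i, ])$action,
                  integer(1))
  expect_lt(mean(a_oracle != a_pol), 0.01)
})

test_that("policy serialization round-trips", {
  m <- random_pomdp(S = 3, A = 2, Z = 4, seed = 95)
  pol <- perseus_solve(m, sample_beliefs(m, 15, seed = 1), seed = 2)
  path <- tempfile(fileext = ".json")
  write_policy_json(pol, path)
  back <- read_policy_json(path)
  expect_lt(max(abs(back$vectors - pol$vectors)), 1e-12)
  expect_identical(back$actions, pol$actions)
  unlink(path)
})
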