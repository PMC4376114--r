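# Shared fixtures: small random POMDPs and oracle solvers, built in code.

rdirichlet1 <- function(n) {
  x <- stats::rgamma(n, 1)
  x / sum(x)
}

# Random generic POMDP with dense strictly positive T and O rows.
random_pomdp <- function(S = 3, A = 2, Z = 4, gamma = 0.9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  T <- array(0, c(S, A, S))
  for (s in seq_len(S)) for (a in seq_len(A)) T[s, a, ] <- rdirichlet1(S)
  O <- t(vapply(seq_len(S), function(s) rdirichlet1(Z), numeric(Z)))
  R <- stats::runif(S, -100, 100)
  pomdp_model(T, O, R = R, gamma = gamma)
}

# Identity-observation embedding: the POMDP is a fully observable MDP.
identity_obs_pomdp <- function(S = 3, A = 2, gamma = 0.9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  T <- array(0, c(S, A, S))
  for (s in seq_len(S)) for (a in seq_len(A)) T[s, a, ] <- rdirichlet1(S)
  R <- stats::runif(S, -100, 100)
  pomdp_model(T, diag(S), R = R, gamma = gamma)
}

corner_beliefs <- function(S) diag(S)

# Exact alpha-vector value iteration by full cross-sum enumeration with
# grid-based pruning; tractable only for tiny models. Independent of the
# package's point-based machinery.
exact_alpha_vi <- function(model, iterations, grid_step = 0.001) {
  stopifnot(model$n_states == 2)
  grid <- cbind(seq(0, 1, by = grid_step), 1 - seq(0, 1, by = grid_step))
  prune <- function(vecs, acts) {
    vals <- grid %*% t(vecs)
    keep <- sort(unique(max.col(vals, ties.method = "first")))
    list(vecs = vecs[keep, , drop = FALSE], acts = acts[keep])
  }
  Gm <- matrix(0, 1, 2)
  Ga <- 0L
  for (it in seq_len(iterations)) {
    new_vecs <- NULL
    new_acts <- integer(0)
    for (a in seq_len(model$n_actions)) {
      Ta <- matrix(model$T[, a, ], 2, 2)
      # g[z][i](s) = sum_s' T(s,a,s') O(s',z) alpha_i(s')
      gz <- lapply(seq_len(model$n_obs), function(z) {
        t(vapply(seq_len(nrow(Gm)), function(i) {
          as.vector(Ta %*% (model$O[, z] * Gm[i, ]))
        }, numeric(2)))
      })
      combos <- expand.grid(lapply(seq_len(model$n_obs),
                                   function(z) seq_len(nrow(Gm))))
      for (r in seq_len(nrow(combos))) {
        v <- model$R
        for (z in seq_len(model$n_obs)) {
          v <- v + model$gamma * gz[[z]][combos[r, z], ]
        }
        new_vecs <- rbind(new_vecs, v)
        new_acts <- c(new_acts, a - 1L)
      }
    }
    pr <- prune(new_vecs, new_acts)
    Gm <- pr$vecs
    Ga <- pr$acts
  }
  alpha_policy(Gm, Ga)
}

strong_cohort <- function(n_patients = 200, seed = 1) {
  truth <- make_scenario("strong_signal", seed = seed)
  simulate_cohort(truth, n_patients, seed = seed)
}

random_snapshot_df <- function(n, seed = 1) {
  set.seed(seed)
  maybe <- function(x, p = 0.3) ifelse(stats::runif(n) < p, NA, x)
  data.frame(
    temperature = maybe(stats::runif(n, 34, 41)),
    heart_rate = maybe(stats::runif(n, 50, 150)),
    respiratory_rate = maybe(stats::runif(n, 8, 40)),
    wbc = maybe(stats::runif(n, 2000, 25000)),
    map = maybe(stats::runif(n, 40, 120)),
    sbp = maybe(stats::runif(n, 60, 180)),
    blood_culture = sample(c("pos", "neg", ""), n, replace = TRUE),
    stringsAsFactors = FALSE)
}
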