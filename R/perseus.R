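#' Construct an alpha-vector policy
#'
#' The POMDP value function is the upper envelope `V(b) = max_i <alpha_i, b>`
#' of a set of action-tagged linear functions over the state space.
#'
#' @param vectors Numeric matrix, one alpha vector per row.
#' @param actions Integer vector of 0-based action indices, one per vector.
#' @param stage Iteration counter (metadata).
#' @param ... Further metadata fields (gamma, tolerance, seed, ...).
#' @return An object of class `alpha_policy`.
#' @export
alpha_policy <- function(vectors, actions, stage = 0L, ...) {
  if (is.vector(vectors)) vectors <- matrix(vectors, nrow = 1)
  stopifnot(nrow(vectors) == length(actions), all(actions >= 0))
  structure(list(vectors = vectors, actions = as.integer(actions),
                 stage = as.integer(stage), meta = list(...)),
            class = "alpha_policy")
}

#' @export
print.alpha_policy <- function(x, ...) {
  cat(sprintf("alpha_policy: %d vectors over %d states, stage %d\n",
              nrow(x$vectors), ncol(x$vectors), x$stage))
  invisible(x)
}

#' Value of a policy at one or more beliefs
#'
#' @param policy An [alpha_policy()].
#' @param beliefs Belief vector or matrix (one belief per row).
#' @return Numeric vector of values `V(b)`.
#' @export
policy_value <- function(policy, beliefs) {
  if (is.vector(beliefs)) beliefs <- matrix(beliefs, nrow = 1)
  vals <- beliefs %*% t(policy$vectors)
  apply(vals, 1, max)
}

#' Point-based Bellman backup at a belief
#'
#' For each action, composes the immediate reward with the discounted,
#' observation-weighted best continuation under the current vector set,
#' back-projected through T and O; returns the action-tagged vector that
#' maximizes `<alpha, b>` (ties broken towards the lowest action index).
#'
#' @param belief Belief simplex.
#' @param policy Current [alpha_policy()] (non-empty).
#' @param model A [pomdp_model()].
#' @param use_cpp Use the compiled kernel (default); the pure-R reference
#'   implementation is retained and tested for agreement.
#' @return List with `vector`, 0-based `action` and `value` at `belief`.
#' @export
point_based_backup <- function(belief, policy, model, use_cpp = TRUE) {
  if (use_cpp) {
    res <- cpp_point_backup(belief, policy$vectors, model$Tp, model$O,
                            model$R, model$gamma)
    return(list(vector = as.vector(res$vector),
                action = as.integer(res$action), value = res$value))
  }
  A <- policy$vectors
  nal <- nrow(A)
  S <- model$n_states
  Z <- model$n_obs
  rb <- sum(belief * model$R)
  best <- NULL
  for (a in seq_len(model$n_actions)) {
    Tm <- t_slice(model, a)
    u <- as.vector(crossprod(Tm, belief))           # u(s') = sum_s b(s) T(s,a,s')
    Sc <- (A * rep(u, each = nal)) %*% model$O      # nal x Z
    j <- if (nal == 1) rep(1L, Z) else max.col(t(Sc), ties.method = "first")
    val <- rb + model$gamma * sum(Sc[cbind(j, seq_len(Z))])
    if (is.null(best) || val > best$value) {
      C <- numeric(S)                               # C(s') = sum_z O(s',z) alpha*_z(s')
      for (i in unique(j)) {
        cols <- which(j == i)
        C <- C + A[i, ] * rowSums(model$O[, cols, drop = FALSE])
      }
      best <- list(vector = model$R + model$gamma * as.vector(Tm %*% C),
                   action = a - 1L, value = val)
    }
  }
  best
}

#' Sample a belief set by forward simulation
#'
#' Simulates trajectories from `b0` under uniformly random actions, sampling
#' a latent state path and observations from the model itself and collecting
#' the belief after every update. Returns up to `n` distinct beliefs,
#' always including `b0`.
#'
#' @param model A [pomdp_model()].
#' @param n Number of beliefs to collect (>= 1).
#' @param horizon Steps per simulated trajectory.
#' @param seed Optional RNG seed for reproducibility.
#' @return Numeric matrix with one belief per row.
#' @export
sample_beliefs <- function(model, n, horizon = 30L, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  S <- model$n_states
  out <- matrix(model$b0, nrow = 1)
  attempts <- 0L
  while (nrow(out) < n && attempts < 200L * n) {
    s <- sample.int(S, 1, prob = model$b0)
    b <- model$b0
    for (t in seq_len(horizon)) {
      attempts <- attempts + 1L
      a <- sample.int(model$n_actions, 1)
      s2 <- sample.int(S, 1, prob = model$T[s, a, ])
      z <- findInterval(stats::runif(1), model$O_cum[s2, ]) + 1L
      z <- min(z, model$n_obs)
      upd <- tryCatch(belief_update(b, a - 1L, z - 1L, model),
                      sepsisCDSS_inconsistent_observation = function(e) NULL)
      if (is.null(upd)) break
      b <- upd$belief
      if (!any(apply(out, 1, function(r) max(abs(r - b)) < 1e-12))) {
        out <- rbind(out, b)
      }
      if (nrow(out) >= n) break
      s <- s2
    }
  }
  dimnames(out) <- NULL
  out
}

#' Perseus randomized point-based value iteration
#'
#' Starting from the uniformly improvable lower bound `min(R)/(1-gamma)`,
#' each stage repeatedly picks a not-yet-improved belief at random, backs it
#' up against the previous stage's vector set and drops every belief whose
#' value already improved. Stages repeat until the largest value change over
#' the belief set falls below `tolerance` or `max_iterations` stages elapse.
#' The value at every sampled belief is non-decreasing across stages.
#'
#' @param model A [pomdp_model()].
#' @param beliefs Belief matrix (one per row) or list of beliefs; see
#'   [sample_beliefs()].
#' @param tolerance Convergence threshold on the max value change per stage;
#'   defaults to `1e-3 * max(abs(R))`.
#' @param max_iterations Maximum number of stages (default 1000).
#' @param seed Optional RNG seed controlling the randomized backup order.
#' @param verbose Print per-stage progress.
#' @return An [alpha_policy()] with metadata (`gamma`, `tolerance`, `seed`,
#'   `converged`, `stage`, `n_beliefs`).
#' @export
perseus_solve <- function(model, beliefs, tolerance = NULL,
                          max_iterations = 1000L, seed = NULL,
                          verbose = FALSE) {
  if (is.list(beliefs)) beliefs <- do.call(rbind, beliefs)
  if (is.vector(beliefs)) beliefs <- matrix(beliefs, nrow = 1)
  stopifnot(nrow(beliefs) >= 1, ncol(beliefs) == model$n_states)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tolerance)) tolerance <- 1e-3 * max(abs(model$R))
  nb <- nrow(beliefs)
  lower <- min(model$R) / (1 - model$gamma)
  cur <- alpha_policy(matrix(lower, 1, model$n_states), 0L)
  vals <- as.vector(beliefs %*% t(cur$vectors))
  converged <- FALSE
  stage <- 0L
  while (stage < max_iterations) {
    stage <- stage + 1L
    vals_old <- vals
    new_vec <- NULL
    new_act <- integer(0)
    new_vals <- rep(-Inf, nb)
    todo <- seq_len(nb)
    while (length(todo) > 0) {
      pick <- todo[sample.int(length(todo), 1)]
      bk <- point_based_backup(beliefs[pick, ], cur, model)
      if (bk$value < vals_old[pick] - 1e-9) {
        # keep the previous best vector for this belief (standard Perseus guard)
        i_old <- which.max(beliefs[pick, ] %*% t(cur$vectors))
        bk <- list(vector = cur$vectors[i_old, ], action = cur$actions[i_old],
                   value = vals_old[pick])
      }
      dup <- FALSE
      if (!is.null(new_vec)) {
        dup <- any(apply(new_vec, 1, function(r) max(abs(r - bk$vector)) < 1e-12))
      }
      if (!dup) {
        new_vec <- rbind(new_vec, bk$vector)
        new_act <- c(new_act, bk$action)
      }
      new_vals <- pmax(new_vals, as.vector(beliefs %*% bk$vector))
      todo <- which(new_vals < vals_old - 1e-9)
    }
    vals <- pmax(new_vals, vals_old)
    cur <- alpha_policy(new_vec, new_act, stage)
    delta <- max(vals - vals_old)
    if (verbose) {
      message(sprintf("stage %d: %d vectors, delta %.6g", stage,
                      nrow(new_vec), delta))
    }
    if (delta < tolerance) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("Perseus did not converge within ", max_iterations, " stages")
  }
  alpha_policy(cur$vectors, cur$actions, stage,
               gamma = model$gamma, tolerance = tolerance, seed = seed,
               converged = converged, n_beliefs = nb)
}

#' Optimal and runner-up action at a belief
#'
#' Returns the action of the maximizing alpha vector at `b`, its value, and
#' the best action differing from it (the second-best alternative). Ties are
#' broken towards the lowest action index.
#'
#' @param policy An [alpha_policy()].
#' @param belief Belief simplex.
#' @return List with `action`, `value`, `runner_up_action`,
#'   `runner_up_value` (the latter two `NA` when only one action appears).
#' @export
extract_action <- function(policy, belief) {
  vals <- as.vector(policy$vectors %*% belief)
  mx <- max(vals)
  cand <- which(vals == mx)
  best <- cand[which.min(policy$actions[cand])]
  act <- policy$actions[best]
  other <- which(policy$actions != act)
  if (length(other) == 0) {
    return(list(action = act, value = mx,
                runner_up_action = NA_integer_, runner_up_value = NA_real_))
  }
  mx2 <- max(vals[other])
  cand2 <- other[vals[other] == mx2]
  ru <- policy$actions[cand2[which.min(policy$actions[cand2])]]
  list(action = act, value = mx, runner_up_action = ru, runner_up_value = mx2)
}
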