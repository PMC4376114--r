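#' Construct a POMDP model
#'
#' Bundles the 8-tuple (S, A, Z, T, O, R, b0, gamma). Accepts either raw
#' arrays (for generic models, e.g. test oracles) or the estimation module's
#' `transition_model` / `observation_model` objects.
#'
#' @param T Transition array `[state, action, next_state]` or a
#'   `transition_model`.
#' @param O Observation matrix `[state, code]` or an `observation_model`.
#' @param R Per-state reward vector (default [default_rewards()] when the
#'   state set matches the sepsis state space).
#' @param b0 Initial belief over states; uniform when `NULL`.
#' @param gamma Discount factor in `[0, 1)`.
#' @param states Optional state labels.
#' @return An object of class `pomdp_model` with components `T` (S x A x S'),
#'   `O` (S x Z), `R`, `b0`, `gamma`, `states`, `n_states`, `n_actions`,
#'   `n_obs` and per-state observation cumulative sums for simulation.
#' @export
pomdp_model <- function(T, O, R = NULL, b0 = NULL, gamma = 0.95, states = NULL) {
  if (inherits(T, "transition_model")) {
    if (is.null(states)) states <- T$states
    T <- T$probs
  }
  if (inherits(O, "observation_model")) O <- observation_matrix(O)
  stopifnot(is.array(T), length(dim(T)) == 3, dim(T)[1] == dim(T)[3])
  S <- dim(T)[1]; A <- dim(T)[2]
  stopifnot(is.matrix(O), nrow(O) == S)
  Z <- ncol(O)
  if (is.null(states)) states <- dimnames(T)[[1]]
  if (is.null(states)) states <- paste0("s", seq_len(S))
  if (is.null(R)) {
    if (identical(states, sepsis_states())) R <- default_rewards()
    else stop("R must be supplied for non-sepsis state spaces")
  }
  if (!is.null(names(R)) && all(states %in% names(R))) R <- R[states]
  stopifnot(length(R) == S)
  if (is.null(b0)) b0 <- rep(1 / S, S)
  stopifnot(length(b0) == S, all(b0 >= 0))
  if (abs(sum(b0) - 1) > 1e-12) stop("b0 must sum to 1 within 1e-12")
  if (!(gamma >= 0 && gamma < 1)) stop("gamma must lie in [0, 1)")
  rs <- apply(T, c(1, 2), sum)
  if (max(abs(rs - 1)) > 1e-6) stop("transition rows must sum to 1")
  ors <- rowSums(O)
  if (max(abs(ors - 1)) > 1e-6) stop("observation rows must sum to 1")
  if (any(T < -1e-12) || any(O < -1e-12)) stop("negative probabilities")
  structure(list(T = T, O = O, R = as.numeric(R), b0 = as.numeric(b0 / sum(b0)),
                 gamma = gamma, states = states, n_states = S,
                 n_actions = A, n_obs = Z,
                 Tp = aperm(T, c(1, 3, 2)),  # [s, s', a]: per-action slices
                 O_cum = t(apply(O, 1, cumsum))),
            class = "pomdp_model")
}

#' @export
print.pomdp_model <- function(x, ...) {
  cat(sprintf("pomdp_model: %d states, %d actions, %d observations, gamma=%g\n",
              x$n_states, x$n_actions, x$n_obs, x$gamma))
  invisible(x)
}

t_slice <- function(model, a) {
  matrix(model$T[, a, ], model$n_states, model$n_states)
}

#' Bayesian belief update
#'
#' `b'(s') ~ O(s', z) * sum_s T(s, a, s') b(s)`, normalized. The normalizer is
#' `P(z | b, a)`. A zero normalizer means the observation is impossible under
#' the belief and raises a condition of class
#' `sepsisCDSS_inconsistent_observation`.
#'
#' @param belief Numeric belief simplex over states.
#' @param action 0-based action index.
#' @param obs 0-based observation code.
#' @param model A [pomdp_model()].
#' @return List with `belief` (updated simplex) and `prob` (the normalizer).
#' @export
belief_update <- function(belief, action, obs, model) {
  stopifnot(length(belief) == model$n_states)
  pred <- as.vector(crossprod(t_slice(model, action + 1L), belief))
  w <- model$O[, obs + 1L] * pred
  nz <- sum(w)
  if (nz <= 0) {
    stop(structure(class = c("sepsisCDSS_inconsistent_observation",
                             "error", "condition"),
                   list(message = "observation impossible under belief",
                        call = NULL)))
  }
  list(belief = w / nz, prob = nz)
}

#' Exact value iteration on the fully observable MDP
#'
#' Iterates `V(s) = max_a [R(s) + gamma * sum_s' T(s,a,s') V(s')]` to a
#' sup-norm change below `tolerance`. Serves as the full-observability oracle
#' for the point-based POMDP solver.
#'
#' @param T Transition array `[s, a, s']` or `transition_model`.
#' @param R Per-state reward vector.
#' @param gamma Discount in `[0, 1)`.
#' @param tolerance Sup-norm stopping threshold.
#' @param max_iterations Iteration cap.
#' @return List with `values`, greedy `policy` (0-based actions, ties to the
#'   lowest index), `Q` matrix and `iterations`.
#' @export
exact_mdp_value_iteration <- function(T, R, gamma, tolerance = 1e-8,
                                      max_iterations = 100000L) {
  if (inherits(T, "transition_model")) T <- T$probs
  S <- dim(T)[1]; A <- dim(T)[2]
  stopifnot(length(R) == S, gamma >= 0, gamma < 1)
  TA <- lapply(seq_len(A), function(a) matrix(T[, a, ], S, S))
  V <- numeric(S)
  for (it in seq_len(max_iterations)) {
    Q <- vapply(seq_len(A), function(a) R + gamma * as.vector(TA[[a]] %*% V),
                numeric(S))
    Q <- matrix(Q, S, A)
    Vn <- apply(Q, 1, max)
    delta <- max(abs(Vn - V))
    V <- Vn
    if (delta < tolerance) break
  }
  policy <- max.col(Q, ties.method = "first") - 1L
  list(values = V, policy = policy, Q = Q, iterations = it)
}
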