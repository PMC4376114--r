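# JSON serialization of fitted models and policies. Arrays are flattened
# column-major with explicit dims so round-trips are lossless to full double
# precision.

pack_array <- function(a) list(dim = dim(a), data = as.numeric(a))

unpack_array <- function(x, dimnames = NULL) {
  a <- array(as.numeric(x$data), dim = as.integer(x$dim))
  if (!is.null(dimnames)) dimnames(a) <- dimnames
  a
}

#' Serialize a fitted model bundle to JSON
#'
#' Writes the transition tensor with its support counts, the observation
#' factors and blood rates, the binning edges, rewards, initial belief and
#' discount of a [build_pomdp()] bundle. [read_model_json()] restores it;
#' round-trips are lossless to 1e-12.
#'
#' @param bundle A `cdss_model_bundle`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_model_json <- function(bundle, path) {
  stopifnot(inherits(bundle, "cdss_model_bundle"))
  om <- bundle$observation
  payload <- list(
    states = sepsis_states(),
    transition = list(probs = pack_array(bundle$transition$probs),
                      counts = pack_array(bundle$transition$counts),
                      backoff = pack_array(bundle$transition$backoff * 1)),
    observation = list(factors = pack_array(om$factors),
                       blood_rate = as.numeric(om$blood_rate),
                       mode = om$mode),
    binning = lapply(om$global, function(g) {
      list(edges = g$edges, probs = g$probs, modal_bin = g$modal_bin, n = g$n)
    }),
    rewards = as.numeric(bundle$model$R),
    b0 = bundle$model$b0,
    gamma = bundle$model$gamma)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Restore a serialized model
#'
#' @param path Path written by [write_model_json()].
#' @return A list with `model` ([pomdp_model()]), `transition`,
#'   `observation` and a minimal `binning` scheme usable for encoding.
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  states <- x$states
  tm <- structure(list(
    probs = unpack_array(x$transition$probs, list(states, NULL, states)),
    counts = unpack_array(x$transition$counts, list(states, NULL, states)),
    backoff = matrix(unpack_array(x$transition$backoff) > 0,
                     length(states), dimnames = list(states, NULL)),
    states = states, n_actions = as.integer(x$transition$probs$dim[2]),
    smoothing = 0), class = "transition_model")
  global <- lapply(x$binning, function(g) {
    list(edges = as.numeric(g$edges), probs = as.numeric(g$probs),
         modal_bin = as.integer(g$modal_bin), n = as.integer(g$n))
  })
  om <- structure(list(
    factors = unpack_array(x$observation$factors,
                           list(states, obs_vitals(), NULL)),
    blood_rate = stats::setNames(as.numeric(x$observation$blood_rate), states),
    states = states, vitals = obs_vitals(), n_bins = 5L,
    global = global, mode = x$observation$mode), class = "observation_model")
  binning <- structure(list(entries = list(), global = global, n_bins = 5L,
                            min_bin_count = 10L, vitals = obs_vitals()),
                       class = "binning_scheme")
  model <- pomdp_model(tm, om, R = as.numeric(x$rewards),
                       b0 = as.numeric(x$b0), gamma = x$gamma,
                       states = states)
  list(model = model, transition = tm, observation = om, binning = binning)
}

#' Serialize an alpha-vector policy to JSON
#'
#' @param policy An [alpha_policy()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_policy_json <- function(policy, path) {
  stopifnot(inherits(policy, "alpha_policy"))
  payload <- list(vectors = pack_array(policy$vectors),
                  actions = policy$actions, stage = policy$stage,
                  meta = policy$meta)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Restore a serialized policy
#'
#' @param path Path written by [write_policy_json()].
#' @return An [alpha_policy()].
#' @export
read_policy_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pol <- alpha_policy(unpack_array(x$vectors), as.integer(x$actions),
                      stage = as.integer(x$stage))
  pol$meta <- x$meta
  pol
}
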