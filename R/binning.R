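# Fallback edges when a vital was never observed anywhere in the cohort:
# clinically plausible ranges.
plausible_ranges <- function() {
  list(temperature = c(30, 43), respiratory_rate = c(5, 60),
       wbc = c(500, 50000), map = c(30, 150), sbp = c(50, 250),
       heart_rate = c(20, 250))
}

#' Six equally spaced bin edges over the sample range
#'
#' @param samples Numeric samples.
#' @param n_bins Number of bins (default 5).
#' @return Numeric vector of `n_bins + 1` strictly increasing edges.
#' @export
bin_edges <- function(samples, n_bins = 5) {
  r <- range(samples, na.rm = TRUE)
  if (!all(is.finite(r))) stop("no finite samples")
  if (r[1] == r[2]) {
    stop(structure(class = c("sepsisCDSS_degenerate_range", "error", "condition"),
                   list(message = "degenerate range: min == max", call = NULL)))
  }
  seq(r[1], r[2], length.out = n_bins + 1)
}

#' Per-bin probabilities of a fitted distribution over given edges
#'
#' The mass of each bin under the fitted CDF, renormalized to the `[min, max]`
#' range covered by the edges. Empirical and degenerate fits use the empirical
#' bin proportions instead.
#'
#' @param edges Vector of 6 edges.
#' @param fit A [fit_vital_distribution()] result.
#' @return Numeric vector of 5 probabilities summing to 1.
#' @export
bin_probabilities <- function(edges, fit) {
  n_bins <- length(edges) - 1
  if (fit$family %in% c("empirical", "degenerate")) {
    counts <- tabulate(assign_bin(fit$samples, edges) + 1L, n_bins)
    return(counts / sum(counts))
  }
  cd <- fit_cdf(fit, edges)
  mass <- diff(cd)
  tot <- sum(mass)
  if (tot <= 0) return(rep(1 / n_bins, n_bins))
  mass / tot
}

make_entry <- function(samples, fit, n_bins, min_bin_count) {
  edges <- bin_edges(samples, n_bins)
  counts <- tabulate(assign_bin(samples, edges) + 1L, n_bins)
  list(edges = edges, probs = bin_probabilities(edges, fit), fit = fit,
       family = fit$family, n = length(samples), bin_counts = counts,
       sparse = any(counts <= min_bin_count))
}

#' Build the observation binning scheme
#'
#' For every (state, vital) with data, six equally spaced edges over the
#' observed min-max range and the fitted-distribution mass of each bin. The
#' scheme additionally carries pooled (state-unconditional) edges per vital:
#' these define the runtime observation code, which cannot depend on the
#' latent state. Bins holding 10 or fewer samples are flagged sparse.
#'
#' @param samples Nested list: `samples[[state]][[vital]]` numeric vectors.
#' @param fits Optional parallel nested list of [fit_vital_distribution()]
#'   results; computed when `NULL`.
#' @param n_bins Number of bins per vital (default 5).
#' @param min_bin_count Sparsity threshold: a bin must hold more than this
#'   many samples (default 10).
#' @return An object of class `binning_scheme` with `entries[[state]][[vital]]`
#'   and `global[[vital]]` (edges, empirical probs, modal bin).
#' @export
build_binning <- function(samples, fits = NULL, n_bins = 5, min_bin_count = 10) {
  vitals <- obs_vitals()
  entries <- list()
  for (st in names(samples)) {
    entries[[st]] <- list()
    for (vt in intersect(names(samples[[st]]), vitals)) {
      x <- samples[[st]][[vt]]
      x <- x[is.finite(x)]
      if (length(x) == 0) next
      fit <- if (!is.null(fits) && !is.null(fits[[st]][[vt]])) {
        fits[[st]][[vt]]
      } else if (length(unique(x)) == 1 || length(x) < 10) {
        suppressWarnings(fit_vital_distribution(x))
      } else {
        fit_vital_distribution(x)
      }
      entries[[st]][[vt]] <- tryCatch(
        make_entry(x, fit, n_bins, min_bin_count),
        sepsisCDSS_degenerate_range = function(e) NULL)
    }
  }
  global <- list()
  for (vt in vitals) {
    pooled <- unlist(lapply(samples, function(sv) sv[[vt]]), use.names = FALSE)
    pooled <- pooled[is.finite(pooled)]
    if (length(pooled) == 0 || diff(range(pooled)) == 0) {
      warning("vital ", vt, " has no usable pooled samples; ",
              "falling back to the plausible clinical range")
      edges <- seq(plausible_ranges()[[vt]][1], plausible_ranges()[[vt]][2],
                   length.out = n_bins + 1)
      counts <- if (length(pooled)) tabulate(assign_bin(pooled, edges) + 1L, n_bins)
                else rep(1, n_bins)
    } else {
      edges <- bin_edges(pooled, n_bins)
      counts <- tabulate(assign_bin(pooled, edges) + 1L, n_bins)
    }
    global[[vt]] <- list(edges = edges, probs = counts / sum(counts),
                         modal_bin = which.max(counts) - 1L, n = length(pooled))
  }
  structure(list(entries = entries, global = global, n_bins = n_bins,
                 min_bin_count = min_bin_count, vitals = vitals),
            class = "binning_scheme")
}
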