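#' Fit a parametric distribution to vital-sign samples
#'
#' Fits each candidate family by maximum likelihood and selects the one with
#' the lowest AIC. Fewer than 10 samples signal sparsity (condition class
#' `sepsisCDSS_sparsity`) and fall back to an empirical histogram fit;
#' constant-valued samples signal degeneracy (`sepsisCDSS_degenerate`).
#'
#' @param samples Positive numeric samples.
#' @param families Candidate families, a subset of
#'   `c("normal", "lognormal", "gamma")`.
#' @return An object of class `vital_fit`: `family`, `params`, `loglik`,
#'   `aic`, the per-family `aic_table` and the sample size `n`.
#' @export
fit_vital_distribution <- function(samples,
                                   families = c("normal", "lognormal", "gamma")) {
  families <- match.arg(families, several.ok = TRUE)
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n == 0) stop("no samples to fit")
  if (diff(range(samples)) == 0) {
    warning(condition_msg("sepsisCDSS_degenerate",
                          "constant-valued samples: degenerate input"))
    return(structure(list(family = "degenerate", value = samples[1],
                          samples = samples, n = n),
                     class = "vital_fit"))
  }
  if (n < 10) {
    warning(condition_msg("sepsisCDSS_sparsity",
                          sprintf("only %d samples (<10): empirical fallback", n)))
    return(empirical_fit(samples))
  }

  fits <- list()
  m <- mean(samples); s2 <- mean((samples - m)^2)
  if ("normal" %in% families) {
    p <- c(mean = m, sd = sqrt(s2))
    fits$normal <- list(params = p,
                        loglik = sum(stats::dnorm(samples, p[1], p[2], log = TRUE)))
  }
  if ("lognormal" %in% families && all(samples > 0)) {
    lx <- log(samples)
    p <- c(meanlog = mean(lx), sdlog = sqrt(mean((lx - mean(lx))^2)))
    fits$lognormal <- list(params = p,
                           loglik = sum(stats::dlnorm(samples, p[1], p[2], log = TRUE)))
  }
  if ("gamma" %in% families && all(samples > 0)) {
    start <- list(shape = m^2 / s2, rate = m / s2)
    g <- tryCatch(
      suppressWarnings(MASS::fitdistr(samples, "gamma", start = start,
                                      lower = c(1e-10, 1e-10))),
      error = function(e) NULL)
    if (!is.null(g)) {
      fits$gamma <- list(params = g$estimate, loglik = as.numeric(g$loglik))
    }
  }
  if (length(fits) == 0) stop("no candidate family could be fitted")
  aic <- vapply(fits, function(f) 2 * 2 - 2 * f$loglik, numeric(1))
  best <- names(which.min(aic))
  structure(list(family = best, params = fits[[best]]$params,
                 loglik = fits[[best]]$loglik, aic = aic[[best]],
                 aic_table = aic, n = n),
            class = "vital_fit")
}

condition_msg <- function(class, msg) {
  structure(class = c(class, "warning", "condition"),
            list(message = msg, call = NULL))
}

empirical_fit <- function(samples) {
  structure(list(family = "empirical", samples = samples, n = length(samples)),
            class = "vital_fit")
}

#' Cumulative distribution function of a fitted vital distribution
#'
#' @param fit A `vital_fit`.
#' @param q Quantiles.
#' @return CDF values at `q`.
#' @export
fit_cdf <- function(fit, q) {
  stopifnot(inherits(fit, "vital_fit"))
  switch(fit$family,
         normal = stats::pnorm(q, fit$params[["mean"]], fit$params[["sd"]]),
         lognormal = stats::plnorm(q, fit$params[["meanlog"]], fit$params[["sdlog"]]),
         gamma = stats::pgamma(q, shape = fit$params[["shape"]], rate = fit$params[["rate"]]),
         empirical = stats::ecdf(fit$samples)(q),
         degenerate = as.numeric(q >= fit$value),
         stop("unknown family ", fit$family))
}

#' @export
print.vital_fit <- function(x, ...) {
  cat(sprintf("vital_fit: family=%s, n=%d\n", x$family, x$n))
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}
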