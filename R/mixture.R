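#' Fit a univariate Gaussian mixture by EM
#'
#' Expectation-maximisation with unequal component variances. The first
#' start places the k means at evenly spread quantiles of the data with
#' standard deviations `sd(x)/k` and uniform weights; additional restarts
#' jitter the means. EM iterates until the relative log-likelihood change
#' falls below `tol` or `max_iter` is reached; the best of the restarts (by
#' log-likelihood) is returned. Component standard deviations are floored at
#' `sd_floor` to prevent singular components on duplicated values.
#'
#' @param values Numeric sample.
#' @param k Component count (>= 1).
#' @param seed Integer seed controlling the restart jitter.
#' @param restarts Number of initialisations (default 10).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @param sd_floor Lower bound on component standard deviations.
#' @return Object of class `ks_mixture`: list with `k`, `weights`, `means`
#'   (sorted ascending, with `weights`/`sds` reordered to match), `sds`,
#'   `loglik`, `bic` (`-2 loglik + (3k - 1) log n`), `n`, and `loglik_trace`
#'   of the winning start.
#' @export
fit_gmm <- function(values, k, seed = 1L, restarts = 10L, tol = 1e-8,
                    max_iter = 500L, sd_floor = 1e-4) {
  x <- as.numeric(values)
  n <- length(x)
  if (k < 1L) stop("k must be >= 1")
  if (n < 5L * k) stop("insufficient data for k: need n >= 5k")
  if (k == 1L) {
    mu <- mean(x)
    sdev <- max(sqrt(mean((x - mu)^2)), sd_floor)
    ll <- sum(dnorm(x, mu, sdev, log = TRUE))
    return(new_ks_mixture(1L, 1, mu, sdev, ll, n, loglik_trace = ll))
  }
  rng <- local_rng(seed)
  base_means <- as.numeric(quantile(x, probs = (seq_len(k) - 0.5) / k,
                                    names = FALSE))
  spread <- max(sd(x), sd_floor)
  best <- NULL
  for (r in seq_len(restarts)) {
    mu <- if (r == 1L) base_means else sort(base_means + rng$rnorm(k) * spread / 2)
    fit <- em_run(x, k, mu, rep(spread / k, k), rep(1 / k, k),
                  tol, max_iter, sd_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$means)
  new_ks_mixture(k, best$weights[ord], best$means[ord], best$sds[ord],
                 best$loglik, n, loglik_trace = best$trace)
}

# one EM run (C++ core); returns weights/means/sds/loglik/trace
em_run <- function(x, k, mu, sdev, w, tol, max_iter, sd_floor) {
  fit <- cpp_em_gmm(x, mu, pmax(sdev, sd_floor), w, tol,
                    as.integer(max_iter), sd_floor)
  list(weights = fit$weights, means = fit$means, sds = fit$sds,
       loglik = fit$loglik, trace = fit$trace)
}

new_ks_mixture <- function(k, weights, means, sds, loglik, n, loglik_trace) {
  p <- 3 * k - 1
  structure(list(k = k, weights = weights, means = means, sds = sds,
                 loglik = loglik, bic = -2 * loglik + p * log(n), n = n,
                 loglik_trace = loglik_trace),
            class = "ks_mixture")
}

#' @export
print.ks_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture: k = %d, n = %d, loglik = %.3f, BIC = %.3f\n",
              x$k, x$n, x$loglik, x$bic))
  print(data.frame(weight = round(x$weights, 4), mean = round(x$means, 4),
                   sd = round(x$sds, 4)))
  invisible(x)
}

#' Select a Gaussian mixture by BIC over a range of component counts
#'
#' Fits every feasible component count in `[k_min, k_max]` (feasible means
#' `n >= 5k`) with [fit_gmm()] and returns the model with the lowest BIC;
#' ties within `1e-6` go to the smaller k. This mirrors mixture-based Ks peak
#' detection with 1-10 components selected by the Bayesian information
#' criterion.
#'
#' @inheritParams fit_gmm
#' @param k_min,k_max Range of component counts (defaults 1 and 10).
#' @return The winning `ks_mixture`, with an extra `bic_table` element
#'   (data frame k -> bic) covering every fitted k.
#' @export
select_mixture <- function(values, k_min = 1L, k_max = 10L, seed = 1L,
                           restarts = 10L) {
  n <- length(values)
  ks <- seq.int(k_min, k_max)
  ks <- ks[n >= 5L * ks]
  if (length(ks) == 0L) stop("insufficient data for k: need n >= 5k")
  fits <- lapply(ks, function(k)
    fit_gmm(values, k, seed = seed + k, restarts = restarts))
  bics <- vapply(fits, `[[`, numeric(1L), "bic")
  best_idx <- which(bics <= min(bics) + 1e-6)[1L]
  best <- fits[[best_idx]]
  best$bic_table <- data.frame(k = ks, bic = bics)
  best
}

#' Partition mixture component means into recent and ancient peaks
#'
#' Peaks at Ks at or below the cutoff are read as current / very recent
#' duplications; the rest as candidate ancient duplication events.
#'
#' @param model A fitted `ks_mixture`.
#' @param recent_cutoff Ks cutoff (default 0.1).
#' @return List with `recent` and `ancient` vectors of component means.
#' @export
classify_peaks <- function(model, recent_cutoff = 0.1) {
  m <- model$means
  list(recent = m[m <= recent_cutoff], ancient = m[m > recent_cutoff])
}

# deterministic local RNG that does not disturb the global .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv()))
              rm(".Random.seed", envir = globalenv()))
    if (is.null(env$state)) set.seed(seed) else assign(".Random.seed", env$state, globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    out
  }
  list(rnorm = function(n, ...) draw(rnorm, n, ...),
       runif = function(n, ...) draw(runif, n, ...),
       sample_int = function(n, size, replace = FALSE, prob = NULL)
         draw(sample.int, n, size, replace = replace, prob = prob))
}
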