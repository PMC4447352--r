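#' SiZer significance map of a univariate sample
#'
#' SIgnificant ZERo crossings of derivatives: for every combination of grid
#' location x and bandwidth h, the Gaussian-kernel estimate of the density
#' derivative and its standard error are computed from the sample, and a
#' simultaneous confidence interval classifies the smoothed slope as
#' significantly increasing, significantly decreasing, or flat. The
#' simultaneous quantile follows the independent-blocks convention with
#' `m(h) = range(x_grid) / (2 h)` effective blocks. Cells whose local
#' effective sample size (data points within `x +/- 2h`) falls below
#' `ess_min` are coded sparse.
#'
#' @param values Numeric sample (n >= 50).
#' @param x_grid Evaluation grid; default 201 equal steps over
#'   `[0, max(values)]`.
#' @param bandwidths Bandwidth family; default 21 log-spaced values spanning
#'   `[range/100, range/2]` of the grid.
#' @param alpha Significance level (default 0.05).
#' @param ess_min Sparseness threshold (default 5).
#' @return Object of class `sizer_map`: list with `x_grid`, `bandwidths`,
#'   `codes` (bandwidth x location character matrix over `"INCREASE"`,
#'   `"DECREASE"`, `"FLAT"`, `"SPARSE"`), `deriv` and `se` matrices, and
#'   `alpha`.
#' @export
sizer_map <- function(values, x_grid = NULL, bandwidths = NULL, alpha = 0.05,
                      ess_min = 5) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 50L) stop("need at least 50 observations for a SiZer map")
  if (is.null(x_grid)) x_grid <- seq(0, max(x), length.out = 201L)
  if (is.null(bandwidths)) {
    rng <- diff(range(x_grid))
    bandwidths <- exp(seq(log(rng / 100), log(rng / 2), length.out = 21L))
  }
  if (any(bandwidths <= 0)) stop("bandwidths must be positive")
  if (length(x_grid) == 0L || length(bandwidths) == 0L) stop("empty grid")
  x_grid <- sort(x_grid)
  bandwidths <- sort(bandwidths)
  nh <- length(bandwidths); ng <- length(x_grid)
  codes <- matrix("FLAT", nh, ng)
  deriv <- matrix(NA_real_, nh, ng)
  se <- matrix(NA_real_, nh, ng)
  grid_range <- diff(range(x_grid))
  xs <- sort(x)
  for (hi in seq_len(nh)) {
    h <- bandwidths[hi]
    m_blocks <- max(grid_range / (2 * h), 1)
    q <- qnorm((1 + (1 - alpha)^(1 / m_blocks)) / 2)
    for (gi in seq_len(ng)) {
      x0 <- x_grid[gi]
      ess <- sum_in_window(xs, x0 - 2 * h, x0 + 2 * h)
      if (ess < ess_min) {
        codes[hi, gi] <- "SPARSE"
        next
      }
      u <- (x0 - x) / h
      # d/dx of the kernel density estimate: mean of phi'((x-Xi)/h)/h^2
      gvals <- -u * dnorm(u) / h^2
      est <- mean(gvals)
      se_hat <- sd(gvals) / sqrt(n)
      deriv[hi, gi] <- est
      se[hi, gi] <- se_hat
      if (se_hat == 0) next
      lo <- est - q * se_hat
      hi_ci <- est + q * se_hat
      if (lo > 0) codes[hi, gi] <- "INCREASE"
      else if (hi_ci < 0) codes[hi, gi] <- "DECREASE"
    }
  }
  structure(list(x_grid = x_grid, bandwidths = bandwidths, codes = codes,
                 deriv = deriv, se = se, alpha = alpha, ess_min = ess_min,
                 n = n),
            class = "sizer_map")
}

sum_in_window <- function(xs, lo, hi) {
  # xs sorted ascending
  findInterval(hi, xs) - findInterval(lo, xs, left.open = TRUE)
}

#' @export
print.sizer_map <- function(x, ...) {
  cat(sprintf("SiZer map: %d bandwidths x %d locations, alpha = %g, n = %d\n",
              length(x$bandwidths), length(x$x_grid), x$alpha, x$n))
  tab <- table(factor(x$codes, c("INCREASE", "DECREASE", "FLAT", "SPARSE")))
  print(tab)
  invisible(x)
}

#' Extract significant peaks from a SiZer map
#'
#' A peak at one bandwidth is a run of INCREASE cells followed, possibly
#' after intervening FLAT cells, by a run of DECREASE cells; the reported
#' interval spans from the start of the increase run to the end of the
#' decrease run. Each peak is reported at the smallest bandwidth exhibiting
#' the pattern, and intervals that overlap across bandwidths are merged
#' (keeping the smallest bandwidth).
#'
#' @param map A `sizer_map`.
#' @return Data frame with `x_start`, `x_end`, `bandwidth`; zero rows when
#'   no bandwidth shows the pattern.
#' @export
significant_peaks <- function(map) {
  found <- list()
  for (hi in seq_along(map$bandwidths)) {
    row <- map$codes[hi, ]
    for (iv in scan_peak_runs(row)) {
      found[[length(found) + 1L]] <- data.frame(
        x_start = map$x_grid[iv[1L]], x_end = map$x_grid[iv[2L]],
        bandwidth = map$bandwidths[hi])
    }
  }
  if (length(found) == 0L) {
    return(data.frame(x_start = numeric(), x_end = numeric(),
                      bandwidth = numeric()))
  }
  peaks <- do.call(rbind, found)
  peaks <- peaks[order(peaks$bandwidth, peaks$x_start), , drop = FALSE]
  # merge overlapping intervals, keeping the smallest contributing bandwidth
  merged <- list()
  for (i in seq_len(nrow(peaks))) {
    placed <- FALSE
    for (j in seq_along(merged)) {
      if (peaks$x_start[i] <= merged[[j]]$x_end &&
          peaks$x_end[i] >= merged[[j]]$x_start) {
        merged[[j]]$x_start <- min(merged[[j]]$x_start, peaks$x_start[i])
        merged[[j]]$x_end <- max(merged[[j]]$x_end, peaks$x_end[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) merged[[length(merged) + 1L]] <- peaks[i, ]
  }
  out <- do.call(rbind, merged)
  out <- out[order(out$x_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# indices (start of INCREASE run, end of DECREASE run) for one bandwidth row
scan_peak_runs <- function(row) {
  out <- list()
  i <- 1L
  n <- length(row)
  while (i <= n) {
    if (row[i] != "INCREASE") { i <- i + 1L; next }
    start <- i
    while (i <= n && row[i] == "INCREASE") i <- i + 1L
    j <- i
    while (j <= n && row[j] == "FLAT") j <- j + 1L
    if (j <= n && row[j] == "DECREASE") {
      while (j <= n && row[j] == "DECREASE") j <- j + 1L
      out[[length(out) + 1L]] <- c(start, j - 1L)
      i <- j
    }
  }
  out
}

#' Export a SiZer map as a long-format table
#'
#' One row per (bandwidth, location) cell with its classification code,
#' suitable for TSV export or plotting.
#'
#' @param map A `sizer_map`.
#' @return Data frame with `bandwidth`, `x`, `code`.
#' @export
sizer_table <- function(map) {
  data.frame(
    bandwidth = rep(map$bandwidths, times = length(map$x_grid)),
    x = rep(map$x_grid, each = length(map$bandwidths)),
    code = as.vector(map$codes))
}

#' Plot a SiZer map
#'
#' Raster rendering with the conventional colour semantics: blue for
#' significant increases, red for decreases, pink (here light grey-pink) for
#' flat, grey for sparse cells. Bandwidths are drawn on a log axis.
#'
#' @param x A `sizer_map`.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.sizer_map <- function(x, ...) {
  codes <- matrix(match(x$codes, c("DECREASE", "FLAT", "INCREASE", "SPARSE")),
                  nrow = nrow(x$codes))
  graphics::image(x = x$x_grid, y = log10(x$bandwidths), z = t(codes),
                  col = c("#d7191c", "#f4c2c2", "#2c7bb6", "#bdbdbd"),
                  zlim = c(1, 4), xlab = "Ks", ylab = "log10 bandwidth", ...)
  invisible(x)
}
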