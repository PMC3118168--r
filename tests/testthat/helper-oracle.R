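# Independent numerical oracles, deliberately avoiding the code paths they
# check.

# standard-normal quantile by bisection on pnorm (oracle for probit_bdev)
qnorm_bisect <- function(p, lo = -10, hi = 10, tol = 1e-10) {
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (stats::pnorm(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# two-sided t tail by numeric integration of the density written out
# explicitly (oracle for segment_pvalue)
t_tail_integrate <- function(t, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(t), Inf, rel.tol = 1e-10)$value
}

# exhaustive least-squares changepoint search for k = 0, 1, 2 breakpoints
# (oracle for the segmentation on short signals)
rss_of <- function(y, bp) {
  bounds <- c(0L, bp, length(y))
  sum(vapply(seq_len(length(bounds) - 1L), function(j) {
    seg <- y[(bounds[j] + 1L):bounds[j + 1L]]
    sum((seg - mean(seg))^2)
  }, numeric(1)))
}

exhaustive_changepoints <- function(y, max_k = 2L) {
  n <- length(y)
  best <- list(`0` = list(bp = integer(0), rss = rss_of(y, integer(0))))
  if (max_k >= 1L) {
    rss1 <- vapply(1:(n - 1L), function(b) rss_of(y, b), numeric(1))
    best$`1` <- list(bp = which.min(rss1), rss = min(rss1))
  }
  if (max_k >= 2L) {
    b2 <- list(bp = NULL, rss = Inf)
    for (i in 1:(n - 2L)) for (j in (i + 1L):(n - 1L)) {
      r <- rss_of(y, c(i, j))
      if (r < b2$rss) b2 <- list(bp = c(i, j), rss = r)
    }
    best$`2` <- b2
  }
  best
}

# best single changepoint by direct RSS comparison, restricted to a window
# (keeps the oracle affordable on long signals)
exhaustive_changepoints_window <- function(y, center, halfwidth) {
  cands <- max(1L, center - halfwidth):min(length(y) - 1L, center + halfwidth)
  rss <- vapply(cands, function(b) rss_of(y, b), numeric(1))
  cands[which.min(rss)]
}

# two-segment t statistics of a breakpoint set, computed directly from
# segment means (no shared code with t_statistics)
oracle_boundary_t <- function(y, bp, sigma) {
  bounds <- c(0L, sort(bp), length(y))
  vapply(seq_along(bp), function(j) {
    L <- y[(bounds[j] + 1L):bounds[j + 1L]]
    R <- y[(bounds[j + 1L] + 1L):bounds[j + 2L]]
    (mean(R) - mean(L)) / (sigma * sqrt(1 / length(L) + 1 / length(R)))
  }, numeric(1))
}
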