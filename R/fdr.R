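#' Two-sided p-value for a segment t-statistic
#'
#' Under the no-alteration null the per-segment statistic follows a
#' Student t distribution with `n - 1` degrees of freedom; for large
#' segments the standard-normal tail is an accurate substitute and can be
#' switched on with `normal_approx` (applied when `n > 200`).
#'
#' @param t segment t-statistic(s).
#' @param n number of probes in the segment(s) (`n >= 2`).
#' @param normal_approx use `pnorm` instead of `pt` when `n > 200`.
#' @return Two-sided tail probability `P(|t_(n-1)| > |t|)` in `[0, 1]`.
#' @export
segment_pvalue <- function(t, n, normal_approx = FALSE) {
  stopifnot(all(n >= 2))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  if (normal_approx) {
    big <- n > 200
    if (any(big)) p[big] <- 2 * stats::pnorm(-abs(t))[big]
  }
  pmin(p, 1)
}

#' Conservative genome-wide FDR estimate for a parameter setting
#'
#' The number of independent minimum-length tests across an array of `N`
#' probes is bounded by the count of disjoint `min_seg_len` windows,
#' `N / min_seg_len`; each false window exceeds the elimination threshold
#' `T` with probability `P(|t_nu| > T)`, `nu = min_seg_len - 1`. The
#' expected number of false calls is their product and the FDR estimate
#' divides by the number of emitted calls (0 calls give FDR 0, with the
#' expected count still recorded, so parameter scans stay well defined).
#' The estimate is monotone non-increasing in both `T` and `min_seg_len`.
#'
#' @param n_called number of emitted segment calls.
#' @param N total number of probes on the array.
#' @param T elimination threshold used.
#' @param min_seg_len minimum segment length used.
#' @return An object of class `fdr_estimate`: list with `fdr`,
#'   `expected_false`, `n_called`, `N`, `T`, `min_seg_len`.
#' @examples
#' estimate_fdr(n_called = 1, N = 1e6, T = 8, min_seg_len = 300)$fdr  # < 1e-4
#' @export
estimate_fdr <- function(n_called, N, T, min_seg_len) {
  stopifnot(N >= min_seg_len, min_seg_len >= 2, T > 0, n_called >= 0)
  p_tail <- 2 * stats::pt(-abs(T), df = min_seg_len - 1)
  expected_false <- (N / min_seg_len) * p_tail
  fdr <- if (n_called == 0) 0 else min(1, expected_false / n_called)
  structure(list(fdr = fdr, expected_false = expected_false,
                 n_called = as.integer(n_called), N = N, T = T,
                 min_seg_len = as.integer(min_seg_len)),
            class = "fdr_estimate")
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat(sprintf("FDR estimate: %.3g (expected false calls %.3g over %d calls; N = %g, T = %g, min_seg_len = %d)\n",
              x$fdr, x$expected_false, x$n_called, x$N, x$T, x$min_seg_len))
  invisible(x)
}

#' Smallest detectable span for a minimum segment length
#'
#' With `N` probes spread over `genome_bp` base pairs, a call must span at
#' least `min_seg_len * genome_bp / N` base pairs. At the reference setting
#' (300 probes on a 1M-probe array over a 3,000 Mb genome) this is 0.9 Mb.
#'
#' @param min_seg_len minimum probes per call.
#' @param n_probes probes on the array.
#' @param genome_bp genome extent covered by the array, in bp.
#' @return Minimum detectable span in Mb.
#' @export
min_detectable_span <- function(min_seg_len, n_probes, genome_bp = 3e9) {
  stopifnot(min_seg_len >= 1, n_probes >= min_seg_len)
  min_seg_len * (genome_bp / n_probes) / 1e6
}

#' Recommend segmentation settings for a target FDR
#'
#' Scales the reference window (300 probes per million array probes)
#' to the array at hand, then picks the smallest threshold `T` on the
#' documented grid `{2, 2.5, 3, 3.5, 4, 4.5, 5, 8}` whose [estimate_fdr()]
#' (evaluated at one call) meets the target. Deterministic; errors with the
#' closest achievable value when no grid point satisfies the target.
#'
#' @param N number of probes on the array.
#' @param target_fdr desired FDR bound in `(0, 1]`.
#' @param a sparseness prior to embed in the returned parameters.
#' @return A [seg_params()] object with the selected `T` and `min_seg_len`.
#' @export
recommend_settings <- function(N, target_fdr, a = 0.8) {
  stopifnot(N > 0, target_fdr > 0, target_fdr <= 1)
  grid_T <- c(2, 2.5, 3, 3.5, 4, 4.5, 5, 8)
  msl <- max(2L, as.integer(round(300 * N / 1e6)))
  fdrs <- vapply(grid_T, function(tt) estimate_fdr(1L, N, tt, msl)$fdr, numeric(1))
  ok <- which(fdrs <= target_fdr)
  if (!length(ok))
    stop(sprintf("target FDR %g unachievable on the settings grid (closest achievable: %g at T = %g)",
                 target_fdr, min(fdrs), grid_T[which.min(fdrs)]))
  seg_params(a = a, T = grid_T[ok[1]], min_seg_len = msl)
}
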