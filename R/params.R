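#' Segmentation and classification parameters
#'
#' Bundles every tunable of the mosaic-calling pipeline. The defaults mirror
#' the conservative preliminary-scan profile for a ~1M-probe array: sparse
#' prior `a = 0.8`, backward-elimination threshold `T = 8` and
#' `min_seg_len = 300` probes, which bounds the genome-wide FDR below 1e-4
#' (see [estimate_fdr()]).
#'
#' @param a sparseness prior of the candidate-breakpoint generator. Larger
#'   values admit more candidates (higher sensitivity, higher FDR before
#'   backward elimination). Typical range 0.2--0.8.
#' @param b second prior parameter, kept at 0 (uninformative) by default.
#' @param T backward-elimination threshold: breakpoints (and emitted
#'   segments) must reach this t-statistic.
#' @param min_seg_len minimum number of probes per emitted segment; segments
#'   shorter than this are merged into the more similar neighbour.
#' @param epsilon clamp for the probit transform; b-deviations below
#'   `epsilon` map to `qnorm(epsilon)` (about -3.72 at the default 1e-4)
#'   instead of `-Inf`.
#' @param het_window open BAF interval used to select heterozygous probes
#'   when no genotype calls are available.
#' @param lrr_upd_band symmetric relative-LRR threshold: segments with mean
#'   relative LRR inside `[-lrr_upd_band, lrr_upd_band]` are copy-neutral
#'   (UPD); below is a deletion, above a duplication.
#' @param trisomy_fraction chromosome-coverage fraction above which a
#'   copy-number call is promoted to a whole-chromosome event (trisomy for
#'   gains, monosomy for losses).
#' @param sigma_estimator noise-scale rule, `"diff_mad"` (median absolute
#'   successive difference / (sqrt(2) * 0.6745)) or `"sd"`.
#' @param informative_only if `TRUE`, segmentation runs on heterozygous
#'   probes only; the default `FALSE` segments all probes, matching the
#'   probe-count semantics of `min_seg_len` on real arrays (300 probes on a
#'   1M array spans ~0.9 Mb).
#' @param use_genotypes use genotype calls (when present) to pick the
#'   expected BAF level and the heterozygous subset; otherwise the
#'   nearest-cluster rule and `het_window` are used.
#' @param normal_approx use the standard-normal tail instead of the exact
#'   t tail for segment p-values when a segment has more than 200 probes.
#' @param max_iter maximum refinement sweeps of the candidate generator.
#' @param tol convergence tolerance of the candidate generator (relative
#'   residual-sum-of-squares improvement per refinement sweep).
#' @return An object of class `seg_params` (a validated list).
#' @examples
#' p <- seg_params(a = 0.5, T = 2, min_seg_len = 900)
#' p$T
#' @export
seg_params <- function(a = 0.8, b = 0, T = 8, min_seg_len = 300,
                       epsilon = 1e-4, het_window = c(0.1, 0.9),
                       lrr_upd_band = 0.10, trisomy_fraction = 0.95,
                       sigma_estimator = c("diff_mad", "sd"),
                       informative_only = FALSE, use_genotypes = TRUE,
                       normal_approx = FALSE, max_iter = 10L, tol = 1e-4) {
  sigma_estimator <- match.arg(sigma_estimator)
  stopifnot(is.numeric(a), length(a) == 1L, a > 0)
  stopifnot(is.numeric(T), length(T) == 1L, T > 0)
  stopifnot(is.numeric(min_seg_len), length(min_seg_len) == 1L, min_seg_len >= 2)
  stopifnot(is.numeric(epsilon), epsilon > 0, epsilon < 0.5)
  stopifnot(length(het_window) == 2L, het_window[1] < het_window[2],
            het_window[1] >= 0, het_window[2] <= 1)
  stopifnot(trisomy_fraction >= 0, trisomy_fraction <= 1)
  structure(list(
    a = a, b = b, T = T, min_seg_len = as.integer(min_seg_len),
    epsilon = epsilon, het_window = het_window,
    lrr_upd_band = lrr_upd_band, trisomy_fraction = trisomy_fraction,
    sigma_estimator = sigma_estimator,
    informative_only = isTRUE(informative_only),
    use_genotypes = isTRUE(use_genotypes),
    normal_approx = isTRUE(normal_approx),
    max_iter = as.integer(max_iter), tol = tol
  ), class = "seg_params")
}

#' @export
print.seg_params <- function(x, ...) {
  cat("Segmentation parameters\n")
  cat(sprintf("  a = %g, b = %g, T = %g, min_seg_len = %d\n",
              x$a, x$b, x$T, x$min_seg_len))
  cat(sprintf("  epsilon = %g, het_window = (%g, %g)\n",
              x$epsilon, x$het_window[1], x$het_window[2]))
  cat(sprintf("  lrr_upd_band = %g, trisomy_fraction = %g\n",
              x$lrr_upd_band, x$trisomy_fraction))
  cat(sprintf("  sigma_estimator = %s, informative_only = %s\n",
              x$sigma_estimator, x$informative_only))
  invisible(x)
}
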