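#' Expected BAF level for a probe
#'
#' Maps each probe to its expected B-allele frequency cluster: `AA -> 0`,
#' `AB -> 0.5`, `BB -> 1` when a genotype call is available; otherwise the
#' nearest of `{0, 0.5, 1}` to the observed BAF, with ties at 0.25/0.75
#' broken toward 0.5 (favouring sensitivity to allelic imbalance).
#'
#' @param baf observed BAF values in `[0, 1]`.
#' @param genotype optional genotype calls (`"AA"`, `"AB"`, `"BB"`; any
#'   other value, e.g. `"NC"`, falls back to the nearest-cluster rule).
#' @return Numeric vector of expected levels; `NA` where the BAF itself is
#'   missing and no genotype resolves the level.
#' @export
expected_baf <- function(baf, genotype = NULL) {
  nearest <- ifelse(is.na(baf), NA_real_,
                    ifelse(baf < 0.25, 0, ifelse(baf <= 0.75, 0.5, 1)))
  if (is.null(genotype)) return(nearest)
  out <- nearest
  out[!is.na(genotype) & genotype == "AA"] <- 0
  out[!is.na(genotype) & genotype == "AB"] <- 0.5
  out[!is.na(genotype) & genotype == "BB"] <- 1
  out
}

#' Per-probe b-deviation
#'
#' The b-deviation is the absolute difference between the observed BAF and
#' the expected level of its genotype cluster; it is ~0 for probes from
#' unaltered diploid cells and grows with the allelic imbalance produced by
#' a mosaic alteration.
#'
#' @param baf observed BAF values.
#' @param expected expected levels (see [expected_baf()]).
#' @return `abs(baf - expected)`.
#' @export
compute_bdev <- function(baf, expected) abs(baf - expected)

#' Probit transform of the b-deviation
#'
#' Applies the standard-normal quantile function to the clamped
#' b-deviation, `qnorm(clamp(b_dev, epsilon, 1 - epsilon))`, spreading the
#' boundary-compressed b-deviation scale before segmentation. The clamp
#' keeps the transform finite at `b_dev = 0` (value `qnorm(epsilon)`,
#' about -3.72 at the default `epsilon = 1e-4`).
#'
#' @param b_dev b-deviation values (non-negative).
#' @param epsilon clamp constant in `(0, 0.5)`.
#' @return Transformed values, finite everywhere.
#' @export
probit_bdev <- function(b_dev, epsilon = 1e-4) {
  stopifnot(epsilon > 0, epsilon < 0.5)
  stats::qnorm(pmin(pmax(b_dev, epsilon), 1 - epsilon))
}

#' Select informative (heterozygous) probes
#'
#' Heterozygous probes are the ones that carry the allelic-imbalance signal
#' of a mosaic alteration. With genotype calls, `AB` probes are selected;
#' without, probes whose BAF lies strictly inside `het_window` are taken.
#' Probes with missing BAF are never informative.
#'
#' @param track a validated [probe_track()].
#' @param het_window open BAF interval, default `(0.1, 0.9)`.
#' @param use_genotypes use genotype calls when the track has them.
#' @return Logical mask over the probes of `track`.
#' @export
select_informative_probes <- function(track, het_window = c(0.1, 0.9),
                                      use_genotypes = TRUE) {
  ok <- !is.na(track$baf)
  if (use_genotypes && !is.null(track$genotype)) {
    return(ok & !is.na(track$genotype) & track$genotype == "AB")
  }
  ok & track$baf > het_window[1] & track$baf < het_window[2]
}

#' Transform a probe track into a segmentation-ready b-deviation signal
#'
#' Composes [expected_baf()], [compute_bdev()] and [probit_bdev()] over the
#' analysis probes of a track. By default all probes with usable BAF enter
#' the signal (so `min_seg_len` counts array probes); with
#' `params$informative_only = TRUE` only heterozygous probes are used.
#'
#' @param track a validated [probe_track()].
#' @param params a [seg_params()] object.
#' @return An object of class `bdev_signal`: list with `values` (probit
#'   scale), `bdev` (original scale), `probe_index` (strictly increasing
#'   indices into `track`), `position`, `informative` (het mask over the
#'   signal probes), `chrom`, `n_track` and `epsilon`.
#' @export
transform_track <- function(track, params = seg_params()) {
  stopifnot(inherits(track, "probe_track"))
  het <- select_informative_probes(track, params$het_window, params$use_genotypes)
  keep <- if (params$informative_only) het else !is.na(track$baf)
  idx <- which(keep)
  gt <- if (params$use_genotypes && !is.null(track$genotype)) track$genotype[idx]
  exp_lvl <- expected_baf(track$baf[idx], gt)
  bdev <- compute_bdev(track$baf[idx], exp_lvl)
  drop <- is.na(bdev)
  if (any(drop)) {
    idx <- idx[!drop]
    bdev <- bdev[!drop]
  }
  structure(list(
    values = probit_bdev(bdev, params$epsilon),
    bdev = bdev,
    probe_index = idx,
    position = track$position[idx],
    informative = het[idx],
    chrom = track$chrom,
    n_track = length(track),
    epsilon = params$epsilon
  ), class = "bdev_signal")
}

#' @export
print.bdev_signal <- function(x, ...) {
  cat(sprintf("bdev_signal: chromosome %s, %d of %d probes (%d heterozygous)\n",
              x$chrom, length(x$values), x$n_track, sum(x$informative)))
  invisible(x)
}
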