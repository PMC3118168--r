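#' Mean segment LRR relative to the diploid genome baseline
#'
#' LRR thresholds are meaningful only relative to the sample's own diploid
#' intensity level, so the baseline is the mean LRR over autosomal probes
#' lying outside every called segment; each call's mean LRR is reported
#' relative to it. Adding a constant to every LRR therefore leaves the
#' relative values (and the classification) unchanged.
#'
#' @param tracks a named list of validated [probe_track()] objects.
#' @param calls a data frame of segment calls with `chrom`, `start_index`,
#'   `end_index` (raw probe indices within their chromosome track).
#' @return `calls` with `mean_lrr` filled with the relative mean LRR.
#' @export
relative_mean_lrr <- function(tracks, calls) {
  baseline_num <- 0
  baseline_n <- 0L
  for (ch in names(tracks)) {
    if (!is_autosome(ch)) next
    tr <- tracks[[ch]]
    excl <- rep(FALSE, length(tr))
    rows <- which(calls$chrom == ch)
    for (r in rows) excl[calls$start_index[r]:calls$end_index[r]] <- TRUE
    lrr <- tr$lrr[!excl]
    lrr <- lrr[!is.na(lrr)]
    baseline_num <- baseline_num + sum(lrr)
    baseline_n <- baseline_n + length(lrr)
  }
  if (baseline_n == 0L)
    stop("no autosomal baseline probes outside called segments; cannot compute relative LRR")
  baseline <- baseline_num / baseline_n
  mean_lrr <- vapply(seq_len(nrow(calls)), function(r) {
    tr <- tracks[[calls$chrom[r]]]
    lrr <- tr$lrr[calls$start_index[r]:calls$end_index[r]]
    mean(lrr, na.rm = TRUE) - baseline
  }, numeric(1))
  calls$mean_lrr <- if (nrow(calls)) mean_lrr else numeric(0)
  calls
}

#' Classify a called segment from its relative LRR
#'
#' A segment with relative mean LRR below `-lrr_upd_band` is a (mosaic)
#' deletion, above `+lrr_upd_band` a duplication, and inside the closed
#' band a copy-neutral event (UPD). Copy-number calls covering more than
#' `trisomy_fraction` of their chromosome are promoted to whole-chromosome
#' events: gains become trisomies, losses monosomies.
#'
#' @param lrr_rel relative mean LRR value(s).
#' @param chrom_coverage fraction(s) of chromosome probes spanned.
#' @param params a [seg_params()] (thresholds `lrr_upd_band`,
#'   `trisomy_fraction`).
#' @return Character vector in
#'   `{"deletion","duplication","UPD","trisomy","monosomy","unclassified"}`.
#' @export
classify_segment <- function(lrr_rel, chrom_coverage, params = seg_params()) {
  band <- params$lrr_upd_band
  out <- ifelse(is.na(lrr_rel), "unclassified",
         ifelse(lrr_rel < -band, "deletion",
         ifelse(lrr_rel > band, "duplication", "UPD")))
  whole <- !is.na(chrom_coverage) & chrom_coverage > params$trisomy_fraction
  out[whole & out == "duplication"] <- "trisomy"
  out[whole & out == "deletion"] <- "monosomy"
  out
}

#' Estimate the affected cell fraction from the mean b-deviation
#'
#' Inverts the allelic-dosage band positions of each event type. With a
#' fraction `p` of affected cells the upper heterozygous band sits at
#' `(1+p)/2` for copy-neutral events (UPD), `1/(2-p)` for deletions and
#' `(1+p)/(2+p)` for duplications/trisomies, giving
#' `p = 2b` (UPD), `p = 2b/(0.5 + b)` (deletion, monosomy) and
#' `p = 2b/(0.5 - b)` (duplication, trisomy) for band offset
#' `b = bdev_mean`. Results are clipped to `[0, 1]`; a duplication with
#' `b >= 0.5` is undefined and returns `NA` with a warning.
#'
#' @param bdev_mean mean (or median) per-probe b-deviation of the call on
#'   the original scale, in `[0, 0.5)`.
#' @param event event label(s) as from [classify_segment()].
#' @return Estimated fraction(s) of affected cells in `[0, 1]`.
#' @examples
#' estimate_cell_fraction(0.05, "UPD")        # 0.10
#' estimate_cell_fraction(0.10, "duplication") # 0.50
#' @export
estimate_cell_fraction <- function(bdev_mean, event) {
  stopifnot(all(is.na(bdev_mean) | bdev_mean >= 0))
  n <- max(length(bdev_mean), length(event))
  b <- rep_len(as.numeric(bdev_mean), n)
  ev <- rep_len(as.character(event), n)
  p <- rep(NA_real_, n)
  upd <- ev == "UPD"
  del <- ev %in% c("deletion", "monosomy")
  dup <- ev %in% c("duplication", "trisomy")
  p[upd] <- 2 * b[upd]
  p[del] <- 2 * b[del] / (0.5 + b[del])
  bad_dup <- dup & !is.na(b) & b >= 0.5
  if (any(bad_dup)) {
    warning("duplication with b-deviation >= 0.5: cell fraction undefined")
    dup <- dup & !bad_dup
  }
  p[dup] <- 2 * b[dup] / (0.5 - b[dup])
  pmin(pmax(p, 0), 1)
}

#' Forward band offset of the heterozygous BAF cluster
#'
#' The counterpart of [estimate_cell_fraction()]: the displacement of the
#' heterozygous BAF band from 0.5 produced by a fraction `p` of affected
#' cells, per event type (`p/2` for UPD, `p/(2(2-p))` for deletions,
#' `p/(2(2+p))` for duplications/trisomies, 0 for `"none"`).
#'
#' @param event event label.
#' @param p affected cell fraction in `[0, 1]`.
#' @return Band offset in `[0, 0.5)`.
#' @export
band_shift <- function(event, p) {
  stopifnot(all(p >= 0 & p <= 1))
  n <- max(length(event), length(p))
  ev <- rep_len(as.character(event), n)
  p <- rep_len(as.numeric(p), n)
  out <- rep(NA_real_, n)
  out[ev == "none"] <- 0
  out[ev == "UPD"] <- p[ev == "UPD"] / 2
  del <- ev %in% c("deletion", "monosomy")
  out[del] <- p[del] / (2 * (2 - p[del]))
  dup <- ev %in% c("duplication", "trisomy")
  out[dup] <- p[dup] / (2 * (2 + p[dup]))
  out
}

#' Call, classify and quantify mosaic alterations genome-wide
#'
#' End-to-end pipeline over a set of chromosome tracks: probit-transformed
#' b-deviation per chromosome, segmentation against a genome-wide
#' background (the 10%-trimmed mean of the pooled transformed signal, so
#' whole-chromosome events remain visible), per-segment p-values, a
#' conservative genome-wide FDR estimate, classification by relative LRR
#' and cell-fraction estimation from the median heterozygous b-deviation
#' inside each call. Deterministic given inputs and parameters.
#'
#' @param tracks a named list of [probe_track()] objects (or a single
#'   track).
#' @param params a [seg_params()] object.
#' @return An object of class `mosaic_calls`: list with `calls` (data
#'   frame, one row per called segment, including `event`,
#'   `cell_fraction`, `chrom_coverage`), `fdr` (an [estimate_fdr()]
#'   result) and `params`.
#' @export
call_mosaics <- function(tracks, params = seg_params()) {
  if (inherits(tracks, "probe_track")) {
    tracks <- stats::setNames(list(tracks), tracks$chrom)
  }
  stopifnot(length(tracks) > 0, all(vapply(tracks, inherits, logical(1), "probe_track")))
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    names(tracks) <- vapply(tracks, `[[`, character(1), "chrom")

  signals <- lapply(tracks, transform_track, params = params)
  pooled <- unlist(lapply(signals, `[[`, "values"), use.names = FALSE)
  background <- mean(pooled, trim = 0.1)

  calls <- do.call(rbind, lapply(signals, function(sg) {
    segment_signal(sg, params, background = background)
  }))
  if (is.null(calls)) calls <- empty_calls()
  rownames(calls) <- NULL

  N <- sum(vapply(signals, function(sg) length(sg$values), numeric(1)))
  fdr <- estimate_fdr(nrow(calls), N = N, T = params$T,
                      min_seg_len = params$min_seg_len)

  if (nrow(calls)) {
    calls$chrom_coverage <- vapply(seq_len(nrow(calls)), function(r) {
      (calls$end_index[r] - calls$start_index[r] + 1) /
        length(tracks[[calls$chrom[r]]])
    }, numeric(1))
    calls <- relative_mean_lrr(tracks, calls)
    calls$event <- classify_segment(calls$mean_lrr, calls$chrom_coverage, params)
    calls$bdev_median <- vapply(seq_len(nrow(calls)), function(r) {
      tr <- tracks[[calls$chrom[r]]]
      idx <- calls$start_index[r]:calls$end_index[r]
      het <- select_informative_probes(tr, params$het_window, params$use_genotypes)
      idx <- idx[het[idx]]
      if (!length(idx)) return(NA_real_)
      gt <- if (params$use_genotypes && !is.null(tr$genotype)) tr$genotype[idx]
      stats::median(compute_bdev(tr$baf[idx], expected_baf(tr$baf[idx], gt)),
                    na.rm = TRUE)
    }, numeric(1))
    calls$cell_fraction <- estimate_cell_fraction(calls$bdev_median, calls$event)
  } else {
    calls$chrom_coverage <- numeric(0)
    calls$bdev_median <- numeric(0)
  }

  structure(list(calls = calls, fdr = fdr, params = params),
            class = "mosaic_calls")
}

#' @export
print.mosaic_calls <- function(x, ...) {
  cat(sprintf("mosaic_calls: %d segment call(s)\n", nrow(x$calls)))
  if (nrow(x$calls)) {
    show <- x$calls[, c("chrom", "start_bp", "end_bp", "n_probes",
                        "mean_lrr", "event", "cell_fraction")]
    print(format(show, digits = 3), row.names = FALSE)
  }
  print(x$fdr)
  invisible(x)
}
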