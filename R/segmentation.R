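# Sparse breakpoint detection on the transformed b-deviation signal:
# a multiscale candidate scan (sensitivity controlled by the sparseness
# prior a) followed by backward elimination of breakpoints on exact
# two-segment t-statistics, thresholded at T.

candidate_threshold <- function(a) max(1.5, 4.2 - 3 * a)

# exact single-changepoint scan within y[l..r] given fixed outer boundaries;
# returns the global boundary index maximising |t|, or NA if the span is
# too short to split
best_split <- function(y, l, r, sigma) {
  m <- r - l + 1L
  if (m < 2L) return(NA_integer_)
  x <- y[l:r]
  cs <- cumsum(x)
  q <- seq_len(m - 1L)
  mL <- cs[q] / q
  mR <- (cs[m] - cs[q]) / (m - q)
  tq <- (mR - mL) / (sigma * sqrt(1 / q + 1 / (m - q)))
  l - 1L + which.max(abs(tq))
}

#' Generate candidate breakpoints (sparse scan stage)
#'
#' Scans the signal at dyadic window sizes for boundaries where the flanking
#' window means differ by more than a threshold number of noise standard
#' deviations; the threshold decreases with the sparseness prior `a`, so a
#' larger `a` admits more candidates. Local maxima of the window statistic
#' are then iteratively relocated to the exact maximum-likelihood changepoint
#' within their flanking spans (up to `max_iter` sweeps). Any boundary whose
#' flanking windows differ by at least 4 noise SDs is guaranteed to be
#' included for every `a` in `[0.2, 0.8]`.
#'
#' @param values numeric signal (probit-transformed b-deviation).
#' @param a sparseness prior (larger = more candidates).
#' @param b second prior parameter (uninformative; kept for the interface).
#' @param max_iter maximum relocation sweeps.
#' @param tol stop when a refinement sweep improves the piecewise fit's
#'   residual sum of squares by less than this relative amount.
#' @param sigma noise SD; estimated from first differences when `NULL`.
#' @return `data.frame(index, t_stat)`: boundary index (boundary sits after
#'   `values[index]`) and provisional t-statistic, sorted by index.
#' @export
sbl_candidates <- function(values, a = 0.8, b = 0, max_iter = 10L,
                           tol = 1e-4, sigma = NULL) {
  y <- as.numeric(values)
  n <- length(y)
  empty <- data.frame(index = integer(0), t_stat = numeric(0))
  if (n < 4L) return(empty)
  if (is.null(sigma)) sigma <- estimate_sigma(y)
  if (!is.finite(sigma) || sigma <= 0) return(empty)
  thr <- candidate_threshold(a)
  S <- c(0, cumsum(y))
  cand <- integer(0)
  w <- 4L
  while (w <= max(4L, n %/% 4L) && w <= 4096L) {
    i <- seq.int(w, n - w)
    if (length(i) == 0L) break
    mL <- (S[i + 1L] - S[i - w + 1L]) / w
    mR <- (S[i + w + 1L] - S[i + 1L]) / w
    z <- (mR - mL) / (sigma * sqrt(2 / w))
    hit <- which(abs(z) >= thr)
    if (length(hit)) {
      gap <- max(2L, w %/% 2L)
      grp <- cumsum(c(TRUE, diff(hit) > gap))
      pick <- vapply(split(seq_along(hit), grp), function(ii) {
        hit[ii[which.max(abs(z[hit[ii]]))]]
      }, integer(1))
      cand <- c(cand, i[pick])
    }
    w <- w * 2L
  }
  cand <- sort(unique(cand))
  cand <- cand[cand >= 1L & cand <= n - 1L]
  if (!length(cand)) return(empty)

  cand <- refine_breakpoints(y, cand, sigma, max_iter = max_iter, tol = tol,
                             warn = TRUE)
  data.frame(index = cand, t_stat = t_statistics(y, cand, sigma))
}

#' Relocate breakpoints to their exact local changepoint optima
#'
#' Sweeps over the breakpoints, moving each to the maximum-likelihood
#' single-changepoint position within the span bounded by its neighbours.
#' Each relocation is a coordinate-descent step on the residual sum of
#' squares of the piecewise-constant fit, so RSS decreases monotonically;
#' sweeps stop once a pass no longer improves it materially. Used both to
#' polish the candidate scan and to sharpen the surviving boundaries after
#' backward elimination.
#'
#' @param values numeric signal.
#' @param breakpoints boundary indices.
#' @param sigma noise SD; estimated from first differences when `NULL`.
#' @param max_iter maximum sweeps.
#' @param tol relative RSS improvement below which sweeps stop.
#' @param warn warn if the sweep budget is exhausted before settling.
#' @return Sorted (unique) relocated breakpoint indices.
#' @export
refine_breakpoints <- function(values, breakpoints, sigma = NULL,
                               max_iter = 10L, tol = 1e-4, warn = FALSE) {
  y <- as.numeric(values)
  n <- length(y)
  cand <- sort(unique(as.integer(breakpoints)))
  cand <- cand[cand >= 1L & cand <= n - 1L]
  if (!length(cand)) return(integer(0))
  if (is.null(sigma)) sigma <- estimate_sigma(y)
  piecewise_rss <- function(bp) {
    bounds <- c(0L, bp, n)
    lens <- diff(bounds)
    S <- c(0, cumsum(y))
    S2 <- c(0, cumsum(y^2))
    sums <- diff(S[bounds + 1L])
    sum(diff(S2[bounds + 1L]) - sums^2 / lens)
  }
  converged <- FALSE
  rss_prev <- piecewise_rss(cand)
  for (it in seq_len(max(1L, max_iter))) {
    k <- length(cand)
    prev <- c(0L, cand[-k])
    nxt <- c(cand[-1L], n)
    moved <- 0L
    for (j in seq_len(k)) {
      s <- best_split(y, prev[j] + 1L, nxt[j], sigma)
      if (!is.na(s) && s != cand[j]) {
        cand[j] <- s
        moved <- moved + 1L
      }
    }
    cand <- sort(unique(cand))
    rss <- piecewise_rss(cand)
    if (moved == 0L || rss_prev - rss <= tol * max(rss_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    rss_prev <- rss
  }
  if (!converged && warn)
    warning(sprintf("candidate refinement did not settle within %d sweeps; returning current set", max_iter))
  cand
}

#' Breakpoint t-statistics
#'
#' For each boundary between adjacent segments L and R of the partition
#' induced by `breakpoints`, computes
#' `t = (mean_R - mean_L) / (sigma * sqrt(1/n_L + 1/n_R))`.
#'
#' @param values numeric signal.
#' @param breakpoints sorted boundary indices (boundary after each index).
#' @param sigma noise SD.
#' @return Numeric vector of t-statistics, one per breakpoint.
#' @export
t_statistics <- function(values, breakpoints, sigma) {
  bp <- as.integer(breakpoints)
  n <- length(values)
  if (!length(bp)) return(numeric(0))
  stopifnot(all(bp >= 1L), all(bp <= n - 1L), !is.unsorted(bp, strictly = TRUE))
  S <- c(0, cumsum(values))
  bounds <- c(0L, bp, n)
  lens <- diff(bounds)
  if (any(lens < 1L)) stop("zero-length segment in breakpoint partition")
  means <- diff(S[bounds + 1L]) / lens
  k <- length(bp)
  (means[-1L] - means[-(k + 1L)]) /
    (sigma * sqrt(1 / lens[-(k + 1L)] + 1 / lens[-1L]))
}

#' Backward elimination of candidate breakpoints
#'
#' Iteratively removes the breakpoint with the smallest absolute
#' t-statistic (recomputing neighbouring statistics after each removal)
#' until every surviving breakpoint has `|t| >= T`; then merges any segment
#' shorter than `min_seg_len` into the neighbour with the closer mean (ties
#' merge left). Because a run at a higher threshold simply continues the
#' elimination sequence of a lower one, the surviving set before the merge
#' step is nested in `T`.
#'
#' @param values numeric signal.
#' @param candidates candidate breakpoints (`data.frame` with `index`, or an
#'   integer vector).
#' @param T elimination threshold.
#' @param min_seg_len minimum probes per segment after merging.
#' @param sigma noise SD; estimated from first differences when `NULL`.
#' @return `data.frame(index, t_stat)` of surviving breakpoints.
#' @export
backward_eliminate <- function(values, candidates, T, min_seg_len = 2L,
                               sigma = NULL) {
  y <- as.numeric(values)
  n <- length(y)
  if (is.null(sigma)) sigma <- estimate_sigma(y)
  bp <- if (is.data.frame(candidates)) candidates$index else candidates
  bp <- sort(unique(as.integer(bp)))
  bp <- bp[bp >= 1L & bp <= n - 1L]

  S <- c(0, cumsum(y))
  t_one <- function(l, m, r) {
    # boundary at m between segments (l, m] and (m, r]
    nL <- m - l
    nR <- r - m
    ((S[r + 1L] - S[m + 1L]) / nR - (S[m + 1L] - S[l + 1L]) / nL) /
      (sigma * sqrt(1 / nL + 1 / nR))
  }
  if (length(bp)) {
    tv <- t_statistics(y, bp, sigma)
    while (length(bp)) {
      j <- which.min(abs(tv))
      if (abs(tv[j]) >= T) break
      bp <- bp[-j]
      tv <- tv[-j]
      k <- length(bp)
      if (k) {
        bounds <- function(i) c(if (i > 1L) bp[i - 1L] else 0L,
                                bp[i],
                                if (i < k) bp[i + 1L] else n)
        for (i in unique(pmin(pmax(c(j - 1L, j), 1L), k))) {
          bb <- bounds(i)
          tv[i] <- t_one(bb[1], bb[2], bb[3])
        }
      }
    }
  }

  # merge segments shorter than min_seg_len into the more similar neighbour
  S <- c(0, cumsum(y))
  while (length(bp)) {
    bounds <- c(0L, bp, n)
    lens <- diff(bounds)
    if (all(lens >= min_seg_len)) break
    means <- diff(S[bounds + 1L]) / lens
    j <- which(lens < min_seg_len)
    j <- j[which.min(lens[j])]          # shortest first; first on ties
    k <- length(bp)
    if (j == 1L) {
      drop <- 1L
    } else if (j == k + 1L) {
      drop <- k
    } else {
      dl <- abs(means[j] - means[j - 1L])
      dr <- abs(means[j] - means[j + 1L])
      drop <- if (dl <= dr) j - 1L else j
    }
    bp <- bp[-drop]
  }

  if (!length(bp)) return(data.frame(index = integer(0), t_stat = numeric(0)))
  data.frame(index = bp, t_stat = t_statistics(y, bp, sigma))
}

empty_calls <- function() {
  data.frame(chrom = character(0), start_probe = integer(0),
             end_probe = integer(0), start_index = integer(0),
             end_index = integer(0), start_bp = numeric(0),
             end_bp = numeric(0), n_probes = integer(0),
             mean_tbdev = numeric(0), t_stat = numeric(0),
             p_value = numeric(0), mean_lrr = numeric(0),
             event = character(0), cell_fraction = numeric(0),
             stringsAsFactors = FALSE)
}

#' Segment a transformed b-deviation signal into altered regions
#'
#' Runs noise estimation, candidate generation and backward elimination,
#' then emits the segments that stand out from the background: mean
#' transformed b-deviation above the background level with a per-segment
#' statistic `t_seg = (mean - background) * sqrt(n) / sigma >= T`.
#' b-deviation increases under every mosaic event type, so the test is
#' one-sided upward.
#'
#' @param signal a [transform_track()] result.
#' @param params a [seg_params()] object.
#' @param background background level of the transformed signal; by default
#'   the 10%-trimmed mean of this signal. [call_mosaics()] passes a
#'   genome-wide background so whole-chromosome events remain visible.
#' @param sigma noise SD override (default: estimated from this signal).
#' @return A data frame of segment calls (possibly 0 rows) with probe and
#'   bp geometry, `mean_tbdev`, `t_stat`, `p_value`; `event` is
#'   `"unclassified"` until [classify_segment()]/[call_mosaics()] runs.
#' @export
segment_signal <- function(signal, params = seg_params(), background = NULL,
                           sigma = NULL) {
  stopifnot(inherits(signal, "bdev_signal"))
  y <- signal$values
  n <- length(y)
  if (n < 2L * params$min_seg_len) {
    warning(sprintf("chromosome %s: %d usable probes < 2 * min_seg_len (%d); skipped",
                    signal$chrom, n, params$min_seg_len))
    return(empty_calls())
  }
  if (is.null(sigma)) sigma <- estimate_sigma(y, params$sigma_estimator)
  cand <- sbl_candidates(y, a = params$a, b = params$b,
                         max_iter = params$max_iter, tol = params$tol,
                         sigma = sigma)
  fin <- backward_eliminate(y, cand, T = params$T,
                            min_seg_len = params$min_seg_len, sigma = sigma)
  seg <- emit_segments(y, fin$index, params, sigma,
                       background %||% mean(y, trim = 0.1))
  if (!nrow(seg)) return(empty_calls())
  sp <- seg$start
  ep <- seg$end
  data.frame(
    chrom = signal$chrom,
    start_probe = sp, end_probe = ep,
    start_index = signal$probe_index[sp], end_index = signal$probe_index[ep],
    start_bp = signal$position[sp], end_bp = signal$position[ep],
    n_probes = seg$len,
    mean_tbdev = seg$mean,
    t_stat = seg$t_seg,
    p_value = segment_pvalue(seg$t_seg, seg$len,
                             normal_approx = params$normal_approx),
    mean_lrr = NA_real_,
    event = "unclassified",
    cell_fraction = NA_real_,
    stringsAsFactors = FALSE
  )
}

# shared post-elimination stage: sharpen surviving boundaries by local
# relocation, re-enforce min_seg_len (relocation can shorten a segment),
# then emit segments standing out one-sidedly from the background with
# t_seg = (mean - background) * sqrt(n) / sigma >= T
emit_segments <- function(y, bp, params, sigma, bg) {
  n <- length(y)
  bp <- refine_breakpoints(y, bp, sigma, max_iter = params$max_iter,
                           tol = params$tol)
  # T = 0 skips elimination: pure minimum-length merging
  bp <- backward_eliminate(y, bp, T = 0, min_seg_len = params$min_seg_len,
                           sigma = sigma)$index
  bounds <- c(0L, bp, n)
  lens <- diff(bounds)
  S <- c(0, cumsum(y))
  means <- diff(S[bounds + 1L]) / lens
  t_seg <- (means - bg) * sqrt(lens) / sigma
  keep <- which(means > bg & t_seg >= params$T & lens >= params$min_seg_len)
  data.frame(start = bounds[keep] + 1L, end = bounds[keep + 1L],
             len = lens[keep], mean = means[keep], t_seg = t_seg[keep])
}
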