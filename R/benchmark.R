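#' Did the caller detect the simulated alteration?
#'
#' A replicate counts as detected when some single call covers at least
#' `min_overlap` of the simulated block's probes (default 50%).
#'
#' @param calls data frame of segment calls (`start_index`, `end_index`
#'   raw probe indices).
#' @param truth a `sim_truth` (see [simulate_track()]).
#' @param min_overlap required fraction of the truth block covered by one
#'   call, in `(0, 1]`.
#' @return `TRUE`/`FALSE`.
#' @export
detection_success <- function(calls, truth, min_overlap = 0.5) {
  stopifnot(min_overlap > 0, min_overlap <= 1)
  if (is.na(truth$start) || nrow(calls) == 0L) return(FALSE)
  len <- truth$end - truth$start + 1
  ov <- pmin(calls$end_index, truth$end) - pmax(calls$start_index, truth$start) + 1
  any(ov / len >= min_overlap)
}

# run the full caller on one simulated track and score the detection
score_replicate <- function(sim, params, min_overlap = 0.5) {
  res <- call_mosaics(sim$track, params)
  list(calls = res$calls,
       detected = detection_success(res$calls, sim$truth, min_overlap),
       false_calls = n_false_calls(res$calls, sim$truth))
}

# calls completely disjoint from the truth block are false discoveries
n_false_calls <- function(calls, truth) {
  if (nrow(calls) == 0L) return(0L)
  if (is.na(truth$start)) return(nrow(calls))
  ov <- pmin(calls$end_index, truth$end) - pmax(calls$start_index, truth$start) + 1
  sum(ov <= 0)
}

#' Sensitivity as a function of mosaic cell proportion
#'
#' Runs the full caller over [simulate_proportion_series()] replicates and
#' reports, per proportion, the fraction of replicates in which a call
#' covered at least `min_overlap` of the simulated block. The area under
#' the curve (trapezoid rule over the proportion range) and its value
#' normalized by the area of the perfect curve `y = 1` summarise overall
#' performance.
#'
#' @param proportions mosaic cell proportions (default 0, 0.01, ..., 0.15).
#' @param reps replicates per proportion.
#' @param params segmentation parameters ([seg_params()]); the reference
#'   comparison uses `a = 0.5`, `T = 2`, `min_seg_len = 900`.
#' @param master_seed integer master seed.
#' @param min_overlap detection overlap threshold.
#' @param n_probes,block_len,sigma forwarded to the simulator.
#' @return An object of class `sensitivity_curve`: list with `curve`
#'   (data frame `proportion`, `sensitivity`, `reps`), `area`,
#'   `normalized_area` and `params`.
#' @export
sensitivity_curve <- function(proportions = seq(0, 0.15, by = 0.01),
                              reps = 200L,
                              params = seg_params(a = 0.5, T = 2, min_seg_len = 900),
                              master_seed = 1L, min_overlap = 0.5,
                              n_probes = 20000L, block_len = 1000L,
                              sigma = 0.03) {
  series <- simulate_proportion_series(proportions, reps, master_seed,
                                       n_probes, block_len, sigma)
  hits <- logical(nrow(series$grid))
  for (i in seq_len(nrow(series$grid))) {
    sim <- series$generate(i)
    hits[i] <- score_replicate(sim, params, min_overlap)$detected
  }
  sens <- tapply(hits, series$grid$proportion, mean)
  curve <- data.frame(proportion = as.numeric(names(sens)),
                      sensitivity = as.numeric(sens), reps = reps)
  curve <- curve[order(curve$proportion), ]
  area <- trapezoid_area(curve$proportion, curve$sensitivity)
  width <- diff(range(curve$proportion))
  structure(list(curve = curve, area = area,
                 normalized_area = if (width > 0) area / width else NA_real_,
                 params = params, min_overlap = min_overlap),
            class = "sensitivity_curve")
}

trapezoid_area <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  cat(sprintf("sensitivity_curve: %d proportions x %d reps\n",
              nrow(x$curve), x$curve$reps[1]))
  print(x$curve, row.names = FALSE)
  cat(sprintf("area = %.4g over [%g, %g]; normalized area = %.3g\n",
              x$area, min(x$curve$proportion), max(x$curve$proportion),
              x$normalized_area))
  invisible(x)
}

# probe-level TPR/FPR of one replicate for a sequence of thresholds T,
# reusing the candidate set (the elimination at a larger T continues the
# smaller one's sequence)
roc_rates_one <- function(sim, a, T_values, params) {
  p0 <- params
  p0$a <- a
  sg <- transform_track(sim$track, p0)
  y <- sg$values
  sigma <- estimate_sigma(y, p0$sigma_estimator)
  cand <- sbl_candidates(y, a = a, b = p0$b, max_iter = p0$max_iter,
                         tol = p0$tol, sigma = sigma)
  truth_mask <- rep(FALSE, length(y))
  if (!is.na(sim$truth$start))
    truth_mask[sg$probe_index >= sim$truth$start &
               sg$probe_index <= sim$truth$end] <- TRUE
  bg <- mean(y, trim = 0.1)
  out <- data.frame(T = T_values, tp = 0, fp = 0,
                    pos = sum(truth_mask), neg = sum(!truth_mask))
  for (k in seq_along(T_values)) {
    p1 <- p0
    p1$T <- T_values[k]
    fin <- backward_eliminate(y, cand, T = p1$T,
                              min_seg_len = p1$min_seg_len, sigma = sigma)
    seg <- emit_segments(y, fin$index, p1, sigma, bg)
    called <- rep(FALSE, length(y))
    for (j in seq_len(nrow(seg))) called[seg$start[j]:seg$end[j]] <- TRUE
    out$tp[k] <- sum(called & truth_mask)
    out$fp[k] <- sum(called & !truth_mask)
  }
  out
}

#' ROC experiment over the simulation grid
#'
#' For each scenario and sparseness prior `a`, sweeps the elimination
#' threshold over `T_values` and accumulates probe-level true- and
#' false-positive rates (fraction of altered probes inside calls, fraction
#' of unaltered probes inside calls) over `reps` replicates.
#'
#' @param scenarios named list of [sim_scenario()] objects (default: the
#'   four large-block members of [simulate_study_grid()]).
#' @param a_values sparseness priors to test.
#' @param T_values elimination thresholds to sweep.
#' @param reps replicates per scenario.
#' @param master_seed integer master seed.
#' @param params base parameters (notably `min_seg_len`).
#' @return Data frame with one row per `(scenario, a, T)`: `tpr`, `fpr`
#'   and the underlying counts. `tpr` is `NA` for scenarios without
#'   altered probes.
#' @export
roc_experiment <- function(scenarios = NULL, a_values = c(0.2, 0.8),
                           T_values = c(2.5, 3, 3.5, 4, 4.5, 5),
                           reps = 100L, master_seed = 1L,
                           params = seg_params(min_seg_len = 100)) {
  if (is.null(scenarios)) {
    grid <- simulate_study_grid(master_seed)
    scenarios <- grid[grepl("large", names(grid))]
  }
  out <- NULL
  for (sc_name in names(scenarios)) {
    sc <- scenarios[[sc_name]]
    for (a in a_values) {
      acc <- data.frame(T = T_values, tp = 0, fp = 0, pos = 0, neg = 0)
      for (r in seq_len(reps)) {
        sc_r <- sc
        sc_r$seed <- derive_seed(master_seed, match(sc_name, names(scenarios)),
                                 match(a, a_values), r)
        sim <- simulate_track(sc_r)
        one <- roc_rates_one(sim, a, T_values, params)
        acc$tp <- acc$tp + one$tp
        acc$fp <- acc$fp + one$fp
        acc$pos <- acc$pos + one$pos
        acc$neg <- acc$neg + one$neg
      }
      out <- rbind(out, data.frame(
        scenario = sc_name, a = a, T = T_values,
        tpr = ifelse(acc$pos > 0, acc$tp / acc$pos, NA_real_),
        fpr = ifelse(acc$neg > 0, acc$fp / acc$neg, NA_real_),
        tp = acc$tp, fp = acc$fp, pos = acc$pos, neg = acc$neg,
        stringsAsFactors = FALSE
      ))
    }
  }
  rownames(out) <- NULL
  out
}

#' Area under a probe-level ROC table
#'
#' Trapezoid area under the `(fpr, tpr)` points of one
#' `(scenario, a)` cell of a [roc_experiment()] table, closed with the
#' `(0,0)` and `(1,1)` endpoints.
#'
#' @param roc_table [roc_experiment()] output (one scenario/a subset).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc_table) {
  fpr <- c(0, sort(roc_table$fpr), 1)
  tpr <- c(0, roc_table$tpr[order(roc_table$fpr)], 1)
  trapezoid_area(fpr, tpr)
}

#' FDR calibration: estimated versus simulated
#'
#' For each scenario and threshold `T`, runs the caller over `reps`
#' replicates, pools the calls and compares the realized false-discovery
#' fraction (calls disjoint from the simulated block / all calls) with the
#' analytic [estimate_fdr()] bound applied to the pooled counts.
#'
#' @param scenarios named list of [sim_scenario()] objects (default: the
#'   four large-block grid members).
#' @param T_values thresholds to sweep.
#' @param reps replicates per cell.
#' @param master_seed integer master seed.
#' @param params base parameters (`a`, `min_seg_len`).
#' @return Data frame with one row per `(scenario, T)`: `fdr_simulated`,
#'   `fdr_estimated`, `n_calls`, `n_false`.
#' @export
fdr_calibration <- function(scenarios = NULL, T_values = c(2.5, 3, 3.5, 4, 4.5, 5),
                            reps = 50L, master_seed = 1L,
                            params = seg_params(min_seg_len = 100)) {
  if (is.null(scenarios)) {
    grid <- simulate_study_grid(master_seed)
    scenarios <- grid[grepl("large", names(grid))]
  }
  out <- NULL
  for (sc_name in names(scenarios)) {
    sc <- scenarios[[sc_name]]
    sims <- lapply(seq_len(reps), function(r) {
      sc_r <- sc
      sc_r$seed <- derive_seed(master_seed, match(sc_name, names(scenarios)), r, 7L)
      simulate_track(sc_r)
    })
    for (tt in T_values) {
      p1 <- params
      p1$T <- tt
      n_calls <- 0L
      n_false <- 0L
      N <- 0
      for (sim in sims) {
        sr <- score_replicate(sim, p1)
        n_calls <- n_calls + nrow(sr$calls)
        n_false <- n_false + sr$false_calls
        N <- N + sim$truth$scenario$n_probes
      }
      est <- estimate_fdr(n_calls, N = N, T = tt,
                          min_seg_len = p1$min_seg_len)
      out <- rbind(out, data.frame(
        scenario = sc_name, T = tt,
        fdr_simulated = if (n_calls > 0) n_false / n_calls else 0,
        fdr_estimated = est$fdr, n_calls = n_calls, n_false = n_false,
        stringsAsFactors = FALSE
      ))
    }
  }
  rownames(out) <- NULL
  out
}
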