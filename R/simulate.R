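#' Describe a simulated SNP-array scenario
#'
#' Captures the statistical design of the validation simulations: 20,000
#' probes per chromosome; homozygous BAF clusters anchored at 0 and 1 with
#' a skewed (log-normal-shaped) deviation of SD `sigma`; heterozygous
#' probes at `Normal(0.5, sigma)`; and, inside an altered block,
#' heterozygous probes split evenly at random between twin bands
#' `0.5 +/- mosaic_shift`. Noise levels 0.03 (good quality) and 0.1
#' (noisy); block lengths 1,000 (small) and 10,000 (large) probes.
#'
#' Either `mosaic_shift` or `proportion` may be given; the missing one is
#' derived through the event's allelic-dosage forward model
#' ([band_shift()]). LRR is simulated per event (0 for UPD,
#' `log2((2-p)/2)` for deletions, `log2((2+p)/2)` for duplications and
#' trisomies) plus `Normal(0, 0.15)` probe noise.
#'
#' @param n_probes probes on the chromosome (default 20,000).
#' @param sigma BAF noise SD (0.03 good quality, 0.1 noisy).
#' @param event one of `"UPD"`, `"deletion"`, `"duplication"`,
#'   `"trisomy"`, `"none"`.
#' @param proportion affected cell fraction in `[0, 1]`.
#' @param mosaic_shift heterozygous band displacement; derived from
#'   `proportion` when `NULL`.
#' @param block_len altered probes (ignored for `"none"`; forced to
#'   `n_probes` for `"trisomy"`).
#' @param block_start first altered probe index; default centres the block.
#' @param genotype_freqs probabilities of AA/AB/BB (sum to 1).
#' @param spacing probe spacing in bp (uniform).
#' @param chrom chromosome label.
#' @param lrr_noise_sd SD of the LRR probe noise.
#' @param seed RNG seed for [simulate_track()]; `NULL` leaves the RNG
#'   state untouched.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_probes = 20000L, sigma = 0.03, event = "UPD",
                         proportion = NULL, mosaic_shift = NULL,
                         block_len = 10000L, block_start = NULL,
                         genotype_freqs = c(AA = 0.25, AB = 0.5, BB = 0.25),
                         spacing = 3000, chrom = "1", lrr_noise_sd = 0.15,
                         seed = NULL) {
  event <- match.arg(event, c("UPD", "deletion", "duplication", "trisomy", "none"))
  stopifnot(n_probes >= 2, sigma > 0,
            abs(sum(genotype_freqs) - 1) < 1e-8, all(genotype_freqs >= 0))
  if (event == "none") {
    proportion <- 0
    mosaic_shift <- 0
    block_len <- 0L
  } else if (is.null(mosaic_shift) && is.null(proportion)) {
    stop("give either proportion or mosaic_shift for an altered scenario")
  } else if (is.null(mosaic_shift)) {
    mosaic_shift <- band_shift(event, proportion)
  } else if (is.null(proportion)) {
    proportion <- estimate_cell_fraction(mosaic_shift, event)
  }
  if (event == "trisomy") block_len <- n_probes
  stopifnot(block_len <= n_probes, block_len >= 0)
  if (is.null(block_start)) {
    block_start <- if (block_len > 0) (n_probes - block_len) %/% 2L + 1L else NA_integer_
  }
  structure(list(
    n_probes = as.integer(n_probes), sigma = sigma, event = event,
    proportion = proportion, mosaic_shift = mosaic_shift,
    block_len = as.integer(block_len),
    block_start = as.integer(block_start),
    genotype_freqs = genotype_freqs, spacing = spacing, chrom = chrom,
    lrr_noise_sd = lrr_noise_sd, seed = seed
  ), class = "sim_scenario")
}

# skewed near-boundary deviation for homozygous clusters: log-normal shaped,
# SD = sigma, mode ~ 0.17 * sigma (about 0.005 at sigma = 0.03)
hom_deviate <- function(n, sigma) {
  exp(stats::rnorm(n, log(sigma) - 0.5 - 0.5 * log(expm1(1)), 1))
}

#' Simulate one SNP-array probe track with known ground truth
#'
#' Draws genotypes from `genotype_freqs`, generates BAF per cluster (see
#' [sim_scenario()]), shifts heterozygous probes inside the altered block
#' into the twin bands `0.5 +/- mosaic_shift` (upper or lower with equal
#' probability), simulates LRR from the event's copy-number dosage, and
#' returns the track with its ground truth.
#'
#' @param scenario a [sim_scenario()].
#' @return A list with `track` (a validated [probe_track()]) and `truth`
#'   (class `sim_truth`: `start`/`end` probe indices of the altered block,
#'   `event`, `proportion`, `mosaic_shift` and the scenario).
#' @export
simulate_track <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  n <- scenario$n_probes
  sg <- scenario$sigma
  gt <- sample(c("AA", "AB", "BB"), n, replace = TRUE,
               prob = scenario$genotype_freqs)
  baf <- numeric(n)
  aa <- gt == "AA"; ab <- gt == "AB"; bb <- gt == "BB"
  baf[aa] <- hom_deviate(sum(aa), sg)
  baf[bb] <- 1 - hom_deviate(sum(bb), sg)
  baf[ab] <- stats::rnorm(sum(ab), 0.5, sg)

  in_block <- rep(FALSE, n)
  if (scenario$block_len > 0) {
    block <- seq.int(scenario$block_start,
                     scenario$block_start + scenario$block_len - 1L)
    in_block[block] <- TRUE
    hit <- which(ab & in_block)
    if (length(hit) && scenario$mosaic_shift > 0) {
      side <- sample(c(-1, 1), length(hit), replace = TRUE)
      baf[hit] <- stats::rnorm(length(hit), 0.5 + side * scenario$mosaic_shift, sg)
    }
  }
  baf <- pmin(pmax(baf, 0), 1)

  lrr_level <- switch(scenario$event,
    none = 0, UPD = 0,
    deletion = log2((2 - scenario$proportion) / 2),
    duplication = log2((2 + scenario$proportion) / 2),
    trisomy = log2((2 + scenario$proportion) / 2))
  lrr <- stats::rnorm(n, 0, scenario$lrr_noise_sd)
  lrr[in_block] <- lrr[in_block] + lrr_level

  track <- probe_track(
    chrom = scenario$chrom,
    position = seq.int(scenario$spacing, by = scenario$spacing, length.out = n),
    baf = baf, lrr = lrr, genotype = gt, validate = TRUE
  )
  truth <- structure(list(
    start = if (scenario$block_len > 0) scenario$block_start else NA_integer_,
    end = if (scenario$block_len > 0)
      scenario$block_start + scenario$block_len - 1L else NA_integer_,
    event = scenario$event, proportion = scenario$proportion,
    mosaic_shift = scenario$mosaic_shift, scenario = scenario
  ), class = "sim_truth")
  list(track = track, truth = truth)
}

#' The eight-scenario validation grid
#'
#' Cartesian product of affected-cell percentage (10%, 20%, i.e.
#' heterozygous bands at 0.55/0.60), altered-block length (small 1,000 /
#' large 10,000 probes) and data quality (sigma 0.03 good / 0.1 noisy),
#' with per-scenario seeds derived from the master seed.
#'
#' @param master_seed integer master seed.
#' @param event event type used for every member (copy-neutral by
#'   default; the band positions are the design constants either way).
#' @return Named list of 8 [sim_scenario()] objects, named
#'   `<good|noisy>-<10|20>-<small|large>`.
#' @export
simulate_study_grid <- function(master_seed = 1L, event = "UPD") {
  grid <- expand.grid(proportion = c(0.10, 0.20),
                      block_len = c(1000L, 10000L),
                      sigma = c(0.03, 0.1),
                      KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  nm <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    out[[i]] <- sim_scenario(
      n_probes = 20000L, sigma = grid$sigma[i], event = event,
      mosaic_shift = grid$proportion[i] / 2,  # bands 0.55 / 0.60
      proportion = grid$proportion[i],
      block_len = grid$block_len[i],
      seed = derive_seed(master_seed, i)
    )
    nm[i] <- sprintf("%s-%d-%s",
                     if (grid$sigma[i] == 0.03) "good" else "noisy",
                     as.integer(100 * grid$proportion[i]),
                     if (grid$block_len[i] == 1000L) "small" else "large")
  }
  stats::setNames(out, nm)
}

#' Replicated tracks over a grid of mosaic proportions
#'
#' The low-proportion sensitivity design: a single 1,000-probe altered
#' block inside a 20,000-probe track, simulated `reps` times for each
#' mosaic cell proportion (default 0, 0.01, ..., 0.15) under the
#' copy-neutral forward model (band shift `p/2`). Each `(proportion,
#' replicate)` pair gets a reproducible sub-seed from the master seed.
#'
#' @param proportions mosaic cell proportions.
#' @param reps replicates per proportion.
#' @param master_seed integer master seed.
#' @param n_probes,block_len,sigma track geometry and noise.
#' @return An object of class `sim_series`: list with `grid` (data frame
#'   `proportion`, `rep`, `seed`) and `generate(i)`, returning the
#'   [simulate_track()] result for row `i` of the grid.
#' @export
simulate_proportion_series <- function(proportions = seq(0, 0.15, by = 0.01),
                                       reps = 200L, master_seed = 1L,
                                       n_probes = 20000L, block_len = 1000L,
                                       sigma = 0.03) {
  stopifnot(all(proportions >= 0 & proportions <= 1), reps >= 1)
  grid <- expand.grid(rep = seq_len(reps), proportion = proportions,
                      KEEP.OUT.ATTRS = FALSE)[, c("proportion", "rep")]
  grid$seed <- vapply(seq_len(nrow(grid)), function(i) {
    derive_seed(master_seed, match(grid$proportion[i], proportions), grid$rep[i])
  }, integer(1))
  generate <- function(i) {
    stopifnot(i >= 1, i <= nrow(grid))
    simulate_track(sim_scenario(
      n_probes = n_probes, sigma = sigma, event = "UPD",
      proportion = grid$proportion[i],
      mosaic_shift = grid$proportion[i] / 2,
      block_len = block_len, seed = grid$seed[i]
    ))
  }
  structure(list(grid = grid, generate = generate),
            class = "sim_series")
}
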