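test_that("simulation is byte-identical under a fixed seed", {
  sc <- sim_scenario(event = "UPD", proportion = 0.1, block_len = 1000, seed = 5)
  expect_identical(simulate_track(sc), simulate_track(sc))
  # different seeds differ
  sc2 <- sim_scenario(event = "UPD", proportion = 0.1, block_len = 1000, seed = 6)
  expect_false(identical(simulate_track(sc)$track$baf,
                         simulate_track(sc2)$track$baf))
})

test_that("genotype composition follows the configured frequencies", {
  sim <- simulate_track(sim_scenario(event = "none", seed = 21))
  counts <- table(factor(sim$track$genotype, levels = c("AA", "AB", "BB")))
  chi <- stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))
  expect_gt(chi$p.value, 1e-4)
})

test_that("BAF clusters have the designed locations, spread and skew", {
  sim <- simulate_track(sim_scenario(event = "none", sigma = 0.03, seed = 22))
  tr <- sim$track
  het <- tr$baf[tr$genotype == "AB"]
  expect_lt(abs(mean(het) - 0.5), 3 * 0.03 / sqrt(length(het)) + 1e-3)
  expect_lt(abs(stats::sd(het) - 0.03), 0.003)
  aa <- tr$baf[tr$genotype == "AA"]
  # heavy-tailed law: the SD estimate itself is noisy at this n
  expect_lt(abs(stats::sd(aa) - 0.03), 0.008)
  expect_lt(stats::median(aa), 0.02)          # concentrated at the anchor
  expect_gt(mean((aa - mean(aa))^3), 0)       # right-skewed away from 0
  bb <- tr$baf[tr$genotype == "BB"]
  expect_gt(stats::median(bb), 0.98)

  noisy <- simulate_track(sim_scenario(event = "none", sigma = 0.1, seed = 23))
  het_n <- noisy$track$baf[noisy$track$genotype == "AB"]
  expect_lt(abs(stats::sd(het_n) - 0.1), 0.01)
})

test_that("altered heterozygous probes sit in twin bands at the designed offset", {
  sim <- simulate_track(sim_scenario(event = "UPD", mosaic_shift = 0.05,
                                     proportion = 0.1, block_len = 10000,
                                     sigma = 0.03, seed = 24))
  tr <- sim$track
  blk <- sim$truth$start:sim$truth$end
  het_blk <- tr$baf[blk][tr$genotype[blk] == "AB"]
  expect_lt(abs(mean(abs(het_blk - 0.5)) - 0.05), 0.003)
  upper <- het_blk[het_blk > 0.5]
  lower <- het_blk[het_blk < 0.5]
  expect_lt(abs(mean(upper) - 0.55), 0.005)
  expect_lt(abs(mean(lower) - 0.45), 0.005)
  # roughly even split between bands
  expect_lt(abs(length(upper) / length(het_blk) - 0.5), 0.05)
})

test_that("LRR levels follow the event dosage model", {
  lev <- function(ev, p, seed) {
    sim <- simulate_track(sim_scenario(event = ev, proportion = p,
                                       block_len = 10000, seed = seed))
    blk <- sim$truth$start:sim$truth$end
    mean(sim$track$lrr[blk]) - mean(sim$track$lrr[-blk])
  }
  expect_lt(abs(lev("deletion", 0.2, 31) - log2(1.8 / 2)), 0.02)
  expect_lt(abs(lev("duplication", 0.2, 32) - log2(2.2 / 2)), 0.02)
  sim_upd <- simulate_track(sim_scenario(event = "UPD", proportion = 0.2,
                                         block_len = 10000, seed = 33))
  expect_lt(abs(mean(sim_upd$track$lrr)), 0.01)
})

test_that("the study grid enumerates the eight designed scenarios", {
  grid <- simulate_study_grid(master_seed = 7)
  expect_length(grid, 8L)
  expect_setequal(names(grid),
                  c("good-10-small", "good-10-large", "good-20-small",
                    "good-20-large", "noisy-10-small", "noisy-10-large",
                    "noisy-20-small", "noisy-20-large"))
  small <- grid[grepl("small", names(grid))]
  expect_true(all(vapply(small, `[[`, integer(1), "block_len") == 1000L))
  large <- grid[grepl("large", names(grid))]
  expect_true(all(vapply(large, `[[`, integer(1), "block_len") == 10000L))
  expect_true(all(vapply(grid[grepl("good", names(grid))], `[[`,
                         numeric(1), "sigma") == 0.03))
  expect_true(all(vapply(grid[grepl("noisy", names(grid))], `[[`,
                         numeric(1), "sigma") == 0.1))
  # 10/20% of cells shift the het band to 0.55/0.60
  expect_equal(grid[["good-10-large"]]$mosaic_shift, 0.05)
  expect_equal(grid[["good-20-large"]]$mosaic_shift, 0.10)
  # seeds are distinct and reproducible
  expect_length(unique(vapply(grid, `[[`, integer(1), "seed")), 8L)
  expect_identical(vapply(simulate_study_grid(7), `[[`, integer(1), "seed"),
                   vapply(grid, `[[`, integer(1), "seed"))
})

test_that("the proportion series covers the designed grid with per-replicate seeds", {
  ser <- simulate_proportion_series(reps = 200, master_seed = 3)
  expect_equal(nrow(ser$grid), 16 * 200)
  expect_equal(sort(unique(ser$grid$proportion)), seq(0, 0.15, by = 0.01))
  expect_length(unique(ser$grid$seed), 16 * 200)

  ser2 <- simulate_proportion_series(reps = 2, master_seed = 3)
  sim0 <- ser2$generate(1)                     # proportion 0
  expect_equal(sim0$truth$mosaic_shift, 0)
  expect_equal(sim0$truth$event, "UPD")
  expect_equal(sim0$truth$end - sim0$truth$start + 1L, 1000L)

  i15 <- which(ser2$grid$proportion == 0.15)[1]
  sim15 <- ser2$generate(i15)
  expect_equal(sim15$truth$mosaic_shift, 0.075)  # bands at 0.575 / 0.425
  blk <- sim15$truth$start:sim15$truth$end
  het <- sim15$track$baf[blk][sim15$track$genotype[blk] == "AB"]
  expect_equal(mean(het[het > 0.5]), 0.575, tolerance = 0.01)
  expect_equal(mean(het[het < 0.5]), 0.425, tolerance = 0.01)
})

test_that("the simulator's forward band model and the inverse cell-fraction formulas round-trip", {
  # median b-deviation of altered het probes recovers the cell fraction
  for (ev in c("UPD", "deletion", "duplication")) {
    sim <- simulate_track(sim_scenario(event = ev, proportion = 0.2,
                                       block_len = 10000, sigma = 0.03,
                                       seed = 40 + match(ev, c("UPD", "deletion", "duplication"))))
    tr <- sim$track
    blk <- sim$truth$start:sim$truth$end
    het <- blk[tr$genotype[blk] == "AB"]
    b <- stats::median(compute_bdev(tr$baf[het], 0.5))
    expect_lt(abs(estimate_cell_fraction(b, ev) - 0.2), 0.02)
  }
})
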