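# small programmatic fixtures shared across test files

write_toy_table <- function(path,
                            chrom = c("1", "1", "2", "2", "2"),
                            position = c(100, 200, 300, 100, 200),
                            baf = c(0.0, 0.5, 1.0, 0.48, 0.02),
                            lrr = c(0.1, -0.1, 0.0, 0.2, -0.2),
                            baf_as = NULL) {
  df <- data.frame(Name = sprintf("rs%03d", seq_along(chrom)),
                   Chr = chrom, Position = position, check.names = FALSE)
  df[["s1.Log R Ratio"]] <- lrr
  df[["s1.B Allele Freq"]] <- if (is.null(baf_as)) baf else baf_as
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

flat_track <- function(n = 400, chrom = "1", lrr = 0, baf = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(baf)) baf <- pmin(pmax(stats::rnorm(n, 0.5, 0.03), 0), 1)
  probe_track(chrom = chrom, position = seq_len(n) * 1000,
              baf = baf, lrr = rep_len(lrr, n))
}

# cache heavyweight shared computations across test files (testthat runs
# them in one session)
.test_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache)
}
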