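`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministically mixes a master seed with one or more integer indices
#' (replicate number, grid position, ...) so that every simulated track in a
#' multi-replicate experiment gets its own RNG stream while the whole
#' experiment remains reproducible from a single integer.
#'
#' @param master integer master seed.
#' @param ... integer indices identifying the sub-stream.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483629
  s <- as.double(master) %% m
  primes <- c(7919, 104729, 1299709, 15485863, 32452843)
  for (i in seq_along(idx)) {
    s <- (s * 48271 + as.double(idx[i]) * primes[((i - 1L) %% 5L) + 1L]) %% m
  }
  as.integer(s) + 1L
}

# robust noise-scale estimate from successive differences: unaffected by the
# (sparse) mean shifts the segmentation is looking for
estimate_sigma <- function(x, method = c("diff_mad", "sd")) {
  method <- match.arg(method)
  if (length(x) < 3L) return(stats::sd(x))
  if (method == "sd") return(stats::sd(x))
  s <- stats::median(abs(diff(x))) / (sqrt(2) * 0.6745)
  if (!is.finite(s) || s <= 0) s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) s <- .Machine$double.eps
  s
}

is_autosome <- function(chrom) {
  !(toupper(sub("^CHR", "", toupper(as.character(chrom)))) %in% c("X", "Y", "XY", "MT", "M"))
}
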