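#' Construct a per-chromosome probe track
#'
#' A `probe_track` holds the ordered probe-level signal of one chromosome:
#' physical position (1-based bp), B-allele frequency (BAF), log R ratio
#' (LRR) and, optionally, the genotype call. Probes whose BAF or LRR could
#' not be parsed are kept but flagged missing so that downstream steps can
#' exclude them without disturbing the probe count.
#'
#' @param chrom chromosome label (kept as a string, e.g. `"1"`, `"X"`).
#' @param position 1-based physical positions in bp.
#' @param baf B-allele frequencies in `[0, 1]` (`NA` = missing).
#' @param lrr log R ratios (`NA` = missing).
#' @param probe optional probe names; generated when absent.
#' @param genotype optional genotype calls in `{"AA","AB","BB","NC"}`.
#' @param validate run [sort_and_validate()] on the result.
#' @return An object of class `probe_track`.
#' @export
probe_track <- function(chrom, position, baf, lrr, probe = NULL,
                        genotype = NULL, validate = TRUE) {
  n <- length(position)
  if (length(baf) != n || length(lrr) != n)
    stop("position, baf and lrr must have identical length")
  if (!is.null(genotype) && length(genotype) != n)
    stop("genotype must match the probe count")
  if (is.null(probe)) probe <- sprintf("p%06d", seq_len(n))
  tr <- structure(list(
    chrom = as.character(chrom)[1],
    probe = as.character(probe),
    position = as.numeric(position),
    baf = as.numeric(baf),
    lrr = as.numeric(lrr),
    genotype = if (is.null(genotype)) NULL else as.character(genotype)
  ), class = "probe_track")
  if (validate) tr <- sort_and_validate(tr) else tr
}

#' @export
length.probe_track <- function(x) length(x$position)

#' @export
print.probe_track <- function(x, ...) {
  cat(sprintf("probe_track: chromosome %s, %d probes, %d missing, genotypes: %s\n",
              x$chrom, length(x), sum(is.na(x$baf) | is.na(x$lrr)),
              if (is.null(x$genotype)) "absent" else "present"))
  invisible(x)
}

#' Sort a probe track by position and enforce its invariants
#'
#' Probes are ordered by physical position; duplicate positions keep the
#' first occurrence (with a warning). Non-missing BAF values outside
#' `[0, 1]` are an error naming the offending probe; a track whose BAF is
#' entirely missing is unusable.
#'
#' @param track a [probe_track()].
#' @return The validated track (positions strictly increasing).
#' @export
sort_and_validate <- function(track) {
  stopifnot(inherits(track, "probe_track"))
  o <- order(track$position)
  fields <- c("probe", "position", "baf", "lrr", "genotype")
  for (f in fields) if (!is.null(track[[f]])) track[[f]] <- track[[f]][o]
  dup <- duplicated(track$position)
  if (any(dup)) {
    warning(sprintf("chromosome %s: dropped %d probe(s) at duplicated positions (kept first occurrence)",
                    track$chrom, sum(dup)))
    for (f in fields) if (!is.null(track[[f]])) track[[f]] <- track[[f]][!dup]
  }
  bad <- which(!is.na(track$baf) & (track$baf < 0 | track$baf > 1))
  if (length(bad))
    stop(sprintf("chromosome %s: BAF outside [0,1] at probe %s (value %g)",
                 track$chrom, track$probe[bad[1]], track$baf[bad[1]]))
  if (all(is.na(track$baf)))
    stop(sprintf("chromosome %s: all BAF values missing; track unusable", track$chrom))
  track
}

#' Column dialect for BeadStudio/PennCNV-style probe tables
#'
#' Describes which columns of a delimited probe table hold the probe name,
#' chromosome, position, LRR, BAF and (optionally) genotype. BeadStudio
#' "Final Report" exports prefix the signal columns with the sample name
#' (`"<sample>.Log R Ratio"`); leave `sample = NULL` to match them by
#' suffix.
#'
#' @param sample sample name prefix, or `NULL` to autodetect by suffix.
#' @param probe,chrom,position,lrr,baf,genotype column names; `lrr`, `baf`
#'   and `genotype` may be `NULL` when `sample`-suffix matching is wanted.
#' @param sep field separator (`"\t"` or `","`).
#' @return A list of class `probe_dialect`.
#' @export
penncnv_dialect <- function(sample = NULL, probe = "Name", chrom = "Chr",
                            position = "Position", lrr = NULL, baf = NULL,
                            genotype = NULL, sep = "\t") {
  structure(list(sample = sample, probe = probe, chrom = chrom,
                 position = position, lrr = lrr, baf = baf,
                 genotype = genotype, sep = sep),
            class = "probe_dialect")
}

resolve_dialect <- function(dialect, header) {
  find_col <- function(explicit, suffix, required) {
    if (!is.null(explicit)) {
      if (!explicit %in% header) {
        if (required) stop(sprintf("missing mandatory column '%s'", explicit))
        return(NULL)
      }
      return(explicit)
    }
    if (!is.null(dialect$sample)) {
      cand <- paste0(dialect$sample, ".", suffix)
      if (cand %in% header) return(cand)
    }
    hit <- header[endsWith(header, suffix)]
    if (length(hit) >= 1L) return(hit[1])
    if (required) stop(sprintf("missing mandatory column ending in '%s'", suffix))
    NULL
  }
  list(
    probe = find_col(dialect$probe, "Name", TRUE),
    chrom = find_col(dialect$chrom, "Chr", TRUE),
    position = find_col(dialect$position, "Position", TRUE),
    lrr = find_col(dialect$lrr, "Log R Ratio", TRUE),
    baf = find_col(dialect$baf, "B Allele Freq", TRUE),
    genotype = find_col(dialect$genotype, "GType", FALSE)
  )
}

#' Read a SNP-array probe table into per-chromosome tracks
#'
#' Reads a tab- or comma-delimited probe table (BeadStudio Final Report /
#' PennCNV signal-file layout), partitions it by chromosome and returns
#' sorted, validated [probe_track()] objects. Rows whose BAF or LRR does
#' not parse as a number are kept and flagged missing.
#'
#' @param path path to the table.
#' @param dialect a [penncnv_dialect()] describing the columns.
#' @return A named list of `probe_track`, keyed by chromosome label, in
#'   order of first appearance.
#' @export
read_probe_table <- function(path, dialect = penncnv_dialect()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (nrow(df) == 0L) stop("empty probe table (no data rows)")
  cols <- resolve_dialect(dialect, names(df))
  num <- function(x) suppressWarnings(as.numeric(x))
  chrom <- as.character(df[[cols$chrom]])
  out <- list()
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    out[[ch]] <- probe_track(
      chrom = ch,
      position = num(df[[cols$position]][i]),
      baf = num(df[[cols$baf]][i]),
      lrr = num(df[[cols$lrr]][i]),
      probe = df[[cols$probe]][i],
      genotype = if (is.null(cols$genotype)) NULL else df[[cols$genotype]][i]
    )
  }
  out
}

seg_call_columns <- c("chrom", "start_bp", "end_bp", "n_probes", "mean_tbdev",
                      "t_stat", "p_value", "mean_lrr", "event", "cell_fraction")

#' Write (and read back) segment calls
#'
#' Writes calls as a tab-delimited table with a fixed header
#' (`chrom, start_bp, end_bp, n_probes, mean_tbdev, t_stat, p_value,
#' mean_lrr, event, cell_fraction`), with numbers at full double precision
#' so a write/read round-trip is exact. `format = "bed"` instead writes a
#' BED track (0-based half-open, name = event, score = t-statistic).
#'
#' @param calls a data frame of segment calls ([segment_signal()] /
#'   [call_mosaics()] output).
#' @param path output path.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return Invisibly, `path`.
#' @export
write_segment_calls <- function(calls, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  calls <- as.data.frame(calls)
  for (col in seg_call_columns)
    if (!col %in% names(calls)) calls[[col]] <- rep(NA, nrow(calls))
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "NA", sprintf("%.17g", x)) else as.character(x)
  }
  if (format == "bed") {
    out <- data.frame(chrom = calls$chrom,
                      start = fmt(calls$start_bp - 1),  # 1-based incl -> 0-based half-open
                      end = fmt(calls$end_bp),
                      name = as.character(calls$event),
                      score = fmt(calls$t_stat))
    con <- file(path, "w")
    on.exit(close(con))
    if (nrow(out))
      utils::write.table(out, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  out <- calls[, seg_call_columns, drop = FALSE]
  out[] <- lapply(out, fmt)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_segment_calls
#' @export
read_segment_calls <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  numcols <- setdiff(seg_call_columns, c("chrom", "event", "n_probes"))
  for (col in numcols) df[[col]] <- as.numeric(df[[col]])
  df$n_probes <- as.integer(df$n_probes)
  df$chrom <- as.character(df$chrom)
  df$event <- as.character(df$event)
  df
}
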