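#' Read a bedGraph coverage file into a coverage track
#'
#' Expects the 4-column bedGraph format (`chrom start end value`, 0-based
#' half-open) with optional `#`/`track`/`browser` header lines. Intervals
#' must be non-overlapping with nonnegative values. Intervals aligned to the
#' window grid map one-to-one onto windows; other intervals are re-binned by
#' length-weighted allocation of their value with a logged notice. Windows
#' with no covering interval get 0; masked windows get `NA`.
#'
#' @param file Path to a bedGraph file.
#' @param genome A [genome_spec()].
#' @param n_bins Number of windows.
#' @param label Sample label (default: file base name).
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(file, genome, n_bins = 10000, label = NULL) {
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(file))
  lines <- readLines(file)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) &
    nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(coverage_track(empty_counts(genome, n_bins), genome, n_bins,
                          label = label))
  parts <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(parts)
  if (any(nf != 4))
    stop(sprintf("line %d: expected 4 bedGraph fields, found %d",
                 lineno[which(nf != 4)[1]], nf[which(nf != 4)[1]]))
  mat <- matrix(unlist(parts), ncol = 4, byrow = TRUE)
  start <- suppressWarnings(as.numeric(mat[, 2]))
  end <- suppressWarnings(as.numeric(mat[, 3]))
  value <- suppressWarnings(as.numeric(mat[, 4]))
  bad <- which(!is.finite(start) | !is.finite(end) | !is.finite(value))[1]
  if (!is.na(bad))
    stop(sprintf("line %d: non-numeric start/end/value", lineno[bad]))
  if (any(value < 0))
    stop(sprintf("line %d: negative value", lineno[which(value < 0)[1]]))
  L <- genome$length
  if (any(start < 0 | end > L | start >= end)) {
    i <- which(start < 0 | end > L | start >= end)[1]
    stop(sprintf("line %d: invalid interval [%s, %s)", lineno[i],
                 mat[i, 2], mat[i, 3]))
  }
  o <- order(start)
  if (any(start[o][-1] < end[o][-length(o)])) {
    i <- which(start[o][-1] < end[o][-length(o)])[1]
    stop(sprintf("line %d: overlapping intervals", lineno[o[i + 1]]))
  }
  start <- start[o]; end <- end[o]; value <- value[o]

  bounds <- window_bounds(n_bins, L)
  counts <- numeric(n_bins)
  ws <- findInterval(start, bounds, rightmost.closed = FALSE)      # 1-based
  we <- findInterval(end - 1e-9, bounds)
  aligned <- ws == we | (start == bounds[ws] & end == bounds[pmin(we, n_bins) + 1])
  simple <- ws == we
  counts_idx <- ws[simple]
  if (length(counts_idx)) {
    add <- tapply(value[simple], counts_idx, sum)
    counts[as.integer(names(add))] <- counts[as.integer(names(add))] + add
  }
  multi <- which(!simple)
  n_rebinned <- 0L
  for (i in multi) {
    wr <- ws[i]:we[i]
    ov <- pmin(end[i], bounds[wr + 1]) - pmax(start[i], bounds[wr])
    counts[wr] <- counts[wr] + value[i] * ov / (end[i] - start[i])
    if (!(start[i] == bounds[ws[i]] && end[i] == bounds[we[i] + 1] &&
          length(wr) == 1))
      n_rebinned <- n_rebinned + 1L
  }
  if (n_rebinned)
    message(sprintf("read_bedgraph: %d interval(s) re-binned by length-weighted allocation",
                    n_rebinned))
  counts[masked_windows(genome, n_bins)] <- NA_real_
  coverage_track(counts, genome, n_bins, label = label)
}

empty_counts <- function(genome, n_bins) {
  counts <- numeric(n_bins)
  counts[masked_windows(genome, n_bins)] <- NA_real_
  counts
}

#' Write a coverage track as bedGraph
#'
#' One line per present (unmasked) window, window-aligned, with an optional
#' `#`-comment provenance header; round-trips through [read_bedgraph()].
#'
#' @param track A [coverage_track()].
#' @param file Output path.
#' @param provenance Optional named list written as `# key: value` header
#'   lines.
#' @return Invisibly, the file path.
#' @export
write_bedgraph <- function(track, file, provenance = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  n <- track$n_bins
  bounds <- window_bounds(n, track$genome$length)
  present <- which(!is.na(track$counts))
  con <- file(file, "w")
  on.exit(close(con))
  write_provenance_header(con, provenance)
  chrom <- gsub("\\s", "_", track$genome$name)
  writeLines(sprintf("%s\t%d\t%d\t%s", chrom, bounds[present],
                     bounds[present + 1],
                     format(track$counts[present], trim = TRUE,
                            scientific = FALSE)), con)
  invisible(file)
}

write_provenance_header <- function(con, provenance) {
  if (is.null(provenance)) return(invisible())
  for (k in names(provenance))
    writeLines(sprintf("# %s: %s", k, as.character(provenance[[k]])), con)
  invisible()
}

#' Read and write BED annotation files
#'
#' Minimal BED3-6 support (0-based half-open). `read_ter_bed()` decodes
#' polar Ter sites from BED: strand `+` blocks clockwise forks, `-` blocks
#' counterclockwise forks; `write_ter_bed()` is the inverse.
#'
#' @param file Path.
#' @return `read_bed()`: data frame with `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(file) {
  lines <- readLines(file)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) &
    nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  parts <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(parts)
  if (any(nf < 3))
    stop(sprintf("line %d: BED needs at least 3 fields", lineno[nf < 3][1]))
  ncol <- min(nf, 6)
  cols <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol)]
  df <- as.data.frame(do.call(rbind,
                              lapply(parts, function(p) p[seq_len(ncol)])),
                      stringsAsFactors = FALSE)
  names(df) <- cols
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (any(!is.finite(df$start) | !is.finite(df$end) | df$start >= df$end)) {
    i <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start >= df$end)[1]
    stop(sprintf("line %d: invalid BED interval", lineno[i]))
  }
  if ("score" %in% names(df)) df$score <- suppressWarnings(as.numeric(df$score))
  df
}

#' @rdname read_bed
#' @param df Data frame with at least `chrom`, `start`, `end`.
#' @param provenance Optional provenance header (see [write_bedgraph()]).
#' @export
write_bed <- function(df, file, provenance = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  write_provenance_header(con, provenance)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  out <- df[, cols, drop = FALSE]
  out$start <- format(out$start, trim = TRUE, scientific = FALSE)
  out$end <- format(out$end, trim = TRUE, scientific = FALSE)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname read_bed
#' @export
read_ter_bed <- function(file) {
  df <- read_bed(file)
  if (!"strand" %in% names(df))
    stop("Ter BED needs a strand column encoding polarity")
  lapply(seq_len(nrow(df)), function(i)
    ter_site(name = if ("name" %in% names(df)) df$name[i]
                    else sprintf("Ter%d", i),
             position = (df$start[i] + df$end[i]) / 2,
             blocks = if (df$strand[i] == "+") "clockwise"
                      else "counterclockwise"))
}

#' @rdname read_bed
#' @param ter_sites List of [ter_site()] objects.
#' @param chrom Chromosome name to write.
#' @export
write_ter_bed <- function(ter_sites, file, chrom = "chr") {
  df <- data.frame(
    chrom = chrom,
    start = vapply(ter_sites, function(t) t$position, numeric(1)),
    end = vapply(ter_sites, function(t) t$position + 1, numeric(1)),
    name = vapply(ter_sites, function(t) t$name, character(1)),
    score = 0,
    strand = vapply(ter_sites, function(t)
      if (t$blocks == "clockwise") "+" else "-", character(1)))
  write_bed(df, file)
}

#' Ingest positioned reads from a BED file
#'
#' Optional adapter for read-level input: each BED record is one read whose
#' 5' start (the `start` field) is binned with [bin_reads()]. When the BED
#' carries a score column it is interpreted as a mapping quality and reads
#' with `score < min_mapq` are dropped before binning (the count of dropped
#' reads is reported as attribute `n_filtered`). Alignment itself is out of
#' scope: the adapter consumes positioned reads, not raw sequencing data.
#'
#' @param file Path to a BED file (one record per read).
#' @param genome A [genome_spec()].
#' @param n_bins Number of windows.
#' @param min_mapq Minimum score for a read to be kept (default 0).
#' @param label Sample label.
#' @return A [coverage_track()].
#' @export
read_reads_bed <- function(file, genome, n_bins = 10000, min_mapq = 0,
                           label = NULL) {
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(file))
  df <- read_bed(file)
  n_filtered <- 0L
  if (min_mapq > 0 && "score" %in% names(df)) {
    keep <- !is.na(df$score) & df$score >= min_mapq
    n_filtered <- sum(!keep)
    df <- df[keep, , drop = FALSE]
  }
  tr <- bin_reads(df$start, genome, n_bins, label = label)
  attr(tr, "n_filtered") <- n_filtered
  tr
}

#' Serialize and restore scenarios as JSON
#'
#' @param scn A [scenario()].
#' @param file Path to a JSON scenario config.
#' @return `read_scenario()` returns a [scenario()].
#' @export
write_scenario <- function(scn, file) {
  stopifnot(inherits(scn, "scenario"))
  g <- scn$genome
  obj <- list(
    genome = list(name = g$name, length = g$length,
                  masked_intervals = unname(apply(g$masked_intervals, 1,
                                                  c, simplify = FALSE)),
                  markers = as.list(g$markers)),
    origins = lapply(scn$origins, unclass),
    ter_sites = lapply(scn$ter_sites, unclass),
    amplifications = lapply(scn$amplifications, unclass),
    inversions = lapply(scn$inversions, unclass),
    mode = scn$mode, k_ct = scn$k_ct,
    barriers = scn$barriers,
    n_bins = scn$n_bins, depth = scn$depth, bias_sd = scn$bias_sd,
    extent_dist = scn$extent_dist)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = FALSE)
  g <- obj$genome
  genome <- genome_spec(
    name = g$name, length = g$length,
    masked_intervals = lapply(g$masked_intervals, unlist),
    markers = if (length(g$markers)) unlist(g$markers) else NULL)
  origins <- lapply(obj$origins, function(o)
    origin_spec(o$name, o$position, o$kind, o$firing_fraction,
                o$extent_scale))
  ters <- lapply(obj$ter_sites, function(t)
    ter_site(t$name, t$position, t$blocks))
  amps <- lapply(obj$amplifications, function(a)
    amplification(a$start, a$end, a$copy_factor))
  invs <- lapply(obj$inversions, function(i) inversion(i$start, i$end))
  barriers <- if (length(obj$barriers))
    do.call(rbind, lapply(obj$barriers, function(b)
      data.frame(name = b$name %||% NA_character_, start = b$start,
                 end = b$end, strand = b$strand,
                 transmission = b$transmission)))
  else NULL
  scenario(genome = genome, origins = origins, ter_sites = ters,
           amplifications = amps, inversions = invs, mode = obj$mode,
           k_ct = obj$k_ct, barriers = barriers, n_bins = obj$n_bins,
           depth = obj$depth, bias_sd = obj$bias_sd,
           extent_dist = obj$extent_dist)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a per-window profile table
#'
#' Plot-ready TSV with one row per window: window index, bp bounds, Mb
#' midpoint, raw log2 (control-free), normalized log2 and the loess curve.
#'
#' @param profile A `normalized_profile`.
#' @param fit A `loess_fit` on the same windows.
#' @param raw Optional control-free `normalized_profile` (raw log2 column).
#' @param file Output path.
#' @param provenance Optional provenance header.
#' @return Invisibly, the data frame written.
#' @export
write_profile_tsv <- function(profile, fit, raw = NULL, file,
                              provenance = NULL) {
  n <- profile$n_bins
  L <- profile$genome$length
  bounds <- window_bounds(n, L)
  df <- data.frame(
    window = seq_len(n) - 1L,
    start = bounds[-(n + 1)],
    end = bounds[-1],
    midpoint_mb = round(window_midpoints(n, L) / 1e6, 4),
    raw_log2 = if (!is.null(raw)) round(raw$log2_ratio, 5) else NA_real_,
    norm_log2 = round(profile$log2_ratio, 5),
    loess = round(fit$fitted, 5))
  con <- file(file, "w")
  on.exit(close(con))
  write_provenance_header(con, provenance)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read back a profile TSV written by [write_profile_tsv()]
#'
#' @param file Path.
#' @return Data frame with the profile columns.
#' @export
read_profile_tsv <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
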