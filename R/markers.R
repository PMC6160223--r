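#' NGS marker-frequency ratio between two loci
#'
#' Estimates the relative copy number of marker A over marker B from a
#' coverage track as the ratio of mean library-scaled counts in a window of
#' `window_bp` centred on each locus (a window, rather than the single
#' amplicon a qPCR assay would use, stabilizes the coverage estimate). The
#' standard deviation propagates Poisson counting error:
#' `sd = ratio * sqrt(1/sum_A + 1/sum_B)`.
#'
#' @param track A [coverage_track()].
#' @param markerA,markerB Marker names (looked up in the track's genome) or
#'   bp positions.
#' @param window_bp Averaging window width in bp (default 5000); must be at
#'   least one bin wide.
#' @return A `marker_ratio` record: list with `numerator`, `denominator`,
#'   `ratio`, `sd`, `method = "NGS"`, `window_bp`, `n_windows`.
#' @export
ngs_marker_ratio <- function(track, markerA, markerB, window_bp = 5000) {
  stopifnot(inherits(track, "coverage_track"))
  g <- track$genome
  n <- track$n_bins
  L <- g$length
  if (window_bp < L / n)
    stop("window_bp must be at least one bin wide")
  posA <- resolve_marker(markerA, g)
  posB <- resolve_marker(markerB, g)
  cA <- marker_window_counts(track, posA$position, window_bp)
  cB <- marker_window_counts(track, posB$position, window_bp)
  if (!length(cA) || !length(cB))
    stop("empty marker window (masked or no data)")
  ratio <- mean(cA) / mean(cB)
  if (!is.finite(ratio)) stop("marker window has zero coverage")
  sd <- ratio * sqrt(1 / sum(cA) + 1 / sum(cB))
  structure(list(numerator = posA$name, denominator = posB$name,
                 num_position = posA$position, den_position = posB$position,
                 ratio = ratio, sd = sd, method = "NGS",
                 window_bp = window_bp,
                 n_windows = c(length(cA), length(cB))),
            class = "marker_ratio")
}

resolve_marker <- function(m, genome) {
  if (is.character(m)) {
    if (is.null(genome$markers) || !m %in% names(genome$markers))
      stop(sprintf("unknown marker '%s'", m))
    list(name = m, position = unname(genome$markers[[m]]))
  } else {
    list(name = sprintf("%.3fMb", m / 1e6), position = as.numeric(m))
  }
}

marker_window_counts <- function(track, pos, window_bp) {
  g <- track$genome
  n <- track$n_bins
  L <- g$length
  mids <- window_midpoints(n, L)
  a <- (pos - window_bp / 2) %% L
  b <- (pos + window_bp / 2) %% L
  sel <- if (a <= b) mids >= a & mids < b else mids >= a | mids < b
  cnt <- track$counts[sel]
  cnt[!is.na(cnt)]
}

#' @export
print.marker_ratio <- function(x, ...) {
  cat(sprintf("<marker_ratio> %s/%s = %.3f (sd %.3f, %s)\n",
              x$numerator, x$denominator, x$ratio, x$sd, x$method))
  invisible(x)
}

#' Read or validate a qPCR Ct replicate table
#'
#' Ct tables are TSV files with columns `marker`, `replicate`, `input_ng`
#' and `ct` — one row per tube.
#'
#' @param file Path to a TSV file.
#' @return A `ct_table` data frame.
#' @export
read_ct_table <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  as_ct_table(df)
}

#' @rdname read_ct_table
#' @param df A data frame with the Ct-table columns.
#' @export
as_ct_table <- function(df) {
  need <- c("marker", "replicate", "input_ng", "ct")
  if (!all(need %in% names(df)))
    stop("ct table needs columns: ", paste(need, collapse = ", "))
  if (any(df$ct <= 0)) stop("Ct values must be positive")
  if (!nrow(df)) stop("ct table is empty")
  class(df) <- c("ct_table", "data.frame")
  df
}

#' qPCR copy ratio by the 2^-dCt method
#'
#' Pairs the replicate tubes of the two markers (by replicate id and input
#' mass; when replicate ids are absent, by input mass and order), computes
#' `ratio_i = 2^-(CtA_i - CtB_i)` per pair, and reports the mean and the
#' sample standard deviation over pairs (computed from the per-pair ratios,
#' not from averaged Cts). Adding a constant to every Ct leaves the result
#' unchanged.
#'
#' @param ct_table A `ct_table` (see [read_ct_table()], [simulate_ct()]).
#' @param markerA,markerB Marker names present in the table.
#' @return A `marker_ratio` record with `method = "qPCR"` and `n_pairs`.
#' @export
delta_ct_ratio <- function(ct_table, markerA, markerB) {
  ct_table <- as_ct_table(as.data.frame(ct_table))
  a <- ct_table[ct_table$marker == markerA, , drop = FALSE]
  b <- ct_table[ct_table$marker == markerB, , drop = FALSE]
  if (!nrow(a) || !nrow(b))
    stop("both markers must be present in the ct table")
  key <- function(d) paste(d$replicate, d$input_ng, sep = "/")
  a <- a[order(a$input_ng, a$replicate), , drop = FALSE]
  b <- b[order(b$input_ng, b$replicate), , drop = FALSE]
  if (nrow(a) == nrow(b) && all(key(a) == key(b))) {
    dct <- a$ct - b$ct
  } else {
    # pair by input mass, in order, as a fallback
    masses <- intersect(unique(a$input_ng), unique(b$input_ng))
    if (!length(masses)) stop("cannot pair replicates across markers")
    dct <- numeric(0)
    for (mss in masses) {
      am <- a$ct[a$input_ng == mss]; bm <- b$ct[b$input_ng == mss]
      k <- min(length(am), length(bm))
      if (!k) stop("cannot pair replicates across markers")
      dct <- c(dct, am[seq_len(k)] - bm[seq_len(k)])
    }
  }
  ratios <- 2^(-dct)
  structure(list(numerator = markerA, denominator = markerB,
                 num_position = NA_real_, den_position = NA_real_,
                 ratio = mean(ratios),
                 sd = if (length(ratios) > 1) stats::sd(ratios) else 0,
                 method = "qPCR", window_bp = NA_real_,
                 n_pairs = length(ratios), ratios = ratios),
            class = "marker_ratio")
}

#' Concordance between an NGS and a qPCR marker ratio
#'
#' @param ngs,qpcr Two `marker_ratio` records for the same marker pair.
#' @param tol_log2 Discordance flag threshold on `|log2(ngs/qpcr)|`
#'   (default 0.2).
#' @return List with `ratio_of_ratios`, `log2_diff`, `abs_diff`,
#'   `discordant`.
#' @export
compare_methods <- function(ngs, qpcr, tol_log2 = 0.2) {
  stopifnot(inherits(ngs, "marker_ratio"), inherits(qpcr, "marker_ratio"))
  if (ngs$numerator != qpcr$numerator ||
      ngs$denominator != qpcr$denominator)
    stop("marker pairs differ between the two records")
  rr <- ngs$ratio / qpcr$ratio
  list(numerator = ngs$numerator, denominator = ngs$denominator,
       ratio_of_ratios = rr, log2_diff = log2(rr),
       abs_diff = abs(ngs$ratio - qpcr$ratio),
       discordant = abs(log2(rr)) > tol_log2, tol_log2 = tol_log2)
}
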