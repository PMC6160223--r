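#' Call origin peaks on a smoothed profile
#'
#' Finds circular local maxima of the loess curve and scores each by
#' topographic prominence (height above the higher of the two saddles
#' separating it from higher terrain, walking both ways around the circle).
#' Calls with prominence below `min_prominence` are dropped; calls at or
#' above `2 * min_prominence` are classified `"peak"`, the rest `"bump"`
#' (the distinction the profiles draw visually). Plateaus are reported at
#' their leftmost window; ties in prominence are broken by leftmost
#' reference coordinate.
#'
#' @param fit A `loess_fit` (from [loess_smooth()]) carrying genome/binning,
#'   or a numeric vector plus explicit `genome`/`n_bins`.
#' @param min_prominence Minimum prominence in log2 units (default 0.15).
#' @param genome,n_bins Required when `fit` is a bare numeric vector.
#' @return Data frame with columns `name`, `window` (0-based), `position`
#'   (bp midpoint), `position_mb`, `value` (fitted log2), `height` (log2
#'   above the genome-wide median), `prominence`, `class`; sorted by
#'   decreasing prominence. Peaks in masked windows are excluded.
#' @export
call_peaks <- function(fit, min_prominence = 0.15, genome = NULL,
                       n_bins = NULL) {
  v <- fit_values(fit, genome, n_bins)
  genome <- v$genome; n_bins <- v$n_bins; x <- v$values
  n <- length(x)
  empty <- data.frame(name = character(0), window = integer(0),
                      position = numeric(0), position_mb = numeric(0),
                      value = numeric(0), height = numeric(0),
                      prominence = numeric(0), class = character(0))
  if (all(is.na(x))) return(empty)
  med <- stats::median(x, na.rm = TRUE)

  maxima <- circular_local_maxima(x)
  if (!length(maxima)) return(empty)
  prom <- vapply(maxima, function(i) circular_prominence(x, i), numeric(1))
  keep <- prom >= min_prominence
  if (!is.null(genome)) {
    msk <- masked_windows(genome, n_bins)
    keep <- keep & !msk[maxima]
  }
  maxima <- maxima[keep]; prom <- prom[keep]
  if (!length(maxima)) return(empty)

  L <- if (!is.null(genome)) genome$length else n
  mids <- window_midpoints(n, L)
  out <- data.frame(
    name = sprintf("peak_%02d", seq_along(maxima)),
    window = maxima - 1L,
    position = mids[maxima],
    position_mb = round(mids[maxima] / 1e6, 3),
    value = x[maxima],
    height = x[maxima] - med,
    prominence = prom,
    class = ifelse(prom >= 2 * min_prominence, "peak", "bump"))
  out <- out[order(-out$prominence, out$position), , drop = FALSE]
  out$name <- sprintf("peak_%02d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

# Indices (1-based) of circular local maxima; plateaus report their leftmost
# window. NAs break the terrain and never count as maxima.
circular_local_maxima <- function(x) {
  n <- length(x)
  pres <- which(!is.na(x))
  if (length(pres) < 3) return(integer(0))
  # work on present windows in circular order
  v <- x[pres]
  m <- length(v)
  nxt <- c(2:m, 1); prv <- c(m, 1:(m - 1))
  out <- integer(0)
  # plateau-aware: find runs of equal value whose neighbors are both lower
  i <- 1
  visited <- rep(FALSE, m)
  for (s in 1:m) {
    if (visited[s]) next
    e <- s
    while (v[nxt[e]] == v[s] && nxt[e] != s) { e <- nxt[e]; visited[e] <- TRUE }
    visited[s] <- TRUE
    if (nxt[e] == s && e != s) { out <- c(out, s); break }  # all-constant
    if (v[prv[s]] < v[s] && v[nxt[e]] < v[s]) out <- c(out, s)
  }
  if (length(out) && stats::var(v) == 0) return(integer(0))  # flat: no peaks
  sort(pres[out])
}

# Topographic prominence of local maximum i on the circle: walk left and
# right to the nearest strictly higher value, tracking the minimum along
# each walk; prominence = height - max(left saddle, right saddle). The
# global maximum keys off the global minimum.
circular_prominence <- function(x, i) {
  n <- length(x)
  h <- x[i]
  walk <- function(step) {
    lo <- h
    j <- i
    for (s in seq_len(n - 1)) {
      j <- ((j - 1 + step) %% n) + 1
      if (is.na(x[j])) next
      if (x[j] > h) return(lo)
      if (x[j] < lo) lo <- x[j]
    }
    NA_real_   # no higher point: global maximum
  }
  ls <- walk(-1L); rs <- walk(1L)
  if (is.na(ls) || is.na(rs)) return(h - min(x, na.rm = TRUE))
  h - max(ls, rs)
}

fit_values <- function(fit, genome, n_bins) {
  if (inherits(fit, "loess_fit")) {
    list(values = fit$fitted,
         genome = if (is.null(genome)) fit$genome else genome,
         n_bins = if (is.null(n_bins)) fit$n_bins else n_bins)
  } else if (inherits(fit, "normalized_profile")) {
    list(values = fit$log2_ratio, genome = fit$genome, n_bins = fit$n_bins)
  } else {
    list(values = as.numeric(fit), genome = genome,
         n_bins = if (is.null(n_bins)) length(fit) else n_bins)
  }
}

#' Segment amplified regions of a profile
#'
#' Finds maximal circular runs of windows whose log2 value sits at least
#' `threshold_log2` above the genome-wide median and spans at least
#' `min_length_bp`, then refines each boundary with a local two-segment
#' mean changepoint fit (minimizing the within-segment sum of squares over a
#' window of `refine_radius` bins around the coarse edge). The copy factor
#' is `2^(mean log2 inside - mean log2 in the flanks)`.
#'
#' @param x A `loess_fit`, `normalized_profile` or numeric vector of log2
#'   values. Segmentation on the lightly-smoothed or raw normalized profile
#'   gives sharper boundaries than on a wide-span loess curve.
#' @param threshold_log2 Elevation above the median to call amplified
#'   (default 0.5, ~1.4-fold).
#' @param min_length_bp Minimum segment length (default 50 kb).
#' @param refine_radius Boundary search radius in windows (default 30).
#' @param flank_windows Number of windows per flank for the copy-factor
#'   baseline (default 100).
#' @param genome,n_bins Required when `x` is a bare numeric vector.
#' @return Data frame with `start`, `end` (bp, 0-based half-open),
#'   `start_mb`, `end_mb`, `n_windows`, `mean_log2`, `copy_factor`.
#' @export
segment_amplification <- function(x, threshold_log2 = 0.5,
                                  min_length_bp = 50000, refine_radius = 30,
                                  flank_windows = 100, genome = NULL,
                                  n_bins = NULL) {
  v <- fit_values(x, genome, n_bins)
  genome <- v$genome; n_bins <- v$n_bins; x <- v$values
  n <- length(x)
  L <- if (!is.null(genome)) genome$length else n
  binw <- L / n
  med <- stats::median(x, na.rm = TRUE)
  above <- !is.na(x) & (x >= med + threshold_log2)
  runs <- circular_runs(above)
  min_len_w <- ceiling(min_length_bp / binw)
  runs <- runs[vapply(runs, function(r) length(r) >= min_len_w, logical(1))]
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      start_mb = numeric(0), end_mb = numeric(0),
                      n_windows = integer(0), mean_log2 = numeric(0),
                      copy_factor = numeric(0))
  if (!length(runs)) return(empty)

  bounds <- window_bounds(n, L)
  out <- lapply(runs, function(r) {
    ws <- r[1]; we <- r[length(r)]          # 1-based first/last window
    ws <- refine_edge(x, ws, "left", refine_radius, n)
    we <- refine_edge(x, we, "right", refine_radius, n)
    seg <- circ_seq(ws, we, n)
    inside <- stats::median(x[seg], na.rm = TRUE)
    fl <- c(circ_seq2(ws - flank_windows, ws - 1, n),
            circ_seq2(we + 1, we + flank_windows, n))
    fl <- setdiff(fl, seg)
    flank <- stats::median(x[fl], na.rm = TRUE)
    if (!is.finite(flank)) flank <- med
    ml <- inside - flank
    data.frame(start = bounds[ws], end = bounds[we + 1],
               start_mb = round(bounds[ws] / 1e6, 3),
               end_mb = round(bounds[we + 1] / 1e6, 3),
               n_windows = length(seg), mean_log2 = ml,
               copy_factor = 2^ml)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Maximal circular runs of TRUE; each run returned as an increasing (mod n)
# 1-based index vector.
circular_runs <- function(b) {
  n <- length(b)
  if (!any(b)) return(list())
  if (all(b)) return(list(1:n))
  # rotate so position 1 is FALSE, then ordinary rle
  shift <- which(!b)[1] - 1
  br <- b[((seq_len(n) - 1 + shift) %% n) + 1]
  r <- rle(br)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    idx <- ((starts[i]:ends[i] - 1 + shift) %% n) + 1
    runs <- c(runs, list(idx))
  }
  runs
}

# indices from a to b inclusive walking clockwise (increasing, mod n)
circ_seq <- function(a, b, n) {
  a <- ((a - 1) %% n) + 1; b <- ((b - 1) %% n) + 1
  if (a <= b) a:b else c(a:n, 1:b)
}
circ_seq2 <- function(a, b, n) {
  if (((b - a) %% n) >= n - 1) return(integer(0))
  circ_seq(a, b, n)
}

# Two-segment mean changepoint refinement of one run edge. For a left edge,
# searches cut points c in [e - r, e + r] minimizing SSE of a low/high
# two-mean model over the local window; returns the first window of the
# high segment (and symmetrically for right edges).
refine_edge <- function(x, e, side = c("left", "right"), radius, n) {
  side <- match.arg(side)
  idx <- circ_seq(e - radius, e + radius, n)
  y <- x[idx]
  # never move an edge across a masked (NA) window: truncate the search
  # range at the nearest NA on each side of the coarse edge
  centre <- radius + 1
  nas <- which(is.na(y))
  lo <- if (any(nas < centre)) max(nas[nas < centre]) + 1 else 1
  hi <- if (any(nas > centre)) min(nas[nas > centre]) - 1 else length(idx)
  idx <- idx[lo:hi]
  y <- x[idx]
  if (length(y) < 4) return(e)
  best <- NULL; best_sse <- Inf
  for (c in 2:(length(idx) - 1)) {
    a <- y[1:(c - 1)]; b <- y[c:length(idx)]
    sse <- sum((a - mean(a, na.rm = TRUE))^2, na.rm = TRUE) +
           sum((b - mean(b, na.rm = TRUE))^2, na.rm = TRUE)
    if (sse < best_sse) { best_sse <- sse; best <- c }
  }
  if (is.null(best)) return(e)
  if (side == "left") idx[best] else idx[best - 1]
}

#' Copy-number drop across polar Ter sites
#'
#' For each Ter site, measures the difference between the mean fitted log2
#' level on the side forks arrive from (the blocking side, where trapped
#' forks pile up) and the far side. Signs are oriented so that a fork
#' pile-up against the trap yields a positive drop: a site blocking
#' counterclockwise forks (e.g. TerA) accumulates copies on its clockwise
#' flank `[pos, pos + flank)`, a site blocking clockwise forks (TerB) on
#' `[pos - flank, pos)`.
#'
#' @param fit A `loess_fit`, `normalized_profile` or numeric vector.
#' @param ter_sites List of [ter_site()] objects.
#' @param flank_bp Flank width in bp (default 100 kb).
#' @param genome,n_bins Required when `fit` is a bare numeric vector.
#' @return Data frame with `name`, `position`, `blocks`, `drop` (log2),
#'   `flank_bp`.
#' @export
ter_asymmetry <- function(fit, ter_sites, flank_bp = 100000, genome = NULL,
                          n_bins = NULL) {
  v <- fit_values(fit, genome, n_bins)
  genome <- v$genome; n_bins <- v$n_bins; x <- v$values
  n <- length(x)
  L <- if (!is.null(genome)) genome$length else n
  rows <- lapply(ter_sites, function(ts) {
    up <- interval_mean(x, ts$position - flank_bp, ts$position, n, L)
    dn <- interval_mean(x, ts$position, ts$position + flank_bp, n, L)
    drop <- if (ts$blocks == "counterclockwise") dn - up else up - dn
    data.frame(name = ts$name, position = ts$position, blocks = ts$blocks,
               drop = drop, flank_bp = flank_bp)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Mean of x over windows whose midpoints lie in the circular bp interval
# [a, b) (a may be negative / b beyond L).
interval_mean <- function(x, a, b, n, L) {
  mids <- window_midpoints(n, L)
  a <- a %% L; b <- b %% L
  sel <- if (a <= b) mids >= a & mids < b else mids >= a | mids < b
  mean(x[sel], na.rm = TRUE)
}

#' Replication "step" score across candidate head-on barrier intervals
#'
#' Scores each candidate interval (e.g. an rrn operon annotation) by the
#' mean fitted log2 level on the far side of the interval, in the direction
#' a head-on fork travels, minus the level on the approach side. A fork that
#' stalls head-on at the interval depresses copy number beyond it, so a
#' negative score indicates a replication step. For a `"+"`-strand interval
#' (transcribed clockwise) head-on forks move counterclockwise: the score is
#' mean over `[start - flank, start)` minus mean over `[end, end + flank)`;
#' `"-"`-strand intervals score the mirror image.
#'
#' @param fit A `loess_fit`, `normalized_profile` or numeric vector.
#' @param intervals Data frame with columns `start`, `end`, `strand` and
#'   optionally `name`.
#' @param flank_bp Flank width in bp (default 25 kb).
#' @param genome,n_bins Required when `fit` is a bare numeric vector.
#' @return Data frame with `name`, `start`, `end`, `strand`, `score`.
#' @export
step_score <- function(fit, intervals, flank_bp = 25000, genome = NULL,
                       n_bins = NULL) {
  v <- fit_values(fit, genome, n_bins)
  genome <- v$genome; n_bins <- v$n_bins; x <- v$values
  n <- length(x)
  L <- if (!is.null(genome)) genome$length else n
  intervals <- as.data.frame(intervals)
  if (is.null(intervals$name))
    intervals$name <- sprintf("interval_%02d", seq_len(nrow(intervals)))
  rows <- lapply(seq_len(nrow(intervals)), function(i) {
    s <- intervals$start[i]; e <- intervals$end[i]
    before <- interval_mean(x, s - flank_bp, s, n, L)
    after <- interval_mean(x, e, e + flank_bp, n, L)
    score <- if (intervals$strand[i] == "+") before - after
             else after - before
    data.frame(name = intervals$name[i], start = s, end = e,
               strand = intervals$strand[i], score = score)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
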