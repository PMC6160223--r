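#' Per-window coverage track over a circular genome
#'
#' The basic data container of the pipeline: one nonnegative read count per
#' window (NA for masked windows), tied to a [genome_spec()] and a fixed
#' window count.
#'
#' @param counts Numeric vector of length `n_bins`; `NA` marks masked or
#'   excluded windows; present values must be `>= 0`.
#' @param genome A [genome_spec()].
#' @param n_bins Number of windows.
#' @param label Sample name.
#' @return A `coverage_track` object with `total_reads` = sum of present
#'   counts.
#' @export
coverage_track <- function(counts, genome, n_bins = length(counts),
                           label = "sample") {
  stopifnot(inherits(genome, "genome_spec"))
  counts <- as.numeric(counts)
  if (length(counts) != n_bins)
    stop("counts length must equal n_bins")
  if (any(counts < 0, na.rm = TRUE))
    stop("counts must be nonnegative")
  structure(list(genome = genome, n_bins = as.integer(n_bins),
                 counts = counts,
                 total_reads = sum(counts, na.rm = TRUE), label = label),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> '%s': %d windows, %.0f reads, %d missing\n",
              x$label, x$n_bins, x$total_reads, sum(is.na(x$counts))))
  invisible(x)
}

#' Bin positioned reads into a coverage track
#'
#' Counts read positions (e.g. 5' start coordinates) per window. Positions
#' falling in masked windows are dropped (and counted as dropped); non-finite
#' or out-of-range positions are skipped with a warning.
#'
#' @param positions Numeric vector of bp positions in `[0, L)`.
#' @param genome A [genome_spec()].
#' @param n_bins Number of windows.
#' @param label Sample name.
#' @return A [coverage_track()]; the number of malformed positions skipped
#'   and masked reads dropped are attached as attributes `n_skipped` and
#'   `n_masked_dropped`.
#' @export
bin_reads <- function(positions, genome, n_bins = 10000, label = "sample") {
  positions <- as.numeric(positions)
  L <- genome$length
  bad <- !is.finite(positions) | positions < 0 | positions >= L
  if (any(bad)) {
    warning(sprintf("skipped %d malformed read position(s)", sum(bad)))
    positions <- positions[!bad]
  }
  w <- if (length(positions)) window_of(positions, n_bins, L) else integer(0)
  counts <- as.numeric(tabulate(w + 1L, nbins = n_bins))
  msk <- masked_windows(genome, n_bins)
  n_masked_dropped <- sum(counts[msk])
  counts[msk] <- NA_real_
  tr <- coverage_track(counts, genome, n_bins, label = label)
  attr(tr, "n_skipped") <- sum(bad)
  attr(tr, "n_masked_dropped") <- n_masked_dropped
  tr
}

#' Normalize a sample track against a control track
#'
#' Computes, per window, the log2 ratio of library-size-scaled sample over
#' control:
#' `r_w = log2(((s_w + pc) / S) / ((c_w + pc) / C))`,
#' with `S` and `C` the total present counts of the two tracks. Windows that
#' are masked in either track or whose control count falls below
#' `control_floor` are excluded (NA).
#'
#' @param sample,control [coverage_track()]s on the same genome and binning.
#' @param pseudocount Added to both numerator and denominator counts
#'   (default 0.5).
#' @param control_floor Minimum control reads for a window to be kept
#'   (default 5; set 0 to disable).
#' @return A `normalized_profile`: list with `log2_ratio` (length `n_bins`),
#'   `excluded` (logical), the pseudocount and the genome/binning.
#' @export
normalize_to_control <- function(sample, control, pseudocount = 0.5,
                                 control_floor = 5) {
  stopifnot(inherits(sample, "coverage_track"),
            inherits(control, "coverage_track"))
  if (sample$n_bins != control$n_bins ||
      sample$genome$length != control$genome$length)
    stop("sample and control binning/genome mismatch")
  s <- sample$counts; c <- control$counts
  S <- sample$total_reads; C <- control$total_reads
  if (S <= 0 || C <= 0) stop("tracks must contain reads")
  excluded <- is.na(s) | is.na(c) | (!is.na(c) & c < control_floor)
  r <- log2(((s + pseudocount) / S) / ((c + pseudocount) / C))
  r[excluded] <- NA_real_
  structure(list(log2_ratio = r, excluded = excluded,
                 pseudocount = pseudocount, control_floor = control_floor,
                 genome = sample$genome, n_bins = sample$n_bins,
                 sample_label = sample$label, control_label = control$label),
            class = "normalized_profile")
}

#' Control-free log2 profile of a single track
#'
#' Log-phase profiles without a control (absolute read counts): per present
#' window, `log2((s_w + pc) / S)` recentred so the genome-wide median is 0.
#'
#' @inheritParams normalize_to_control
#' @return A `normalized_profile` with `control_label = NA`.
#' @export
log2_track <- function(sample, pseudocount = 0.5) {
  stopifnot(inherits(sample, "coverage_track"))
  s <- sample$counts
  S <- sample$total_reads
  if (S <= 0) stop("track must contain reads")
  r <- log2((s + pseudocount) / S)
  r <- r - stats::median(r, na.rm = TRUE)
  structure(list(log2_ratio = r, excluded = is.na(s),
                 pseudocount = pseudocount, control_floor = 0,
                 genome = sample$genome, n_bins = sample$n_bins,
                 sample_label = sample$label, control_label = NA_character_),
            class = "normalized_profile")
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat(sprintf("<normalized_profile> '%s' vs '%s': %d windows, %d excluded\n",
              x$sample_label, x$control_label, x$n_bins, sum(x$excluded)))
  invisible(x)
}

#' Circular loess smoothing of a windowed profile
#'
#' Locally weighted polynomial regression on the circle: for every window
#' (including missing ones, which are interpolated), the `span * m` nearest
#' present windows by circular distance (m = number of present windows) are
#' fit with a degree-`degree` polynomial under tricube weights and the fit
#' is evaluated at the window. Optional robustness iterations reweight by
#' Tukey's bisquare of the residuals. Because neighborhoods use circular
#' distance there is no edge artifact at coordinate 0.
#'
#' @param x A `normalized_profile` or a numeric vector of per-window values
#'   with `NA` for missing windows.
#' @param span Fraction of present windows per neighborhood (default 0.1).
#' @param degree Local polynomial degree, 0 or 1 (default 1).
#' @param robust_iters Bisquare robustness iterations (default 2).
#' @return A `loess_fit`: list with `fitted` (length n, finite everywhere),
#'   `span`, `degree`, `robust_iters`, `k` (neighborhood size) and the
#'   genome/binning when smoothing a profile.
#' @export
loess_smooth <- function(x, span = 0.1, degree = 1, robust_iters = 2) {
  genome <- NULL; n_bins <- NULL
  if (inherits(x, "normalized_profile")) {
    genome <- x$genome; n_bins <- x$n_bins
    x <- x$log2_ratio
  }
  x <- as.numeric(x)
  n <- length(x)
  pres <- which(!is.na(x))
  m <- length(pres)
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  if (!degree %in% c(0, 1)) stop("degree must be 0 or 1")
  if (m < degree + 2) stop("too few present windows")
  k <- ceiling(span * m)
  if (k < degree + 2)
    stop("span too small for the requested degree")
  k <- min(k, m)

  nb <- circular_neighborhoods(seq_len(n) - 1L, pres - 1L, k, n)
  rw <- rep(1, n)  # robustness weights indexed by window
  fitted <- rep(NA_real_, n)
  for (iter in 0:robust_iters) {
    fitted <- loess_pass(x, pres, nb, k, n, degree, rw)
    if (iter == robust_iters) break
    res <- x[pres] - fitted[pres]
    s <- 6 * stats::median(abs(res), na.rm = TRUE)
    if (!is.finite(s) || s <= 0) break
    rb <- rep(0, n)
    rb[pres] <- ifelse(abs(res) < s, (1 - (res / s)^2)^2, 0)
    rw <- rb
  }
  structure(list(fitted = fitted, span = span, degree = degree,
                 robust_iters = robust_iters, k = k,
                 genome = genome, n_bins = n_bins),
            class = "loess_fit")
}

#' @export
print.loess_fit <- function(x, ...) {
  cat(sprintf("<loess_fit> span %.3g, degree %d, k = %d neighbors\n",
              x$span, x$degree, x$k))
  invisible(x)
}

# For every target window (0-based indices `targets`), find the contiguous
# run of k nearest present windows (0-based indices `pres0`, sorted) by
# circular distance on an n-window circle. Vectorized two-pointer expansion.
# Returns list(start = 0-based rank into pres0 of the run start, dmax =
# largest circular distance in the run).
circular_neighborhoods <- function(targets, pres0, k, n) {
  m <- length(pres0)
  cd <- function(a, b) { d <- abs(a - b); pmin(d, n - d) }
  # rank (0-based) of the rightmost present window at or left of target
  r0 <- findInterval(targets, pres0) - 1L   # -1 when none at/left
  lrank <- r0 %% m                          # left candidate rank
  rrank <- (r0 + 1L) %% m                   # right candidate rank
  nt <- length(targets)
  taken_left <- integer(nt)
  dmax <- numeric(nt)
  for (j in seq_len(k)) {
    dl <- cd(targets, pres0[lrank + 1L])
    dr <- cd(targets, pres0[rrank + 1L])
    if (k == m && j == k) {
      # last pick when the whole present set is used: pointers have met
      same <- lrank == rrank
      takeL <- same | (dl <= dr)
    } else takeL <- dl <= dr
    d_taken <- ifelse(takeL, dl, dr)
    dmax <- pmax(dmax, d_taken)
    taken_left <- taken_left + as.integer(takeL)
    lrank <- ifelse(takeL, (lrank - 1L) %% m, lrank)
    rrank <- ifelse(takeL, rrank, (rrank + 1L) %% m)
  }
  start <- (r0 - taken_left + 1L) %% m
  list(start = start, dmax = dmax)
}

# One weighted local-regression pass over all windows, chunked to bound
# memory. x: data with NA; pres: 1-based present indices; nb: neighborhoods.
loess_pass <- function(x, pres, nb, k, n, degree, rw) {
  m <- length(pres)
  pres0 <- pres - 1L
  fitted <- numeric(n)
  chunk <- max(1L, min(n, as.integer(2e6 / k)))
  off <- 0L
  while (off < n) {
    tgt <- (off + 1L):min(n, off + chunk)
    nt <- length(tgt)
    ranks <- (outer(nb$start[tgt], 0:(k - 1L), "+")) %% m   # nt x k
    W <- matrix(pres0[ranks + 1L], nt, k)                    # window idx
    Y <- matrix(x[W + 1L], nt, k)
    o <- W - (tgt - 1L)
    o <- ((o + n %/% 2) %% n) - n %/% 2                      # signed offset
    d <- abs(o)
    dm <- pmax(nb$dmax[tgt], 1e-12)
    wt_tri <- (1 - pmin(d / dm, 1)^3)^3
    wt <- wt_tri * matrix(rw[W + 1L], nt, k)
    sw <- rowSums(wt)
    # robustness weights can zero out an entire neighborhood; fall back to
    # plain tricube there rather than emit NaN
    dead <- which(!is.finite(sw) | sw <= 0)
    if (length(dead)) {
      wt[dead, ] <- wt_tri[dead, ]
      sw[dead] <- rowSums(wt_tri[dead, , drop = FALSE])
    }
    swy <- rowSums(wt * Y)
    if (degree == 0) {
      fitted[tgt] <- swy / sw
    } else {
      swx <- rowSums(wt * o)
      swxx <- rowSums(wt * o * o)
      swxy <- rowSums(wt * o * Y)
      denom <- sw * swxx - swx^2
      beta1 <- ifelse(abs(denom) > 1e-10 * pmax(sw * swxx, 1e-300),
                      (sw * swxy - swx * swy) / denom, 0)
      fitted[tgt] <- (swy - beta1 * swx) / sw
    }
    off <- off + nt
  }
  fitted
}

#' Brute-force loess oracle at a single window
#'
#' Independent re-derivation of the circular loess fit at one window:
#' enumerates all circular distances, selects the k nearest present windows,
#' builds tricube weights and solves the weighted least squares with
#' [stats::lm()]. Used by the test suite to validate [loess_smooth()]; not
#' part of the pipeline.
#'
#' @param x Numeric per-window values with `NA` missing.
#' @param target 1-based window index to fit.
#' @param span,degree As in [loess_smooth()].
#' @param rw Optional robustness weights per window.
#' @return Fitted value at `target`.
#' @export
loess_fit_at <- function(x, target, span = 0.1, degree = 1, rw = NULL) {
  n <- length(x)
  pres <- which(!is.na(x))
  m <- length(pres)
  k <- min(max(ceiling(span * m), degree + 2), m)
  if (is.null(rw)) rw <- rep(1, n)
  dall <- abs(pres - target)
  dall <- pmin(dall, n - dall)
  ord <- order(dall, pres)     # ties: lower window index first
  sel <- pres[ord[seq_len(k)]]
  d <- dall[ord[seq_len(k)]]
  dm <- max(d, 1e-12)
  w <- (1 - pmin(d / dm, 1)^3)^3 * rw[sel]
  o <- sel - target
  o <- ((o + n %/% 2) %% n) - n %/% 2
  y <- x[sel]
  if (degree == 0) return(sum(w * y) / sum(w))
  fit <- stats::lm(y ~ o, weights = w)
  unname(stats::predict(fit, newdata = data.frame(o = 0)))
}
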