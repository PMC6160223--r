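#' Describe a circular bacterial chromosome
#'
#' A `genome_spec` fixes the coordinate system used everywhere else in the
#' package: a single circular replicon of `length` base pairs, 0-based
#' half-open internal coordinates, a set of masked intervals excluded from
#' analysis (e.g. a strain deletion that produces a coverage gap), and named
#' marker loci used for copy-ratio statistics.
#'
#' The defaults emulate an *E. coli* K-12 W3110-like chromosome of 4.64 Mb
#' with one ~35 kb masked gap around 0.33-0.36 Mb (a codB-lacI-style
#' deletion) and markers ydcM (1.505 Mb), lepA (2.705 Mb), qseC (3.169 Mb),
#' parC (3.162 Mb), parE (3.172 Mb) and oriC (3.925 Mb).
#'
#' @param name Chromosome name (used as the bedGraph/BED chrom field).
#' @param length Chromosome length in bp; must be positive.
#' @param masked_intervals Numeric matrix or list of `c(start, end)` 0-based
#'   half-open bp intervals excluded from analysis. May be `NULL`.
#' @param markers Named numeric vector of marker bp positions.
#' @return An object of class `genome_spec`.
#' @examples
#' g <- genome_spec()
#' g$length
#' g$markers[["oriC"]]
#' @export
genome_spec <- function(name = "W3110-like",
                        length = 4640000,
                        masked_intervals = list(c(330000, 365000)),
                        markers = c(ydcM = 1505000, lepA = 2705000,
                                    qseC = 3169000, parC = 3162000,
                                    parE = 3172000, oriC = 3925000)) {
  length <- as.numeric(length)
  if (!is.finite(length) || length <= 0)
    stop("genome length must be a positive number")
  mi <- normalize_intervals(masked_intervals, length)
  if (!is.null(markers)) {
    if (is.null(names(markers)) || anyDuplicated(names(markers)))
      stop("marker names must be present and unique")
    if (any(markers < 0 | markers >= length))
      stop("marker positions must lie in [0, length)")
  }
  structure(list(name = name, length = length,
                 masked_intervals = mi, markers = markers),
            class = "genome_spec")
}

# Coerce intervals to a 2-column matrix, sort, check bounds and overlap.
normalize_intervals <- function(x, L) {
  if (is.null(x) || (is.list(x) && !length(x)))
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  if (is.list(x)) x <- do.call(rbind, x)
  x <- matrix(as.numeric(x), ncol = 2)
  colnames(x) <- c("start", "end")
  if (any(!is.finite(x))) stop("intervals must be finite")
  if (any(x[, 1] < 0 | x[, 2] > L | x[, 1] >= x[, 2]))
    stop("intervals must satisfy 0 <= start < end <= genome length")
  x <- x[order(x[, 1]), , drop = FALSE]
  if (nrow(x) > 1 && any(x[-1, 1] < x[-nrow(x), 2]))
    stop("intervals overlap after sorting")
  x
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %s: %s bp circular, %d masked interval(s), %d marker(s)\n",
              x$name, format(x$length, big.mark = ","),
              nrow(x$masked_intervals),
              if (is.null(x$markers)) 0L else length(x$markers)))
  invisible(x)
}

#' Define a polar replication-fork trap (Ter/Tus site)
#'
#' Ter sites bound by Tus arrest replication forks arriving from one
#' direction only. `blocks` names the fork direction that is arrested:
#' `"clockwise"` stops forks moving toward increasing coordinates,
#' `"counterclockwise"` stops forks moving toward decreasing coordinates.
#' Forks of the opposite polarity pass through unimpeded.
#'
#' @param name Site name (e.g. "TerA").
#' @param position bp position of the site.
#' @param blocks `"clockwise"` or `"counterclockwise"`.
#' @return A `ter_site` object.
#' @export
ter_site <- function(name, position, blocks = c("counterclockwise", "clockwise")) {
  blocks <- match.arg(blocks)
  position <- as.numeric(position)
  if (!is.finite(position) || position < 0)
    stop("ter site position must be a nonnegative number")
  structure(list(name = name, position = position, blocks = blocks),
            class = "ter_site")
}

#' Default TerA/TerB fork traps
#'
#' The Ter-region trap used throughout the presets: TerA at 1.34 Mb arrests
#' counterclockwise-moving forks, TerB at 1.68 Mb arrests clockwise-moving
#' forks, so forks entering the 1.34-1.68 Mb region from either side are
#' confined within it.
#'
#' @return List of two `ter_site` objects.
#' @export
default_ter_sites <- function() {
  list(ter_site("TerA", 1340000, "counterclockwise"),
       ter_site("TerB", 1680000, "clockwise"))
}

#' Structural variants: inversion and amplification
#'
#' `inversion(start, end)` declares that the segment `[start, end]` of the
#' reference chromosome is inverted in the physical chromosome;
#' `amplification(start, end, copy_factor)` declares a tandem copy-number
#' gain of `copy_factor` over `[start, end)`.
#'
#' @param start,end bp coordinates, `start < end`.
#' @param copy_factor Copy-number multiplier, `>= 1`.
#' @return An `inversion` or `amplification` object.
#' @export
inversion <- function(start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start < 0 || start >= end)
    stop("inversion requires 0 <= start < end")
  structure(list(start = start, end = end), class = "inversion")
}

#' @rdname inversion
#' @export
amplification <- function(start, end, copy_factor) {
  start <- as.numeric(start); end <- as.numeric(end)
  copy_factor <- as.numeric(copy_factor)
  if (!is.finite(start) || !is.finite(end) || start < 0 || start >= end)
    stop("amplification requires 0 <= start < end")
  if (!is.finite(copy_factor) || copy_factor < 1)
    stop("copy_factor must be >= 1")
  structure(list(start = start, end = end, copy_factor = copy_factor),
            class = "amplification")
}

#' Map a coordinate through a chromosomal inversion
#'
#' Coordinates inside the inverted segment `[start, end]` are reflected to
#' `start + end - p`; coordinates outside are unchanged. The map is an
#' involution: applying it twice returns the input.
#'
#' @param p bp coordinate(s); vectorized.
#' @param inv An [inversion()] object.
#' @param L Genome length in bp (for range checking).
#' @return Mapped bp coordinate(s).
#' @examples
#' map_through_inversion(1520000, inversion(1390000, 2280000), 4640000)
#' @export
map_through_inversion <- function(p, inv, L) {
  stopifnot(inherits(inv, "inversion"))
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0 | p >= L))
    stop("coordinate out of range [0, L)")
  if (inv$end >= L) stop("inversion end out of range")
  inside <- p >= inv$start & p <= inv$end
  p[inside] <- inv$start + inv$end - p[inside]
  p
}

#' Distance between two points on a circular chromosome
#'
#' @param p,q bp positions in `[0, L)`; vectorized (recycled).
#' @param direction `"shortest"`, `"clockwise"` (from `p` toward increasing
#'   coordinates until `q`), or `"counterclockwise"`.
#' @param L Genome length in bp.
#' @return Nonnegative bp distance(s); the shortest distance is `<= L/2`.
#' @examples
#' circular_distance(0, 4639999, direction = "clockwise", L = 4640000)
#' @export
circular_distance <- function(p, q, direction = c("shortest", "clockwise",
                                                  "counterclockwise"),
                              L) {
  direction <- match.arg(direction)
  p <- as.numeric(p); q <- as.numeric(q)
  if (any(p < 0 | p >= L) || any(q < 0 | q >= L))
    stop("positions must lie in [0, L)")
  cw <- (q - p) %% L
  switch(direction,
         clockwise = cw,
         counterclockwise = (p - q) %% L,
         shortest = pmin(cw, L - cw))
}

#' Window index of a bp position
#'
#' The chromosome is divided into `n_bins` equal-width, 0-based, half-open
#' windows; window `n_bins - 1` is circularly adjacent to window 0. For the
#' default W3110-like genome and 10,000 windows each window is 464 bp.
#'
#' @param p bp position(s) in `[0, L)`; vectorized.
#' @param n_bins Number of windows, `>= 1`.
#' @param L Genome length in bp.
#' @return 0-based integer window index(es) in `[0, n_bins)`.
#' @examples
#' window_of(1505000, 10000, 4640000)
#' @export
window_of <- function(p, n_bins, L) {
  p <- as.numeric(p)
  if (n_bins < 1) stop("n_bins must be >= 1")
  if (any(!is.finite(p)) || any(p < 0 | p >= L))
    stop("position out of range [0, L)")
  idx <- floor(p * n_bins / L)
  # guard against floating-point landing exactly on n_bins
  pmin(idx, n_bins - 1)
}

#' Window midpoints and boundaries
#'
#' @param n_bins Number of windows.
#' @param L Genome length in bp.
#' @return `window_midpoints`: numeric vector of bp midpoints of the
#'   `n_bins` windows; `window_bounds`: numeric vector of `n_bins + 1`
#'   boundary coordinates (integral bp).
#' @export
window_midpoints <- function(n_bins, L) {
  (seq_len(n_bins) - 0.5) * L / n_bins
}

#' @rdname window_midpoints
#' @export
window_bounds <- function(n_bins, L) {
  floor((0:n_bins) * L / n_bins)
}

#' Which windows fall in masked intervals?
#'
#' A window is masked when its midpoint lies inside a masked interval of the
#' genome. Masked windows carry `NA` coverage and are excluded from
#' normalization, smoothing neighborhoods and feature calls.
#'
#' @param genome A [genome_spec()].
#' @param n_bins Number of windows.
#' @return Logical vector of length `n_bins`.
#' @export
masked_windows <- function(genome, n_bins) {
  mids <- window_midpoints(n_bins, genome$length)
  m <- rep(FALSE, n_bins)
  mi <- genome$masked_intervals
  if (nrow(mi)) {
    for (i in seq_len(nrow(mi)))
      m <- m | (mids >= mi[i, 1] & mids < mi[i, 2])
  }
  m
}

# Map an interval through an inversion. Intervals fully inside the segment
# are reflected; fully outside pass through; partial overlap is unsupported.
map_interval_through_inversion <- function(start, end, inv, L) {
  inside_s <- start >= inv$start & start <= inv$end
  # end is an exclusive bound; the last covered point is end - 1
  inside_e <- (end - 1) >= inv$start & (end - 1) <= inv$end
  if (inside_s != inside_e)
    stop("interval straddles an inversion boundary: unsupported")
  if (!inside_s) return(c(start, end))
  c(inv$start + inv$end - (end - 1), inv$start + inv$end - start + 1)
}
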