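#' Declare a replication origin for simulation
#'
#' The population model treats each origin as firing independently in a
#' fraction `firing_fraction` of chromosomes sampled at harvest; a firing
#' event launches two divergent forks whose progressed distances are drawn
#' independently from an exponential (default) or uniform distribution with
#' mean `extent_scale` bp, truncated by any polar Ter trap they meet.
#'
#' @param name Origin name.
#' @param position bp position.
#' @param kind `"oriC"` (drives the deterministic log-phase gradient) or
#'   `"oriK"` (cSDR origin contributing probabilistic fork coverage).
#' @param firing_fraction Probability in `[0, 1]` that a chromosome carries
#'   one active replication event from this origin at sampling time.
#' @param extent_scale Mean fork progression distance in bp; `> 0`.
#' @return An `origin_spec` object.
#' @export
origin_spec <- function(name, position, kind = c("oriK", "oriC"),
                        firing_fraction = 0.5, extent_scale = 250000) {
  kind <- match.arg(kind)
  if (firing_fraction < 0 || firing_fraction > 1)
    stop("firing_fraction must lie in [0, 1]")
  if (extent_scale <= 0) stop("extent_scale must be > 0")
  structure(list(name = name, position = as.numeric(position), kind = kind,
                 firing_fraction = firing_fraction,
                 extent_scale = as.numeric(extent_scale)),
            class = "origin_spec")
}

#' Assemble a replication scenario
#'
#' A scenario is the full generative description of one sample: the genome,
#' the active origins, polar Ter traps, structural variants, growth mode and
#' noise model. It is the unit that [expected_copy_number()] turns into a
#' ground-truth copy-number curve and [sample_coverage()] turns into a noisy
#' coverage track.
#'
#' @param genome A [genome_spec()].
#' @param origins List of [origin_spec()] objects.
#' @param ter_sites List of [ter_site()] objects (may be empty).
#' @param amplifications List of [amplification()] objects.
#' @param inversions List of [inversion()] objects.
#' @param mode `"log_phase"` (exponential growth: oriC copy-number gradient
#'   `2^(k_ct * (1 - u))` with `u` the normalized fork-arrival time),
#'   `"runout"` (replication run-out after blocking initiation, e.g. by
#'   spectinomycin: flat base level 1, cSDR still visible) or
#'   `"stationary"` (flat base level 1).
#' @param k_ct Dimensionless C-period over doubling-time ratio governing the
#'   steepness of the log-phase oriC gradient (default 0.8).
#' @param barriers Optional data frame with columns `start`, `end`, `strand`
#'   (`"+"` = transcribed clockwise) and `transmission` (probability in
#'   `(0, 1]` that a head-on fork transits the interval). Stalling applies
#'   to oriK forks traversing the interval head-on (against transcription);
#'   codirectional forks and the deterministic oriC gradient are unaffected.
#' @param n_bins Number of analysis windows (default 10000).
#' @param depth Expected reads per window for [sample_coverage()].
#' @param bias_sd Lognormal per-window bias standard deviation.
#' @param extent_dist `"exponential"` or `"uniform"` fork-extent law.
#' @return A `scenario` object.
#' @export
scenario <- function(genome = genome_spec(), origins = list(),
                     ter_sites = list(), amplifications = list(),
                     inversions = list(),
                     mode = c("runout", "log_phase", "stationary"),
                     k_ct = 0.8, barriers = NULL, n_bins = 10000,
                     depth = 100, bias_sd = 0.05,
                     extent_dist = c("exponential", "uniform")) {
  mode <- match.arg(mode)
  extent_dist <- match.arg(extent_dist)
  stopifnot(inherits(genome, "genome_spec"))
  if (depth <= 0) stop("depth must be > 0")
  if (k_ct < 0) stop("k_ct must be >= 0")
  L <- genome$length
  for (o in origins) {
    stopifnot(inherits(o, "origin_spec"))
    if (o$position < 0 || o$position >= L) stop("origin position out of range")
    mi <- genome$masked_intervals
    if (nrow(mi) && any(o$position >= mi[, 1] & o$position < mi[, 2]))
      warning(sprintf("origin %s lies inside a masked interval", o$name))
  }
  for (ts in ter_sites) {
    stopifnot(inherits(ts, "ter_site"))
    if (ts$position < 0 || ts$position >= L) stop("ter position out of range")
  }
  for (v in amplifications) stopifnot(inherits(v, "amplification"))
  for (v in inversions) stopifnot(inherits(v, "inversion"))
  if (!is.null(barriers)) {
    barriers <- as.data.frame(barriers)
    stopifnot(all(c("start", "end", "strand", "transmission") %in%
                    names(barriers)))
    if (any(barriers$transmission <= 0 | barriers$transmission > 1))
      stop("barrier transmission must lie in (0, 1]")
    if (!all(barriers$strand %in% c("+", "-")))
      stop("barrier strand must be '+' or '-'")
  }
  structure(list(genome = genome, origins = origins, ter_sites = ter_sites,
                 amplifications = amplifications, inversions = inversions,
                 mode = mode, k_ct = k_ct, barriers = barriers,
                 n_bins = as.integer(n_bins), depth = depth,
                 bias_sd = bias_sd, extent_dist = extent_dist),
            class = "scenario")
}

#' Where does a fork stop?
#'
#' Displaces a fork from `origin` by `extent` bp in the stated direction
#' around the circle, truncating at the first Ter site encountered whose
#' blocking polarity matches the fork direction; Ter sites of the opposite
#' polarity are passed through. A blocking Ter located exactly at the origin
#' does not arrest the departing fork.
#'
#' @param origin bp start position.
#' @param direction `"clockwise"` or `"counterclockwise"`.
#' @param extent Fork progression distance in bp, `>= 0`.
#' @param ter_sites List of [ter_site()] objects.
#' @param L Genome length in bp.
#' @return bp coordinate reached by the fork.
#' @examples
#' traps <- default_ter_sites()
#' fork_stop(1520000, "counterclockwise", 1e6, traps, 4640000)  # TerA arrest
#' @export
fork_stop <- function(origin, direction = c("clockwise", "counterclockwise"),
                      extent, ter_sites, L) {
  direction <- match.arg(direction)
  if (extent < 0) stop("extent must be >= 0")
  travel <- min(extent, L)
  bd <- blocking_distance(origin, direction, ter_sites, L)
  travel <- min(travel, bd)
  if (direction == "clockwise") (origin + travel) %% L
  else (origin - travel) %% L
}

# Distance along `direction` from `origin` to the nearest Ter site that
# blocks that direction; Inf when unblocked. Zero-distance sites ignored.
blocking_distance <- function(origin, direction, ter_sites, L) {
  d <- Inf
  for (ts in ter_sites) {
    if (ts$blocks != direction) next
    dt <- circular_distance(origin, ts$position, direction, L)
    if (dt > 0 && dt < d) d <- dt
  }
  d
}

# Barrier entry edges and transmissions seen by a fork leaving `origin` in
# `direction`; returns a data.frame ordered by entry distance. Head-on means
# the fork direction opposes the annotated transcription strand.
headon_barriers <- function(origin, direction, barriers, L) {
  if (is.null(barriers) || !nrow(barriers))
    return(data.frame(dist = numeric(0), transmission = numeric(0)))
  headon_strand <- if (direction == "clockwise") "-" else "+"
  b <- barriers[barriers$strand == headon_strand, , drop = FALSE]
  if (!nrow(b)) return(data.frame(dist = numeric(0), transmission = numeric(0)))
  edge <- if (direction == "clockwise") b$start else b$end %% L
  d <- circular_distance(origin, edge %% L, direction, L)
  keep <- d > 0
  out <- data.frame(dist = d[keep], transmission = b$transmission[keep])
  out[order(out$dist), , drop = FALSE]
}

# P(extent >= d) under the scenario's fork-extent law with mean `scale`.
extent_survival <- function(d, scale, dist = "exponential") {
  if (dist == "exponential") exp(-d / scale)
  else pmax(0, 1 - d / (2 * scale))  # uniform on [0, 2*scale], mean scale
}

# Coverage probability of each window midpoint by one arm of an oriK event:
# needs extent >= d, no blocking Ter strictly closer than d, and survival of
# every head-on barrier whose entry edge was passed (entry distance < d).
arm_coverage_prob <- function(origin, direction, scale, ter_sites, barriers,
                              mids, L, extent_dist) {
  d <- circular_distance(origin, mids, direction, L)
  bd <- blocking_distance(origin, direction, ter_sites, L)
  p <- extent_survival(d, scale, extent_dist)
  p[d > bd] <- 0
  hb <- headon_barriers(origin, direction, barriers, L)
  if (nrow(hb)) {
    for (i in seq_len(nrow(hb)))
      p[d > hb$dist[i]] <- p[d > hb$dist[i]] * hb$transmission[i]
  }
  p
}

# Deterministic oriC fork-arrival distance at each midpoint: min over all
# oriC origins and both fork directions of the travel distance, Inf where a
# blocking Ter intervenes. Windows unreachable by any fork (fully trapped
# configurations) are assigned the maximum finite arrival.
oric_arrival <- function(origins, ter_sites, mids, L) {
  t <- rep(Inf, length(mids))
  for (o in origins) {
    if (o$kind != "oriC") next
    for (dir in c("clockwise", "counterclockwise")) {
      d <- circular_distance(o$position, mids, dir, L)
      bd <- blocking_distance(o$position, dir, ter_sites, L)
      d[d > bd] <- Inf
      t <- pmin(t, d)
    }
  }
  if (all(!is.finite(t))) stop("log_phase mode requires an oriC origin")
  t[!is.finite(t)] <- max(t[is.finite(t)])
  t
}

#' Expected relative copy number of a scenario
#'
#' Computes the ground-truth ("truth record") expected copy-number curve of
#' the population model over the scenario's windows. Per unmasked window
#' midpoint `x`:
#' `copies(x) = base(x) * ampfactor(x) + sum_i ff_i * P[x covered by oriK i]`
#' where `base(x) = 2^(k_ct * (1 - u(x)))` in log-phase mode (`u(x)` the
#' normalized oriC fork-arrival time with Ter trapping) and `base(x) = 1` in
#' run-out and stationary modes. The oriK coverage probability integrates
#' the fork-extent law with Ter truncation on each arm and head-on barrier
#' transmission; `ampfactor` multiplies the base level inside amplification
#' intervals.
#'
#' @param scn A [scenario()]. Inversions, if present, are handled by
#'   [simulate_with_inversion()]; this function requires an inversion-free
#'   scenario.
#' @return A `truth_record`: list with `copies` (length `n_bins`, `NA` in
#'   masked windows), the generating annotations, `mode` and `n_bins`.
#' @export
expected_copy_number <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  if (length(scn$inversions))
    stop("scenario contains inversions; use simulate_with_inversion()")
  g <- scn$genome
  L <- g$length
  n <- scn$n_bins
  mids <- window_midpoints(n, L)

  base <- if (scn$mode == "log_phase") {
    t <- oric_arrival(scn$origins, scn$ter_sites, mids, L)
    u <- if (max(t) > 0) t / max(t) else t
    2^(scn$k_ct * (1 - u))
  } else rep(1, n)

  ampf <- rep(1, n)
  for (a in scn$amplifications) {
    inside <- mids >= a$start & mids < a$end
    ampf[inside] <- ampf[inside] * a$copy_factor
  }

  copies <- base * ampf
  for (o in scn$origins) {
    if (o$kind != "oriK") next
    p_cw <- arm_coverage_prob(o$position, "clockwise", o$extent_scale,
                              scn$ter_sites, scn$barriers, mids, L,
                              scn$extent_dist)
    p_ccw <- arm_coverage_prob(o$position, "counterclockwise", o$extent_scale,
                               scn$ter_sites, scn$barriers, mids, L,
                               scn$extent_dist)
    copies <- copies + o$firing_fraction * (p_cw + p_ccw - p_cw * p_ccw)
  }

  copies[masked_windows(g, n)] <- NA_real_
  new_truth(copies, scn)
}

new_truth <- function(copies, scn, physical = NULL) {
  structure(list(copies = copies,
                 genome = scn$genome, n_bins = scn$n_bins, mode = scn$mode,
                 origins = origins_df(scn$origins),
                 ter_sites = ter_df(scn$ter_sites),
                 amplifications = variants_df(scn$amplifications),
                 inversions = variants_df(scn$inversions),
                 barriers = scn$barriers,
                 depth = scn$depth, bias_sd = scn$bias_sd,
                 physical = physical),
            class = "truth_record")
}

origins_df <- function(origins) {
  if (!length(origins))
    return(data.frame(name = character(0), position = numeric(0),
                      kind = character(0), firing_fraction = numeric(0),
                      extent_scale = numeric(0)))
  do.call(rbind, lapply(origins, function(o)
    data.frame(name = o$name, position = o$position, kind = o$kind,
               firing_fraction = o$firing_fraction,
               extent_scale = o$extent_scale)))
}

ter_df <- function(ter_sites) {
  if (!length(ter_sites))
    return(data.frame(name = character(0), position = numeric(0),
                      blocks = character(0)))
  do.call(rbind, lapply(ter_sites, function(ts)
    data.frame(name = ts$name, position = ts$position, blocks = ts$blocks)))
}

variants_df <- function(v) {
  if (!length(v))
    return(data.frame(start = numeric(0), end = numeric(0),
                      copy_factor = numeric(0)))
  do.call(rbind, lapply(v, function(x)
    data.frame(start = x$start, end = x$end,
               copy_factor = if (!is.null(x$copy_factor)) x$copy_factor
                             else NA_real_)))
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf("<truth_record> %d windows, mode %s, %d origin(s), %d Ter site(s)\n",
              x$n_bins, x$mode, nrow(x$origins), nrow(x$ter_sites)))
  invisible(x)
}

# Build the physical-genome scenario implied by a single inversion: every
# annotated element inside the segment moves to its image coordinate and
# polar elements flip polarity.
physicalize_scenario <- function(scn) {
  inv <- scn$inversions[[1]]
  g <- scn$genome
  L <- g$length
  inside <- function(p) p >= inv$start & p <= inv$end

  origins <- lapply(scn$origins, function(o) {
    o$position <- map_through_inversion(o$position, inv, L); o
  })
  ters <- lapply(scn$ter_sites, function(ts) {
    if (inside(ts$position)) {
      ts$position <- map_through_inversion(ts$position, inv, L)
      ts$blocks <- if (ts$blocks == "clockwise") "counterclockwise"
                   else "clockwise"
    }
    ts
  })
  amps <- lapply(scn$amplifications, function(a) {
    se <- map_interval_through_inversion(a$start, a$end, inv, L)
    amplification(se[1], se[2], a$copy_factor)
  })
  barriers <- scn$barriers
  if (!is.null(barriers) && nrow(barriers)) {
    for (i in seq_len(nrow(barriers))) {
      if (inside(barriers$start[i])) {
        se <- map_interval_through_inversion(barriers$start[i],
                                             barriers$end[i], inv, L)
        barriers$start[i] <- se[1]; barriers$end[i] <- se[2]
        barriers$strand[i] <- if (barriers$strand[i] == "+") "-" else "+"
      }
    }
  }
  mi <- g$masked_intervals
  if (nrow(mi)) {
    mi <- t(apply(mi, 1, function(r)
      map_interval_through_inversion(r[1], r[2], inv, L)))
  }
  gphys <- genome_spec(name = g$name, length = L,
                       masked_intervals = mi, markers = g$markers)
  scenario(genome = gphys, origins = origins, ter_sites = ters,
           amplifications = amps, inversions = list(), mode = scn$mode,
           k_ct = scn$k_ct, barriers = barriers, n_bins = scn$n_bins,
           depth = scn$depth, bias_sd = scn$bias_sd,
           extent_dist = scn$extent_dist)
}

# Contiguous run of window indices (1-based) whose midpoints lie inside the
# inverted segment [start, end].
inversion_window_range <- function(inv, n_bins, L) {
  mids <- window_midpoints(n_bins, L)
  which(mids >= inv$start & mids <= inv$end)
}

#' Simulate a scenario that carries a chromosomal inversion
#'
#' Replication dynamics are computed on the physical (inverted) genome:
#' every annotated element inside the segment is moved to its image
#' coordinate and polar elements (Ter sites, barrier strands) flip polarity.
#' The resulting per-window expected copies are then re-indexed back to
#' reference coordinates by reversing the run of windows whose midpoints
#' fall inside the segment, so the returned truth record is a coordinate
#' permutation of the physical one — a fixed origin inside the segment
#' therefore reappears at its reference coordinate, not its physical one.
#'
#' @param scn A [scenario()] carrying exactly one inversion. Scenarios with
#'   no inversion fall through to [expected_copy_number()]; nested or
#'   multiple inversions are unsupported.
#' @return A `truth_record` indexed in reference coordinates; the physical
#'   scenario used is attached as `$physical`.
#' @export
simulate_with_inversion <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  if (!length(scn$inversions)) return(expected_copy_number(scn))
  if (length(scn$inversions) > 1)
    stop("multiple/nested inversions are unsupported")
  inv <- scn$inversions[[1]]
  phys <- physicalize_scenario(scn)
  tr_phys <- expected_copy_number(phys)
  idx <- inversion_window_range(inv, scn$n_bins, scn$genome$length)
  copies <- tr_phys$copies
  copies[idx] <- copies[rev(idx)]
  out <- new_truth(copies, scn,
                   physical = list(origins = origins_df(phys$origins),
                                   ter_sites = ter_df(phys$ter_sites)))
  out
}

#' Sample a noisy coverage track from a truth record
#'
#' Per unmasked window `w`, the read count is
#' `Poisson(depth * copies_w * bias_w / mean(copies))` with `bias_w`
#' lognormal(0, `bias_sd`); masked windows are `NA`. The same seed always
#' reproduces the same track.
#'
#' @param truth A `truth_record` from [expected_copy_number()] or
#'   [simulate_with_inversion()].
#' @param depth Expected reads per window (default: the scenario's).
#' @param bias_sd Lognormal bias sd (default: the scenario's).
#' @param seed Optional integer seed.
#' @param label Sample label attached to the track.
#' @return A [coverage_track()].
#' @export
sample_coverage <- function(truth, depth = truth$depth,
                            bias_sd = truth$bias_sd, seed = NULL,
                            label = "sim") {
  stopifnot(inherits(truth, "truth_record"))
  if (depth <= 0) stop("depth must be > 0")
  if (!is.null(seed)) set.seed(seed)
  copies <- truth$copies
  n <- length(copies)
  present <- !is.na(copies)
  lambda <- rep(NA_real_, n)
  bias <- stats::rlnorm(n, 0, bias_sd)
  lambda[present] <- depth * copies[present] * bias[present] /
    mean(copies[present])
  counts <- rep(NA_real_, n)
  counts[present] <- stats::rpois(sum(present), lambda[present])
  coverage_track(counts, truth$genome, truth$n_bins, label = label)
}

#' Monte-Carlo population oracle for expected copy number
#'
#' Samples an explicit population of chromosomes (origin firing, fork
#' extents, Ter truncation, Bernoulli barrier stalls) and averages window
#' coverage. This is the independent check on the closed-form
#' [expected_copy_number()]; it is deliberately a different code path and is
#' used by the test suite, not the pipeline.
#'
#' @param scn An inversion-free [scenario()].
#' @param n_chrom Number of chromosomes to sample.
#' @param seed Optional integer seed.
#' @return Numeric vector of estimated expected copies per window (`NA` in
#'   masked windows).
#' @export
mc_expected_copies <- function(scn, n_chrom = 1e5, seed = NULL) {
  stopifnot(inherits(scn, "scenario"))
  if (length(scn$inversions)) stop("oracle handles inversion-free scenarios")
  if (!is.null(seed)) set.seed(seed)
  g <- scn$genome
  L <- g$length
  n <- scn$n_bins
  binw <- L / n
  mids <- window_midpoints(n, L)

  base <- if (scn$mode == "log_phase") {
    t <- oric_arrival(scn$origins, scn$ter_sites, mids, L)
    u <- if (max(t) > 0) t / max(t) else t
    2^(scn$k_ct * (1 - u))
  } else rep(1, n)
  ampf <- rep(1, n)
  for (a in scn$amplifications) {
    inside <- mids >= a$start & mids < a$end
    ampf[inside] <- ampf[inside] * a$copy_factor
  }

  cover <- numeric(n)
  for (o in scn$origins) {
    if (o$kind != "oriK") next
    nf <- stats::rbinom(1, n_chrom, o$firing_fraction)
    if (!nf) next
    t_cw <- mc_arm_travel(o, "clockwise", nf, scn, L)
    t_ccw <- mc_arm_travel(o, "counterclockwise", nf, scn, L)
    a <- o$position - t_ccw
    b <- o$position + t_cw
    full <- (b - a) >= L
    cover <- cover + full_circle_count(sum(full), n)
    if (any(!full)) {
      w_lo <- ceiling(a[!full] / binw - 0.5)
      w_hi <- floor(b[!full] / binw - 0.5)
      ok <- w_hi >= w_lo
      cover <- cover + arc_counts(w_lo[ok] %% n, w_hi[ok] %% n, n)
    }
  }
  copies <- base * ampf + cover / n_chrom
  copies[masked_windows(g, n)] <- NA_real_
  copies
}

# Sampled travel distances for `nf` fork arms: exponential/uniform extent,
# Ter truncation, then sequential Bernoulli stalls at head-on barriers.
mc_arm_travel <- function(o, direction, nf, scn, L) {
  extent <- if (scn$extent_dist == "exponential")
    stats::rexp(nf, 1 / o$extent_scale)
  else stats::runif(nf, 0, 2 * o$extent_scale)
  bd <- blocking_distance(o$position, direction, scn$ter_sites, L)
  travel <- pmin(extent, bd, L)
  hb <- headon_barriers(o$position, direction, scn$barriers, L)
  if (nrow(hb)) {
    alive <- rep(TRUE, nf)
    for (i in seq_len(nrow(hb))) {
      attempting <- alive & travel > hb$dist[i]
      n_att <- sum(attempting)
      if (!n_att) next
      stalled <- stats::runif(n_att) > hb$transmission[i]
      idx <- which(attempting)[stalled]
      travel[idx] <- hb$dist[i]
      alive[idx] <- FALSE
    }
  }
  travel
}

full_circle_count <- function(k, n) rep(k, n)

# Count, per window index 0..n-1, how many circular index arcs [lo, hi]
# (0-based, possibly wrapped) cover it.
arc_counts <- function(lo, hi, n) {
  if (!length(lo)) return(numeric(n))
  wrapped <- lo > hi
  starts <- c(lo[!wrapped], lo[wrapped], rep(0, sum(wrapped)))
  ends <- c(hi[!wrapped], rep(n - 1, sum(wrapped)), hi[wrapped])
  delta <- numeric(n + 1)
  st <- tabulate(starts + 1, nbins = n + 1)
  en <- tabulate(ends + 2, nbins = n + 1)
  cumsum(st - en)[seq_len(n)]
}

#' Simulate qPCR Ct replicate tables for two loci
#'
#' The generative inverse of the 2^-dCt formula: each replicate tube yields
#' `Ct = c0(mass) - log2(copies) + Normal(0, ct_noise_sd)`, where
#' `c0(mass) = c0 - log2(mass / min(mass))` so that more input DNA lowers Ct
#' by one cycle per doubling. Replicate tubes for the two markers share
#' input masses, so the per-tube difference `CtA - CtB` cancels `c0`.
#'
#' @param copiesA,copiesB Relative copy numbers at the two loci; `> 0`.
#' @param ct_noise_sd Per-tube Ct noise standard deviation (cycles).
#' @param replicates Number of replicate pairs per input mass.
#' @param input_ng Input DNA masses (ng) cycled across tubes (default the
#'   two-tube 8/20 ng design).
#' @param c0 Baseline cycle threshold at the smallest input mass.
#' @param markerA,markerB Marker names used in the output table.
#' @param seed Optional integer seed.
#' @return A `ct_table` data frame with columns `marker`, `replicate`,
#'   `input_ng`, `ct`.
#' @export
simulate_ct <- function(copiesA, copiesB, ct_noise_sd = 0.1, replicates = 2,
                        input_ng = c(8, 20), c0 = 20,
                        markerA = "A", markerB = "B", seed = NULL) {
  if (copiesA <= 0 || copiesB <= 0) stop("copies must be > 0")
  if (!is.null(seed)) set.seed(seed)
  tubes <- expand.grid(replicate = seq_len(replicates), input_ng = input_ng)
  c0m <- c0 - log2(tubes$input_ng / min(input_ng))
  ctA <- c0m - log2(copiesA) + stats::rnorm(nrow(tubes), 0, ct_noise_sd)
  ctB <- c0m - log2(copiesB) + stats::rnorm(nrow(tubes), 0, ct_noise_sd)
  out <- rbind(
    data.frame(marker = markerA, replicate = tubes$replicate,
               input_ng = tubes$input_ng, ct = ctA),
    data.frame(marker = markerB, replicate = tubes$replicate,
               input_ng = tubes$input_ng, ct = ctB))
  class(out) <- c("ct_table", "data.frame")
  out
}
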