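#' Named scenario presets
#'
#' Ready-made scenarios reproducing the canonical profile shapes of
#' replication profiling on a W3110-like chromosome:
#'
#' * `wt_log` — exponential growth, oriC-only bidirectional gradient
#'   (`k_ct = 0.8`) with TerA/TerB trapping.
#' * `wt_runout` — wild-type after initiation arrest (spectinomycin
#'   run-out): replication completes, flat unit profile.
#' * `wt_stationary` — stationary phase, flat unit profile.
#' * `rnhA_runout` — RNase HI-deficient run-out: cSDR origins (oriKs) at
#'   1.52 Mb (dominant, inside the TerA/TerB trap) and 1.83 / 2.23 /
#'   2.54 Mb, with head-on rrn barrier intervals producing steps. Each
#'   non-Ter oriK is a two-component fork-extent mixture: a frequent
#'   short-range component (the sharp visible bump) and a rare processive
#'   one whose counterclockwise forks pass TerB and pile up at TerA.
#' * `topAtopB_runout` — topA topB null run-out: strong 1.52 Mb Ter-region
#'   origin, weak bumps at 1.88 / 2.23 / 2.56 Mb, and a 3x DNA
#'   amplification over 2.99-3.24 Mb.
#' * `rnhA_inv` — `rnhA_runout` on a chromosome carrying the 1.39-2.28 Mb
#'   inversion (simulate with [simulate_with_inversion()], which reports
#'   reference coordinates).
#'
#' Firing fractions and extent scales are free model parameters chosen once
#' to reproduce the published profile shapes (peak and bump heights in log2
#' units); they are not measured quantities.
#'
#' @param name Preset name; see [preset_names()].
#' @param depth Expected reads per window (default 100, a scaled-down stand
#'   -in for production depths of ~1000+ reads per window).
#' @param n_bins Number of windows (default 10000).
#' @return A [scenario()].
#' @export
preset_scenario <- function(name, depth = 100, n_bins = 10000) {
  g <- genome_spec()
  traps <- default_ter_sites()
  rrn <- rrn_barriers()
  switch(
    name,
    wt_log = scenario(
      genome = g,
      origins = list(origin_spec("oriC", 3925000, "oriC")),
      ter_sites = traps, barriers = rrn, mode = "log_phase",
      k_ct = 0.8, depth = depth, n_bins = n_bins),
    wt_runout = scenario(
      genome = g, origins = list(), ter_sites = traps, barriers = rrn,
      mode = "runout", depth = depth, n_bins = n_bins),
    wt_stationary = scenario(
      genome = g, origins = list(), ter_sites = traps,
      mode = "stationary", depth = depth, n_bins = n_bins),
    rnhA_runout = scenario(
      genome = g,
      origins = c(
        list(origin_spec("oriK_Ter", 1520000, "oriK",
                         firing_fraction = 0.80, extent_scale = 120000)),
        mixture_oriK("oriK_1.83", 1830000, 0.50),
        mixture_oriK("oriK_2.23", 2230000, 0.45),
        mixture_oriK("oriK_2.54", 2540000, 0.50)),
      ter_sites = traps, barriers = rrn, mode = "runout",
      depth = depth, n_bins = n_bins),
    topAtopB_runout = scenario(
      genome = g,
      origins = c(
        list(origin_spec("oriK_Ter", 1520000, "oriK",
                         firing_fraction = 0.90, extent_scale = 130000)),
        mixture_oriK("oriK_1.88", 1880000, 0.22, lr_fraction = 0.06),
        mixture_oriK("oriK_2.23", 2230000, 0.20, lr_fraction = 0.06),
        mixture_oriK("oriK_2.56", 2560000, 0.22, lr_fraction = 0.06)),
      ter_sites = traps, barriers = rrn,
      amplifications = list(amplification(2990000, 3240000, 3)),
      mode = "runout", depth = depth, n_bins = n_bins),
    rnhA_inv = {
      scn <- preset_scenario("rnhA_runout", depth = depth, n_bins = n_bins)
      scn$inversions <- list(inversion(1390000, 2280000))
      scn
    },
    stop(sprintf("unknown preset '%s'; see preset_names()", name)))
}

#' @rdname preset_scenario
#' @export
preset_names <- function() {
  c("wt_log", "wt_runout", "wt_stationary", "rnhA_runout",
    "topAtopB_runout", "rnhA_inv")
}

# A non-Ter oriK as a two-component fork-extent mixture: a frequent
# short-range component (the sharp visible bump) plus a rare processive
# component whose counterclockwise forks pass TerB and arrest at TerA,
# producing the TerA-biased asymmetry of the Ter region. Expressed as two
# origin_spec entries at the same coordinate.
mixture_oriK <- function(name, position, firing_fraction,
                         extent_scale = 45000, lr_fraction = 0.10,
                         lr_scale = 500000) {
  list(origin_spec(name, position, "oriK", firing_fraction, extent_scale),
       origin_spec(paste0(name, "_lr"), position, "oriK", lr_fraction,
                   lr_scale))
}

# rrn operon barrier annotations. Operons left of oriC (3.925 Mb) are
# transcribed counterclockwise (codirectional with the oriC fork of that
# replichore), hence "-" strand; rrnE right of oriC is "+". Head-on
# stalling therefore affects clockwise-moving cSDR forks at rrnG and the
# rrnD/B/A/C cluster. Transmission 0.7 per operon is a free parameter.
rrn_barriers <- function(transmission = 0.7) {
  data.frame(
    name = c("rrnG", "rrnD", "rrnB", "rrnA", "rrnC", "rrnE"),
    start = c(2725000, 3420000, 3540000, 3600000, 3684000, 4205000),
    end = c(2731000, 3426000, 3546000, 3606000, 3690000, 4211000),
    strand = c("-", "-", "-", "-", "-", "+"),
    transmission = transmission,
    stringsAsFactors = FALSE)
}
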