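# Shared fixtures: everything is generated in code at test time.

# Small maskless circular genome for unit tests
tiny_genome <- function(L = 1e6, markers = NULL) {
  genome_spec(name = "tiny", length = L, masked_intervals = NULL,
              markers = markers)
}

default_traps <- function() default_ter_sites()

# Single Ter-region oriK scenario used by the localization targets: the
# rnhA preset's dominant origin alone, between the polar traps.
ter_orik_scenario <- function(n_bins = 10000) {
  scn <- preset_scenario("rnhA_runout", n_bins = n_bins)
  scn$origins <- Filter(function(o) o$name == "oriK_Ter", scn$origins)
  scn
}

# Sample -> control-normalized -> loess pipeline on a truth record; the
# control is a wild-type run-out simulation with a seed derived from the
# sample seed.
sim_profile <- function(truth, seed, span = 0.03, depth = 100) {
  ctrl_truth <- expected_copy_number(
    preset_scenario("wt_runout", n_bins = truth$n_bins))
  smp <- sample_coverage(truth, depth = depth, seed = seed, label = "sample")
  ctl <- sample_coverage(ctrl_truth, depth = depth, seed = seed + 500000,
                         label = "control")
  prof <- normalize_to_control(smp, ctl)
  list(profile = prof, fit = loess_smooth(prof, span = span))
}

# Rotate every coordinate of a maskless scenario by `off` bp (a multiple of
# the bin width keeps windows aligned).
rotate_scenario <- function(scn, off) {
  L <- scn$genome$length
  scn$origins <- lapply(scn$origins, function(o) {
    o$position <- (o$position + off) %% L; o
  })
  scn$ter_sites <- lapply(scn$ter_sites, function(t) {
    t$position <- (t$position + off) %% L; t
  })
  scn$amplifications <- lapply(scn$amplifications, function(a) {
    amplification((a$start + off) %% L, (a$end - 1 + off) %% L + 1,
                  a$copy_factor)
  })
  if (!is.null(scn$barriers)) {
    scn$barriers$start <- (scn$barriers$start + off) %% L
    scn$barriers$end <- (scn$barriers$end - 1 + off) %% L + 1
  }
  scn
}
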