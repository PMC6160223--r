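---
title: "Replication profiling by marker frequency analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replication profiling by marker frequency analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfakit)
```

# The measurement

Marker frequency analysis (MFA) infers replication dynamics from relative
DNA abundance. In a replicating population, loci replicated early are
present in more copies than loci replicated late, so deep-sequencing
coverage along the chromosome traces fork progression: origins appear as
coverage maxima and termini as minima. In exponentially growing *E. coli*
the dominant signal is the bidirectional gradient descending from *oriC*.
After blocking new initiation (a "run-out", e.g. with spectinomycin),
ongoing rounds finish and the profile flattens — except where replication
keeps initiating independently of *oriC*. That residual, RNase
HI-sensitive synthesis (constitutive stable DNA replication, cSDR)
initiates at R-loop-dependent *oriK* sites, which surface in run-out
profiles as peaks, most prominently inside the terminus (Ter) region
between the polar TerA/TerB fork traps.

`mfakit` implements both halves of that experiment at desk scale: a
population-level simulator that produces binned coverage with the
statistical structure the analysis assumes, and the analysis pipeline
itself (binning, control normalization, circular loess smoothing, feature
detection, marker-ratio statistics). Every pipeline stage can therefore be
validated against known ground truth.

# The population replication model

A chromosome of length $L$ (default 4.64 Mb, W3110-like) is divided into
$n$ equal windows (default 10,000, ~464 bp). For each unmasked window
midpoint $x$ the expected relative copy number is

$$
c(x) \;=\; b(x)\,a(x) \;+\; \sum_{i \in \text{oriK}} f_i \,
P_i[x \text{ covered}],
$$

with the following components.

**Base level** $b(x)$. In `log_phase` mode,
$b(x) = 2^{k_{C/\tau}\,(1-u(x))}$ where $u(x) \in [0,1]$ is the normalized
fork-arrival time at $x$ from *oriC*, computed with constant fork speed and
polar Ter trapping (a blocked arm never delivers a fork beyond its trap;
unreachable windows inherit the latest arrival). $k_{C/\tau}$ — the
replication-period-to-doubling-time ratio — defaults to 0.8, giving the
~1.7-fold oriC-to-terminus gradient typical of moderate growth. In
`runout` and `stationary` modes $b(x) = 1$.

**oriK coverage** $P_i$. Each cSDR origin fires in a fraction $f_i$ of
chromosomes; a firing launches two divergent forks whose progressed
distances are independent draws from an exponential law with mean
`extent_scale` (a memoryless stand-in for an asynchronously initiating
population; a uniform law is available). An arm covers $x$ at signed
distance $d$ if its extent reaches $d$, no matching polar Ter site lies
strictly closer than $d$, and the fork survives a Bernoulli stall at every
head-on transcription barrier entered on the way (each barrier transmits
with probability `transmission`, producing the "step" signature at rrn
operons). The two arms combine as independent events.

**Structural variants.** Amplifications multiply the base level by
`copy_factor` inside their interval. Following the model contract, the
amplification factor scales only $b(x)$, not the oriK term; the shipped
scenarios never overlap an amplification with an origin, so the
distinction is immaterial there. Inversions are handled physically: every
element inside the segment is reflected to its image coordinate and polar
elements flip polarity; dynamics run on the physical genome, and the truth
track is re-indexed to reference coordinates by reversing the run of
windows whose midpoints fall in the segment. Window-run reversal is an
exact permutation (the copy-value multiset is conserved), at the price of
at most one window of coordinate offset when the reflection centre is not
bin-aligned — well inside the localization noise discussed below.

A deliberately independent Monte-Carlo implementation
(`mc_expected_copies()`) samples explicit chromosome populations with the
same semantics; the test suite requires the closed form and the sampler to
agree within 2% on every window for scenarios combining traps, barriers
and variants.

**Noise.** `sample_coverage()` draws window counts as
$\mathrm{Poisson}(\text{depth} \cdot c_w \beta_w / \bar c)$ with
$\beta_w \sim \text{lognormal}(0, \sigma_b)$, $\sigma_b = 0.05$ by
default — a mild multiplicative bias standing in for mappability/GC
effects. The default depth of 100 reads per window (~10^6 reads) is a
scaled-down stand-in for production runs of 11–16 million reads
(~1,100–1,600 reads per window); tests state depth explicitly.

# The analysis pipeline

**Binning.** Windows are equal-width, 0-based, half-open and circularly
adjacent. Read positions are counted per window; windows whose midpoint
falls in a masked interval (default: a ~35 kb gap at 0.33–0.36 Mb
emulating a strain deletion) carry `NA` throughout.

**Normalization.** Profiles are log2 ratios of library-size-scaled counts
against a run-out control:
$r_w = \log_2\frac{(s_w + q)/S}{(c_w + q)/C}$ with pseudocount $q = 0.5$
and a control floor of 5 reads (windows below it are excluded). The
arithmetic is the standard ratio-of-proportions choice: stable at low
counts, exactly zero when sample and control agree, and antisymmetric when
the floor is disabled. A control-free mode (`log2_track()`) median-centres
log2 scaled counts for log-phase absolute profiles.

**Circular loess.** Smoothing is locally weighted regression on the
circle: for each window (missing windows included, as interpolation
targets), the $\lceil \text{span} \cdot m \rceil$ nearest *present*
windows by circular distance form the neighborhood ($m$ = number of
present windows), tricube weights decay to zero at the neighborhood edge,
and a degree-1 polynomial in the signed circular offset is evaluated at
the window. Two bisquare robustness iterations are applied by default.
Neighborhoods wrap, so there is no edge artifact at coordinate 0. The
implementation is closed-form weighted least squares (validated against
`stats::loess` away from its boundaries and against a brute-force
per-window WLS oracle, `loess_fit_at()`); the fit is computed on log2
ratios, not on counts — the natural scale for ratio profiles. The display
span default is 0.1, the value conventionally used for these profiles.

**Display span versus detection span.** A span of 0.1 over 10,000 windows
is a tricube kernel of half-width ~232 kb. That is wider than half the
spacing of the known oriK sites (310–400 kb apart), so *no* parameter
choice can make four such origins survive span-0.1 smoothing as separate
prominent maxima — neighboring peaks merge into shoulders. The pipeline
therefore distinguishes the display curve (span 0.1, written to profile
tables) from the detection curve used by peak calling (span 0.03, kernel
half-width ~70 kb: below half the origin spacing, above the bump width).
Both are exposed as flags.

# Feature detection

**Peaks.** `call_peaks()` finds circular local maxima (plateaus report
their leftmost window) and scores topographic prominence by walking both
ways to the nearest higher terrain; the global maximum keys off the global
minimum. Calls below `min_prominence` (default 0.15 log2) are dropped;
calls at twice the threshold are classified `"peak"`, others `"bump"`.
Ties rank by leftmost coordinate. No significance model is attached — the
threshold is an exposed flag, mirroring how such profiles are read.

**Amplification segments.** `segment_amplification()` thresholds the
profile at `threshold_log2` (default 0.5, ~1.4-fold) above the genome
median, keeps circular runs of at least `min_length_bp` (default 50 kb),
then refines each boundary by a local two-segment mean changepoint fit
(radius 30 windows). Edges never cross masked windows, so calls cannot
span masked intervals. The copy factor is $2^{\Delta}$ with $\Delta$ the
median elevation of the segment over its flanks. Defaults make a 3-fold,
250 kb amplification unambiguous while the log-phase oriC gradient (range
< 0.5 log2 at $k_{C/\tau} = 0.8$) is never called. Tall origin peaks can
exceed the threshold over >50 kb on noise-free curves; segmentation is
therefore run on the (noisy or lightly smoothed) normalized profile, where
the threshold crossing is plateau-selective, and callers should treat
segment/peak coincidence with judgment.

**Ter asymmetry.** For each polar trap, `ter_asymmetry()` subtracts the
mean fitted level on the far side from the side forks arrive from
(the blocking side), over a 100 kb flank: a pile-up against the trap gives
a positive drop. In the cSDR presets the drop at TerA exceeds the drop at
TerB because counterclockwise forks from the non-Ter oriKs pass through
TerB (wrong polarity) and arrest at TerA — passing elevates both flanks of
TerB equally while arrest creates a step at TerA.

**Steps.** `step_score()` scores candidate intervals (rrn annotations) as
the mean level beyond the interval minus the level before it, walked in
the direction a head-on fork travels (opposite the annotated strand);
stalls make the score negative.

# Marker ratios

`ngs_marker_ratio()` averages library-scaled counts in a 5 kb window
centred on each locus (a qPCR assay interrogates a single amplicon; the
window stabilizes the coverage estimate) and propagates Poisson error.
`delta_ct_ratio()` implements relative quantification: replicate tubes are
paired by replicate id and input mass (the two-tube 8/20 ng design),
$2^{-\Delta C_t}$ is computed per pair, and the mean and *sample* standard
deviation are taken over the per-pair ratios — not from averaged $C_t$
values — with the pair count recorded. Adding any constant to all $C_t$
values cancels. `simulate_ct()` is the generative inverse
($C_t = c_0(\text{mass}) - \log_2 \text{copies} + \varepsilon$), and
`compare_methods()` reports the log2 discordance between the sequencing
and qPCR estimates of the same ratio.

# The scenario presets and their calibration

`preset_scenario()` ships `wt_log`, `wt_runout`, `wt_stationary`,
`rnhA_runout`, `topAtopB_runout` and `rnhA_inv` (the cSDR preset on a
chromosome carrying the 1.39–2.28 Mb inversion). Published coordinates
(origins at 1.52/1.83/2.23/2.54 Mb or 1.52/1.88/2.23/2.56 Mb, the
amplification at 2.99–3.24 Mb, TerA/TerB at 1.34/1.68 Mb, markers ydcM/
lepA/qseC/parC/parE) are fixed inputs. Firing fractions and extent scales
are *free* parameters — no quantitative firing rates exist for oriK sites
— chosen once, from noise-free truth curves only, so that the
post-smoothing profile reproduces the published curve shapes: a dominant
~0.8 log2 Ter-region peak declining into trap plateaus, sharp ~0.3 log2
bumps at the outer origins, TerA-biased asymmetry. Two consequences of
that calibration are worth stating. First, each outer oriK is a
two-component extent mixture (frequent short-range forks, mean 45 kb,
giving the visible bump; rare processive forks, mean 500 kb, supplying the
trans-TerB flux that arrests at TerA): a single exponential component
cannot produce both the sharp bump and the trap asymmetry. Second, the rrn
barrier at 4.21 Mb sits clockwise of *oriC*, where the preset geometry
gives cSDR forks no head-on passage, so the simulator does not reproduce
the step reported there; the steps at 2.73 Mb and the 3.42–3.69 Mb
cluster are reproduced.

# What a green test does and does not establish

The generator emulates binned coverage with Poisson counting noise, mild
lognormal bias, masked intervals, trap plateaus, barrier steps and
structural variants. It does not emulate GC/mappability structure beyond
the lognormal bias, duplicate or multi-mapping reads (mapping-quality
filtering belongs upstream; the BED adapter's `min_mapq` merely mimics its
interface), replication-transcription interactions beyond the Bernoulli
stall, cell-cycle structure (the firing-fraction/extent mixture is a
snapshot model), or strain-to-strain coordinate drift. Recovery of a
feature from simulated data therefore establishes that the pipeline's
arithmetic and geometry are right at the stated depth — not that real
libraries are free of artifacts the generator does not model.

# Numerical choices and known limitations

* **Localization precision.** At 100 reads per window the per-window log2
  noise after control normalization is ~0.2, and the Fisher information a
  ~100 kb exponential peak carries about its own location caps argmax-type
  estimators at roughly 4–8 windows of standard error (measured: sd ~5–8
  windows across seeds). Precision scales as depth$^{-1/2}$: at
  production depth (~1,500 reads/window) the same estimator localizes to
  ~1–2 windows, which is why peak coordinates are printed at two decimals
  of a megabase. Tolerances of ±2 windows at depth 100 — asserted as
  stated by two acceptance checks — sit below this limit and are expected
  to fail; they are retained, red, as a record of the depth/tolerance
  mismatch rather than loosened.
* **Ter polarity convention.** `blocks` names the arrested fork direction
  directly (TerA arrests counterclockwise forks, TerB clockwise, matching
  the arrest behaviour of forks confined between them); either convention
  from the literature can be expressed explicitly.
* **Ties and degenerate inputs.** Peak ties rank leftmost; constant
  profiles yield no peaks; all-missing fits yield empty call sets;
  zero-coverage marker windows are errors, not silent NaNs; robustness
  iterations stop when the residual scale collapses to zero, and
  neighborhoods whose robustness weights vanish fall back to plain
  tricube.
* **Masked gap placement.** The default masked interval sits at
  0.33–0.36 Mb (the deletion gap visible "around 0.3" on published
  profiles); masked windows are excluded as predictors everywhere and
  interpolated only as smoothing targets.
* **Seeds.** All stochastic stages take explicit seeds; identical
  configuration and seed reproduce outputs byte-identically, and every
  output file carries a provenance header (tool, version, config hash,
  seed).
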