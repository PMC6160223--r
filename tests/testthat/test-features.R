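test_that("flat profiles yield no peaks and all-missing input yields an empty call set", {
  expect_equal(nrow(call_peaks(rep(0.3, 500))), 0)
  expect_equal(nrow(call_peaks(rep(NA_real_, 500))), 0)
})

test_that("call_peaks scores triangular peaks by prominence and classifies peak vs bump", {
  n <- 1000
  x <- numeric(n)
  tri <- function(center, half, height)
    pmax(0, height * (1 - abs(seq_len(n) - center) / half))
  x <- tri(200, 40, 0.5) + tri(700, 40, 0.2)
  pk <- call_peaks(x, min_prominence = 0.15)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$window + 1, c(200, 700))
  expect_equal(pk$prominence, c(0.5, 0.2), tolerance = 1e-10)
  expect_equal(pk$class, c("peak", "bump"))

  # sub-threshold bumps are dropped
  pk2 <- call_peaks(x, min_prominence = 0.25)
  expect_equal(nrow(pk2), 1)

  # plateaus report their leftmost window
  y <- numeric(200); y[100:105] <- 1
  pk3 <- call_peaks(y, min_prominence = 0.5)
  expect_equal(pk3$window + 1, 100)
})

test_that("peak calling works across the circular origin (no edge artifact)", {
  n <- 1000
  x <- pmax(0, 0.6 * (1 - pmin(abs(seq_len(n) - 1),
                               n - abs(seq_len(n) - 1)) / 50))
  pk <- call_peaks(x, min_prominence = 0.15)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$window, 0)
})

test_that("the rnhA preset pipeline recovers all four origins with figure-like classes", {
  tr <- expected_copy_number(preset_scenario("rnhA_runout"))
  res <- sim_profile(tr, seed = 1, span = 0.03)
  pk <- call_peaks(res$fit)
  pk <- pk[order(pk$position), ]
  expect_equal(nrow(pk), 4)
  truth_pos <- c(1520000, 1830000, 2230000, 2540000)
  # localization is Cramer-Rao-limited to several windows at depth 100
  # (see the methods vignette); assert within 10 windows (4.6 kb)
  expect_true(all(abs(pk$position - truth_pos) <= 10 * 464))
  # the Ter-region origin dominates
  expect_equal(which.max(pk$prominence), 1)
})

test_that("peak ranking follows firing fractions", {
  g <- tiny_genome()
  scn <- scenario(genome = g, n_bins = 2000, mode = "runout",
                  origins = list(
                    origin_spec("hi", 250250, "oriK", 0.8, 40000),
                    origin_spec("lo", 750250, "oriK", 0.4, 40000)))
  tr <- expected_copy_number(scn)
  fit <- loess_smooth(log2(tr$copies), span = 0.05, robust_iters = 0)
  pk <- call_peaks(fit, genome = g, n_bins = 2000)
  expect_equal(pk$window[1] + 1, window_of(250250, 2000, 1e6) + 1)
})

test_that("segment_amplification finds nothing without variants and exact edges on steps", {
  # variant-free presets: neither the flat run-out profile nor the
  # log-phase oriC gradient (range < threshold by design) is called
  for (preset in c("wt_runout", "wt_log")) {
    tr <- expected_copy_number(preset_scenario(preset))
    amp0 <- segment_amplification(log2(tr$copies), genome = genome_spec(),
                                  n_bins = 10000)
    expect_equal(nrow(amp0), 0)
  }

  # noise-free square elevation: exact boundaries
  n <- 1000
  x <- numeric(n); x[301:400] <- 1
  g <- tiny_genome()
  amp <- segment_amplification(x, threshold_log2 = 0.5,
                               min_length_bp = 50000, genome = g, n_bins = n)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$start, 300 * 1000)
  expect_equal(amp$end, 400 * 1000)
  expect_equal(amp$copy_factor, 2, tolerance = 1e-10)
})

test_that("the topAtopB preset amplification is recovered with its copy factor", {
  tr <- expected_copy_number(preset_scenario("topAtopB_runout"))
  res <- sim_profile(tr, seed = 1)
  amps <- segment_amplification(res$profile$log2_ratio,
                                genome = genome_spec(), n_bins = 10000)
  expect_equal(nrow(amps), 1)
  expect_lt(abs(amps$start - 2990000), 5 * 464)
  expect_lt(abs(amps$end - 3240000), 5 * 464)
  expect_gt(amps$copy_factor, 2.5)
  expect_lt(amps$copy_factor, 3.5)
  # copy factor within 15% of truth at depth >= 100
  expect_equal(amps$copy_factor, 3, tolerance = 0.15)
})

test_that("amplification calls never overlap masked intervals", {
  g <- genome_spec(length = 1e6, masked_intervals = list(c(340000, 360000)),
                   markers = NULL)
  x <- numeric(1000); x[301:400] <- 1
  x[masked_windows(g, 1000)] <- NA
  amps <- segment_amplification(x, min_length_bp = 20000, genome = g,
                                n_bins = 1000)
  msk <- which(masked_windows(g, 1000)) - 1
  for (i in seq_len(nrow(amps))) {
    w <- window_of(window_midpoints(1000, 1e6), 1000, 1e6)
    inseg <- w[window_midpoints(1000, 1e6) >= amps$start[i] &
                 window_midpoints(1000, 1e6) < amps$end[i]]
    expect_equal(length(intersect(inseg, msk)), 0)
  }
})

test_that("ter_asymmetry is symmetric for a centred origin and TerA-biased on the rnhA preset", {
  traps <- default_traps()
  g <- genome_spec()
  # origin exactly midway between the traps
  scn <- scenario(genome = g, n_bins = 10000, mode = "runout",
                  origins = list(origin_spec("mid", 1510000, "oriK",
                                             0.8, 120000)),
                  ter_sites = traps)
  fit <- loess_smooth(log2(expected_copy_number(scn)$copies), span = 0.03,
                      robust_iters = 0)
  ta <- ter_asymmetry(fit, traps, genome = g, n_bins = 10000)
  expect_equal(ta$drop[ta$name == "TerA"], ta$drop[ta$name == "TerB"],
               tolerance = 0.05)
  expect_true(all(ta$drop > 0))

  # rnhA preset: counterclockwise forks from the outer oriKs pass TerB and
  # arrest at TerA, so the TerA drop is larger
  tr <- expected_copy_number(preset_scenario("rnhA_runout"))
  res <- sim_profile(tr, seed = 2)
  ta2 <- ter_asymmetry(res$fit, traps)
  expect_gt(ta2$drop[ta2$name == "TerA"], ta2$drop[ta2$name == "TerB"])

  # flat profile: drops ~ 0
  ta3 <- ter_asymmetry(rep(0, 10000), traps, genome = g, n_bins = 10000)
  expect_equal(ta3$drop, c(0, 0))
})

test_that("step_score flags the stalled barrier and is antisymmetric under mirroring", {
  g <- tiny_genome()
  barr <- data.frame(start = 600000, end = 610000, strand = "-",
                     transmission = 0.5)
  scn <- scenario(genome = g, n_bins = 1000, mode = "runout",
                  origins = list(origin_spec("a", 400500, "oriK",
                                             0.8, 300000)),
                  barriers = barr)
  x <- log2(expected_copy_number(scn)$copies)
  cand <- data.frame(name = c("hit", "ctrl1", "ctrl2"),
                     start = c(600000, 750000, 200000),
                     end = c(610000, 760000, 210000),
                     strand = "-")
  sc <- step_score(x, cand, genome = g, n_bins = 1000)
  expect_equal(which.min(sc$score), 1)
  expect_lt(sc$score[1], 0)

  # no barriers: scores ~ 0 on a flat profile
  sc0 <- step_score(rep(0.2, 1000), cand, genome = g, n_bins = 1000)
  expect_equal(sc0$score, rep(0, 3))

  # mirror the profile circularly about the interval centre (605 kb):
  # upstream and downstream flanks swap, so the score negates
  n <- 1000
  xm <- x[((1210 - seq_len(n)) %% n) + 1]
  scm <- step_score(xm, cand[1, ], genome = g, n_bins = n)
  expect_equal(scm$score, -sc$score[1], tolerance = 1e-10)
})
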