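test_that("bin_reads counts positions per window and drops masked/malformed reads", {
  g <- tiny_genome(L = 4640000)
  tr <- bin_reads(c(0, 1, 2), g, n_bins = 10000)
  expect_equal(tr$counts[1], 3)
  expect_equal(sum(tr$counts), 3)
  expect_equal(tr$total_reads, 3)

  tr0 <- bin_reads(numeric(0), g, n_bins = 100)
  expect_equal(sum(tr0$counts), 0)

  expect_warning(trb <- bin_reads(c(10, -5, NA, 20), g, n_bins = 100),
                 "2 malformed")
  expect_equal(attr(trb, "n_skipped"), 2)
  expect_equal(trb$total_reads, 2)

  gm <- genome_spec(length = 1000, masked_intervals = list(c(0, 100)),
                    markers = NULL)
  trm <- bin_reads(c(50, 500), gm, n_bins = 10)
  expect_true(is.na(trm$counts[1]))
  expect_equal(attr(trm, "n_masked_dropped"), 1)
  expect_equal(trm$total_reads, 1)
})

test_that("uniform random reads bin uniformly (chi-square GOF)", {
  g <- tiny_genome(L = 4640000)
  set.seed(123)
  pos <- runif(1e5, 0, g$length)
  tr <- bin_reads(pos, g, n_bins = 200)
  p <- suppressWarnings(stats::chisq.test(tr$counts)$p.value)
  expect_gt(p, 0.001)
})

test_that("normalization is zero for identical tracks and matches the direct formula", {
  g <- tiny_genome(L = 1e5)
  set.seed(21)
  cnt <- rpois(100, 50)
  a <- coverage_track(cnt, g, 100, label = "a")
  prof <- normalize_to_control(a, a)
  expect_equal(prof$log2_ratio, rep(0, 100))

  # independent window-by-window formula evaluation on random tracks
  cb <- rpois(100, 80)
  b <- coverage_track(cb, g, 100, label = "b")
  prof2 <- normalize_to_control(a, b, pseudocount = 0.5, control_floor = 5)
  S <- sum(cnt); C <- sum(cb)
  manual <- log2(((cnt + 0.5) / S) / ((cb + 0.5) / C))
  manual[cb < 5] <- NA
  expect_equal(prof2$log2_ratio, manual)

  # doubling example with symmetric handling (pseudocount 0)
  s <- c(20, 10, 10); c <- c(10, 10, 20)
  ts <- coverage_track(s, tiny_genome(L = 300), 3)
  tc <- coverage_track(c, tiny_genome(L = 300), 3)
  p3 <- normalize_to_control(ts, tc, pseudocount = 0, control_floor = 0)
  expect_equal(p3$log2_ratio[1], 1)

  expect_error(normalize_to_control(a, coverage_track(rpois(50, 5),
                                                      g, 50)),
               "mismatch")
})

test_that("normalization is antisymmetric when handling is symmetric", {
  g <- tiny_genome(L = 1e5)
  set.seed(31)
  a <- coverage_track(rpois(100, 60) + 6, g, 100)
  b <- coverage_track(rpois(100, 40) + 6, g, 100)
  ab <- normalize_to_control(a, b, control_floor = 0)
  ba <- normalize_to_control(b, a, control_floor = 0)
  expect_equal(ab$log2_ratio, -ba$log2_ratio)
})

test_that("loess reproduces constants exactly and is exact on locally linear data", {
  expect_equal(loess_smooth(rep(2.5, 400), span = 0.1)$fitted, rep(2.5, 400))

  # circular tent: windows whose whole neighborhood lies on one flank are
  # fit exactly by the degree-1 local polynomial
  n <- 200
  x <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1))  # tent peaked at window 101
  fit <- loess_smooth(as.numeric(x), span = 0.1)   # k = 20 neighbors
  flank <- 30:70
  expect_equal(fit$fitted[flank], as.numeric(x[flank]), tolerance = 1e-10)
})

test_that("loess equals a brute-force tricube WLS oracle at random windows", {
  set.seed(5)
  n <- 500
  y <- sin(2 * pi * (1:n) / n) + rnorm(n, 0, 0.3)
  y[sample.int(n, 25)] <- NA   # missing windows interpolated as targets
  fit <- loess_smooth(y, span = 0.1, robust_iters = 0)
  for (w in sample.int(n, 12)) {
    expect_equal(fit$fitted[w], loess_fit_at(y, w, span = 0.1),
                 tolerance = 1e-8)
  }
})

test_that("loess is shift-equivariant and circular", {
  set.seed(6)
  n <- 300
  y <- cos(2 * pi * (1:n) / n) + rnorm(n, 0, 0.2)
  f1 <- loess_smooth(y, span = 0.15)
  f2 <- loess_smooth(y + 3, span = 0.15)
  expect_equal(f2$fitted, f1$fitted + 3)

  k <- 77
  yr <- y[((seq_len(n) - 1 + k) %% n) + 1]
  fr <- loess_smooth(yr, span = 0.15)
  expect_equal(fr$fitted, f1$fitted[((seq_len(n) - 1 + k) %% n) + 1],
               tolerance = 1e-10)
})

test_that("loess rejects degenerate spans and inputs", {
  expect_error(loess_smooth(rnorm(100), span = 0), "span")
  expect_error(loess_smooth(rnorm(100), span = 0.01), "span too small")
  expect_error(loess_smooth(c(1, 2, NA), span = 1), "too few")
})

test_that("end-to-end run-out wild type is flat after smoothing", {
  tr <- expected_copy_number(preset_scenario("wt_runout"))
  res <- sim_profile(tr, seed = 17, span = 0.1)
  expect_lt(max(abs(res$fit$fitted)), 0.1)
})

test_that("log2_track is median-centred and respects missing windows", {
  g <- genome_spec(length = 1000, masked_intervals = list(c(0, 100)),
                   markers = NULL)
  cnt <- c(NA, rpois(9, 100))
  tr <- coverage_track(cnt, g, 10)
  p <- log2_track(tr)
  expect_true(is.na(p$log2_ratio[1]))
  expect_equal(stats::median(p$log2_ratio, na.rm = TRUE), 0)
})
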