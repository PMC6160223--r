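test_that("fork_stop truncates at the first matching polar trap only", {
  traps <- default_traps()
  L <- 4640000
  # counterclockwise fork from the Ter-region origin arrests at TerA
  expect_equal(fork_stop(1520000, "counterclockwise", 1e6, traps, L),
               1340000)
  # counterclockwise fork from 1.83 Mb passes TerB and arrests at TerA
  expect_equal(fork_stop(1830000, "counterclockwise", 1e6, traps, L),
               1340000)
  expect_equal(fork_stop(100000, "clockwise", 50000, list(), L), 150000)
  # opposite-polarity fork passes through
  expect_equal(fork_stop(1520000, "clockwise", 1e6, traps, L),
               1680000)  # TerB blocks clockwise
  expect_error(fork_stop(0, "clockwise", -1, list(), L), ">= 0")
})

test_that("run-out with no oriK gives an exactly flat truth", {
  scn <- preset_scenario("wt_runout")
  tr <- expected_copy_number(scn)
  expect_s3_class(tr, "truth_record")
  expect_equal(max(abs(log2(tr$copies)), na.rm = TRUE), 0)
  expect_true(all(is.na(tr$copies[masked_windows(scn$genome, scn$n_bins)])))
})

test_that("log-phase oriC gradient follows the 2^(k_ct (1 - u)) closed form", {
  # symmetric circle, no traps: oriC-to-antipode ratio is exactly 2^k_ct
  g <- tiny_genome(L = 1e6)
  scn <- scenario(genome = g,
                  origins = list(origin_spec("oriC", 500500, "oriC")),
                  mode = "log_phase", k_ct = 1, n_bins = 1000)
  tr <- expected_copy_number(scn)
  w_ori <- window_of(500500, 1000, 1e6) + 1
  w_anti <- window_of(500, 1000, 1e6) + 1
  expect_equal(tr$copies[w_ori] / tr$copies[w_anti], 2)
  # closed form at arbitrary windows
  mids <- window_midpoints(1000, 1e6)
  d <- circular_distance(rep(500500, 1000), mids, "shortest", L = 1e6)
  expect_equal(tr$copies, 2^(1 - d / max(d)))
})

test_that("a trapped single oriK peaks at its origin and plateaus beyond the traps", {
  scn <- ter_orik_scenario(n_bins = 2000)
  tr <- expected_copy_number(scn)
  w_pk <- which.max(tr$copies)
  expect_equal(w_pk, window_of(1520000, 2000, 4640000) + 1)
  mids <- window_midpoints(2000, 4640000)
  outside <- mids < 1330000 | mids > 1690000
  expect_equal(tr$copies[outside & !is.na(tr$copies)],
               rep(1, sum(outside & !is.na(tr$copies))))
  # monotone non-increasing with distance from the origin inside the trap
  inside_r <- which(mids > 1520000 & mids < 1680000)
  expect_true(all(diff(tr$copies[inside_r]) <= 1e-12))
  inside_l <- which(mids > 1340000 & mids < 1520000)
  expect_true(all(diff(tr$copies[inside_l]) >= -1e-12))
})

test_that("closed-form expected copies match the Monte-Carlo population oracle", {
  g <- genome_spec()
  scn <- scenario(
    genome = g,
    origins = list(origin_spec("a", 1520000, "oriK", 0.6, 200000),
                   origin_spec("b", 2540000, "oriK", 0.3, 120000)),
    ter_sites = default_traps(), barriers = mfakit:::rrn_barriers(),
    amplifications = list(amplification(2990000, 3240000, 3)),
    mode = "runout", n_bins = 2000)
  det <- expected_copy_number(scn)
  mc <- mc_expected_copies(scn, n_chrom = 2e5, seed = 42)
  rel <- abs(mc - det$copies) / det$copies
  expect_lt(max(rel, na.rm = TRUE), 0.02)
})

test_that("uniform fork-extent law also matches the oracle", {
  scn <- scenario(
    genome = tiny_genome(), n_bins = 500,
    origins = list(origin_spec("a", 300000, "oriK", 0.5, 100000)),
    ter_sites = list(ter_site("T", 150000, "counterclockwise")),
    mode = "runout", extent_dist = "uniform")
  det <- expected_copy_number(scn)
  mc <- mc_expected_copies(scn, n_chrom = 2e5, seed = 9)
  expect_lt(max(abs(mc - det$copies) / det$copies), 0.02)
})

test_that("simulate_with_inversion moves elements, flips polarity, and reports reference coordinates", {
  scn <- ter_orik_scenario(n_bins = 10000)
  scn$inversions <- list(inversion(1390000, 2280000))
  tr <- simulate_with_inversion(scn)
  # physical origin relocated by reflection, TerB flipped, TerA untouched
  expect_equal(tr$physical$origins$position, 2150000)
  phys_ter <- tr$physical$ter_sites
  expect_equal(phys_ter$position[phys_ter$name == "TerB"], 1990000)
  expect_equal(phys_ter$blocks[phys_ter$name == "TerB"], "counterclockwise")
  expect_equal(phys_ter$position[phys_ter$name == "TerA"], 1340000)
  # reference-coordinate peak is back at the origin's reference window
  # (to within one window: the reflection centre of this inversion is not
  # bin-aligned, and the permutation re-indexing absorbs that sub-bin
  # offset into at most one window)
  expect_lte(abs(which.max(tr$copies) -
                   (window_of(1520000, 10000, 4640000) + 1)), 1)
  # no inversion: identical to the plain computation
  scn0 <- ter_orik_scenario(n_bins = 2000)
  expect_equal(simulate_with_inversion(scn0)$copies,
               expected_copy_number(scn0)$copies)
  scn2 <- scn
  scn2$inversions <- list(inversion(1390000, 2280000),
                          inversion(3000000, 3100000))
  expect_error(simulate_with_inversion(scn2), "unsupported")
})

test_that("inversion conserves the multiset of expected copies", {
  scn <- preset_scenario("rnhA_inv")
  tr_ref <- simulate_with_inversion(scn)
  tr_phys <- expected_copy_number(mfakit:::physicalize_scenario(scn))
  expect_equal(sort(tr_ref$copies), sort(tr_phys$copies))
})

test_that("truth is equivariant under rotation of all scenario coordinates", {
  scn <- scenario(
    genome = tiny_genome(), n_bins = 1000,
    origins = list(origin_spec("a", 300500, "oriK", 0.6, 80000)),
    ter_sites = list(ter_site("T", 150500, "counterclockwise")),
    barriers = data.frame(start = 400000, end = 410000, strand = "-",
                          transmission = 0.5),
    mode = "runout")
  off <- 250000  # 250 windows of 1000 bp
  tr <- expected_copy_number(scn)
  tr_rot <- expected_copy_number(rotate_scenario(scn, off))
  k <- off / 1000
  expect_equal(tr_rot$copies[((seq_len(1000) - 1 + k) %% 1000) + 1],
               tr$copies)
})

test_that("sample_coverage has Poisson moments, scales with copies, and is seed-reproducible", {
  scn <- preset_scenario("wt_runout", n_bins = 10000)
  tr <- expected_copy_number(scn)
  trk <- sample_coverage(tr, depth = 100, bias_sd = 0, seed = 5)
  cnt <- trk$counts[!is.na(trk$counts)]
  n <- length(cnt)
  expect_equal(mean(cnt), 100, tolerance = 3 / sqrt(n) / 10)    # 3 se of mean
  expect_equal(stats::var(cnt), 100, tolerance = 0.05)
  expect_equal(sum(cnt), 100 * n, tolerance = 3 * sqrt(100 * n) / (100 * n))
  expect_true(all(is.na(trk$counts[masked_windows(scn$genome, 10000)])))

  trk2 <- sample_coverage(tr, depth = 100, bias_sd = 0, seed = 5)
  expect_identical(trk$counts, trk2$counts)

  # amplification recovery in the sampled track
  scn3 <- scenario(genome = tiny_genome(), n_bins = 1000,
                   amplifications = list(amplification(200000, 400000, 3)),
                   mode = "runout")
  tr3 <- expected_copy_number(scn3)
  trk3 <- sample_coverage(tr3, depth = 500, bias_sd = 0, seed = 6)
  mids <- window_midpoints(1000, 1e6)
  inside <- mids >= 200000 & mids < 400000
  expect_equal(mean(trk3$counts[inside]) / mean(trk3$counts[!inside]), 3,
               tolerance = 0.05)
})

test_that("simulate_ct inverts the 2^-dCt formula", {
  ct <- simulate_ct(2, 2, ct_noise_sd = 0, replicates = 2)
  expect_equal(ct$ct[ct$marker == "A"], ct$ct[ct$marker == "B"])
  ct2 <- simulate_ct(2, 1, ct_noise_sd = 0, replicates = 2)
  expect_equal(ct2$ct[ct2$marker == "A"], ct2$ct[ct2$marker == "B"] - 1)
  # more template lowers Ct one cycle per doubling
  a8 <- ct2$ct[ct2$marker == "A" & ct2$input_ng == 8]
  a20 <- ct2$ct[ct2$marker == "A" & ct2$input_ng == 20]
  expect_equal(unique(a8) - unique(a20), log2(20 / 8))
  # noisy replicates still recover the ratio downstream within 10%
  set.seed(3)
  ratios <- replicate(30, {
    tab <- simulate_ct(3, 1, ct_noise_sd = 0.1, replicates = 3)
    delta_ct_ratio(tab, "A", "B")$ratio
  })
  expect_lt(unname(stats::quantile(abs(ratios / 3 - 1), 0.9)), 0.10)
  expect_equal(mean(ratios), 3, tolerance = 0.05)
})
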