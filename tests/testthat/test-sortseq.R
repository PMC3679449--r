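test_that("ratio track is depth-free and filters thin bins", {
  lay <- one_chrom()
  S <- read_counts(lay, 50, "S")
  G2 <- read_counts(lay, 200, "G2")
  r <- compute_ratio(S, G2, min_count = 10)
  expect_true(all(r$value == 1))  # equal after total normalization
  G2$value[5] <- 0
  r <- compute_ratio(S, G2, min_count = 10)
  expect_true(is.na(r$value[5]))
  expect_false(anyNA(r$value[-5]))
  expect_error(compute_ratio(S, read_counts(one_chrom(1e5), 10, "G2")),
               "grid")
})

test_that("two-level profile gives a ratio of bin-averages near 2", {
  # left half r = 2, right half r = 1, high depth: the S/G2 ratio between
  # halves approaches the Poisson expectation 2
  lay <- one_chrom(len = 4e5, cen = 2e5)
  prof <- bin_track(lay, 1000, subclass = "copy_number_profile")
  left <- track_centers(prof) < 2e5
  prof$value <- ifelse(left, 2, 1)
  cts <- simulate_sortseq_counts(prof, depth = 2000, seed = 12)
  r <- compute_ratio(cts$S, cts$G2)
  expect_equal(mean(r$value[left]) / mean(r$value[!left]), 2,
               tolerance = 0.02)
})

test_that("normalization maps onto [1, 2] and inverts an affine distortion", {
  lay <- genome_layout("chrA", 1e6, 5e5)
  tr <- bin_track(lay, 1000, subclass = "ratio_track")
  truth <- seq(1, 2, length.out = nrow(tr))
  tr$value <- 0.4 * truth + 3  # arbitrary affine scale
  prof <- normalize_profile(tr, anchor_window = NULL)
  expect_gte(min(prof$value), 1)
  expect_lte(max(prof$value), 2)
  # recovered up to the 1%/99% anchors; interior error is tiny
  interior <- truth > 1.05 & truth < 1.95
  expect_lt(max(abs(prof$value - truth)[interior]), 0.02)
  expect_lt(max(abs(prof$value - truth)), 0.03)
})

test_that("degenerate and undersized ratio tracks are rejected", {
  lay <- one_chrom()
  tr <- bin_track(lay, 1000, 1.23, subclass = "ratio_track")
  expect_error(normalize_profile(tr), "degenerate")
  small <- bin_track(one_chrom(5e4), 1000, subclass = "ratio_track")
  small$value <- runif(nrow(small))
  expect_error(normalize_profile(small), "100")
})

test_that("smoothing averages a spike down and respects chromosomes", {
  lay <- one_chrom()
  prof <- bin_track(lay, 1000, 1.5, subclass = "copy_number_profile")
  expect_equal(smooth_profile(prof, 15)$value, prof$value)  # constant
  prof$value[100] <- 1.8
  sm <- smooth_profile(prof, 5)  # 5-bin window
  expect_equal(sm$value[100], 1.5 + 0.3 / 5)
  expect_error(smooth_profile(prof, 0.5), "window")
  # missing bins are excluded from neighbors and stay missing
  prof$value[50] <- NA
  sm <- smooth_profile(prof, 5)
  expect_true(is.na(sm$value[50]))
  expect_equal(sm$value[49], 1.5)
  # no bleed across chromosomes
  lay2 <- genome_layout(c("a", "b"), c(5e4, 5e4), c(2e4, 2e4))
  p2 <- bin_track(lay2, 1000, subclass = "copy_number_profile")
  p2$value <- ifelse(p2$chrom == "a", 2, 1)
  expect_equal(smooth_profile(p2, 7)$value, p2$value)
})

test_that("smoothing never increases variance", {
  set.seed(13)
  lay <- one_chrom(len = 5e4)
  for (i in 1:200) {
    prof <- bin_track(lay, 1000, subclass = "copy_number_profile")
    prof$value <- runif(nrow(prof), 1, 2)
    sm <- smooth_profile(prof, 5)
    expect_lte(var(sm$value), var(prof$value))
  }
})

test_that("differential profiles are anti-symmetric and zero on identity", {
  p <- demo_pair()
  d0 <- differential_profile(p$wt, p$wt)
  expect_true(all(d0$value == 0))
  ab <- differential_profile(p$wt, p$mut)
  ba <- differential_profile(p$mut, p$wt)
  expect_equal(ab$value, -ba$value)
})

test_that("the WT-mutant difference is pericentromeric, not arm-wide", {
  p <- demo_pair()
  d <- differential_profile(p$wt, p$mut)
  cen_d <- centromere_distance(p$g$layout, d$chrom, track_centers(d))
  expect_gt(max(d$value[cen_d <= 17.5]), 0.1)
  expect_true(all(abs(d$value[cen_d > 60]) < 1e-9))
})

test_that("profile peaks coincide with origins on noise-free input", {
  g <- make_genome(n_chrom = 1, chrom_length = 2e5, origin_spacing = 4e4)
  k <- default_kin()
  prof <- copy_number_profile(replication_time(g$layout, g$origins, k), k)
  pk <- profile_peaks(prof, min_prominence = 0.02)
  expect_gt(nrow(pk), 0)
  near <- vapply(seq_len(nrow(pk)), function(i) {
    min(abs(pk$pos[i] - g$origins$pos[g$origins$chrom == pk$chrom[i]]))
  }, numeric(1))
  expect_true(all(near <= 1000))  # within one bin of an origin
})

test_that("monotone and flat profiles have no peaks", {
  lay <- one_chrom()
  prof <- bin_track(lay, 1000, subclass = "copy_number_profile")
  prof$value <- seq(1, 2, length.out = nrow(prof))
  expect_equal(nrow(profile_peaks(prof)), 0)
  prof$value <- 1.5
  expect_equal(nrow(profile_peaks(prof)), 0)
})
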