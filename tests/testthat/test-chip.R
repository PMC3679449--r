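qpcr_panel <- function() {
  data.frame(
    locus = rep(c("CEN6", "peri", "arm", "control"), 2),
    condition = rep(c("WT", "mutant"), each = 4),
    ip = c(0.20, 0.12, 0.05, 0.05, 0.10, 0.07, 0.05, 0.05),
    wce = 1
  )
}

test_that("fold enrichment is anchored at exactly 1 on the reference control", {
  fe <- fold_enrichment(qpcr_panel(), "control", "WT")
  ref <- fe$folds$locus == "control" & fe$folds$condition == "WT"
  expect_identical(fe$folds$fold[ref], 1)
  expect_equal(fe$folds$fold[fe$folds$locus == "CEN6" &
                               fe$folds$condition == "WT"], 4)
  # identical IP/WCE everywhere gives all folds 1
  flat <- qpcr_panel(); flat$ip <- 0.1
  expect_true(all(fold_enrichment(flat, "control", "WT")$folds$fold == 1))
  bad <- qpcr_panel(); bad$wce[1] <- 0
  expect_error(fold_enrichment(bad, "control", "WT"), "> 0")
})

test_that("alternative anchoring and replicate summaries work", {
  pan <- rbind(qpcr_panel(), qpcr_panel())  # duplicate rows = replicates
  fe <- fold_enrichment(pan, "control", "WT",
                        anchor = list(locus = "CEN6", condition = "WT"))
  expect_equal(fe$summary$mean[fe$summary$locus == "CEN6" &
                                 fe$summary$condition == "WT"], 1)
  expect_true(all(fe$summary$n == 2))
  expect_true(all(fe$summary$sd == 0))
})

test_that("enrichment track is 1 for IP == input and filters thin input", {
  lay <- one_chrom()
  ip <- read_counts(lay, 100, "IP")
  input <- read_counts(lay, 100, "input")
  tr <- enrichment_track(ip, input)
  expect_true(all(tr$value == 1))
  input$value[7] <- 3
  tr <- enrichment_track(ip, input, min_input = 10)
  expect_true(is.na(tr$value[7]))
})

test_that("a simulated peak reaches its expected apex ratio at high depth", {
  lay <- one_chrom()
  site <- data.frame(chrom = "chrA", pos = 100500)  # at a bin center
  sim <- simulate_chip_counts(lay, site, amplitude = 5, depth = 5e4,
                              seed = 17)
  tr <- enrichment_track(sim$ip, sim$input)
  apex <- track_bin_index(tr, "chrA", 100500)
  expect_equal(tr$value[apex], 6, tolerance = 0.05)  # 1 + amplitude
})

test_that("peak calling is sound: thresholded strict maxima, separated", {
  lay <- one_chrom()
  flat <- bin_track(lay, 1000, 1, subclass = "enrichment_track")
  expect_equal(nrow(find_peaks(flat, lay, threshold = 1.2)), 0)

  tr <- bin_track(lay, 1000, 1, subclass = "enrichment_track")
  x <- track_centers(tr)
  tr$value <- 1 + 4 * pmax(0, 1 - abs(x - 50500) / 3000)
  pk <- find_peaks(tr, lay, threshold = 2)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$pos, 50500)
  expect_equal(pk$height, 5)
  expect_equal(pk$cen_dist_kb, (1e5 - 50500) / 1000)
})

test_that("of two close maxima only the higher survives the separation filter", {
  lay <- one_chrom()
  tr <- bin_track(lay, 1000, 1, subclass = "enrichment_track")
  tr$value[c(40, 41, 42)] <- c(3, 2, 4)  # two maxima 2 kb apart
  # brute-force enumeration of strict maxima finds both
  both <- find_peaks(tr, lay, threshold = 1.5, min_separation = 0.001)
  expect_equal(nrow(both), 2)
  one <- find_peaks(tr, lay, threshold = 1.5, min_separation = 3)
  expect_equal(nrow(one), 1)
  expect_equal(one$height, 4)
})

test_that("peak ratios are 1 between identical tracks", {
  lay <- one_chrom()
  sites <- data.frame(chrom = "chrA", pos = c(3e4, 6e4, 9e4, 12e4, 15e4))
  e <- chip_expected_enrichment(lay, sites, amplitude = 3)
  pk <- find_peaks(e, lay, threshold = 2)
  expect_equal(nrow(pk), 5)
  prr <- peak_ratio_regression(pk, e, e)
  expect_true(all(prr$table$ratio == 1))
  expect_equal(prr$fit$a, 0)
  expect_equal(prr$fit$rss, 0)
})

test_that("noise-free mutant reduction gives the closed-form apex ratio", {
  lay <- one_chrom()
  site <- data.frame(chrom = "chrA", pos = 100500)  # at the centromere
  A <- 2; rho <- 0.5; lc <- 8
  wt <- chip_expected_enrichment(lay, site, A)
  mut <- chip_expected_enrichment(lay, site, A,
                                  mutant = list(rho = rho, lambda_c = lc))
  pk <- find_peaks(wt, lay, threshold = 2)
  prr <- peak_ratio_regression(pk, wt, mut)
  d <- pk$cen_dist_kb
  expected <- (1 + A) / (1 + A * (1 - rho * exp(-d / lc)))
  expect_equal(prr$table$ratio, expected)
  expect_null(prr$fit)  # a single peak cannot support the regression
})

test_that("arm peaks far beyond the decay length have ratios near 1", {
  lay <- one_chrom(len = 4e5, cen = 2e5)
  sites <- data.frame(chrom = "chrA",
                      pos = c(200500, seq(10500, 399500, by = 2e4)))
  wt <- chip_expected_enrichment(lay, sites, 2)
  mut <- chip_expected_enrichment(lay, sites, 2,
                                  mutant = list(rho = 0.5, lambda_c = 8))
  pk <- find_peaks(wt, lay, threshold = 2)
  prr <- peak_ratio_regression(pk, wt, mut)
  far <- prr$table$cen_dist_kb > 80  # 10 decay lengths
  expect_true(all(abs(prr$table$ratio[far] - 1) < 1e-4))
  expect_gt(prr$table$ratio[which.min(prr$table$cen_dist_kb)], 1.3)
})

test_that("missing apexes in the second track are dropped with a warning", {
  lay <- one_chrom()
  sites <- data.frame(chrom = "chrA", pos = c(3e4, 9e4))
  e <- chip_expected_enrichment(lay, sites, 3)
  e2 <- e
  pk <- find_peaks(e, lay, threshold = 2)
  e2$value[track_bin_index(e2, pk$chrom[1], pk$pos[1])] <- NA
  expect_warning(prr <- peak_ratio_regression(pk, e, e2), "dropped")
  expect_equal(nrow(prr$table), nrow(pk) - 1)
})
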