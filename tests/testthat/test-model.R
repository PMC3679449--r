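test_that("deterministic timing follows the min rule closed form", {
  lay <- one_chrom()
  k <- kinetics_params(v = 2, S_dur = 40)
  ori <- origin_set("chrA", 1e5, t_mean = 10)
  tm <- replication_time(lay, ori, k)
  at <- function(pos) tm$value[track_bin_index(tm, "chrA", pos)]
  # T(150 kb) = 10 + 50/2 = 35 (bin-center evaluation)
  expect_equal(at(150e3), 10 + abs(150500 - 1e5) / 2000)
  # the genome-wide earliest origin's own bin carries its firing time
  expect_equal(at(1e5), 10 + abs(100500 - 1e5) / 2000)
})

test_that("converging forks meet where the closed form says", {
  lay <- one_chrom(len = 2e5, cen = 1e5)
  k <- kinetics_params(v = 1, S_dur = 120)
  ori <- origin_set("chrA", c(0, 1e5), t_mean = c(0, 10))
  tm <- replication_time(lay, ori, k)
  x <- track_centers(tm) / 1000
  expected <- pmin(x, 10 + abs(x - 100))
  expect_equal(tm$value, expected)
  expect_equal(max(expected[x < 100]), 55, tolerance = 0.01)
})

test_that("copy-number conversion is the linear 2 - T/S map, clipped", {
  lay <- one_chrom()
  k <- kinetics_params(S_dur = 40)
  tm <- bin_track(lay, 1000, subclass = "timing_map")
  tm$value <- rep(c(0, 20, 40, 80), length.out = nrow(tm))
  pr <- copy_number_profile(tm, k)
  expect_equal(unique(pr$value[tm$value == 0]), 2.0)
  expect_equal(unique(pr$value[tm$value == 20]), 1.5)
  expect_equal(unique(pr$value[tm$value == 40]), 1.0)
  expect_equal(unique(pr$value[tm$value == 80]), 1.0)  # clipped
  expect_true(all(pr$value >= 1 & pr$value <= 2))
})

test_that("lattice oracle agrees with the analytic map on random instances", {
  set.seed(101)
  k <- kinetics_params()
  tol <- 0.2 + 0.5 / 1.5  # dt + dx/v
  for (i in 1:25) {
    L <- 6e4
    lay <- genome_layout("c1", L, sample.int(L, 1) - 1)
    n <- sample(1:10, 1)
    ori <- origin_set("c1", sort(sample.int(L, n)) - 1, runif(n, 0, 30))
    a <- replication_time(lay, ori, k)
    o <- lattice_fork_oracle(lay, ori, k, dt = 0.2, dx = 500)
    expect_lte(max(abs(a$value - o$value)), tol + 1e-9)
  }
})

test_that("oracle rejects CFL violations and matches a single-origin wedge", {
  lay <- one_chrom()
  k <- kinetics_params(v = 1.5)
  ori <- origin_set("chrA", 1e5, 5)
  expect_error(lattice_fork_oracle(lay, ori, k, dt = 1, dx = 500), "CFL")
  o <- lattice_fork_oracle(lay, ori, k, dt = 0.2, dx = 500)
  a <- replication_time(lay, ori, k)
  expect_lte(max(abs(a$value - o$value)), 0.2 + 0.5 / 1.5 + 1e-9)
})

test_that("stochastic mode with zero spread and full competence is deterministic", {
  g <- make_genome(n_chrom = 2)
  det <- replication_time(g$layout, g$origins,
                          kinetics_params(mode = "deterministic"))
  sto <- replication_time(g$layout, g$origins,
                          kinetics_params(mode = "stochastic", n_cells = 3),
                          seed = 1)
  expect_equal(sto$value, det$value, tolerance = 1e-12)
})

test_that("stochastic mode is seeded and respects competence", {
  lay <- one_chrom()
  ori <- origin_set("chrA", c(5e4, 1.5e5), t_mean = 10, t_sigma = 3,
                    competence = 0.8)
  k <- kinetics_params(mode = "stochastic", n_cells = 50)
  a <- replication_time(lay, ori, k, seed = 9)
  b <- replication_time(lay, ori, k, seed = 9)
  expect_identical(a$value, b$value)
  # with competence < 1 some cells replicate late; mean exceeds the
  # deterministic map somewhere
  det <- replication_time(lay, ori, kinetics_params())
  expect_gt(mean(a$value - det$value), 0)
})

test_that("delaying one origin never makes any locus earlier", {
  set.seed(77)
  k <- kinetics_params()
  for (i in 1:10) {
    lay <- one_chrom()
    n <- sample(3:8, 1)
    ori <- origin_set("chrA", sort(sample.int(2e5, n)) - 1, runif(n, 0, 30))
    base <- replication_time(lay, ori, k)
    j <- sample(n, 1)
    ori2 <- ori
    ori2$t_mean[j] <- ori2$t_mean[j] + runif(1, 1, 15)
    later <- replication_time(lay, ori2, k)
    expect_true(all(later$value >= base$value - 1e-12))
  }
})

test_that("an undelayed neighbor alleviates the delay beyond the fork-meeting point", {
  # pericentromeric origin at 20 kb (delayed in the mutant), arm origin at
  # 60 kb untouched: past the wild-type meeting point both strains are
  # replicated by the arm origin's fork, so the difference is exactly 0
  lay <- one_chrom(len = 2e5, cen = 2e4)
  k <- kinetics_params(v = 2, S_dur = 60)
  wt_ori <- origin_set("chrA", c(2e4, 6e4), t_mean = c(10, 10))
  mut_ori <- apply_mutant(wt_ori, lay, mutant_spec(cutoff_D = 5,
                                                   delay_delta = 10))
  expect_equal(mut_ori$t_mean, c(20, 10))
  wt <- copy_number_profile(replication_time(lay, wt_ori, k), k)
  mut <- copy_number_profile(replication_time(lay, mut_ori, k), k)
  diff <- differential_profile(wt, mut)
  x <- track_centers(diff)
  meet_wt <- 4e4  # midpoint of equal-time origins at 20 and 60 kb
  expect_true(all(diff$value[x > meet_wt] == 0))
  expect_gt(max(diff$value[x <= meet_wt]), 0)
})
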