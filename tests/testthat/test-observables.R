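test_that("g(z) is flat at one for uniform samples", {
  set.seed(6)
  Lz <- 200
  z <- list(runif(20000, 0, Lz), runif(20000, 0, Lz))
  gz <- gz_profile(z, bin_width = 10, Lz = Lz)
  expect_true(all(abs(gz$value - 1) < 0.12))
  in_bulk <- gz$z_mid >= 0.7 * Lz & gz$z_mid <= 0.9 * Lz
  expect_equal(mean(gz$value[in_bulk]), 1, tolerance = 0.02)
  # conservation: counts sum to the total number of samples
  expect_equal(sum(gz$n), 40000)
})

test_that("g(z) flags enhancement against a constructed sample set", {
  set.seed(7)
  Lz <- 200
  # half the samples concentrated below 20 A, the rest uniform
  z <- c(runif(5000, 0, 20), runif(5000, 0, Lz))
  gz <- gz_profile(list(z), bin_width = 10, Lz = Lz)
  near <- gz$z_mid < 20
  bulk <- gz$z_mid >= 0.7 * Lz & gz$z_mid <= 0.9 * Lz
  # brute-force expectation for the first bin:
  # density = (0.5/20 + 0.5/200) vs bulk density 0.5/200
  expect_equal(gz$value[near][1], (0.5 / 20 + 0.5 / 200) / (0.5 / 200),
               tolerance = 0.1)
  expect_true(all(gz$value[near] > 1))
  expect_equal(mean(gz$value[bulk]), 1, tolerance = 0.05)
  # empty bulk slab is an error unless the pseudocount floor is requested,
  # in which case the profile is a flagged lower bound
  surf <- list(runif(2000, 0, 20))
  expect_error(gz_profile(surf, bin_width = 10, Lz = Lz), "bulk")
  lb <- gz_profile(surf, bin_width = 10, Lz = Lz, bulk_pseudocount = TRUE)
  expect_true(attr(lb, "lower_bound"))
  expect_gt(max(lb$value[lb$z_mid < 20], na.rm = TRUE), 1)
})

test_that("dipole moments obey hand calculations and symmetry", {
  d <- dipole_moment(rbind(c(0, 0, 1), c(0, 0, -1)), c(1, -1))
  expect_equal(d$mu, c(0, 0, 2))
  expect_equal(d$norm, 2)
  # all charges zero: zero dipole, alignment undefined
  d0 <- dipole_moment(matrix(rnorm(9), 3, 3), c(0, 0, 0))
  expect_equal(d0$norm, 0)
  expect_true(is.na(dipole_alignment(d0$mu)))
  # mirror symmetry: z -> -z flips mu_z and the alignment
  set.seed(8)
  pos <- matrix(rnorm(30), 10, 3)
  q <- sample(c(-1, 0, 1), 10, replace = TRUE)
  m1 <- dipole_moment(pos, q)$mu
  pos2 <- pos; pos2[, 3] <- -pos2[, 3]
  m2 <- dipole_moment(pos2, q)$mu
  expect_equal(m2[3], -m1[3])
  expect_equal(dipole_alignment(m2), -dipole_alignment(m1))
})

test_that("the alignment metric is exactly 1 toward the surface, bounded", {
  # dipole parallel to the inward surface normal (-z): metric is 1 exactly
  expect_identical(dipole_alignment(c(0, 0, -2)), 1)
  expect_identical(dipole_alignment(c(0, 0, 5)), -1)
  set.seed(9)
  mus <- matrix(rnorm(3000), ncol = 3)
  a <- dipole_alignment(mus)
  expect_true(all(abs(a) <= 1))
  # isotropic orientations average to zero within 3 SE
  expect_lt(abs(mean(a)), 3 * sd(a) / sqrt(length(a)))
})

test_that("alignment profiles bin by z and stay within bounds", {
  set.seed(10)
  n <- 5000
  z <- runif(n, 0, 100)
  # construct dipoles pointing at the surface for z < 50, random above
  mu <- matrix(rnorm(3 * n), ncol = 3)
  mu[z < 50, 3] <- -abs(mu[z < 50, 3]) * 10
  dat <- data.frame(z = z, a = dipole_alignment(mu))
  pr <- alignment_profile(list(dat, dat), bin_width = 10, Lz = 100)
  expect_true(all(pr$value[is.finite(pr$value)] <= 1))
  expect_true(all(pr$value[pr$z_mid < 50] > 0.5))
  expect_true(all(abs(pr$value[pr$z_mid > 50]) < 0.2))
})

test_that("charge summaries report per-species means with spread", {
  # no titratable sites: charge identically zero with zero spread
  ggg <- protein_sequence("GGGGG", has_free_nterm = FALSE,
                          has_free_cterm = FALSE)
  sys <- slit_system(free_seq = ggg, tail_seq = NULL, n_tails = 0,
                     c_salt = 0.1)
  r <- cpmc_run(sys, 20, 100, 5, seed = 1, runs = 2)
  cs <- charge_summary(r)
  expect_equal(cs$mean_net_charge, 0)
  expect_equal(cs$spread, 0)
  # isolated acid at pH = pKa: mean charge -0.5
  sys2 <- single_site_system("acid", pKa = 4.4, pH = 4.4)
  r2 <- cpmc_run(sys2, 200, 4000, 1, seed = 2, runs = 2)
  cs2 <- charge_summary(r2)
  expect_equal(cs2$mean_net_charge, -0.5, tolerance = 0.05)
})

test_that("profiles write as TSV round trips", {
  set.seed(12)
  gz <- gz_profile(list(runif(5000, 0, 100)), bin_width = 10, Lz = 100)
  f <- tempfile(fileext = ".tsv")
  write_profile(gz, f)
  back <- read.delim(f)
  expect_equal(back$value, gz$value, tolerance = 1e-9)
  expect_equal(names(back), c("z_mid", "value", "spread", "n"))
})
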