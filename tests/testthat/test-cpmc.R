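test_that("Debye length follows the 1:1 electrolyte formula", {
  # independent reference: ~3.04/sqrt(c) Angstrom for water-like Bjerrum
  expect_equal(debye_length(0.1, bjerrum = 7.0), 9.61, tolerance = 0.02)
  # inverse-square-root scaling: c x4 halves the screening length
  expect_equal(debye_length(0.4), debye_length(0.1) / 2, tolerance = 1e-12)
  expect_true(is.infinite(debye_length(0)))
  expect_error(debye_length(-0.1), ">= 0")
})

test_that("pair energy reproduces hand-evaluated values", {
  # LJ zero crossing at r = sigma for neutral beads
  expect_equal(pair_energy(4, 0, 0, sigma1 = 4, sigma2 = 4), 0,
               tolerance = 1e-12)
  # long-distance limit vanishes
  expect_lt(abs(pair_energy(1e4, 1, 1, debye = 9.6)), 1e-8)
  # screened Coulomb at r = lambda_D: l_B e^-1 / lambda_D
  u <- pair_energy(9.6, 1, 1, sigma1 = 0, sigma2 = 0, bjerrum = 7,
                   debye = 9.6)
  expect_equal(u, 0.268, tolerance = 1e-2)
  expect_true(is.infinite(pair_energy(0, 1, 1)))
})

test_that("total energy handles bonded dimers analytically", {
  two <- protein_sequence("GG", has_free_nterm = FALSE,
                          has_free_cterm = FALSE)
  sys <- slit_system(free_seq = two, tail_seq = NULL, n_tails = 0,
                     c_salt = 0.1)
  # place the two beads at the bond equilibrium length: bond energy zero,
  # LJ at r_eq remains (bonded pairs carry no nonbonded term)
  pos <- rbind(c(50, 50, 50), c(50, 50, 50 + sys$bond_req))
  expect_equal(total_energy(sys, pos = pos), 0, tolerance = 1e-12)
  # stretched by 1 A: k/2 * 1^2
  pos2 <- rbind(c(50, 50, 50), c(50, 50, 51 + sys$bond_req))
  expect_equal(total_energy(sys, pos = pos2), sys$bond_k / 2,
               tolerance = 1e-12)
  # engine energy agrees with the plain-R oracle
  expect_equal(total_energy(sys, pos = pos2, engine = TRUE),
               total_energy(sys, pos = pos2), tolerance = 1e-12)
})

test_that("running energy equals from-scratch recomputation", {
  for (cut in list(c(0, 0), c(40, 12))) {
    sys <- small_system(cutoff_el = cut[1], cutoff_lj = cut[2])
    r <- cpmc_run(sys, n_equil = 50, n_prod = 150, sample_every = 10,
                  seed = 3, runs = 1)
    expect_lt(r$runs[[1]]$drift_max, 1e-6)
    # independent R recomputation of the final configuration
    e_r <- total_energy(sys, pos = r$runs[[1]]$pos,
                        prot = r$runs[[1]]$site_prot_final)
    expect_equal(r$runs[[1]]$energy, e_r, tolerance = 1e-8)
  }
})

test_that("anchored beads never move and walls confine the rest", {
  sys <- small_system()
  r <- cpmc_run(sys, n_equil = 100, n_prod = 200, sample_every = 10,
                seed = 5, runs = 1)
  anchors <- sys$chain_start[sys$grafted] + 1L
  expect_equal(unname(r$runs[[1]]$pos[anchors, ]),
               unname(sys$pos[anchors, ]), tolerance = 1e-12)
  nonanchor <- setdiff(seq_len(nrow(sys$pos)), anchors)
  expect_true(all(r$runs[[1]]$pos[nonanchor, 3] > 0 &
                    r$runs[[1]]$pos[nonanchor, 3] < sys$Lz))
})

test_that("a non-interacting bead samples the slit uniformly", {
  sys <- single_site_system("acid", pKa = 4.4, pH = 5.5)
  r <- cpmc_run(sys, n_equil = 500, n_prod = 150000, sample_every = 150,
                seed = 1, runs = 1, moves = list(do_titration = FALSE))
  z <- r$runs[[1]]$samples$z_cm
  # all proposals are dU = 0 except wall rejections: near-full acceptance
  ms <- r$runs[[1]]$move_stats
  bead <- ms[ms$move == "bead", ]
  expect_gt(bead$accepts / bead$attempts, 0.9)
  # chi-squared uniformity over 8 bins at alpha = 0.01
  ct <- table(cut(z, breaks = seq(0, sys$Lz, length.out = 9)))
  chi <- sum((ct - length(z) / 8)^2 / (length(z) / 8))
  expect_lt(chi, qchisq(0.99, df = 7))
})

test_that("isolated-site titration reproduces Henderson-Hasselbalch", {
  for (dpH in c(-2, -1, 0, 1, 2)) {
    sys <- single_site_system("acid", pKa = 4.4, pH = 4.4 + dpH)
    r <- cpmc_run(sys, n_equil = 500, n_prod = 4000, sample_every = 1,
                  seed = 2, runs = 1)
    prot <- 1 - r$runs[[1]]$site_frac_prot  # deprotonated fraction
    expected <- 1 / (1 + 10^(-dpH))
    # standard error from batch means over the production series
    nb <- 20
    s <- r$runs[[1]]$samples
    batches <- split(s$q_free, cut(seq_len(nrow(s)), nb))
    bm <- vapply(batches, function(b) mean(b == -1), numeric(1))
    se <- max(sd(bm) / sqrt(nb), 1 / nrow(s))
    expect_lt(abs(prot - expected), 3 * se + 0.01)
  }
  # base at pH >> pKa discharges completely
  sysb <- single_site_system("base", pKa = 10.4, pH = 13.5)
  rb <- cpmc_run(sysb, n_equil = 200, n_prod = 2000, sample_every = 1,
                 seed = 2, runs = 1)
  expect_lt(mean(rb$runs[[1]]$samples$q_free), 0.01)
})

test_that("runs are bit-reproducible for a fixed seed", {
  sys <- small_system()
  a <- cpmc_run(sys, 50, 200, 2, seed = 9, runs = 1)
  b <- cpmc_run(sys, 50, 200, 2, seed = 9, runs = 1)
  expect_identical(a$runs[[1]]$samples, b$runs[[1]]$samples)
  expect_identical(a$runs[[1]]$pos, b$runs[[1]]$pos)
  c <- cpmc_run(sys, 50, 200, 2, seed = 10, runs = 1)
  expect_false(identical(a$runs[[1]]$samples, c$runs[[1]]$samples))
})

test_that("trajectory output writes XYZ and sample TSVs", {
  sys <- small_system()
  r <- cpmc_run(sys, 20, 60, 10, seed = 1, runs = 2)
  d <- tempfile("traj")
  paths <- write_trajectory(r, d)
  expect_length(paths, 4)
  xyz <- readLines(paths[1])
  expect_equal(as.integer(xyz[1]), nrow(sys$pos))
  smp <- read.delim(paths[2])
  expect_equal(nrow(smp), nrow(r$runs[[1]]$samples))
})
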