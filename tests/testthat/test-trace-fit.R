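test_that("normalisation recovers baseline and amplitude of a sigmoid", {
  t <- seq(0, 64, 0.25)
  tr <- tht_trace(t, logistic_trace(t, 100, 900, 20, 2), 5, 0.05, 0, 1)
  nz <- normalize_trace(tr)
  expect_true(nz$aggregating)
  expect_equal(nz$baseline, 100, tolerance = 0.01)
  expect_equal(nz$amplitude, 900, tolerance = 0.01)
  expect_true(all(nz$y > -0.1 & nz$y < 1.1))

  # a trace already in [0, 1] is unchanged within tolerance
  tr01 <- tht_trace(t, logistic_trace(t, 0, 1, 20, 2), 5, 0.05, 0, 1)
  nz01 <- normalize_trace(tr01)
  expect_equal(nz01$y, tr01$F, tolerance = 1e-6)

  # constant trace: non-aggregating flag
  trc <- tht_trace(t, rep(50, length(t)), 5, 0.05, 500, 1)
  expect_false(normalize_trace(trc)$aggregating)

  expect_error(tht_trace(c(1, 1, 0:10), rep(1, 13), 5, 0.05, 0, 1),
               "increasing")
})

test_that("median trace is the pointwise median", {
  t <- seq(0, 10, 0.5)
  mk <- function(y) {
    structure(list(t = t, y = y, baseline = 0, amplitude = 1,
                   aggregating = TRUE,
                   condition = list(monomer_uM = 5, seed_uM = 0.05,
                                    salt_mM = 0, replicate = 1),
                   well = "w"),
              class = "normalized_trace")
  }
  same <- lapply(1:3, function(i) mk(sin(t)))
  expect_equal(median_trace(same)$y, sin(t))

  const <- lapply(0:2, function(k) mk(rep(k, length(t))))
  expect_equal(median_trace(const)$y, rep(1, length(t)))

  # five replicates, one shifted outlier: median is the unshifted value
  reps <- c(lapply(1:4, function(i) mk(cos(t))), list(mk(cos(t) + 5)))
  brute <- apply(sapply(reps, `[[`, "y"), 1, median)
  expect_equal(median_trace(reps)$y, brute)
  expect_equal(median_trace(reps)$y, cos(t))

  expect_error(median_trace(list()), "replicate")
})

test_that("noiseless synthetic series is recovered almost exactly", {
  spec <- make_salt_series(salts_mM = c(0, 40, 120),
                          seeds_uM = 0.05,
                          noise = list(multiplicative_sd = 0,
                                       additive_sd = 0, baseline = 100,
                                       amplitude = 900,
                                       amplitude_rel_sd = 0,
                                       baseline_sd = 0),
                          rng_seed = 3L)
  pl <- simulate_plate(spec)
  tr <- lapply(pl$meta$well, function(w) {
    m <- pl$meta[pl$meta$well == w, ]
    tht_trace(pl$plate$time_h, pl$plate[[w]], m$monomer_uM, m$seed_uM,
              m$salt_mM, m$replicate, well = w)
  })
  fit <- fit_salt_series(tr)
  m <- merge(fit$table, pl$truth, by = c("seed_uM", "salt_mM"))
  m <- m[m$aggregating, ]
  expect_equal(nrow(m), 3)
  expect_true(all(abs(m$k2kplus / m$k2kplus_true - 1) < 0.01))
})

test_that("fig2-analog recovery: within 10% and strictly decreasing", {
  pl <- fig2_plate()
  fit <- fig2_fit()
  m <- merge(fit$table, pl$truth[, c("seed_uM", "salt_mM",
                                     "k2kplus_true", "flat")],
             by = c("seed_uM", "salt_mM"))
  agg <- m[!m$flat, ]
  expect_true(all(agg$aggregating))
  expect_true(all(agg$converged))
  expect_true(all(abs(agg$k2kplus / agg$k2kplus_true - 1) < 0.10))
  for (s in unique(agg$seed_uM)) {
    sub <- agg[agg$seed_uM == s, ]
    sub <- sub[order(sub$salt_mM), ]
    expect_true(all(diff(sub$k2kplus) < 0))
  }
  # flat conditions (inhibited regime) are excluded, not fitted
  expect_true(all(!m$aggregating[m$flat]))
  expect_true(all(is.na(m$k2kplus[m$flat])))
  # confidence intervals bracket the estimates
  ok <- agg$converged & is.finite(agg$ci_lo)
  expect_true(all(agg$ci_lo[ok] < agg$k2kplus[ok] &
                    agg$k2kplus[ok] < agg$ci_hi[ok]))
})

test_that("fit residuals on generator-matched data are trend-free", {
  fit <- fig2_fit()
  rs <- residuals(fit)
  for (key in unique(paste(rs$seed_uM, rs$salt_mM))) {
    sub <- rs[paste(rs$seed_uM, rs$salt_mM) == key, ]
    expect_lt(abs(cor(sub$t, sub$residual)), 0.15)
  }
})

test_that("half times increase with salt and censor flat conditions", {
  th <- t_half_vs_salt(fig2_traces())
  for (s in unique(th$seed_uM)) {
    sub <- th[th$seed_uM == s, ]
    sub <- sub[order(sub$salt_mM), ]
    obs <- sub[!sub$censored, ]
    expect_true(all(diff(obs$t_half) > 0))
    cen <- sub[sub$censored, ]
    expect_true(all(cen$salt_mM >= 200))
    expect_true(all(cen$censored_at == 64))
  }
  # single replicate: the median is that replicate
  t <- seq(0, 64, 0.25)
  one <- list(tht_trace(t, logistic_trace(t, 0, 1, 12, 1.5), 5, 0.05, 0, 1))
  th1 <- t_half_vs_salt(one)
  nz <- normalize_trace(one[[1]])
  expect_equal(th1$t_half,
               half_time(nz$y, nz$t, baseline = 0, amplitude = 1))
})

test_that("summary and methods of the fit object work", {
  fit <- fig2_fit()
  sm <- summary(fit)
  expect_lt(sm$spearman_salt_trend, -0.9)
  expect_equal(length(coef(fit)), nrow(fit$table))
  pr <- predict(fit, t = seq(0, 10, 1))
  expect_true(all(pr$M_frac >= 0 & pr$M_frac <= 1))
})
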