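# Normalisation of replicate ThT traces, median traces, and global fitting
# of the seeded secondary-nucleation model per salt concentration.

#' Construct a ThT trace
#'
#' @param t Time (h), strictly increasing, at least 10 points.
#' @param F Fluorescence (a.u.), finite.
#' @param monomer_uM,seed_uM,salt_mM,replicate Condition metadata.
#' @param well Optional well identifier.
#' @return List of class \code{tht_trace}.
#' @export
tht_trace <- function(t, F, monomer_uM, seed_uM, salt_mM, replicate,
                      well = NA_character_) {
  if (any(diff(t) <= 0)) stop("time must be strictly increasing")
  if (length(t) < 10L) stop("a trace needs at least 10 time points")
  if (any(!is.finite(F))) stop("fluorescence must be finite")
  structure(list(t = t, F = F,
                 condition = list(monomer_uM = monomer_uM,
                                  seed_uM = seed_uM, salt_mM = salt_mM,
                                  replicate = replicate),
                 well = well),
            class = "tht_trace")
}

#' @export
print.tht_trace <- function(x, ...) {
  cat(sprintf(
    "tht_trace %s: %d points over %.2g h (%g uM monomer, %g uM seed, %g mM NaCl, rep %s)\n",
    x$well, length(x$t), max(x$t), x$condition$monomer_uM,
    x$condition$seed_uM, x$condition$salt_mM, x$condition$replicate))
  invisible(x)
}

# sigmoid envelope used for baseline/amplitude estimation
.logistic4 <- function(t, b, a, t0, w) b + a / (1 + exp(-(t - t0) / w))

.fit_envelope <- function(t, F) {
  b0 <- stats::quantile(F, 0.05, names = FALSE)
  a0 <- stats::quantile(F, 0.98, names = FALSE) - b0
  t05 <- t[which(F >= b0 + 0.5 * a0)[1]]
  if (is.na(t05)) t05 <- stats::median(t)
  fit <- suppressWarnings(
    try(stats::nls(F ~ .logistic4(t, b, a, t0, w),
                   start = list(b = b0, a = max(a0, 1e-8), t0 = t05,
                                w = diff(range(t)) / 20),
                   control = stats::nls.control(maxiter = 200,
                                                warnOnly = TRUE)),
        silent = TRUE))
  bad <- list(ok = FALSE, b = b0, a = a0, t0 = NA_real_, w = NA_real_,
              noise = stats::mad(diff(F)) / sqrt(2))
  if (inherits(fit, "try-error")) return(bad)
  cf <- stats::coef(fit)
  rng <- max(F) - min(F)
  # plausibility: the fitted plateau rise must describe the actual data
  # range, not a degenerate far-away logistic branch
  if (!all(is.finite(cf)) || cf[["a"]] <= 0 || cf[["a"]] > 2 * rng ||
      cf[["b"]] < min(F) - rng || cf[["b"]] > max(F) + rng ||
      cf[["t0"]] < min(t) - diff(range(t)) || cf[["t0"]] > 2 * max(t))
    return(bad)
  list(ok = TRUE, b = unname(cf[["b"]]), a = unname(cf[["a"]]),
       t0 = unname(cf[["t0"]]), w = abs(unname(cf[["w"]])),
       noise = stats::mad(stats::residuals(fit)))
}

#' Normalise a ThT trace to [0, 1]
#'
#' The baseline is the robust mean (median) of the pre-growth segment and
#' the amplitude is plateau minus baseline from a four-parameter sigmoid
#' envelope fit.  Traces whose fitted amplitude does not rise above the
#' baseline noise are flagged non-aggregating and returned unscaled
#' (amplitude \code{NA}).
#'
#' @param trace A \code{\link{tht_trace}}.
#' @return List of class \code{normalized_trace}: \code{t}, \code{y},
#'   \code{baseline}, \code{amplitude}, \code{aggregating} flag and the
#'   inherited \code{condition}.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "tht_trace"))
  t <- trace$t; F <- trace$F
  env <- .fit_envelope(t, F)
  # robust baseline: median of the pre-growth segment when one exists,
  # otherwise the fitted plateau baseline
  baseline <- env$b
  if (env$ok && is.finite(env$t0)) {
    # robust local correction of the fitted baseline over the pre-growth
    # segment (residuals to the envelope, so the sigmoid toe cancels)
    pre <- t <= env$t0 - 6 * env$w
    if (sum(pre) >= 3)
      baseline <- env$b +
        stats::median(F[pre] - .logistic4(t[pre], env$b, env$a, env$t0,
                                          env$w))
  }
  amp <- if (env$ok) env$a else max(F) - baseline
  scale_floor <- 1e-3 * max(abs(F), 1)
  aggregating <- env$ok && is.finite(amp) &&
    amp > max(10 * env$noise, scale_floor)
  y <- if (aggregating) (F - baseline) / amp else F - baseline
  structure(list(t = t, y = y, baseline = baseline,
                 amplitude = if (aggregating) amp else NA_real_,
                 aggregating = aggregating, condition = trace$condition,
                 well = trace$well),
            class = "normalized_trace")
}

#' Pointwise median of replicate normalised traces
#'
#' Replicates are interpolated onto the intersection of their time ranges
#' (the grid of the first replicate restricted to the common range) and the
#' median is taken pointwise.
#'
#' @param replicates List of \code{normalized_trace} objects (>= 1).
#' @return A \code{normalized_trace} holding the median trace.
#' @export
median_trace <- function(replicates) {
  if (length(replicates) < 1L) stop("need at least one replicate")
  stopifnot(all(vapply(replicates, inherits, TRUE, "normalized_trace")))
  lo <- max(vapply(replicates, function(r) min(r$t), numeric(1)))
  hi <- min(vapply(replicates, function(r) max(r$t), numeric(1)))
  if (hi <= lo) stop("replicates share no common time range")
  grid <- replicates[[1]]$t
  grid <- grid[grid >= lo & grid <= hi]
  ys <- vapply(replicates, function(r) {
    stats::approx(r$t, r$y, xout = grid)$y
  }, numeric(length(grid)))
  ys <- matrix(ys, nrow = length(grid))
  structure(list(t = grid, y = apply(ys, 1, stats::median),
                 baseline = 0, amplitude = 1,
                 aggregating = any(vapply(replicates, `[[`, TRUE,
                                          "aggregating")),
                 condition = replicates[[1]]$condition,
                 well = "median"),
            class = "normalized_trace")
}

# model curve for one condition: seeded secondary nucleation, k_n = 0.
# Internal convention k_plus = 1, so the first shape parameter is exactly
# the product k2*k_plus and the second the elongation-seeding rate k_plus*P0
# (numerically equal to the internal P0, in M when k_plus = 1 M^-1 h^-1).
.seeded_model_curve <- function(log10_prod, log10_kpP0, t, m0, seed,
                                n2, n_c) {
  p <- kinetic_params(k_n = 0, k2 = 10^log10_prod, k_plus = 1, n_c = n_c,
                      n2 = n2, m0 = m0, M0 = seed, P0 = 10^log10_kpP0)
  closed_form_mass(p, t)$M_frac
}

# profiled residual sum of squares: per-well amplitude/baseline solved by
# linear least squares given the shape curve
.profiled_rss <- function(theta, wells, m0, seed, n2, n_c,
                          share_amplitude = FALSE) {
  rss <- 0
  if (share_amplitude) {
    x <- unlist(lapply(wells, function(w)
      .seeded_model_curve(theta[1], theta[2], w$t, m0, seed, n2, n_c)))
    y <- unlist(lapply(wells, function(w) w$y))
    ft <- stats::lm.fit(cbind(1, x), y)
    rss <- sum(ft$residuals^2)
  } else {
    for (w in wells) {
      x <- .seeded_model_curve(theta[1], theta[2], w$t, m0, seed, n2, n_c)
      ft <- stats::lm.fit(cbind(1, x), w$y)
      rss <- rss + sum(ft$residuals^2)
    }
  }
  rss
}

#' Fit the seeded model to a salt series of ThT traces
#'
#' Groups traces by condition (seed and salt concentration), normalises
#' them, flags non-aggregating conditions (fitted amplitude below 5 per
#' cent of the series maximum), and for every aggregating condition fits
#' the seeded secondary-nucleation integrated rate law jointly to all
#' replicates.  Seeded traces constrain exactly two shape parameters: the
#' rate-constant product \eqn{k_2 k_+} (which sets the amplification rate
#' \eqn{\kappa}) and the elongation-seeding rate \eqn{k_+ P_0} (the early
#' growth contributed by seed ends); the individual constants are not
#' identifiable, so internally \eqn{k_+} is fixed to 1 and the two
#' combinations are fitted and reported.  Per-well amplitude and baseline
#' are profiled out as linear nuisance parameters; the time offset is
#' fixed at zero.  Optimisation is a log-spaced multi-start scan over
#' \code{log10(k2*k_plus)} refined by Brent's method, followed by a joint
#' Nelder-Mead refinement of both shape parameters; the confidence
#' interval comes from the curvature (Hessian) of the profiled sum of
#' squares.
#'
#' @param traces List of \code{\link{tht_trace}} objects.
#' @param n2,n_c Reaction orders (fixed; defaults 2).
#' @param L_seed Average seed length in monomers; together with
#'   \code{k_plus_prior} it sets the starting value of the
#'   elongation-seeding rate, \code{k_plus_prior * seed / L_seed}.
#'   Default 500.
#' @param share_amplitude Share one amplitude/baseline across replicates of
#'   a condition instead of one pair per well.  Default \code{FALSE}.
#' @param search_range Range of log10(k2*k_plus / M^-(n2+1) h^-2) scanned
#'   by the multi-start search.
#' @param n_starts Number of log-spaced starts.
#' @param k_plus_prior Elongation constant (M^-1 h^-1) used only to
#'   initialise the seeding-rate parameter.
#' @return Object of class \code{salt_series_fit}: a list with a
#'   \code{table} data.frame (seed_uM, salt_mM, k2kplus, ci_lo, ci_hi,
#'   t_half, aggregating, converged, rss, n_wells) and the fitted
#'   condition details.
#' @export
fit_salt_series <- function(traces, n2 = 2, n_c = 2, L_seed = 500,
                            share_amplitude = FALSE,
                            search_range = c(12, 19), n_starts = 25,
                            k_plus_prior = 1e7) {
  stopifnot(length(traces) > 0)
  norm <- lapply(traces, normalize_trace)
  amps <- vapply(norm, function(x)
    if (is.na(x$amplitude)) 0 else x$amplitude, numeric(1))
  amp_max <- max(amps)
  key <- vapply(norm, function(x)
    paste(x$condition$seed_uM, x$condition$salt_mM, sep = "@"), character(1))
  groups <- split(norm, key)
  rows <- list(); fits <- list()
  for (g in groups) {
    cond <- g[[1]]$condition
    g_amps <- vapply(g, function(x)
      if (is.na(x$amplitude)) 0 else x$amplitude, numeric(1))
    aggregating <- vapply(g, `[[`, TRUE, "aggregating") &
      g_amps >= 0.05 * amp_max
    row <- data.frame(seed_uM = cond$seed_uM, salt_mM = cond$salt_mM,
                      k2kplus = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, t_half = NA_real_,
                      aggregating = any(aggregating), converged = FALSE,
                      rss = NA_real_, n_wells = sum(aggregating))
    if (any(aggregating)) {
      wells <- g[aggregating]
      m0 <- cond$monomer_uM * 1e-6
      seed <- cond$seed_uM * 1e-6
      th <- vapply(wells, function(w) {
        half_time(w$y, w$t, baseline = 0, amplitude = 1)
      }, numeric(1))
      row$t_half <- stats::median(th, na.rm = TRUE)
      # elongation-seeding rate prior from the configured seed length
      lq0 <- log10(k_plus_prior * seed / L_seed)
      obj1 <- function(lp) .profiled_rss(c(lp, lq0), wells, m0, seed,
                                         n2, n_c, share_amplitude)
      starts <- seq(search_range[1], search_range[2],
                    length.out = n_starts)
      vals <- vapply(starts, obj1, numeric(1))
      best <- starts[which.min(vals)]
      lo <- max(search_range[1], best - 0.5)
      hi <- min(search_range[2], best + 0.5)
      opt1 <- stats::optimize(obj1, c(lo, hi), tol = 1e-6)
      # joint refinement of (log10 k2k+, log10 k+P0)
      obj2 <- function(th) .profiled_rss(th, wells, m0, seed, n2, n_c,
                                         share_amplitude)
      opt <- stats::optim(c(opt1$minimum, lq0), obj2,
                          method = "Nelder-Mead",
                          control = list(maxit = 1000, reltol = 1e-12))
      lp_hat <- opt$par[1]; lq_hat <- opt$par[2]
      interior <- lp_hat > search_range[1] + 0.05 &&
        lp_hat < search_range[2] - 0.05
      # curvature-based standard error on log10(k2k+) from the 2x2 Hessian
      h <- 0.02
      f0 <- opt$value
      H <- matrix(0, 2, 2)
      for (a in 1:2) for (b in 1:2) {
        ea <- h * (a == 1:2); eb <- h * (b == 1:2)
        H[a, b] <- (obj2(opt$par + ea + eb) - obj2(opt$par + ea - eb) -
                    obj2(opt$par - ea + eb) + obj2(opt$par - ea - eb)) /
          (4 * h^2)
      }
      npts <- sum(vapply(wells, function(w) length(w$t), integer(1)))
      npar <- 2 + if (share_amplitude) 2 else 2 * length(wells)
      sigma2 <- f0 / max(npts - npar, 1)
      se <- tryCatch({
        V <- solve(H / (2 * sigma2))
        if (V[1, 1] > 0) sqrt(V[1, 1]) else NA_real_
      }, error = function(e) NA_real_)
      row$k2kplus <- 10^lp_hat
      if (is.finite(se)) {
        row$ci_lo <- 10^(lp_hat - 1.96 * se)
        row$ci_hi <- 10^(lp_hat + 1.96 * se)
      }
      row$converged <- interior && opt$convergence == 0
      row$rss <- f0
      fits[[paste(cond$seed_uM, cond$salt_mM, sep = "@")]] <-
        list(condition = cond, log10_k2kplus = lp_hat,
             log10_kpP0 = lq_hat, se_log10 = se, wells = wells)
    }
    rows[[length(rows) + 1L]] <- row
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$seed_uM, tab$salt_mM), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, n2 = n2, n_c = n_c,
                 L_seed = L_seed, share_amplitude = share_amplitude),
            class = "salt_series_fit")
}

#' @export
print.salt_series_fit <- function(x, ...) {
  cat("Seeded secondary-nucleation fits by salt concentration\n")
  cat(sprintf("  n2 = %g, n_c = %g, L_seed = %g, %d conditions\n",
              x$n2, x$n_c, x$L_seed, nrow(x$table)))
  print(x$table, digits = 4)
  invisible(x)
}

#' @export
summary.salt_series_fit <- function(object, ...) {
  tab <- object$table
  agg <- tab[tab$aggregating & tab$converged, , drop = FALSE]
  trend <- NA_real_
  if (nrow(agg) >= 3) {
    ct <- stats::cor.test(agg$salt_mM, log10(agg$k2kplus),
                          method = "spearman", exact = FALSE)
    trend <- unname(ct$estimate)
  }
  out <- list(table = tab, n_aggregating = sum(tab$aggregating),
              n_censored = sum(!tab$aggregating),
              spearman_salt_trend = trend)
  class(out) <- "summary.salt_series_fit"
  out
}

#' @export
print.summary.salt_series_fit <- function(x, ...) {
  print(x$table, digits = 4)
  cat(sprintf("aggregating conditions: %d, censored: %d\n",
              x$n_aggregating, x$n_censored))
  if (is.finite(x$spearman_salt_trend))
    cat(sprintf("Spearman rho of log10(k2*k+) vs salt: %.3f\n",
                x$spearman_salt_trend))
  invisible(x)
}

#' @export
coef.salt_series_fit <- function(object, ...) {
  stats::setNames(object$table$k2kplus,
                  paste0("seed", object$table$seed_uM, "_salt",
                         object$table$salt_mM))
}

#' Predicted model curves from a salt-series fit
#'
#' @param object A \code{salt_series_fit}.
#' @param t Time grid (h); defaults to 0..64 h.
#' @param ... Unused.
#' @return data.frame with columns seed_uM, salt_mM, t, M_frac for each
#'   converged condition.
#' @export
predict.salt_series_fit <- function(object, t = seq(0, 64, 0.25), ...) {
  out <- lapply(object$fits, function(f) {
    cond <- f$condition
    x <- .seeded_model_curve(f$log10_k2kplus, f$log10_kpP0, t,
                             cond$monomer_uM * 1e-6,
                             cond$seed_uM * 1e-6, object$n2, object$n_c)
    data.frame(seed_uM = cond$seed_uM, salt_mM = cond$salt_mM, t = t,
               M_frac = x)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' @export
plot.salt_series_fit <- function(x, ...) {
  tab <- x$table[x$table$aggregating & x$table$converged, , drop = FALSE]
  if (nrow(tab) == 0) stop("no converged conditions to plot")
  graphics::plot(tab$salt_mM, tab$k2kplus, log = "y", pch = 19,
                 col = as.factor(tab$seed_uM),
                 xlab = "NaCl (mM)",
                 ylab = expression(k[2] * k["+"] ~ (M^-3 ~ h^-2)), ...)
  invisible(x)
}

#' Residuals of a salt-series fit
#'
#' @param object A \code{salt_series_fit}.
#' @param ... Unused.
#' @return data.frame with seed_uM, salt_mM, well, t and residual columns.
#' @export
residuals.salt_series_fit <- function(object, ...) {
  out <- lapply(object$fits, function(f) {
    cond <- f$condition
    do.call(rbind, lapply(f$wells, function(w) {
      xm <- .seeded_model_curve(f$log10_k2kplus, f$log10_kpP0, w$t,
                                cond$monomer_uM * 1e-6,
                                cond$seed_uM * 1e-6, object$n2,
                                object$n_c)
      ft <- stats::lm.fit(cbind(1, xm), w$y)
      data.frame(seed_uM = cond$seed_uM, salt_mM = cond$salt_mM,
                 well = w$well, t = w$t, residual = ft$residuals)
    }))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Median half time per condition
#'
#' Normalises all traces, groups them by condition and reports the median
#' half time of the aggregating replicates.  Conditions in which no
#' replicate aggregates are censored at the end of the observation window
#' and reported as \code{t_half = NA} with \code{censored_at = max(t)}
#' (read: "> censored_at h").
#'
#' @param traces List of \code{\link{tht_trace}} objects.
#' @return data.frame with columns seed_uM, salt_mM, t_half, censored,
#'   censored_at, n_replicates.
#' @export
t_half_vs_salt <- function(traces) {
  norm <- lapply(traces, normalize_trace)
  amp_max <- max(vapply(norm, function(x)
    if (is.na(x$amplitude)) 0 else x$amplitude, numeric(1)))
  key <- vapply(norm, function(x)
    paste(x$condition$seed_uM, x$condition$salt_mM, sep = "@"), character(1))
  groups <- split(norm, key)
  rows <- lapply(groups, function(g) {
    cond <- g[[1]]$condition
    ok <- vapply(g, function(x) {
      x$aggregating && x$amplitude >= 0.05 * amp_max
    }, logical(1))
    th <- if (any(ok)) {
      stats::median(vapply(g[ok], function(w)
        half_time(w$y, w$t, baseline = 0, amplitude = 1), numeric(1)),
        na.rm = TRUE)
    } else NA_real_
    data.frame(seed_uM = cond$seed_uM, salt_mM = cond$salt_mM,
               t_half = th, censored = !any(ok) || is.na(th),
               censored_at = max(g[[1]]$t), n_replicates = length(g))
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$seed_uM, out$salt_mM), , drop = FALSE]
}
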