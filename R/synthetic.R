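# Synthetic plate-reader data with the statistical structure of the seeded
# salt-series experiment, plus small MC fixture configurations.  Every
# generated dataset carries its truth table so recovery tests compare
# against generating parameters, never against hard-coded numbers.

#' Build a seeded salt-series plate specification
#'
#' The generating truth is a log-linear decay of the rate-constant product
#' with salt, \eqn{k_2 k_+(c) = \mathrm{base} \cdot 10^{-\mathrm{decay}
#' \cdot c}}, with complete inhibition (flat traces) at and above the
#' inhibition threshold.  Defaults mirror the seeded assay: 5 uM monomer,
#' seed levels 0.005 and 0.05 uM (monomer equivalents), NaCl 0, 20, 40,
#' 80, 120, 200, 500 and 1200 mM, three replicates, 64 h horizon sampled
#' every 0.25 h.
#'
#' @param base_k2kplus Product k2*k_plus at 0 mM NaCl (M^-(n2+1) h^-2).
#'   The default 1.6e16 gives kappa ~ 2 h^-1 at 5 uM monomer (overall
#'   aggregation within a few hours without added salt).
#' @param decay_per_mM Log10 decay of the product per mM NaCl (> 0).  The
#'   default 0.015 stretches half times several-fold by 120 mM while
#'   keeping them inside the 64 h window.
#' @param salts_mM Salt concentrations (mM).
#' @param inhibition_threshold_mM Conditions at or above this salt level
#'   get zero-rate (flat) truth.  Default 200.
#' @param monomer_uM Free monomer concentration (uM).
#' @param seeds_uM Seed concentrations in monomer equivalents (uM).
#' @param n_replicates Replicates per condition (>= 3, as in the assay).
#' @param k_plus True elongation rate constant used to split the product
#'   (M^-1 h^-1); only the product is identifiable from seeded traces.
#' @param L_seed Average seed length (monomers); P0 = seed / L_seed.
#' @param n2,n_c Reaction orders.
#' @param noise List with \code{multiplicative_sd} (relative),
#'   \code{additive_sd} (a.u.), \code{baseline} (a.u.), \code{amplitude}
#'   (a.u.), \code{amplitude_rel_sd} and \code{baseline_sd} (per-well
#'   variation).
#' @param t_end,dt Time horizon and sampling interval (h).
#' @param rng_seed Seed for \code{\link{simulate_plate}}.
#' @return List of class \code{plate_spec} with a \code{conditions}
#'   data.frame carrying the generating truth per condition.
#' @export
make_salt_series <- function(base_k2kplus = 1.6e16, decay_per_mM = 0.015,
                             salts_mM = c(0, 20, 40, 80, 120, 200, 500,
                                          1200),
                             inhibition_threshold_mM = 200,
                             monomer_uM = 5, seeds_uM = c(0.005, 0.05),
                             n_replicates = 3, k_plus = 1e7, L_seed = 500,
                             n2 = 2, n_c = 2,
                             noise = list(multiplicative_sd = 0.01,
                                          additive_sd = 4.5,
                                          baseline = 100, amplitude = 900,
                                          amplitude_rel_sd = 0.05,
                                          baseline_sd = 2),
                             t_end = 64, dt = 0.25, rng_seed = 1L) {
  stopifnot(decay_per_mM >= 0, n_replicates >= 3, base_k2kplus > 0)
  grid <- expand.grid(seed_uM = seeds_uM, salt_mM = salts_mM,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$seed_uM, grid$salt_mM), , drop = FALSE]
  flat <- grid$salt_mM >= inhibition_threshold_mM
  prod <- ifelse(flat, 0,
                 base_k2kplus * 10^(-decay_per_mM * grid$salt_mM))
  cond <- data.frame(grid,
                     monomer_uM = monomer_uM,
                     n_replicates = n_replicates,
                     k2kplus_true = prod,
                     k_plus = k_plus,
                     k2 = ifelse(flat, 0, prod / k_plus),
                     L_seed = L_seed,
                     flat = flat)
  rownames(cond) <- NULL
  structure(list(conditions = cond, n2 = n2, n_c = n_c, noise = noise,
                 t_end = t_end, dt = dt, rng_seed = rng_seed),
            class = "plate_spec")
}

#' @export
print.plate_spec <- function(x, ...) {
  cat(sprintf(
    "plate_spec: %d conditions x %d replicates, 0..%g h every %g h\n",
    nrow(x$conditions), x$conditions$n_replicates[1], x$t_end, x$dt))
  print(x$conditions[, c("seed_uM", "salt_mM", "k2kplus_true", "flat")],
        digits = 3)
  invisible(x)
}

#' Simulate a ThT plate from a specification
#'
#' The noiseless signal per well is an affine transform of the seeded
#' integrated rate law, \eqn{F(t) = b_w + a_w M_{frac}(t)}; noise is
#' multiplicative plus additive iid Gaussian,
#' \eqn{F = b_w + a_w x (1 + \epsilon_m) + \epsilon_a}.  Flat (inhibited)
#' conditions emit baseline plus noise.  Reproducible for a fixed seed.
#'
#' @param spec A \code{\link{make_salt_series}} specification.
#' @param rng_seed Overrides \code{spec$rng_seed}.
#' @return List of class \code{tht_plate}: \code{plate} (wide data.frame,
#'   first column \code{time_h}), \code{meta} (well metadata) and
#'   \code{truth} (generating parameters per condition).
#' @export
simulate_plate <- function(spec, rng_seed = spec$rng_seed) {
  stopifnot(inherits(spec, "plate_spec"))
  t <- seq(0, spec$t_end, by = spec$dt)
  nz <- spec$noise
  amp_sd <- if (is.null(nz$amplitude_rel_sd)) 0 else nz$amplitude_rel_sd
  base_sd <- if (is.null(nz$baseline_sd)) 0 else nz$baseline_sd
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng_seed)
  plate <- data.frame(time_h = t)
  meta <- NULL
  widx <- 0L
  for (i in seq_len(nrow(spec$conditions))) {
    cnd <- spec$conditions[i, ]
    x <- if (cnd$flat) rep(0, length(t)) else {
      p <- kinetic_params(k_n = 0, k2 = cnd$k2, k_plus = cnd$k_plus,
                          n_c = spec$n_c, n2 = spec$n2,
                          m0 = cnd$monomer_uM * 1e-6,
                          M0 = cnd$seed_uM * 1e-6,
                          P0 = cnd$seed_uM * 1e-6 / cnd$L_seed)
      closed_form_mass(p, t)$M_frac
    }
    for (r in seq_len(cnd$n_replicates)) {
      widx <- widx + 1L
      well <- sprintf("W%03d", widx)
      a_w <- nz$amplitude * (1 + stats::rnorm(1, 0, amp_sd))
      b_w <- nz$baseline + stats::rnorm(1, 0, base_sd)
      F <- b_w + a_w * x * (1 + stats::rnorm(length(t), 0,
                                             nz$multiplicative_sd)) +
        stats::rnorm(length(t), 0, nz$additive_sd)
      plate[[well]] <- F
      meta <- rbind(meta, data.frame(
        well = well, monomer_uM = cnd$monomer_uM, seed_uM = cnd$seed_uM,
        salt_mM = cnd$salt_mM, replicate = r))
    }
  }
  structure(list(plate = plate, meta = meta, truth = spec$conditions,
                 rng_seed = rng_seed),
            class = "tht_plate")
}

# save/restore the global RNG state so generators do not disturb user code
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.tht_plate <- function(x, ...) {
  cat(sprintf("tht_plate: %d wells x %d time points (seed %d)\n",
              ncol(x$plate) - 1L, nrow(x$plate), x$rng_seed))
  invisible(x)
}

#' Monte Carlo fixture configurations
#'
#' Emits the run configurations used by the slit-simulation module:
#' \describe{
#'   \item{full}{208 grafted C-terminal tails at one tail per 1,200 A^2
#'     (box side ~499.6 A), one free full-length chain.}
#'   \item{desk}{32 grafted tails at the same grafting density (box side
#'     ~196 A); the preset for desk-scale runs.}
#'   \item{oracle_single_acid}{a single titratable acidic bead, no
#'     electrostatics partner; titration-only oracle system.}
#'   \item{oracle_free_bead}{a single neutral free bead in the slit;
#'     ideal-gas oracle system.}
#' }
#'
#' @param dir Optional directory; when given, each configuration is also
#'   written as a YAML file and the paths are attached.
#' @param c_salt_M Salt concentration stored in the configs (M).
#' @param pH Solution pH stored in the configs.
#' @return Named list of configuration lists.
#' @export
make_mc_fixtures <- function(dir = NULL, c_salt_M = 0.02, pH = 5.5) {
  base <- list(pH = pH, c_salt = c_salt_M, temperature = 300,
               bjerrum = 7.0, eps_lj = 0.05, sigma = 4.0,
               bond_req = 4.1, bond_k = 0.76, area_per_tail = 1200,
               n_equil = 2000, n_prod = 8000, sample_every = 5,
               runs = 2, seed = 1)
  cfgs <- list(
    full = c(list(preset = "full", n_tails = 208), base),
    desk = c(list(preset = "desk", n_tails = 32), base),
    oracle_single_acid = c(list(preset = "oracle_single_acid",
                                n_tails = 0), base),
    oracle_free_bead = c(list(preset = "oracle_free_bead",
                              n_tails = 0), base))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(cfgs)) {
      path <- file.path(dir, paste0(nm, ".yml"))
      yaml::write_yaml(cfgs[[nm]], path)
      cfgs[[nm]]$path <- path
    }
  }
  cfgs
}
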