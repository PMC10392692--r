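# Constant-pH coarse-grained Monte Carlo of a free monomer above a
# grafted layer of C-terminal tails in a slit.

#' Debye screening length of a 1:1 electrolyte
#'
#' \eqn{\lambda_D = (8 \pi l_B N_A c)^{-1/2}} in Angstrom, with the salt
#' concentration in mol/l.  A concentration of zero returns \code{Inf}
#' (unscreened Coulomb interactions).
#'
#' @param c_salt Salt concentration (M), >= 0.
#' @param bjerrum Bjerrum length (Angstrom), default 7.0 (water, ~300 K).
#' @return Screening length in Angstrom.
#' @examples
#' debye_length(0.1)   # ~9.7 A
#' debye_length(0.02)  # ~21.7 A
#' @export
debye_length <- function(c_salt, bjerrum = 7.0) {
  if (any(c_salt < 0)) stop("salt concentration must be >= 0")
  c_A3 <- c_salt * 6.02214076e-4   # number density in A^-3
  ifelse(c_salt == 0, Inf, 1 / sqrt(8 * pi * bjerrum * c_A3))
}

# grid of anchor positions for n grafted chains on the z = 0 plane
.anchor_grid <- function(n, Lxy) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  nx <- ceiling(sqrt(n))
  ny <- ceiling(n / nx)
  g <- expand.grid(ix = seq_len(nx) - 0.5, iy = seq_len(ny) - 0.5)
  g <- g[seq_len(n), , drop = FALSE]
  cbind(g$ix * Lxy / nx, g$iy * Lxy / ny)
}

# initial tail conformation: vertical runs folded to fit inside the slit,
# every step exactly one bond length (anchor at z = 0)
.tail_fold <- function(L, req, Lz, anchor) {
  x <- numeric(L); z <- numeric(L)
  zc <- 0; xc <- 0; dir <- 1
  for (i in seq_len(L - 1)) {
    znew <- zc + dir * req
    if (znew > 0.9 * Lz || znew < 0.5 * req) {
      xc <- xc + req
      dir <- -dir
    } else zc <- znew
    x[i + 1] <- xc; z[i + 1] <- zc
  }
  cbind(anchor[1] + x, rep(anchor[2], L), z)
}

# compact snake-fold initial placement for the free chain
.snake_fold <- function(n, step, centre) {
  per_row <- max(8L, ceiling(sqrt(n)) * 2L)
  ix <- (seq_len(n) - 1) %% per_row
  iy <- (seq_len(n) - 1) %/% per_row
  x <- ifelse(iy %% 2 == 0, ix, per_row - 1 - ix) * step
  y <- iy * step
  cbind(x - mean(x) + centre[1], y - mean(y) + centre[2],
        rep(centre[3], n))
}

.site_table <- function(seq, pka_set) {
  s <- titratable_sites(seq, pka_set)
  # local bead index per site: terminal pseudo-positions map onto the
  # terminal beads
  s$bead_local <- pmin(pmax(s$position, 1L), length(seq))
  s
}

#' Build a slit system of grafted tails plus one free chain
#'
#' Constructs the coarse-grained system: \code{n_tails} copies of the tail
#' sequence anchored by their N-terminal beads to the \code{z = 0} plane
#' of a slit that is periodic in x and y, plus one free chain.  The box
#' side is set by the grafting density, \eqn{L_{xy} =
#' \sqrt{n_{tails} \cdot a}}, with \eqn{a} the area per tail; the slit
#' height defaults to \eqn{L_z = L_{xy}} (cubic slit).  Beads are one
#' residue each; titratable residues (D, E, H, Y, K, R, C and free
#' termini) carry Henderson-Hasselbalch sites whose protonation
#' fluctuates in the simulation.
#'
#' @param free_seq \code{\link{protein_sequence}} of the free chain
#'   (default: full-length alpha-synuclein fixture); \code{NULL} for none.
#' @param tail_seq Sequence of the grafted tails (default: the C-terminal
#'   tail fixture, grafted N-terminus).
#' @param n_tails Number of grafted chains (208 full scale, 32 desk
#'   scale).
#' @param area_per_tail Grafting area per tail (A^2), default 1200.
#' @param Lz Slit height (A); default equals the box side.
#' @param pH Solution pH.
#' @param c_salt Salt concentration (M).
#' @param temperature Temperature (K); enters only through the quoted
#'   Bjerrum length default.
#' @param bjerrum Bjerrum length (A).
#' @param eps_lj Lennard-Jones interaction strength (kT).
#' @param sigma Bead Lennard-Jones diameter (A).
#' @param bond_req,bond_k Harmonic bond equilibrium length (A) and force
#'   constant (kT/A^2).
#' @param pka_set Intrinsic pKa set, see \code{\link{default_pka_set}}.
#' @param cutoff_el Electrostatic cutoff (A): 0 for none (all minimum
#'   image pairs, the default), a positive number, or \code{"auto"} for
#'   \code{min(6 lambda_D, Lxy/2)} (truncation error below
#'   \eqn{l_B e^{-6}/r} kT per unit-charge pair).
#' @param cutoff_lj Lennard-Jones cutoff (A): 0 for none.
#' @return List of class \code{slit_system} (bead table, site table and
#'   parameters) ready for \code{\link{cpmc_run}}.
#' @export
slit_system <- function(free_seq = asyn_sequence(),
                        tail_seq = asyn_ctail(),
                        n_tails = 32, area_per_tail = 1200,
                        Lz = NULL, pH = 5.5, c_salt = 0.02,
                        temperature = 300, bjerrum = 7.0,
                        eps_lj = 0.05, sigma = 4.0,
                        bond_req = 4.1, bond_k = 0.76,
                        pka_set = default_pka_set(),
                        cutoff_el = 0, cutoff_lj = 0) {
  if (n_tails > 0) stopifnot(inherits(tail_seq, "protein_sequence"))
  if (is.null(free_seq) && n_tails == 0)
    stop("system needs at least one chain")
  Lxy <- if (n_tails > 0) sqrt(n_tails * area_per_tail) else
    sqrt(32 * area_per_tail)
  if (is.null(Lz)) Lz <- Lxy
  lambda <- debye_length(c_salt, bjerrum)
  if (identical(cutoff_el, "auto"))
    cutoff_el <- if (is.finite(lambda)) min(6 * lambda, Lxy / 2) else 0
  anchors <- .anchor_grid(n_tails, Lxy)

  res <- character(0); cx <- cy <- cz <- numeric(0)
  chain <- integer(0); chain_start <- integer(0); chain_len <- integer(0)
  grafted <- logical(0)
  sites <- NULL
  nb <- 0L; nc <- 0L
  add_chain <- function(seqobj, pos, is_grafted) {
    L <- length(seqobj)
    res <<- c(res, as.character(seqobj))
    cx <<- c(cx, pos[, 1]); cy <<- c(cy, pos[, 2]); cz <<- c(cz, pos[, 3])
    chain <<- c(chain, rep(nc, L))
    chain_start <<- c(chain_start, nb)
    chain_len <<- c(chain_len, L)
    grafted <<- c(grafted, is_grafted)
    st <- .site_table(seqobj, pka_set)
    if (nrow(st) > 0) {
      st$bead <- nb + st$bead_local - 1L   # 0-based global bead index
      st$chain <- nc
      sites <<- rbind(sites, st)
    }
    nb <<- nb + L; nc <<- nc + 1L
  }
  if (n_tails > 0) {
    Lt <- length(tail_seq)
    for (k in seq_len(n_tails)) {
      pos <- .tail_fold(Lt, bond_req, Lz, anchors[k, ])
      add_chain(tail_seq, pos, TRUE)
    }
  }
  free_chain <- -1L
  if (!is.null(free_seq)) {
    stopifnot(inherits(free_seq, "protein_sequence"))
    free_chain <- nc
    pos <- .snake_fold(length(free_seq), bond_req,
                       c(Lxy / 2, Lxy / 2, Lz / 2))
    add_chain(free_seq, pos, FALSE)
  }
  if (is.null(sites))
    sites <- data.frame(position = integer(0), residue = character(0),
                        kind = character(0), pKa = numeric(0),
                        charge_protonated = numeric(0),
                        charge_deprotonated = numeric(0),
                        bead_local = integer(0), bead = integer(0),
                        chain = integer(0))
  # deterministic initial protonation from the intrinsic pKa
  sites$prot <- pH < sites$pKa

  structure(list(
    pos = cbind(cx, cy, cz), residue = res, sigma = rep(sigma, nb),
    chain = chain, chain_start = chain_start, chain_len = chain_len,
    grafted = grafted, free_chain = free_chain, sites = sites,
    Lxy = Lxy, Lz = Lz, pH = pH, c_salt = c_salt,
    temperature = temperature, lB = bjerrum, debye = lambda,
    eps_lj = eps_lj, bond_req = bond_req, bond_k = bond_k,
    cutoff_el = cutoff_el, cutoff_lj = cutoff_lj,
    n_tails = n_tails, area_per_tail = area_per_tail),
    class = "slit_system")
}

#' Oracle micro-system with a single titratable bead
#'
#' One free bead carrying one titratable site and no interaction partner:
#' the constant-pH machinery must reproduce the Henderson-Hasselbalch
#' occupancy exactly on this system.
#'
#' @param kind "acid" or "base".
#' @param pKa Intrinsic pKa of the site.
#' @inheritParams slit_system
#' @return A \code{slit_system}.
#' @export
single_site_system <- function(kind = "acid", pKa = 4.4, pH = 5.5,
                               c_salt = 0.02) {
  res <- if (kind == "acid") "E" else "K"
  pka_set <- default_pka_set()
  pka_set[res] <- pKa
  seqobj <- protein_sequence(res, name = paste0("single_", kind),
                             has_free_nterm = FALSE,
                             has_free_cterm = FALSE)
  slit_system(free_seq = seqobj, tail_seq = NULL, n_tails = 0,
              pH = pH, c_salt = c_salt, pka_set = pka_set)
}

#' @export
print.slit_system <- function(x, ...) {
  cat(sprintf(
    "slit_system: %d beads in %d chains (%d grafted), box %.1f x %.1f x %.1f A\n",
    nrow(x$pos), length(x$chain_len), sum(x$grafted), x$Lxy, x$Lxy, x$Lz))
  cat(sprintf("  pH %.2f, %.3g M salt (lambda_D %s A), l_B %.2f A\n",
              x$pH, x$c_salt,
              if (is.finite(x$debye)) sprintf("%.2f", x$debye) else "Inf",
              x$lB))
  if (x$n_tails > 0)
    cat(sprintf("  grafting density 1/%.0f A^-2\n",
                x$Lxy^2 / x$n_tails))
  cat(sprintf("  %d titratable sites\n", nrow(x$sites)))
  invisible(x)
}

# flat list handed to the C++ engine
.sys_to_engine <- function(sys, pos = NULL, prot = NULL) {
  list(pos = if (is.null(pos)) unname(sys$pos) else unname(pos),
       sigma = sys$sigma, chain = as.integer(sys$chain),
       chain_start = as.integer(sys$chain_start),
       chain_len = as.integer(sys$chain_len),
       grafted = sys$grafted, free_chain = as.integer(sys$free_chain),
       site_bead = as.integer(sys$sites$bead),
       site_acid = sys$sites$kind == "acid",
       site_prot = if (is.null(prot)) sys$sites$prot else prot,
       site_pka = as.numeric(sys$sites$pKa),
       Lxy = sys$Lxy, Lz = sys$Lz, lB = sys$lB,
       debye = if (is.finite(sys$debye)) sys$debye else 0,
       eps_lj = sys$eps_lj, bond_k = sys$bond_k,
       bond_req = sys$bond_req, pH = sys$pH,
       cutoff_el = sys$cutoff_el, cutoff_lj = sys$cutoff_lj)
}

#' Screened-Coulomb plus Lennard-Jones pair energy
#'
#' \deqn{u(r) = l_B z_1 z_2 e^{-r/\lambda_D} / r +
#'   4 \epsilon [ (\sigma/r)^{12} - (\sigma/r)^6 ]}
#' in kT, with \eqn{\sigma = (\sigma_1 + \sigma_2)/2}.  Plain R reference
#' implementation (no cutoffs), used directly for small systems and as the
#' independent check of the simulation engine's energies.
#'
#' @param r Separation (A), > 0.
#' @param z1,z2 Charge valencies (e).
#' @param sigma1,sigma2 Bead diameters (A).
#' @param bjerrum Bjerrum length (A).
#' @param debye Screening length (A); \code{Inf} for unscreened.
#' @param eps_lj LJ interaction strength (kT).
#' @return Energy in kT (\code{Inf} at r = 0).
#' @examples
#' pair_energy(9.6, 1, 1, bjerrum = 7, debye = 9.6, sigma1 = 0, sigma2 = 0)
#' @export
pair_energy <- function(r, z1, z2, sigma1 = 4, sigma2 = 4, bjerrum = 7,
                        debye = Inf, eps_lj = 0.05) {
  if (any(r < 0)) stop("separation must be positive")
  scr <- if (is.finite(debye)) exp(-r / debye) else 1
  el <- ifelse(r == 0, Inf, bjerrum * z1 * z2 * scr / r)
  s <- (sigma1 + sigma2) / 2
  lj <- if (s > 0) {
    sr6 <- (s / pmax(r, 1e-300))^6
    4 * eps_lj * (sr6^2 - sr6)
  } else 0
  out <- el + lj
  out[r == 0] <- Inf
  out
}

#' Total energy of a slit-system configuration
#'
#' Sum of nonbonded pair energies (excluding bonded neighbours) plus
#' harmonic bond energies, with minimum-image distances in x and y.  A
#' configuration with any mobile bead outside the slit has infinite
#' energy.  This is the plain-R recomputation oracle for the engine's
#' incrementally updated running energy; \code{engine = TRUE} calls the
#' compiled version instead.
#'
#' @param sys A \code{\link{slit_system}}.
#' @param pos Optional n x 3 coordinate matrix overriding \code{sys$pos}.
#' @param prot Optional logical vector of site protonation states.
#' @param engine Use the compiled energy (default FALSE: plain R).
#' @return Energy in kT.
#' @export
total_energy <- function(sys, pos = NULL, prot = NULL, engine = FALSE) {
  stopifnot(inherits(sys, "slit_system"))
  if (engine) return(.cpmc_total_energy(.sys_to_engine(sys, pos, prot)))
  p <- if (is.null(pos)) sys$pos else pos
  if (is.null(prot)) prot <- sys$sites$prot
  n <- nrow(p)
  q <- numeric(n)
  if (nrow(sys$sites) > 0) {
    qs <- ifelse(sys$sites$kind == "acid",
                 ifelse(prot, 0, -1), ifelse(prot, 1, 0))
    for (k in seq_len(nrow(sys$sites)))
      q[sys$sites$bead[k] + 1L] <- q[sys$sites$bead[k] + 1L] + qs[k]
  }
  anchored <- logical(n)
  for (c in which(sys$grafted)) anchored[sys$chain_start[c] + 1L] <- TRUE
  if (any(!anchored & (p[, 3] <= 0 | p[, 3] >= sys$Lz))) return(Inf)
  mi <- function(d) d - sys$Lxy * round(d / sys$Lxy)
  u <- 0
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    dx <- mi(p[i, 1] - p[j, 1]); dy <- mi(p[i, 2] - p[j, 2])
    dz <- p[i, 3] - p[j, 3]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    bonded <- sys$chain[j] == sys$chain[i] & (j - i) == 1L
    if (any(bonded))
      u <- u + sys$bond_k / 2 * (r[bonded] - sys$bond_req)^2
    nb <- !bonded
    if (any(nb)) {
      rs <- r[nb]
      keep_lj <- if (sys$cutoff_lj > 0) rs < sys$cutoff_lj else
        rep(TRUE, length(rs))
      sr6 <- (sys$sigma[i] / rs)^6   # uniform sigma
      u <- u + sum(4 * sys$eps_lj * (sr6^2 - sr6) * keep_lj)
      qq <- q[i] * q[j[nb]]
      keep_el <- if (sys$cutoff_el > 0) rs < sys$cutoff_el else
        rep(TRUE, length(rs))
      scr <- if (is.finite(sys$debye)) exp(-rs / sys$debye) else 1
      u <- u + sum(sys$lB * qq * scr / rs * keep_el)
    }
  }
  u
}

#' Run the constant-pH Monte Carlo simulation
#'
#' Samples the canonical ensemble of a \code{\link{slit_system}} with
#' Metropolis Monte Carlo.  One sweep comprises, on average, one
#' single-bead translation attempt per mobile bead, one rigid
#' translation/rotation per chain (rotation about the anchor for grafted
#' chains), one pivot rotation around a randomly selected bond per chain,
#' and one titration swap attempt per titratable site.  Step sizes are
#' auto-tuned to 30-50 per cent acceptance during equilibration, then
#' frozen.  By default two independent runs (derived seeds) are performed
#' so that observable profiles carry a run-to-run spread.
#'
#' @param sys A \code{\link{slit_system}}.
#' @param n_equil,n_prod Equilibration and production sweeps.
#' @param sample_every Production sampling interval (sweeps).
#' @param seed Integer seed; run r uses \code{seed + r - 1}.
#' @param runs Number of independent runs (>= 1; 2 for spread).
#' @param moves Named list overriding the move set: \code{d_bead},
#'   \code{d_chain} (A), \code{d_rot} (rad), \code{p_teleport} (fraction
#'   of free-chain rigid moves proposed as a symmetric global re-placement
#'   of the mass centre in the slit, which exchanges adsorbed and bulk
#'   states), logical \code{do_bead}, \code{do_chain}, \code{do_pivot},
#'   \code{do_titration}, \code{tune}.
#' @return Object of class \code{cpmc_run}: \code{runs} is a list with
#'   one element per independent run (\code{samples} data.frame with
#'   z_cm, dipole components, net charges and energy; \code{site_frac_prot};
#'   \code{move_stats}; \code{drift_max}; final \code{pos}), plus the
#'   originating \code{sys}.
#' @export
cpmc_run <- function(sys, n_equil = 2000, n_prod = 8000, sample_every = 5,
                     seed = 1, runs = 2, moves = list()) {
  stopifnot(inherits(sys, "slit_system"))
  mv <- list(d_bead = 3, d_chain = min(20, sys$Lxy / 8), d_rot = 0.8,
             p_teleport = 0.2, do_bead = TRUE, do_chain = TRUE,
             do_pivot = TRUE, do_titration = TRUE, tune = TRUE)
  mv[names(moves)] <- moves
  out_runs <- vector("list", runs)
  for (r in seq_len(runs)) {
    eng <- .cpmc_engine(.sys_to_engine(sys), as.integer(n_equil),
                        as.integer(n_prod), as.integer(sample_every),
                        as.double(seed + r - 1), mv)
    smp <- as.data.frame(eng$samples)
    if (eng$drift_max > 1e-4)
      stop(sprintf(
        "energy bookkeeping drift %.3g kT exceeds tolerance; aborting",
        eng$drift_max))
    out_runs[[r]] <- list(samples = smp,
                          site_frac_prot = eng$site_frac_prot,
                          site_prot_final = eng$site_prot_final,
                          move_stats = eng$move_stats,
                          energy = eng$energy,
                          drift_max = eng$drift_max,
                          pos = eng$pos, steps = eng$steps,
                          seed = seed + r - 1)
  }
  structure(list(runs = out_runs, sys = sys, n_equil = n_equil,
                 n_prod = n_prod, sample_every = sample_every,
                 seed = seed, moves = mv),
            class = "cpmc_run")
}

#' @export
print.cpmc_run <- function(x, ...) {
  cat(sprintf(
    "cpmc_run: %d run(s) of %d + %d sweeps (sampled every %d), seed %d\n",
    length(x$runs), x$n_equil, x$n_prod, x$sample_every, x$seed))
  cat(sprintf("  system: %d beads, pH %.2f, %.3g M salt\n",
              nrow(x$sys$pos), x$sys$pH, x$sys$c_salt))
  for (r in seq_along(x$runs))
    cat(sprintf("  run %d: %d samples, max drift %.2g kT\n", r - 1,
                nrow(x$runs[[r]]$samples), x$runs[[r]]$drift_max))
  invisible(x)
}

#' @export
summary.cpmc_run <- function(object, ...) {
  ms <- do.call(rbind, lapply(seq_along(object$runs), function(r) {
    s <- object$runs[[r]]$move_stats
    s$run <- r - 1
    s$acceptance <- s$accepts / pmax(s$attempts, 1)
    s
  }))
  zq <- do.call(rbind, lapply(seq_along(object$runs), function(r) {
    s <- object$runs[[r]]$samples
    data.frame(run = r - 1, mean_z_cm = mean(s$z_cm),
               mean_q_free = mean(s$q_free),
               mean_q_tails = mean(s$q_tails),
               mean_energy = mean(s$energy))
  }))
  out <- list(move_stats = ms, run_means = zq)
  class(out) <- "summary.cpmc_run"
  out
}

#' @export
print.summary.cpmc_run <- function(x, ...) {
  cat("move statistics:\n"); print(x$move_stats, digits = 3)
  cat("run means:\n"); print(x$run_means, digits = 4)
  invisible(x)
}

#' @export
plot.cpmc_run <- function(x, ...) {
  gz <- gz_profile(x)
  plot(gz, ...)
  invisible(x)
}

#' Write trajectory outputs of a run
#'
#' Writes, per independent run, the final configuration as an XYZ file
#' and the sample series as TSV (sample index, z_cm, dipole components,
#' net charges, energy).
#'
#' @param run A \code{\link{cpmc_run}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_trajectory <- function(run, dir) {
  stopifnot(inherits(run, "cpmc_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (r in seq_along(run$runs)) {
    rr <- run$runs[[r]]
    xyz <- file.path(dir, sprintf("run-%d.xyz", r - 1))
    n <- nrow(rr$pos)
    lines <- c(as.character(n),
               sprintf("final configuration, run %d, seed %d", r - 1,
                       rr$seed),
               sprintf("%s %.4f %.4f %.4f", run$sys$residue,
                       rr$pos[, 1], rr$pos[, 2], rr$pos[, 3]))
    writeLines(lines, xyz)
    tsv <- file.path(dir, sprintf("run-%d-samples.tsv", r - 1))
    utils::write.table(rr$samples, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, xyz, tsv)
  }
  invisible(paths)
}
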