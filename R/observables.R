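# Trajectory-derived observables: mass-centre density g(z) relative to
# bulk, dipole moments and orientation profiles, and average net charges,
# each with run-to-run spread.

.zbins <- function(Lz, bin_width) {
  edges <- seq(0, Lz, by = bin_width)
  if (edges[length(edges)] < Lz) edges <- c(edges, Lz)
  edges
}

# per-run binned mean of a quantity against z; weight = NULL counts
.bin_stat <- function(z, value, edges) {
  idx <- findInterval(z, edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1; idx[idx > length(edges) - 1] <- length(edges) - 1
  n <- tabulate(idx, nbins = length(edges) - 1)
  s <- rep(NA_real_, length(edges) - 1)
  agg <- tapply(value, factor(idx, levels = seq_len(length(edges) - 1)),
                mean)
  s[!is.na(agg)] <- agg[!is.na(agg)]
  list(n = n, mean = s)
}

#' Mass-centre density profile relative to bulk
#'
#' Histogram of the free-chain mass-centre height above the grafting
#' surface, normalised by the mean density in the bulk slab
#' \eqn{z \in [0.7, 0.9] L_z} so the far field tends to 1.  Computed per
#' independent run; the returned profile holds the across-run mean and
#' standard deviation.
#'
#' @param run A \code{\link{cpmc_run}} (or a list of per-run z-sample
#'   vectors, in which case \code{Lz} must be given).
#' @param bin_width Bin width (A), default 5.
#' @param Lz Slit height (A); taken from the run if omitted.
#' @param bulk Fractional z-range used as the bulk slab, default
#'   \code{c(0.7, 0.9)}.
#' @param bulk_pseudocount When the chain is so strongly adsorbed that no
#'   sample falls in the bulk slab, the density ratio is undefined and the
#'   default is an error.  With \code{bulk_pseudocount = TRUE} the bulk
#'   density is instead floored at one sample per slab, making the
#'   returned profile a conservative lower bound on g(z) (attribute
#'   \code{lower_bound} set when the floor was active).
#' @return data.frame of class \code{z_profile}: \code{z_mid},
#'   \code{value}, \code{spread}, \code{n} (total samples per bin).
#' @export
gz_profile <- function(run, bin_width = 5, Lz = NULL,
                       bulk = c(0.7, 0.9), bulk_pseudocount = FALSE) {
  zs <- .extract_runs(run, "z")
  if (is.null(Lz)) Lz <- attr(zs, "Lz")
  edges <- .zbins(Lz, bin_width)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  widths <- diff(edges)
  floored <- FALSE
  per_run <- lapply(zs, function(z) {
    n_tot <- length(z)
    if (n_tot < 1) stop("no samples")
    b <- .bin_stat(z, rep(1, length(z)), edges)
    dens <- b$n / (widths * n_tot)            # probability density in z
    in_bulk <- mids >= bulk[1] * Lz & mids <= bulk[2] * Lz
    if (!any(in_bulk)) stop("empty bulk slab; shrink bin_width")
    n_bulk <- sum(b$n[in_bulk])
    if (n_bulk == 0) {
      if (!bulk_pseudocount) stop("no samples in the bulk slab")
      n_bulk <- 1
      floored <<- TRUE
    }
    bulk_dens <- n_bulk / (sum(widths[in_bulk]) * n_tot)
    list(g = dens / bulk_dens, n = b$n)
  })
  g <- matrix(sapply(per_run, `[[`, "g"), nrow = length(mids))
  n <- rowSums(matrix(sapply(per_run, `[[`, "n"), nrow = length(mids)))
  out <- data.frame(z_mid = mids,
                    value = rowMeans(g),
                    spread = if (ncol(g) > 1) apply(g, 1, stats::sd)
                             else rep(0, length(mids)),
                    n = n)
  class(out) <- c("z_profile", "data.frame")
  attr(out, "observable") <- "g(z)"
  attr(out, "lower_bound") <- floored
  out
}

#' Molecular dipole moment of a configuration
#'
#' \eqn{\mu = \sum_i q_i (r_i - r_{cm})} with the mass centre of the
#' (equal-mass) beads as reference.
#'
#' @param pos n x 3 coordinate matrix (A).
#' @param q Charge valencies (e).
#' @return List with \code{mu} (length-3 vector, e*A) and \code{norm}.
#' @examples
#' dipole_moment(rbind(c(0, 0, 1), c(0, 0, -1)), c(1, -1))$mu  # (0, 0, 2)
#' @export
dipole_moment <- function(pos, q) {
  pos <- matrix(pos, ncol = 3)
  stopifnot(nrow(pos) == length(q))
  cm <- colMeans(pos)
  mu <- colSums(q * sweep(pos, 2, cm))
  list(mu = mu, norm = sqrt(sum(mu^2)))
}

#' Dipole alignment with the surface normal
#'
#' The orientation order parameter \eqn{(\mu \cdot \hat n)/|\mu|}, where
#' \eqn{\hat n} is the unit normal pointing from the solution toward the
#' grafting surface (the \eqn{-z} direction).  It is the cosine of the
#' angle between dipole and inward normal: +1 when the positive end of
#' the molecule points at the surface, bounded by 1 in magnitude.
#'
#' @param mu Dipole vector (length 3) or an n x 3 matrix of dipoles.
#' @return Numeric in [-1, 1]; \code{NA} for zero dipoles.
#' @examples
#' dipole_alignment(c(0, 0, -2))  # 1: dipole points at the surface
#' @export
dipole_alignment <- function(mu) {
  mu <- matrix(mu, ncol = 3)
  nrm <- sqrt(rowSums(mu^2))
  out <- -mu[, 3] / nrm
  out[nrm == 0] <- NA_real_
  out
}

#' Dipole-orientation profile against distance from the surface
#'
#' Per z-bin mean of the alignment \eqn{(\mu \cdot \hat n)/|\mu|} of the
#' free chain, with across-run spread.  Samples with zero dipole are
#' excluded.
#'
#' @inheritParams gz_profile
#' @return data.frame of class \code{z_profile} (columns as in
#'   \code{\link{gz_profile}}).
#' @export
alignment_profile <- function(run, bin_width = 5, Lz = NULL) {
  dat <- .extract_runs(run, "align")
  if (is.null(Lz)) Lz <- attr(dat, "Lz")
  edges <- .zbins(Lz, bin_width)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  per_run <- lapply(dat, function(d) {
    keep <- !is.na(d$a)
    .bin_stat(d$z[keep], d$a[keep], edges)
  })
  a <- matrix(sapply(per_run, `[[`, "mean"), nrow = length(mids))
  n <- rowSums(matrix(sapply(per_run, `[[`, "n"), nrow = length(mids)))
  out <- data.frame(z_mid = mids,
                    value = rowMeans(a, na.rm = TRUE),
                    spread = if (ncol(a) > 1)
                      apply(a, 1, stats::sd, na.rm = TRUE)
                    else rep(0, length(mids)),
                    n = n)
  out$value[is.nan(out$value)] <- NA_real_
  class(out) <- c("z_profile", "data.frame")
  attr(out, "observable") <- "alignment"
  out
}

#' Maximum of an orientation or density profile
#'
#' The profile maximum over bins with adequate sampling (at least
#' \code{min_n} samples), used e.g. for the peak alignment of a run.
#'
#' @param profile A \code{z_profile}.
#' @param min_n Minimum per-bin sample count, default 20.
#' @return Numeric scalar.
#' @export
profile_max <- function(profile, min_n = 20) {
  ok <- profile$n >= min_n & is.finite(profile$value)
  if (!any(ok)) stop("no bin has enough samples")
  max(profile$value[ok])
}

#' Average net charges of the free chain and the grafted tails
#'
#' Time-averaged net charge per species with across-run spread.
#'
#' @param run A \code{\link{cpmc_run}} with at least one run (two for a
#'   meaningful spread).
#' @return data.frame with columns \code{species}, \code{mean_net_charge},
#'   \code{spread}, \code{c_salt}, \code{pH}.
#' @export
charge_summary <- function(run) {
  stopifnot(inherits(run, "cpmc_run"))
  qf <- vapply(run$runs, function(r) mean(r$samples$q_free), numeric(1))
  qt <- vapply(run$runs, function(r) mean(r$samples$q_tails), numeric(1))
  sp <- function(v) if (length(v) > 1) stats::sd(v) else 0
  out <- data.frame(
    species = c("free-chain", "grafted-tail"),
    mean_net_charge = c(mean(qf), mean(qt)),
    spread = c(sp(qf), sp(qt)),
    c_salt = run$sys$c_salt, pH = run$sys$pH)
  if (run$sys$n_tails == 0) out <- out[1, , drop = FALSE]
  if (run$sys$free_chain < 0) out <- out[out$species != "free-chain", ,
                                         drop = FALSE]
  out
}

#' @export
plot.z_profile <- function(x, ...) {
  graphics::plot(x$z_mid, x$value, type = "l",
                 xlab = "z (A)", ylab = attr(x, "observable"), ...)
  ok <- x$spread > 0
  if (any(ok)) {
    graphics::arrows(x$z_mid[ok], x$value[ok] - x$spread[ok],
                     x$z_mid[ok], x$value[ok] + x$spread[ok],
                     angle = 90, code = 3, length = 0.02, col = "grey50")
  }
  invisible(x)
}

#' Write a z-profile as TSV
#'
#' @param profile A \code{z_profile}.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_profile <- function(profile, file) {
  utils::write.table(profile, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

# pull per-run z samples / alignment samples out of a cpmc_run or a
# plain list of sample vectors
.extract_runs <- function(run, what) {
  if (inherits(run, "cpmc_run")) {
    Lz <- run$sys$Lz
    out <- lapply(run$runs, function(r) {
      s <- r$samples
      if (what == "z") s$z_cm
      else data.frame(z = s$z_cm,
                      a = dipole_alignment(cbind(s$mux, s$muy, s$muz)))
    })
    attr(out, "Lz") <- Lz
    out
  } else {
    if (!is.list(run)) run <- list(run)
    if (what == "align") {
      stopifnot(all(vapply(run, is.data.frame, TRUE)))
    }
    run
  }
}
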