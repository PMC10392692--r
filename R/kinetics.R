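# Forward model of seeded amyloid aggregation: moment ODEs for primary
# nucleation, elongation and secondary nucleation, the integrated rate law,
# and half-time extraction.
#
# Units: concentrations in M, time in h.  Rate constants:
#   k_n  M^(1-nc) h^-1   primary nucleation
#   k2   M^(-n2)  h^-1   secondary nucleation
#   kp   M^-1     h^-1   elongation
# The fibril mass concentration M is in monomer equivalents; m_tot = m0 + M0
# is conserved.

#' Kinetic parameter set for the aggregation model
#'
#' @param k_n Primary nucleation rate constant (conc^(1-n_c) h^-1).
#' @param k2 Secondary nucleation rate constant (conc^(-n2) h^-1).
#' @param k_plus Elongation rate constant (M^-1 h^-1).
#' @param n_c,n2 Reaction orders of primary and secondary nucleation
#'   (dimensionless, >= 1).  Defaults 2 and 2.
#' @param m0 Initial free monomer concentration (M).
#' @param M0 Initial fibril mass concentration in monomer equivalents (M).
#' @param P0 Initial fibril number concentration (M).  Seeds must carry both
#'   mass and number: \code{P0 == 0} iff \code{M0 == 0}.
#' @return A list of class \code{kinetic_params}.
#' @export
kinetic_params <- function(k_n = 0, k2, k_plus, n_c = 2, n2 = 2,
                           m0, M0 = 0, P0 = 0) {
  stopifnot(k_n >= 0, k2 >= 0, k_plus >= 0, n_c >= 1, n2 >= 1,
            m0 > 0, M0 >= 0, P0 >= 0)
  if ((M0 == 0) != (P0 == 0))
    stop("P0 must be zero exactly when M0 is zero")
  structure(list(k_n = k_n, k2 = k2, k_plus = k_plus, n_c = n_c, n2 = n2,
                 m0 = m0, M0 = M0, P0 = P0, m_tot = m0 + M0),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("kinetic_params:\n")
  cat(sprintf("  k_n = %.3g, k2 = %.3g, k_plus = %.3g (n_c = %g, n2 = %g)\n",
              x$k_n, x$k2, x$k_plus, x$n_c, x$n2))
  cat(sprintf("  m0 = %.3g M, M0 = %.3g M, P0 = %.3g M\n", x$m0, x$M0, x$P0))
  invisible(x)
}

#' Auxiliary rate combinations of the integrated rate law
#'
#' Evaluates the combinations entering the generalized-logistic integrated
#' rate law for aggregation with secondary nucleation:
#' \deqn{\kappa = \sqrt{2 k_+ k_2 m(0)^{n_2+1}}, \quad
#'       \lambda = \sqrt{2 k_+ k_n m(0)^{n_c}},}
#' \deqn{C_\pm = \pm \lambda^2/(2\kappa^2), \quad
#'       k_\infty = \sqrt{2\kappa^2/[n_2(n_2+1)] + 2\lambda^2/n_c},}
#' \deqn{\bar k_\infty = \sqrt{k_\infty^2 - 4 C_+ C_- \kappa^2}, \quad
#'       B_\pm = (k_\infty \pm \bar k_\infty)/(2\kappa).}
#' Here \eqn{m(0)} is the initial free monomer concentration.  These
#' definitions carry no seed terms; in the seeded limit \eqn{k_n = 0} they
#' give \eqn{\lambda = 0}, \eqn{C_\pm = 0}, \eqn{\bar k_\infty = k_\infty}
#' and \eqn{B_- = 0}.
#'
#' @param p A \code{\link{kinetic_params}} object.
#' @return List of class \code{derived_rates} with elements \code{kappa},
#'   \code{lam}, \code{B_plus}, \code{B_minus}, \code{C_plus},
#'   \code{C_minus}, \code{k_inf}, \code{k_inf_bar} (rates in h^-1,
#'   B and C dimensionless).
#' @export
derived_rates <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  kappa <- sqrt(2 * p$k_plus * p$k2 * p$m0^(p$n2 + 1))
  lam <- sqrt(2 * p$k_plus * p$k_n * p$m0^p$n_c)
  C_plus <- lam^2 / (2 * kappa^2)
  C_minus <- -C_plus
  k_inf <- sqrt(2 * kappa^2 / (p$n2 * (p$n2 + 1)) + 2 * lam^2 / p$n_c)
  rad <- k_inf^2 - 4 * C_plus * C_minus * kappa^2
  if (rad < 0) stop("internal error: negative radicand in k_inf_bar")
  k_inf_bar <- sqrt(rad)
  structure(list(kappa = kappa, lam = lam,
                 B_plus = (k_inf + k_inf_bar) / (2 * kappa),
                 B_minus = (k_inf - k_inf_bar) / (2 * kappa),
                 C_plus = C_plus, C_minus = C_minus,
                 k_inf = k_inf, k_inf_bar = k_inf_bar),
            class = "derived_rates")
}

#' @export
print.derived_rates <- function(x, ...) {
  cat("derived_rates (h^-1 unless dimensionless):\n")
  for (nm in names(x)) cat(sprintf("  %-10s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' Numerical integration of the moment equations
#'
#' Integrates
#' \deqn{dP/dt = k_n m^{n_c} + k_2 m^{n_2} M, \qquad dM/dt = 2 k_+ m P}
#' with \eqn{m = m_{tot} - M}, from \eqn{(P_0, M_0)}, using a stiff-capable
#' integrator (lsoda, relative tolerance 1e-8).  Mass is conserved by
#' construction; the returned curve reports the fibril mass fraction
#' \eqn{M(t)/m_{tot}}.
#'
#' @param p A \code{\link{kinetic_params}} object.
#' @param t_grid Increasing time grid starting at 0 (h).
#' @param rtol Relative tolerance of the integrator.
#' @return data.frame of class \code{mass_curve} with columns \code{t},
#'   \code{M_frac} and \code{P} (fibril number concentration, M).
#' @export
moment_odes <- function(p, t_grid, rtol = 1e-8) {
  stopifnot(inherits(p, "kinetic_params"))
  if (t_grid[1] != 0 || any(diff(t_grid) <= 0))
    stop("t_grid must increase from 0")
  mtot <- p$m_tot
  rhs <- function(t, y, parms) {
    m <- max(mtot - y[2], 0)
    list(c(p$k_n * m^p$n_c + p$k2 * m^p$n2 * y[2],
           2 * p$k_plus * m * y[1]))
  }
  sol <- deSolve::ode(c(P = p$P0, M = p$M0), t_grid, rhs, parms = NULL,
                      method = "lsoda", rtol = rtol,
                      atol = c(1e-16 * max(p$P0, 1e-12), 1e-12 * mtot))
  if (attr(sol, "istate")[1] < 0)
    stop("stiff integration failed; retry with a larger rtol ",
         "(current rtol = ", rtol, ")")
  out <- data.frame(t = sol[, "time"],
                    M_frac = pmin(pmax(sol[, "M"] / mtot, 0), 1),
                    P = sol[, "P"])
  class(out) <- c("mass_curve", "data.frame")
  out
}

# Exact first integral of the seeded (k_n = 0) model:
#   kp * P(M)^2 = kp * P0^2 + k2 * \int_{M0}^{M} (mtot-u)^{n2-1} u du
# The integral equals mtot^(n2+1) * [G(x) - G(x0)] with x = M/mtot and
# G(x) = Beta(2, n2) * pbeta(x, 2, n2).
.seeded_P_of_x <- function(x, p) {
  mtot <- p$m_tot
  G <- function(z) beta(2, p$n2) * stats::pbeta(z, 2, p$n2)
  x0 <- p$M0 / mtot
  J <- mtot^(p$n2 + 1) * (G(x) - G(x0))
  sqrt(pmax(p$P0^2 + (p$k2 / p$k_plus) * J, 0))
}

# Exact integrated rate law for k_n = 0, evaluated by quadrature of
# dt = du / (2 kp P) with u = -log(1 - x) and inverted by interpolation.
.closed_form_seeded <- function(p, t_grid, n_panel = 4000L, eps = 1e-9) {
  mtot <- p$m_tot
  x0 <- p$M0 / mtot
  if (p$P0 <= 0)                       # no seeds, no primary: nothing grows
    return(rep(x0, length(t_grid)))
  u0 <- -log1p(-x0)
  umax <- -log(eps)
  # geometric grid: the integrand 1/(2 kp P) decays over many orders of
  # magnitude just above u0 (P ~ P0 there), so cluster nodes at the start
  u <- u0 + (umax - u0) * c(0, 10^seq(-14, 0, length.out = n_panel))
  Pu <- .seeded_P_of_x(-expm1(-u), p)
  f <- 1 / (2 * p$k_plus * Pu)         # dt/du, smooth and monotone
  tu <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * diff(u)))
  k_end <- 2 * p$k_plus * Pu[length(Pu)]   # ~ 2 kp P(inf): tail rate
  x_of_t <- numeric(length(t_grid))
  inside <- t_grid <= tu[length(tu)]
  if (any(inside)) {
    ui <- stats::approx(tu, u, xout = t_grid[inside], rule = 2)$y
    x_of_t[inside] <- -expm1(-ui)
  }
  if (any(!inside)) {                  # exponential tail beyond the grid
    dt <- t_grid[!inside] - tu[length(tu)]
    x_of_t[!inside] <- 1 - eps * exp(-k_end * dt)
  }
  x_of_t
}

# Generalized-logistic integrated rate law (the fitted plate-reader
# equation).  Seeds enter through the initial mass fraction and through the
# growing-mode amplitude and terminal rate; accuracy is ~1e-3..1e-2 in mass
# fraction, see closed_form_mass().
.closed_form_logistic <- function(p, t_grid) {
  mtot <- p$m_tot
  x0 <- p$M0 / mtot
  d <- derived_rates(p)
  kap <- d$kappa
  if (kap <= 0)
    stop("the logistic form requires k2 > 0 and k_plus > 0")
  # growing/decaying mode amplitudes including seed mass and number
  Cp <- x0 / 2 + p$k_plus * p$P0 / kap + d$C_plus
  Cm <- x0 / 2 - p$k_plus * p$P0 / kap + d$C_minus
  # terminal rate 2 kp P(inf); seed number adds in quadrature
  if (Cp <= 0) return(rep(x0, length(t_grid)))  # nothing nucleates or grows
  kinf <- sqrt(d$k_inf^2 + (2 * p$k_plus * p$P0)^2)
  kbar <- sqrt(kinf^2 - 4 * Cp * Cm * kap^2)
  Bp <- (kinf + kbar) / (2 * kap)
  Bm <- (kinf - kbar) / (2 * kap)
  # log-space evaluation guards overflow of exp(kappa * t); B_minus may be
  # (slightly) negative in the seeded extension, so factor out Cp*exp(kt)
  lekt <- kap * t_grid
  log_num <- log(Cp) + lekt + log1p((Bm / Cp) * exp(-lekt))
  log_den <- log(Cp) + lekt + log1p((Bp / Cp) * exp(-lekt))
  logg <- log_num - log_den + log(Bp + Cp) - log(Bm + Cp)
  pmin(pmax(1 - (1 - x0) *
              exp(-kinf * t_grid + (kinf^2 / (kap * kbar)) * logg), 0), 1)
}

#' Integrated rate law for aggregation with secondary nucleation
#'
#' Evaluates the fibril mass fraction \eqn{M(t)/m_{tot}} of the
#' nucleation-elongation-secondary-nucleation model without integrating the
#' moment equations.
#'
#' For the seeded model (\code{k_n = 0}, the case fitted to seeded
#' plate-reader data) the conservation law yields an exact first integral
#' \eqn{P(M)} and the rate law separates; \code{method = "exact"} evaluates
#' this integrated rate law by high-resolution quadrature and matches
#' \code{\link{moment_odes}} to better than 1e-5 in mass fraction.
#'
#' \code{method = "logistic"} evaluates the generalized-logistic closed
#' form built from \code{\link{derived_rates}} (the equation used to fit
#' plate-reader traces), extended to seeded initial conditions through the
#' initial mass fraction, the growing-mode amplitude
#' \eqn{C_\pm \to x_0/2 \pm k_+P_0/\kappa + C_\pm} and the terminal rate
#' \eqn{k_\infty \to \sqrt{k_\infty^2 + (2k_+P_0)^2}}.  It is an
#' early-time-linearised approximation, accurate to about 1e-3..1e-2 in
#' mass fraction, and is the only option when \code{k_n > 0}.
#'
#' @param p A \code{\link{kinetic_params}} object.
#' @param t_grid Increasing time grid from 0 (h).
#' @param method "exact" (default; requires \code{k_n = 0}) or "logistic".
#' @return data.frame of class \code{mass_curve} with columns \code{t} and
#'   \code{M_frac}.
#' @export
closed_form_mass <- function(p, t_grid, method = c("exact", "logistic")) {
  stopifnot(inherits(p, "kinetic_params"))
  method <- match.arg(method)
  if (method == "exact" && p$k_n > 0)
    stop("the exact integrated rate law requires k_n = 0; ",
         "use method = 'logistic' or moment_odes()")
  x <- if (method == "exact") .closed_form_seeded(p, t_grid)
       else .closed_form_logistic(p, t_grid)
  out <- data.frame(t = t_grid, M_frac = x)
  class(out) <- c("mass_curve", "data.frame")
  out
}

#' @export
plot.mass_curve <- function(x, ...) {
  graphics::plot(x$t, x$M_frac, type = "l", xlab = "time (h)",
                 ylab = "fibril mass fraction", ylim = c(0, 1), ...)
  invisible(x)
}

#' Half time of an aggregation trace
#'
#' The time at which a trace first reaches 50 per cent of its amplitude
#' (baseline + 0.5 * amplitude), linearly interpolated between the
#' bracketing samples of the first upward crossing.  For a
#' \code{mass_curve} the baseline is \code{M_frac[1]} and the amplitude the
#' total rise; for a numeric trace supply \code{baseline}/\code{amplitude}
#' or let them default to the first value and the total range.
#'
#' @param curve A \code{mass_curve}, or a numeric vector of responses.
#' @param t Time grid (required when \code{curve} is a bare numeric).
#' @param baseline,amplitude Optional baseline and amplitude overriding the
#'   defaults.
#' @return Half time in h, or \code{NA_real_} when the trace never reaches
#'   the 50 per cent level (flat or incomplete traces).
#' @examples
#' tt <- seq(0, 10, 0.1)
#' half_time(1 / (1 + exp(-(tt - 5))), tt)  # 5
#' @export
half_time <- function(curve, t = NULL, baseline = NULL, amplitude = NULL) {
  if (inherits(curve, "mass_curve")) {
    y <- curve$M_frac; t <- curve$t
  } else {
    y <- as.numeric(curve)
    if (is.null(t)) stop("t must be supplied for a numeric trace")
  }
  if (is.null(baseline)) baseline <- y[1]
  if (is.null(amplitude)) amplitude <- max(y) - baseline
  if (!is.finite(amplitude) || amplitude <= 0) return(NA_real_)
  level <- baseline + 0.5 * amplitude
  above <- y >= level
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1L) return(t[1])
  t[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
}
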