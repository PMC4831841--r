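# Growth-stretch evolution: the three growth laws, the Lubarda-Hoger
# limiter, mass sources for solid-only vs solid/fluid growth, porosity after
# growth and deformation, porosity admissibility bounds, and the per-element
# backward-Euler local Newton update.

#' Growth-law parameter set
#'
#' @param law One of `"time_linear"` (constant rate `alpha`),
#'   `"concentration"` (driver `c - c_thresh`) or `"stress"` (driver
#'   `tr(M^eff,e)`, the trace of the effective, elastic Mandel stress).
#' @param alpha Constant growth rate (1/s), time-linear law only.
#' @param tau_plus,tau_minus Relaxation scales of the limiter for growth and
#'   resorption (s per driver unit); positive.
#' @param gamma_plus,gamma_minus Limiter exponents, `>= 1`.
#' @param theta_max,theta_min Bounds on the growth stretch;
#'   `theta_min < 1 < theta_max`.
#' @param c_thresh Concentration threshold (mol/m^3), concentration law only.
#' @return A `gmphets_growth_law` list.
#' @export
growth_law_params <- function(law = c("time_linear", "concentration", "stress"),
                              alpha = 0.0008,
                              tau_plus = 200, tau_minus = tau_plus,
                              gamma_plus = 2, gamma_minus = 3,
                              theta_max = 1.2, theta_min = 0.8,
                              c_thresh = 0.009185) {
  law <- match.arg(law)
  if (law != "time_linear") {
    if (!(theta_min < 1 && 1 < theta_max))
      gmphets_stop("need theta_min < 1 < theta_max", "parameter_error")
    if (tau_plus <= 0 || tau_minus <= 0)
      gmphets_stop("tau_plus, tau_minus must be positive", "parameter_error")
    if (gamma_plus < 1 || gamma_minus < 1)
      gmphets_stop("gamma_plus, gamma_minus must be >= 1", "parameter_error")
  }
  structure(list(law = law, alpha = alpha, tau_plus = tau_plus,
                 tau_minus = tau_minus, gamma_plus = gamma_plus,
                 gamma_minus = gamma_minus, theta_max = theta_max,
                 theta_min = theta_min, c_thresh = c_thresh),
            class = "gmphets_growth_law")
}

#' Growth-rate limiter k_theta
#'
#' Lubarda-Hoger style limiter preventing unbounded growth:
#' `(1/tau+) ((theta_max - theta)/(theta_max - 1))^gamma+` for a positive
#' driver, the mirrored expression with `tau-`, `gamma-`, `theta_min` for a
#' negative driver, and 0 for a zero driver.
#'
#' @param theta Growth stretch, inside `[theta_min, theta_max]`. Vectorised.
#' @param driver_sign Sign of the growth driver (`phi_g`). Vectorised.
#' @param p A `gmphets_growth_law`.
#' @return `k_theta` values (1/s per driver unit).
#' @export
k_theta <- function(theta, driver_sign, p) {
  if (any(theta < p$theta_min - 1e-12 | theta > p$theta_max + 1e-12))
    gmphets_stop("theta outside [theta_min, theta_max]", "admissibility_error")
  theta <- pmin(pmax(theta, p$theta_min), p$theta_max)
  out <- numeric(length(theta))
  s <- sign(driver_sign)
  up <- s > 0
  dn <- s < 0
  out[up] <- (1 / p$tau_plus) *
    ((p$theta_max - theta[up]) / (p$theta_max - 1))^p$gamma_plus
  out[dn] <- (1 / p$tau_minus) *
    ((theta[dn] - p$theta_min) / (1 - p$theta_min))^p$gamma_minus
  out
}

# derivative of k_theta wrt theta on the active branch
k_theta_dtheta <- function(theta, driver_sign, p) {
  out <- numeric(length(theta))
  s <- sign(driver_sign)
  up <- s > 0; dn <- s < 0
  out[up] <- -(p$gamma_plus / p$tau_plus) / (p$theta_max - 1) *
    ((p$theta_max - theta[up]) / (p$theta_max - 1))^(p$gamma_plus - 1)
  out[dn] <- (p$gamma_minus / p$tau_minus) / (1 - p$theta_min) *
    ((theta[dn] - p$theta_min) / (1 - p$theta_min))^(p$gamma_minus - 1)
  out
}

#' Exact update for the time-linear growth law
#'
#' `theta_{n+1} = theta_n + alpha * dt`; the finite-difference update is
#' exact because the rate is constant.
#'
#' @param theta_n Growth stretch at the start of the step. Vectorised.
#' @param alpha Growth rate (1/s).
#' @param dt Time step (s), positive.
#' @return Updated growth stretch.
#' @export
theta_update_linear <- function(theta_n, alpha, dt) {
  if (dt <= 0) gmphets_stop("dt must be positive", "parameter_error")
  theta_n + alpha * dt
}

#' Backward-Euler local Newton update of the growth stretch
#'
#' Solves `R(theta) = theta - theta_n - dt * k_theta(theta) * phi_g(theta)`
#' for the root in `[theta_min, theta_max]` with a bracketed
#' Newton-bisection iteration (total deformation held fixed, so for the
#' stress driver `Ce = C / theta^2` varies with the trial stretch).
#'
#' @param theta_n Growth stretch at the start of the step (scalar).
#' @param driver_fn Function of the trial stretch returning
#'   `list(phi = phi_g, dphi = d phi_g / d theta)`.
#' @param p A `gmphets_growth_law`.
#' @param dt Time step (s).
#' @param tol Residual tolerance (default 1e-12).
#' @param maxit Maximum iterations (default 50).
#' @return Converged `theta_{n+1}`, clipped to `[theta_min, theta_max]`.
#' @export
theta_update_local_newton <- function(theta_n, driver_fn, p, dt,
                                      tol = 1e-12, maxit = 50L) {
  resid <- function(th) {
    d <- driver_fn(th)
    k <- k_theta(th, sign(d$phi), p)
    th - theta_n - dt * k * d$phi
  }
  th <- theta_n
  lo <- p$theta_min; hi <- p$theta_max
  # bracket: R(theta_min) <= 0 <= R(theta_max) whenever theta_n is inside
  for (it in seq_len(maxit)) {
    d <- driver_fn(th)
    k <- k_theta(th, sign(d$phi), p)
    r <- th - theta_n - dt * k * d$phi
    if (abs(r) < tol) return(min(max(th, p$theta_min), p$theta_max))
    if (r > 0) hi <- th else lo <- th
    dk <- k_theta_dtheta(th, sign(d$phi), p)
    dr <- 1 - dt * (dk * d$phi + k * d$dphi)
    step_ok <- is.finite(dr) && dr != 0
    th_new <- if (step_ok) th - r / dr else NA_real_
    if (!step_ok || th_new <= lo || th_new >= hi) th_new <- (lo + hi) / 2
    th <- th_new
  }
  gmphets_stop("local growth update failed to converge (reduce the time step)",
               "local_growth_divergence_error")
}

#' Mass source terms for growth
#'
#' The volumetric source entering the fluid conservation equation is
#' `3 theta^2 theta_dot` for both growth cases. Solid-only growth puts all
#' of it in the solid (`R0s / rhoTs = 3 theta^2 theta_dot`, fluid term 0);
#' solid/fluid growth splits it by the initial porosity
#' (`R0s / rhoTs = 3 (1 - n0) theta^2 theta_dot`,
#' `R0f / rhoTf = 3 n0 theta^2 theta_dot`), so the density-specific terms
#' always sum to the volumetric source.
#'
#' @param theta Growth stretch. Vectorised.
#' @param theta_dot Growth-stretch rate (1/s).
#' @param growth_case `"solid_only"` or `"solid_fluid"`.
#' @param n0 Initial porosity (used by the solid/fluid split).
#' @return List with `R0s_over_rhoTs`, `R0f_over_rhoTf`, `volumetric_source`
#'   (all 1/s).
#' @export
source_terms <- function(theta, theta_dot,
                         growth_case = c("solid_only", "solid_fluid"),
                         n0 = 0.5) {
  growth_case <- match.arg(growth_case)
  if (any(theta <= 0)) gmphets_stop("theta must be positive", "parameter_error")
  vol <- 3 * theta^2 * theta_dot
  if (growth_case == "solid_only")
    list(R0s_over_rhoTs = vol, R0f_over_rhoTf = 0 * vol, volumetric_source = vol)
  else
    list(R0s_over_rhoTs = (1 - n0) * vol, R0f_over_rhoTf = n0 * vol,
         volumetric_source = vol)
}

#' Normalised solid growth density for a growth case
#'
#' `rho_bar_s = rho0s* / rhoTs`: 1 for solid-only growth (mass added at the
#' true solid density) and `1 - n0` for solid/fluid growth (mass added at
#' the initial apparent densities). True densities never enter the discrete
#' equations; only this ratio does.
#'
#' @param growth_case `"solid_only"` or `"solid_fluid"`.
#' @param n0 Initial porosity.
#' @return Scalar `rho_bar_s`.
#' @export
rho_bar_s_for <- function(growth_case = c("solid_only", "solid_fluid"), n0 = 0.5) {
  growth_case <- match.arg(growth_case)
  if (growth_case == "solid_only") 1 else 1 - n0
}

#' Eulerian porosity after growth and deformation
#'
#' `n = 1 - J^{-1} [(1 - n0) + rho_bar_s (theta^3 - 1)]`. With `theta = 1`
#' this is the classical no-growth formula; with `J = theta^3` it reduces to
#' `n0 / theta^3` for solid-only growth and to exactly `n0` for solid/fluid
#' growth.
#'
#' @param J Jacobian of the total deformation, positive. Vectorised.
#' @param theta Growth stretch, positive.
#' @param n0 Initial porosity.
#' @param rho_bar_s Normalised solid growth density.
#' @return Porosity `n` (may fall outside `[0, 1]`; see
#'   [check_admissibility()]).
#' @export
porosity_after_growth <- function(J, theta, n0, rho_bar_s) {
  if (any(J <= 0) || any(theta <= 0))
    gmphets_stop("J and theta must be positive", "parameter_error")
  1 - ((1 - n0) + rho_bar_s * (theta^3 - 1)) / J
}

#' Porosity admissibility bounds on the growth stretch
#'
#' The porous-media model requires `0 < n < 1`; equivalently the growth
#' stretch must satisfy
#' `[1 + (n0 - 1)/rho_bar_s]^(1/3) < theta < [1 + (J - 1 + n0)/rho_bar_s]^(1/3)`.
#'
#' @param J Jacobian of the total deformation. Vectorised.
#' @param theta Growth stretch.
#' @param n0 Initial porosity.
#' @param rho_bar_s Normalised solid growth density.
#' @return List with logical `admissible` and the bounds `theta_upper`,
#'   `theta_lower`.
#' @export
check_admissibility <- function(J, theta, n0, rho_bar_s) {
  if (any(J <= 0)) gmphets_stop("J must be positive", "parameter_error")
  up <- (1 + (J - 1 + n0) / rho_bar_s)^(1 / 3)
  lo <- (1 + (n0 - 1) / rho_bar_s)^(1 / 3)
  list(admissible = (theta > lo) & (theta < up),
       theta_upper = up, theta_lower = rep(lo, length.out = length(up)))
}
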