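# Closed-form solutions for time-driven growth of an internally pressurised
# rigid porohyperelastic cylinder.  With every material point held fixed
# (F = I for all time) the fluid conservation equation reduces, at each
# instant, to a quasi-static Poisson problem for the pore pressure with the
# growth volumetric source on the right-hand side, and the effective stress
# is spatially homogeneous and available in closed form.  These solutions
# validate the finite element solver.

#' Specification of the rigid-cylinder validation problem
#'
#' @param ri,ro Inner and outer radius (m).
#' @param Pi Inner pore pressure (Pa), `>= 0`; the outer face is at zero.
#' @param kff Permeability, m^4/(N s).
#' @param alpha Time-linear growth rate (1/s); growth is
#'   `theta(t) = 1 + alpha * t`.
#' @param n0 Initial porosity.
#' @param rho_bar_s Normalised solid growth density (1 solid-only, `1 - n0`
#'   solid/fluid).
#' @param mat A `gmphets_material`.
#' @return A `gmphets_rigid_spec` list.
#' @export
rigid_cylinder_spec <- function(ri = 1e-3, ro = 1.25e-3,
                                Pi = 100 * 133.322, kff = 2e-14,
                                alpha = 0.0008, n0 = 0.5, rho_bar_s = 1,
                                mat = material_params()) {
  if (!(ri > 0 && ro > ri)) gmphets_stop("need 0 < ri < ro", "invalid_geometry_error")
  if (Pi < 0) gmphets_stop("Pi must be >= 0", "parameter_error")
  structure(list(ri = ri, ro = ro, Pi = Pi, kff = kff, alpha = alpha,
                 n0 = n0, rho_bar_s = rho_bar_s, mat = mat),
            class = "gmphets_rigid_spec")
}

#' Pore-pressure profile in the growing rigid cylinder
#'
#' At growth time `t` the profile solves
#' `(1/r) d/dr (r dpf/dr) = -s(t) / kff` with
#' `s(t) = 3 (1 + alpha t)^2 alpha`, `pf(ri) = Pi`, `pf(ro) = 0`:
#' `pf(r) = -(s / (4 kff)) r^2 + A log(r) + B`. With `alpha = 0` it reduces
#' to the consolidated logarithmic profile.
#'
#' @param spec A `gmphets_rigid_spec`.
#' @param t Growth time (s); `t = 0` (or `alpha = 0`) gives the no-growth
#'   steady state.
#' @param r Radii at which to evaluate (m); defaults to 200 points across
#'   the wall.
#' @return Data frame with columns `r [m]` and `pf [Pa]`.
#' @export
rigid_pf_profile <- function(spec, t = 0,
                             r = seq(spec$ri, spec$ro, length.out = 200)) {
  th <- 1 + spec$alpha * t
  s <- 3 * th^2 * spec$alpha
  f <- function(rr) -s * rr^2 / (4 * spec$kff)
  A <- (spec$Pi - f(spec$ri) + f(spec$ro)) / log(spec$ri / spec$ro)
  B <- -f(spec$ro) - A * log(spec$ro)
  data.frame(`r [m]` = r, `pf [Pa]` = f(r) + A * log(r) + B,
             check.names = FALSE)
}

#' Effective stress in the growing rigid cylinder
#'
#' With rigid kinematics `Fe = I / theta`, the effective second
#' Piola-Kirchhoff stress is homogeneous and isotropic:
#' `Seff = -3 lambda log(theta) + mu (theta^{-2} - 1)` per diagonal
#' component; it is negative (compressive) for `theta > 1`.
#'
#' @param spec A `gmphets_rigid_spec`.
#' @param t Growth time (s). Vectorised.
#' @return Diagonal effective-stress value (Pa).
#' @export
rigid_effective_stress <- function(spec, t) {
  th <- 1 + spec$alpha * t
  -3 * spec$mat$lam * log(th) + spec$mat$mu * (th^-2 - 1)
}

#' Porosity history in the growing rigid cylinder
#'
#' With `J = 1`, the porosity closed form is
#' `n(t) = n0 - rho_bar_s (theta^3 - 1)`: solid-only growth
#' (`rho_bar_s = 1`) loses porosity fastest; solid/fluid growth
#' (`rho_bar_s = 1 - n0`) loses it more slowly.
#'
#' @param spec A `gmphets_rigid_spec`.
#' @param t Growth time (s). Vectorised.
#' @return Porosity values.
#' @export
rigid_porosity <- function(spec, t) {
  th <- 1 + spec$alpha * t
  spec$n0 - spec$rho_bar_s * (th^3 - 1)
}

#' Limiting growth time from the porosity constraint
#'
#' Inserting `theta = 1 + alpha t` into the admissibility upper bound gives
#' `t_limit = ([1 + (n0 + J - 1)/rho_bar_s]^{1/3} - 1) / alpha`, independent
#' of the time-step size. Returns `Inf` for `alpha <= 0`.
#'
#' @param spec A `gmphets_rigid_spec`.
#' @param J Jacobian of the total deformation (1 for the rigid problem).
#' @return Limiting time (s).
#' @examples
#' limiting_growth_time(rigid_cylinder_spec())  # ~180.9 s
#' @export
limiting_growth_time <- function(spec, J = 1) {
  if (spec$alpha <= 0) return(Inf)
  ((1 + (spec$n0 + J - 1) / spec$rho_bar_s)^(1 / 3) - 1) / spec$alpha
}
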