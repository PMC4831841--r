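# Pointwise material computation: finite-strain kinematics with the
# multiplicative growth split, compressible Neo-Hookean effective stress and
# its Lagrangian tangent, the growth pullback and effective-stress principle,
# Onsager transport coefficients, and the mechano-chemical potentials that
# link the nodal primaries to pore pressure and concentration.

#' Lame parameters from (C10, D1)
#'
#' The Neo-Hookean material is parameterised by `C10` and `D1`; the
#' equivalent Lame set is `mu = 2 C10`, `kappa = 2 / D1`,
#' `lambda = kappa - (2/3) mu`.
#'
#' @param C10 Shear-like modulus parameter (Pa), positive.
#' @param D1 Compressibility parameter (1/Pa), positive.
#' @return List with `lam`, `mu`, `kappa` (all Pa).
#' @examples
#' lame_from_c10_d1(1e6, 5.5e-9)
#' @export
lame_from_c10_d1 <- function(C10, D1) {
  stopifnot_scalar(C10, "C10"); stopifnot_scalar(D1, "D1")
  if (C10 <= 0 || D1 <= 0)
    gmphets_stop("C10 and D1 must be positive", "parameter_error")
  mu <- 2 * C10
  kappa <- 2 / D1
  list(lam = kappa - 2 / 3 * mu, mu = mu, kappa = kappa)
}

#' Neo-Hookean material parameter set
#'
#' @param C10 Pa. Default is the coronary-artery value 1e6 Pa.
#' @param D1 1/Pa. Default 5.5e-9 1/Pa.
#' @return A `gmphets_material`: list with `C10`, `D1`, `lam`, `mu`, `kappa`.
#' @export
material_params <- function(C10 = 1e6, D1 = 5.5e-9) {
  lm <- lame_from_c10_d1(C10, D1)
  structure(c(list(C10 = C10, D1 = D1), lm), class = "gmphets_material")
}

#' Transport and mixture parameter set
#'
#' Darcy permeability, fluid/species convection coupling, Fickian
#' diffusivity, porosity and the chemical datum constants for the
#' mechano-chemical potentials. The convection coupling is symmetric
#' (`bfc = bcf`) and is stored once.
#'
#' @param kff Permeability, m^4/(N s).
#' @param bfc Convection coupling coefficient (unitless, equals `bcf`).
#' @param dcc Diffusivity, m^2/s.
#' @param n0 Initial porosity, in (0, 1).
#' @param phi_c Osmotic coefficient (unitless).
#' @param gamma_mat Activity coefficient of the species in the material.
#' @param theta Absolute temperature (K), default body temperature 310 K.
#' @param Rbar Universal gas constant, 8.31 J/(K mol).
#' @param p0o Baseline osmotic potential (Pa). Any consistent datum works;
#'   results are datum-invariant. Default 0.
#' @param c_floor Concentration datum (mol/m^3) used to set the baseline
#'   chemical potential `mu0c = -Rbar * theta * log(gamma_mat * c_floor)`,
#'   chosen below the lowest concentration expected in the problem so the
#'   logarithm stays defined. Default one tenth of the outer-boundary
#'   equilibrium concentration of the arterial test problems.
#' @param mu0c Baseline chemical potential (J/mol); overrides `c_floor` if
#'   given.
#' @return A `gmphets_transport` list.
#' @export
transport_params <- function(kff = 2e-14, bfc = 6e-4, dcc = 4.55e-14,
                             n0 = 0.5, phi_c = 0, gamma_mat = 0.5,
                             theta = 310, Rbar = 8.31, p0o = 0,
                             c_floor = 1.28e-4, mu0c = NULL) {
  if (!(n0 > 0 && n0 < 1))
    gmphets_stop("initial porosity n0 must lie in (0, 1)", "parameter_error")
  if (kff < 0 || dcc < 0 || theta <= 0 || gamma_mat <= 0)
    gmphets_stop("kff, dcc must be >= 0; theta, gamma_mat > 0", "parameter_error")
  if (is.null(mu0c)) mu0c <- -Rbar * theta * log(gamma_mat * c_floor)
  structure(list(kff = kff, bfc = bfc, dcc = dcc, n0 = n0, phi_c = phi_c,
                 gamma_mat = gamma_mat, theta = theta, Rbar = Rbar,
                 p0o = p0o, mu0c = mu0c), class = "gmphets_transport")
}

# ---------------------------------------------------------------------------
# Kinematics

#' Axisymmetric kinematics with the isotropic growth split
#'
#' Builds the full deformation gradient from the in-plane displacement
#' gradient and the hoop stretch `(R + u_R) / R`, then applies the
#' multiplicative split `F = Fe Fg` with isotropic growth `Fg = theta_g * I`,
#' so `Fe = F / theta_g`, `Jg = theta_g^3`, `Je = J / theta_g^3`.
#'
#' @param dudX 2 x 2 matrix of in-plane derivatives
#'   (`du_R/dR`, `du_R/dZ`; `du_Z/dR`, `du_Z/dZ`).
#' @param hoop_stretch Hoop component `(R + u_R) / R` at the point.
#' @param theta_g Growth stretch, positive.
#' @return A `gmphets_kinematics` list: `F`, `J`, `C`, `E`, `H` (Finger
#'   tensor, equal to `C^{-1}`), `Fe`, `Ce`, `Je`, `Jg`, `theta_g`
#'   (all 3 x 3 in (R, Z, Theta) ordering).
#' @export
compute_kinematics <- function(dudX, hoop_stretch, theta_g = 1) {
  if (theta_g <= 0) gmphets_stop("theta_g must be positive", "parameter_error")
  F <- diag(3)
  F[1:2, 1:2] <- diag(2) + dudX
  F[3, 3] <- hoop_stretch
  J <- det(F)
  if (J <= 0)
    gmphets_stop("det F <= 0: element inversion", "inverted_element_error")
  C <- crossprod(F)            # F^T F
  H <- solve(C)                # F^{-1} F^{-T}
  E <- (C - diag(3)) / 2
  Fe <- F / theta_g
  Ce <- C / theta_g^2
  Je <- J / theta_g^3
  structure(list(F = F, J = J, C = C, E = E, H = H, Fe = Fe, Ce = Ce,
                 Je = Je, Jg = theta_g^3, theta_g = theta_g),
            class = "gmphets_kinematics")
}

check_spd3 <- function(Ce) {
  if (!isTRUE(all.equal(Ce, t(Ce), tolerance = 1e-8)))
    gmphets_stop("Ce must be symmetric", "kinematics_error")
  ev <- eigen(Ce, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    gmphets_stop("Ce must be positive definite", "kinematics_error")
  invisible(ev)
}

#' Neo-Hookean effective, elastic second Piola-Kirchhoff stress
#'
#' `Seff_e = (lambda * log(Je) - mu) * Ce^{-1} + mu * I` with
#' `Je = sqrt(det Ce)`.
#'
#' @param Ce Elastic right Cauchy-Green tensor, 3 x 3 symmetric positive
#'   definite.
#' @param mat A `gmphets_material`.
#' @return 3 x 3 symmetric stress tensor (Pa).
#' @export
neo_hookean_stress <- function(Ce, mat) {
  check_spd3(Ce)
  Je <- sqrt(det(Ce))
  Cei <- solve(Ce)
  (mat$lam * log(Je) - mat$mu) * Cei + mat$mu * diag(3)
}

#' Elastic Lagrangian tangent modulus
#'
#' Fourth-order tensor
#' `Le_ijkl = lam * Cei_ij Cei_kl + (mu - lam log Je)(Cei_ik Cei_lj +
#' Cei_il Cei_kj)` with both minor symmetries and major symmetry.
#'
#' @inheritParams neo_hookean_stress
#' @return Numeric array `dim = c(3, 3, 3, 3)` (Pa).
#' @export
elastic_tangent <- function(Ce, mat) {
  check_spd3(Ce)
  Je <- sqrt(det(Ce))
  Cei <- solve(Ce)
  g <- mat$mu - mat$lam * log(Je)
  Le <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    Le[i, j, k, l] <- mat$lam * Cei[i, j] * Cei[k, l] +
      g * (Cei[i, k] * Cei[l, j] + Cei[i, l] * Cei[k, j])
  Le
}

#' Total second Piola-Kirchhoff stress with growth pullback
#'
#' Applies the isotropic growth pullback `Seff = Seff_e / theta_g^2` and the
#' effective stress principle `S = Seff - J H pf`; also returns the trace of
#' the effective, elastic Mandel stress `trM = tr(Ce Seff_e)` (the driver of
#' stress-dependent growth) and the Cauchy stress `sigma = F S F^T / J`.
#'
#' @param Seff_e Effective, elastic second Piola-Kirchhoff stress (3 x 3).
#' @param kin A `gmphets_kinematics`.
#' @param theta_g Growth stretch used for the pullback.
#' @param pf Pore fluid pressure (Pa).
#' @return A `gmphets_stress` list: `Seff_e`, `Seff`, `S`, `trM`, `sigma`.
#' @export
total_stress <- function(Seff_e, kin, theta_g = kin$theta_g, pf = 0) {
  Seff <- Seff_e / theta_g^2
  S <- Seff - kin$J * kin$H * pf
  sigma <- kin$F %*% S %*% t(kin$F) / kin$J
  structure(list(Seff_e = Seff_e, Seff = Seff, S = S,
                 trM = sum(kin$Ce * Seff_e), sigma = sigma),
            class = "gmphets_stress")
}

# ---------------------------------------------------------------------------
# Transport

#' Lagrangian Onsager transport coefficients
#'
#' Pulls the isotropic Eulerian Darcy/Fick parameters back to the reference
#' configuration: `Lff = J H kff`, `Lfc = Lcf = J H kff bfc c`,
#' `Lcc = J H (c dcc / (Rbar theta) + c^2 kff bfc^2)`. The diffusive term
#' carries `1 / (Rbar theta)` so that, with the logarithmic chemical
#' potential, the dilute-limit species flux is exactly Fick's law
#' `-dcc grad(c)` in mol/(m^2 s).
#'
#' @param kin A `gmphets_kinematics`.
#' @param c Species concentration (mol/m^3), positive.
#' @param tp A `gmphets_transport`.
#' @return List of 3 x 3 tensors `Lff`, `Lfc`, `Lcf`, `Lcc`.
#' @export
transport_coeffs <- function(kin, c, tp) {
  if (c <= 0) gmphets_stop("concentration must be positive", "state_error")
  JH <- kin$J * kin$H
  Lff <- JH * tp$kff
  Lfc <- JH * (tp$kff * tp$bfc * c)
  Lcc <- JH * (c * tp$dcc / (tp$Rbar * tp$theta) + c^2 * tp$kff * tp$bfc^2)
  list(Lff = Lff, Lfc = Lfc, Lcf = Lfc, Lcc = Lcc)
}

#' Lagrangian relative fluxes (generalised Darcy/Fick laws)
#'
#' `jfr = -Lff grad(mu_f) - Lfc grad(mu_c)`;
#' `jcr = -Lcf grad(mu_f) - Lcc grad(mu_c)`.
#'
#' @param grad_mu_f Gradient of the fluid potential (Pa/m), length-3 vector.
#' @param grad_mu_c Gradient of the chemical potential ((J/mol)/m).
#' @param coeffs Output of [transport_coeffs()].
#' @return List with vectors `jfr`, `jcr`.
#' @export
fluxes <- function(grad_mu_f, grad_mu_c, coeffs) {
  list(jfr = -as.vector(coeffs$Lff %*% grad_mu_f + coeffs$Lfc %*% grad_mu_c),
       jcr = -as.vector(coeffs$Lcf %*% grad_mu_f + coeffs$Lcc %*% grad_mu_c))
}

# ---------------------------------------------------------------------------
# Mechano-chemical potentials

#' Potentials from pore pressure and concentration
#'
#' `mu_f = pf + p0o - Rbar theta phi_c c` and
#' `mu_c = mu0c + Rbar theta log(gamma_mat c)`.
#'
#' @param pf Pore fluid pressure (Pa).
#' @param c Concentration (mol/m^3), positive.
#' @param tp A `gmphets_transport`.
#' @return List with `mu_f` (Pa) and `mu_c` (J/mol). Vectorised.
#' @export
potentials_forward <- function(pf, c, tp) {
  if (any(c <= 0))
    gmphets_stop("concentration must be positive (log undefined)", "domain_error")
  RT <- tp$Rbar * tp$theta
  list(mu_f = pf + tp$p0o - RT * tp$phi_c * c,
       mu_c = tp$mu0c + RT * log(tp$gamma_mat * c))
}

#' Secondary variables from the potentials
#'
#' Closed-form inversion of the mechano-chemical potentials:
#' `c = exp((mu_c - mu0c) / (Rbar theta)) / gamma_mat`, always positive, and
#' `pf = mu_f - p0o + Rbar theta phi_c c`.
#'
#' @param mu_f Fluid potential (Pa).
#' @param mu_c Chemical potential (J/mol).
#' @param tp A `gmphets_transport`.
#' @return List with `pf` and `c`. Vectorised.
#' @export
secondary_from_potentials <- function(mu_f, mu_c, tp) {
  RT <- tp$Rbar * tp$theta
  c <- exp((mu_c - tp$mu0c) / RT) / tp$gamma_mat
  if (any(!is.finite(c)))
    gmphets_stop("chemical potential overflow while recovering concentration",
                 "diverged_state_error")
  list(pf = mu_f - tp$p0o + RT * tp$phi_c * c, c = c)
}

#' Material-side concentration across a bath interface
#'
#' At equal chemical potential, the activity is continuous, so the
#' concentration jumps by the inverse of the partition coefficient
#' `gamma_mat / gamma_bath`: `c_mat = c_bath / partition`.
#'
#' @param c_bath Bath concentration (mol/m^3).
#' @param partition Partition coefficient `gamma_mat / gamma_bath`.
#' @return Material-side concentration (mol/m^3). Vectorised.
#' @examples
#' partition_concentration(6.40e-3, 0.5)  # 0.0128
#' @export
partition_concentration <- function(c_bath, partition = 0.5) {
  if (any(partition <= 0))
    gmphets_stop("partition coefficient must be positive", "parameter_error")
  c_bath / partition
}
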