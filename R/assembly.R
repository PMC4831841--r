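# Galerkin residuals and consistent tangents for the three conservation
# laws on linear axisymmetric triangles with single-point quadrature.
#
# All tensors at a Gauss point share the axisymmetric block structure
#   [ T11 T12  0  ]
#   [ T21 T22  0  ]   (rows/cols ordered R, Z, Theta)
#   [  0   0  T33 ]
# so the assembly stores only the independent components as vectors over
# elements and evaluates every constitutive formula in closed component
# form.  Directional derivatives with respect to the six nodal displacement
# dofs give the displacement tangent blocks; the potential blocks follow
# from the closed-form secondary-variable recovery.

# Precompute element geometry, shape gradients and dof indexing.
fe_precompute <- function(mesh, dofmap) {
  el <- mesh$elements
  ne <- nrow(el)
  x <- matrix(mesh$nodes$R[el], ne, 3L)
  y <- matrix(mesh$nodes$Z[el], ne, 3L)
  two_a <- (x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) -
           (x[, 3] - x[, 1]) * (y[, 2] - y[, 1])
  if (any(two_a <= 0))
    gmphets_stop("degenerate element in mesh", "degenerate_element_error")
  BR <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2]) / two_a
  BZ <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1]) / two_a
  Rc <- rowMeans(x)
  area <- two_a / 2
  w <- 2 * pi * Rc * area

  flds <- dofmap$fields
  nl <- 3L * length(flds)
  idx <- matrix(0L, ne, nl)
  for (a in 1:3) {
    idx[, a]      <- dof_index(dofmap, el[, a], "u_R")
    idx[, 3L + a] <- dof_index(dofmap, el[, a], "u_Z")
    if ("mu_f" %in% flds) idx[, 6L + a] <- dof_index(dofmap, el[, a], "mu_f")
    if ("mu_c" %in% flds) idx[, 9L + a] <- dof_index(dofmap, el[, a], "mu_c")
  }
  list(ne = ne, nl = nl, el = el, BR = BR, BZ = BZ, Rc = Rc, area = area,
       w = w, idx = idx, mode = dofmap$mode, ndof = dofmap$ndof,
       trip_i = as.vector(idx[, rep(seq_len(nl), times = nl)]),
       trip_j = as.vector(idx[, rep(seq_len(nl), each = nl)]))
}

# Gauss-point fields from the global primary vector.
element_fields <- function(fe, p, tp) {
  g <- function(k) cbind(p[fe$idx[, k + 1L]], p[fe$idx[, k + 2L]],
                         p[fe$idx[, k + 3L]])
  uR <- g(0L); uZ <- g(3L)
  F11 <- 1 + rowSums(uR * fe$BR); F12 <- rowSums(uR * fe$BZ)
  F21 <- rowSums(uZ * fe$BR);     F22 <- 1 + rowSums(uZ * fe$BZ)
  F33 <- 1 + rowMeans(uR) / fe$Rc
  J2 <- F11 * F22 - F12 * F21
  J <- J2 * F33
  if (any(J <= 0))
    gmphets_stop(sprintf("element inversion (det F <= 0) in %d element(s)",
                         sum(J <= 0)), "inverted_element_error")
  out <- list(F11 = F11, F12 = F12, F21 = F21, F22 = F22, F33 = F33, J = J,
              C11 = F11^2 + F21^2, C12 = F11 * F12 + F21 * F22,
              C22 = F12^2 + F22^2, C33 = F33^2)
  out$trC <- out$C11 + out$C22 + out$C33
  mode <- fe$mode
  RT <- tp$Rbar * tp$theta
  if (mode == "MPHETS") {
    mf <- rowMeans(g(6L)); mc <- rowMeans(g(9L))
    cc <- exp((mc - tp$mu0c) / RT) / tp$gamma_mat
    if (any(!is.finite(cc)))
      gmphets_stop("chemical potential overflow at a Gauss point",
                   "diverged_state_error")
    out$c <- cc
    out$pf <- mf - tp$p0o + RT * tp$phi_c * cc
    out$gfR <- rowSums(g(6L) * fe$BR); out$gfZ <- rowSums(g(6L) * fe$BZ)
    out$gcR <- rowSums(g(9L) * fe$BR); out$gcZ <- rowSums(g(9L) * fe$BZ)
  } else if (mode == "PHE") {
    mf <- rowMeans(g(6L))
    out$c <- rep(0, fe$ne)
    out$pf <- mf - tp$p0o
    out$gfR <- rowSums(g(6L) * fe$BR); out$gfZ <- rowSums(g(6L) * fe$BZ)
  } else {
    out$c <- rep(0, fe$ne)
    out$pf <- rep(0, fe$ne)
  }
  out
}

# Residual, tangent and per-element auxiliary state for the full system.
# hist carries the converged previous-step values (J, c); th/th_n the
# current and previous growth stretch.  dt = Inf gives the rate-free
# (static) operator.
assemble_core <- function(fe, mat, tp, rho_bar_s, p, th, th_n, hist, dt,
                          want_tangent = TRUE, growth = NULL) {
  ef <- element_fields(fe, p, tp)
  ne <- fe$ne; w <- fe$w; Rc <- fe$Rc
  lam <- mat$lam; mu <- mat$mu
  RT <- tp$Rbar * tp$theta
  mode <- fe$mode
  has_f <- mode != "HE"; has_c <- mode == "MPHETS"

  J <- ef$J
  det2 <- ef$C11 * ef$C22 - ef$C12^2
  Ci11 <- ef$C22 / det2; Ci12 <- -ef$C12 / det2; Ci22 <- ef$C11 / det2
  Ci33 <- 1 / ef$C33
  lnJe <- log(J) - 3 * log(th)
  se <- lam * lnJe - mu
  th2 <- th^2
  # effective elastic stress and total stress components
  Se11 <- se * th2 * Ci11 + mu; Se12 <- se * th2 * Ci12
  Se22 <- se * th2 * Ci22 + mu; Se33 <- se * th2 * Ci33 + mu
  pf <- ef$pf
  S11 <- Se11 / th2 - J * pf * Ci11
  S12 <- Se12 / th2 - J * pf * Ci12
  S22 <- Se22 / th2 - J * pf * Ci22
  S33 <- Se33 / th2 - J * pf * Ci33
  trM <- 3 * se + mu * ef$trC / th2

  P11 <- ef$F11 * S11 + ef$F12 * S12; P12 <- ef$F11 * S12 + ef$F12 * S22
  P21 <- ef$F21 * S11 + ef$F22 * S12; P22 <- ef$F21 * S12 + ef$F22 * S22
  P33 <- ef$F33 * S33

  Jdot  <- (J - hist$J) / dt
  thdot <- (th - th_n) / dt
  src   <- 3 * th2 * thdot
  cc    <- ef$c
  cdot  <- (cc - hist$c) / dt
  n_e   <- 1 - ((1 - tp$n0) + rho_bar_s * (th^3 - 1)) / J
  Jn    <- J - (1 - tp$n0) - rho_bar_s * (th^3 - 1)   # = J * n_e

  aff <- tp$kff
  afc <- tp$kff * tp$bfc * cc
  acc <- cc * tp$dcc / RT + tp$kff * (tp$bfc * cc)^2
  JC11 <- J * Ci11; JC12 <- J * Ci12; JC22 <- J * Ci22
  if (has_f) {
    vfR <- aff * ef$gfR; vfZ <- aff * ef$gfZ
    if (has_c) { vfR <- vfR + afc * ef$gcR; vfZ <- vfZ + afc * ef$gcZ }
    # Onsager mobility times potential gradients (reference frame)
    LgfR <- JC11 * vfR + JC12 * vfZ; LgfZ <- JC12 * vfR + JC22 * vfZ
    if (has_c) {
      vcR <- afc * ef$gfR + acc * ef$gcR; vcZ <- afc * ef$gfZ + acc * ef$gcZ
      LgcR <- JC11 * vcR + JC12 * vcZ; LgcZ <- JC12 * vcR + JC22 * vcZ
    }
  }

  nl <- fe$nl
  Rel <- matrix(0, ne, nl)
  for (a in 1:3) {
    Rel[, a] <- w * (P11 * fe$BR[, a] + P12 * fe$BZ[, a] + P33 / (3 * Rc))
    Rel[, 3L + a] <- w * (P21 * fe$BR[, a] + P22 * fe$BZ[, a])
    if (has_f)
      Rel[, 6L + a] <- w * (fe$BR[, a] * LgfR + fe$BZ[, a] * LgfZ +
                              (Jdot - src) / 3)
    if (has_c)
      Rel[, 9L + a] <- w * (fe$BR[, a] * LgcR + fe$BZ[, a] * LgcZ +
                              (Jdot * cc - rho_bar_s * src * cc + Jn * cdot) / 3)
  }

  aux <- list(J = J, c = cc, pf = pf, n = n_e, trM = trM, theta = th,
              lnJe = lnJe,
              Seff11 = Se11 / th2, Seff22 = Se22 / th2, Seff33 = Se33 / th2,
              Seff12 = Se12 / th2,
              S11 = S11, S22 = S22, S33 = S33,
              sigma_hoop = ef$F33^2 * S33 / J,
              sigma_eff_hoop = ef$F33^2 * (Se33 / th2) / J,
              F33 = ef$F33, src = src)

  if (!want_tangent)
    return(list(Rel = Rel, aux = aux, ef = ef))

  Kel <- array(0, c(ne, nl, nl))

  # Sensitivity of the converged growth stretch to the primaries, from the
  # implicit function theorem on the local backward-Euler residual
  # R(theta) = theta - theta_n - dt k_theta(theta) phi_g(theta, C, c).
  # d theta = (dt k / D) d phi_g, D = 1 - dt (k' phi_g + k dphi_g/dtheta),
  # D >= 1 for the limiter. Where the driver vanishes or theta sits at a
  # limiter bound, k = 0 and the sensitivity vanishes with it.
  gfac <- NULL; glaw <- NULL
  if (!is.null(growth) && isTRUE(growth$active) &&
      growth$gl$law %in% c("stress", "concentration")) {
    gl <- growth$gl; glaw <- gl$law
    phig <- if (glaw == "stress") trM else cc - gl$c_thresh
    dphig_dth <- if (glaw == "stress") -9 * lam / th - 2 * mu * ef$trC / th^3
                 else 0
    kv <- k_theta(th, sign(phig), gl)
    kpv <- k_theta_dtheta(th, sign(phig), gl)
    D <- 1 - dt * (kpv * phig + kv * dphig_dth)
    gfac <- dt * kv / D
    # dS/dtheta at fixed C and pf; growth also enters the fluid/species
    # sources and J n
    dSth_ci <- -3 * lam / th          # coefficient of Cinv
    dSth_i  <- -2 * mu / th^3         # coefficient of I
    dsrcdth <- (6 * th * (th - th_n) + 3 * th^2) / dt
    dJndth  <- -3 * rho_bar_s * th^2
  }
  # Q = F (J Cinv), used by the pressure columns
  if (has_f) {
    Q11 <- ef$F11 * JC11 + ef$F12 * JC12; Q12 <- ef$F11 * JC12 + ef$F12 * JC22
    Q21 <- ef$F21 * JC11 + ef$F22 * JC12; Q22 <- ef$F21 * JC12 + ef$F22 * JC22
    Q33 <- ef$F33 * J * Ci33
  }

  # --- displacement directions -------------------------------------------
  for (beta in 1:6) {
    a <- if (beta <= 3L) beta else beta - 3L
    if (beta <= 3L) {
      dF11 <- fe$BR[, a]; dF12 <- fe$BZ[, a]; dF21 <- 0; dF22 <- 0
      dF33 <- 1 / (3 * Rc)
    } else {
      dF11 <- 0; dF12 <- 0; dF21 <- fe$BR[, a]; dF22 <- fe$BZ[, a]
      dF33 <- 0
    }
    dC11 <- 2 * (ef$F11 * dF11 + ef$F21 * dF21)
    dC12 <- ef$F11 * dF12 + dF11 * ef$F12 + ef$F21 * dF22 + dF21 * ef$F22
    dC22 <- 2 * (ef$F12 * dF12 + ef$F22 * dF22)
    dC33 <- 2 * ef$F33 * dF33
    CidC <- Ci11 * dC11 + 2 * Ci12 * dC12 + Ci22 * dC22 + Ci33 * dC33
    dJ <- 0.5 * J * CidC
    # T = Cinv dC Cinv (symmetric, blockwise)
    U11 <- Ci11 * dC11 + Ci12 * dC12; U12 <- Ci11 * dC12 + Ci12 * dC22
    U21 <- Ci12 * dC11 + Ci22 * dC12; U22 <- Ci12 * dC12 + Ci22 * dC22
    T11 <- U11 * Ci11 + U12 * Ci12; T12 <- U11 * Ci12 + U12 * Ci22
    T22 <- U21 * Ci12 + U22 * Ci22
    T33 <- Ci33 * dC33 * Ci33
    coefA <- 0.5 * lam * CidC - pf * dJ
    coefB <- mu - lam * lnJe + pf * J
    dS11 <- coefA * Ci11 + coefB * T11
    dS12 <- coefA * Ci12 + coefB * T12
    dS22 <- coefA * Ci22 + coefB * T22
    dS33 <- coefA * Ci33 + coefB * T33
    dthb <- NULL
    if (identical(glaw, "stress")) {
      # growth responds to the strain through the converged local update
      dthb <- gfac * (1.5 * lam * CidC + (mu / th^2) * (dC11 + dC22 + dC33))
      dS11 <- dS11 + (dSth_ci * Ci11 + dSth_i) * dthb
      dS12 <- dS12 + dSth_ci * Ci12 * dthb
      dS22 <- dS22 + (dSth_ci * Ci22 + dSth_i) * dthb
      dS33 <- dS33 + (dSth_ci * Ci33 + dSth_i) * dthb
    }
    dP11 <- dF11 * S11 + dF12 * S12 + ef$F11 * dS11 + ef$F12 * dS12
    dP12 <- dF11 * S12 + dF12 * S22 + ef$F11 * dS12 + ef$F12 * dS22
    dP21 <- dF21 * S11 + dF22 * S12 + ef$F21 * dS11 + ef$F22 * dS12
    dP22 <- dF21 * S12 + dF22 * S22 + ef$F21 * dS12 + ef$F22 * dS22
    dP33 <- dF33 * S33 + ef$F33 * dS33
    for (b in 1:3) {
      Kel[, b, beta] <- w * (dP11 * fe$BR[, b] + dP12 * fe$BZ[, b] +
                               dP33 / (3 * Rc))
      Kel[, 3L + b, beta] <- w * (dP21 * fe$BR[, b] + dP22 * fe$BZ[, b])
    }
    if (has_f) {
      dJC11 <- dJ * Ci11 - J * T11
      dJC12 <- dJ * Ci12 - J * T12
      dJC22 <- dJ * Ci22 - J * T22
      src_u <- if (identical(glaw, "stress")) dsrcdth * dthb else 0
      jn_u  <- if (identical(glaw, "stress")) dJndth * dthb else 0
      for (b in 1:3) {
        Kel[, 6L + b, beta] <- w *
          (fe$BR[, b] * (dJC11 * vfR + dJC12 * vfZ) +
           fe$BZ[, b] * (dJC12 * vfR + dJC22 * vfZ) +
           (dJ / dt - src_u) / 3)
        if (has_c)
          Kel[, 9L + b, beta] <- w *
            (fe$BR[, b] * (dJC11 * vcR + dJC12 * vcZ) +
             fe$BZ[, b] * (dJC12 * vcR + dJC22 * vcZ) +
             (dJ * cc / dt + dJ * cdot -
                rho_bar_s * src_u * cc + jn_u * cdot) / 3)
      }
    }
  }

  # --- potential columns --------------------------------------------------
  if (has_f) {
    phi_c_eff <- if (has_c) tp$phi_c else 0
    for (a in 1:3) {                       # column: mu_f at node a
      for (b in 1:3) {
        # momentum rows: dpf = N_a = 1/3
        Kel[, b, 6L + a] <- -w / 3 *
          (Q11 * fe$BR[, b] + Q12 * fe$BZ[, b] + Q33 / (3 * Rc))
        Kel[, 3L + b, 6L + a] <- -w / 3 * (Q21 * fe$BR[, b] + Q22 * fe$BZ[, b])
        Gba <- fe$BR[, b] * (JC11 * fe$BR[, a] + JC12 * fe$BZ[, a]) +
               fe$BZ[, b] * (JC12 * fe$BR[, a] + JC22 * fe$BZ[, a])
        Kel[, 6L + b, 6L + a] <- w * aff * Gba
        if (has_c) Kel[, 9L + b, 6L + a] <- w * afc * Gba
      }
    }
    if (has_c) {
      # gradients of mobility-weighted potentials used by the c-derivative
      HfR <- JC11 * ef$gfR + JC12 * ef$gfZ; HfZ <- JC12 * ef$gfR + JC22 * ef$gfZ
      HcR <- JC11 * ef$gcR + JC12 * ef$gcZ; HcZ <- JC12 * ef$gcR + JC22 * ef$gcZ
      dafc <- tp$kff * tp$bfc                    # d afc / dc
      dacc <- tp$dcc / RT + 2 * tp$kff * tp$bfc^2 * cc
      dcdq <- cc / RT / 3                        # dc / d mu_c(node) at GP
      src_c <- (Jdot - rho_bar_s * src + Jn / dt) / 3
      conc_coup <- identical(glaw, "concentration")
      if (conc_coup) {
        dth_q <- gfac * dcdq                     # d theta / d mu_c(node)
        gS11 <- (dSth_ci * Ci11 + dSth_i) * dth_q
        gS12 <- dSth_ci * Ci12 * dth_q
        gS22 <- (dSth_ci * Ci22 + dSth_i) * dth_q
        gS33 <- (dSth_ci * Ci33 + dSth_i) * dth_q
        gP11 <- ef$F11 * gS11 + ef$F12 * gS12
        gP12 <- ef$F11 * gS12 + ef$F12 * gS22
        gP21 <- ef$F21 * gS11 + ef$F22 * gS12
        gP22 <- ef$F21 * gS12 + ef$F22 * gS22
        gP33 <- ef$F33 * gS33
      }
      for (a in 1:3) {                     # column: mu_c at node a
        for (b in 1:3) {
          Gba <- fe$BR[, b] * (JC11 * fe$BR[, a] + JC12 * fe$BZ[, a]) +
                 fe$BZ[, b] * (JC12 * fe$BR[, a] + JC22 * fe$BZ[, a])
          Hc_b <- fe$BR[, b] * HcR + fe$BZ[, b] * HcZ
          Hf_b <- fe$BR[, b] * HfR + fe$BZ[, b] * HfZ
          Kel[, 6L + b, 9L + a] <- w * (afc * Gba + dafc * dcdq * Hc_b)
          Kel[, 9L + b, 9L + a] <- w * (acc * Gba +
              dcdq * (dafc * Hf_b + dacc * Hc_b) + src_c * dcdq)
          if (conc_coup) {
            # growth responds to the concentration: stress, source and
            # porosity terms all move with the locally converged stretch
            Kel[, b, 9L + a] <- Kel[, b, 9L + a] + w *
              (gP11 * fe$BR[, b] + gP12 * fe$BZ[, b] + gP33 / (3 * Rc))
            Kel[, 3L + b, 9L + a] <- Kel[, 3L + b, 9L + a] + w *
              (gP21 * fe$BR[, b] + gP22 * fe$BZ[, b])
            Kel[, 6L + b, 9L + a] <- Kel[, 6L + b, 9L + a] -
              w * dsrcdth * dth_q / 3
            Kel[, 9L + b, 9L + a] <- Kel[, 9L + b, 9L + a] + w *
              (-rho_bar_s * dsrcdth * cc + dJndth * cdot) * dth_q / 3
          }
          if (phi_c_eff != 0) {
            Kel[, b, 9L + a] <- Kel[, b, 9L + a] - w * phi_c_eff * cc / 3 *
              (Q11 * fe$BR[, b] + Q12 * fe$BZ[, b] + Q33 / (3 * Rc))
            Kel[, 3L + b, 9L + a] <- Kel[, 3L + b, 9L + a] -
              w * phi_c_eff * cc / 3 * (Q21 * fe$BR[, b] + Q22 * fe$BZ[, b])
          }
        }
      }
    }
  }

  list(Rel = Rel, Kel = Kel, aux = aux, ef = ef)
}

# Scatter element residuals/tangents into the global system.
scatter_residual <- function(fe, Rel) {
  Psi <- numeric(fe$ndof)
  acc <- rowsum(as.vector(Rel), as.vector(fe$idx))
  Psi[as.integer(rownames(acc))] <- acc
  Psi
}

scatter_tangent <- function(fe, Kel) {
  Matrix::sparseMatrix(i = fe$trip_i, j = fe$trip_j, x = as.vector(Kel),
                       dims = c(fe$ndof, fe$ndof))
}
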