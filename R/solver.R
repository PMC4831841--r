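# Model setup, boundary conditions, the per-element growth update, the
# backward-Euler Newton-Raphson time stepper, and the single-element
# residual/tangent surface used for verification.

#' Assemble a GMPHETS model
#'
#' Binds the mesh, the dof map for the chosen mode, material, transport and
#' growth descriptions into one object consumed by [time_step()] and
#' [run_scenario()].
#'
#' @param mesh A `gmphets_mesh`.
#' @param mode `"MPHETS"`, `"PHE"` or `"HE"`.
#' @param mat A `gmphets_material`.
#' @param tp A `gmphets_transport`.
#' @param growth_law A `gmphets_growth_law`, or `NULL` for no growth.
#' @param growth_case `"solid_only"` or `"solid_fluid"`; sets the
#'   normalised solid growth density `rho_bar_s`.
#' @return A `gmphets_model` list.
#' @export
gmphets_model <- function(mesh, mode = "MPHETS", mat = material_params(),
                          tp = transport_params(),
                          growth_law = NULL,
                          growth_case = c("solid_only", "solid_fluid")) {
  growth_case <- match.arg(growth_case)
  dofmap <- dof_map(mesh, mode)
  structure(list(
    mesh = mesh, dofmap = dofmap, mode = mode, mat = mat, tp = tp,
    growth_law = growth_law, growth_case = growth_case,
    rho_bar_s = rho_bar_s_for(growth_case, tp$n0),
    fe = fe_precompute(mesh, dofmap)
  ), class = "gmphets_model")
}

#' Boundary conditions for the annular strip
#'
#' Dirichlet data are given in physical units (pore pressure in Pa,
#' concentration in mol/m^3) and converted to the potential primaries with
#' the model's datums, which keeps every result invariant under a shift of
#' the baselines. The inner pressure of the arterial benchmarks acts
#' twice: as a follower traction on the current inner
#' radius and as the pore-pressure Dirichlet value at the inner nodes.
#'
#' @param pressure_inner Inner lumen pressure (Pa) applied as traction
#'   (ignored when `rigid`).
#' @param pf_inner,pf_outer Pore-pressure Dirichlet values (Pa); `NULL`
#'   leaves the face free (natural, zero-flux).
#' @param c_inner,c_outer Material-side concentration Dirichlet values
#'   (mol/m^3); `NULL` leaves the face free.
#' @param rigid Fix all displacement dofs ("held fixed at every point").
#' @param plane_strain Fix every axial displacement (long-cylinder
#'   cross-section).
#' @return A `gmphets_bc` list.
#' @export
boundary_conditions <- function(pressure_inner = 0,
                                pf_inner = NULL, pf_outer = NULL,
                                c_inner = NULL, c_outer = NULL,
                                rigid = FALSE, plane_strain = TRUE) {
  structure(list(pressure_inner = pressure_inner,
                 pf_inner = pf_inner, pf_outer = pf_outer,
                 c_inner = c_inner, c_outer = c_outer,
                 rigid = rigid, plane_strain = plane_strain),
            class = "gmphets_bc")
}

# Fixed dofs and their (fully ramped) values; Dirichlet scaling by the load
# factor is applied to pressure-like values, concentrations are held at
# their bath-equilibrated values from the start.
bc_tables <- function(model, bc) {
  dm <- model$dofmap; mesh <- model$mesh; tp <- model$tp
  fixed <- integer(0); value <- numeric(0); ramped <- logical(0)
  add <- function(dofs, vals, rmp) {
    fixed  <<- c(fixed, dofs)
    value  <<- c(value, rep_len(vals, length(dofs)))
    ramped <<- c(ramped, rep_len(rmp, length(dofs)))
  }
  all_nodes <- mesh$nodes$id
  if (bc$rigid) {
    add(dof_index(dm, all_nodes, "u_R"), 0, FALSE)
    add(dof_index(dm, all_nodes, "u_Z"), 0, FALSE)
  } else if (bc$plane_strain) {
    add(dof_index(dm, all_nodes, "u_Z"), 0, FALSE)
  }
  if ("mu_f" %in% dm$fields) {
    mu_f_of <- function(pf, cc) {
      if (model$mode == "MPHETS" && !is.null(cc))
        potentials_forward(pf, cc, tp)$mu_f
      else pf + tp$p0o
    }
    if (!is.null(bc$pf_inner))
      add(dof_index(dm, mesh$boundary_sets$inner, "mu_f"),
          mu_f_of(bc$pf_inner, bc$c_inner), TRUE)
    if (!is.null(bc$pf_outer))
      add(dof_index(dm, mesh$boundary_sets$outer, "mu_f"),
          mu_f_of(bc$pf_outer, bc$c_outer), TRUE)
  }
  if ("mu_c" %in% dm$fields) {
    if (!is.null(bc$c_inner))
      add(dof_index(dm, mesh$boundary_sets$inner, "mu_c"),
          potentials_forward(0, bc$c_inner, tp)$mu_c, FALSE)
    if (!is.null(bc$c_outer))
      add(dof_index(dm, mesh$boundary_sets$outer, "mu_c"),
          potentials_forward(0, bc$c_outer, tp)$mu_c, FALSE)
  }
  if (anyDuplicated(fixed))
    gmphets_stop("a dof is constrained twice", "parameter_error")
  free <- setdiff(seq_len(dm$ndof), fixed)
  list(fixed = fixed, value = value, ramped = ramped, free = free)
}

#' Initial state of a model
#'
#' Zero displacement, zero pore pressure and a uniform initial
#' concentration; growth stretch one everywhere.
#'
#' @param model A `gmphets_model`.
#' @param c_init Initial uniform concentration (mol/m^3) for MPHETS mode.
#' @return A `gmphets_state` list with the global primary vector `p`,
#'   per-element `theta`, and per-element histories `J`, `c`.
#' @export
initial_state <- function(model, c_init = 1.28e-3) {
  dm <- model$dofmap
  p <- numeric(dm$ndof)
  ne <- nrow(model$mesh$elements)
  if ("mu_f" %in% dm$fields)
    p[dof_index(dm, model$mesh$nodes$id, "mu_f")] <- model$tp$p0o  # pf = 0
  c_el <- rep(0, ne)
  if ("mu_c" %in% dm$fields) {
    p[dof_index(dm, model$mesh$nodes$id, "mu_c")] <-
      potentials_forward(0, c_init, model$tp)$mu_c
    c_el <- rep(c_init, ne)
  }
  structure(list(t = 0, p = p, theta = rep(1, ne), J = rep(1, ne),
                 c = c_el, n = rep(model$tp$n0, ne), step = 0L),
            class = "gmphets_state")
}

# Vectorised per-element growth update at fixed total deformation.
# Returns the new theta vector.
update_growth <- function(model, ef, th_n, dt, control) {
  gl <- model$growth_law
  if (is.null(gl)) return(th_n)
  if (gl$law == "time_linear") return(theta_update_linear(th_n, gl$alpha, dt))

  lam <- model$mat$lam; mu <- model$mat$mu
  phi_of <- switch(gl$law,
    concentration = function(th) list(phi = ef$c - gl$c_thresh,
                                      dphi = 0 * th),
    stress = function(th) list(
      phi  = 3 * (lam * (log(ef$J) - 3 * log(th)) - mu) + mu * ef$trC / th^2,
      dphi = -9 * lam / th - 2 * mu * ef$trC / th^3))

  ne <- length(th_n)
  th <- th_n
  lo <- rep(gl$theta_min, ne); hi <- rep(gl$theta_max, ne)
  active <- rep(TRUE, ne)
  for (it in 1:50) {
    d <- phi_of(th)
    k <- k_theta(th, sign(d$phi), gl)
    r <- th - th_n - dt * k * d$phi
    hi <- ifelse(active & r > 0, pmin(hi, th), hi)
    lo <- ifelse(active & r <= 0, pmax(lo, th), lo)
    active <- active & abs(r) >= 1e-12
    if (!any(active)) break
    dk <- k_theta_dtheta(th, sign(d$phi), gl)
    dr <- 1 - dt * (dk * d$phi + k * d$dphi)
    step <- ifelse(is.finite(dr) & dr != 0, r / dr, NA_real_)
    thn <- th - step
    bad <- !is.finite(thn) | thn <= lo | thn >= hi
    thn[bad] <- (lo[bad] + hi[bad]) / 2
    th <- ifelse(active, thn, th)
  }
  if (any(active))
    gmphets_stop("local growth update failed to converge (reduce the time step)",
                 "local_growth_divergence_error")
  pmin(pmax(th, gl$theta_min), gl$theta_max)
}

# Follower traction on the inner face: total radial force p * 2 pi r * h
# split between the two inner nodes; evaluated at the current radius.
external_force <- function(model, bc, p, load_factor) {
  dm <- model$dofmap
  f <- numeric(dm$ndof)
  if (!bc$rigid && bc$pressure_inner != 0) {
    nodes <- model$mesh$boundary_sets$inner
    dofs <- dof_index(dm, nodes, "u_R")
    r_cur <- model$mesh$nodes$R[nodes] + p[dofs]
    f[dofs] <- load_factor * bc$pressure_inner * 2 * pi * r_cur *
      model$mesh$strip_height / 2
  }
  f
}

default_control <- function(control = list()) {
  utils::modifyList(list(tol_r = 1e-8, tol_p = 1e-10, maxit = 25L,
                         atol = 1e-30), control)
}

# Blockwise norms of a residual restricted to free dofs.
block_norms <- function(dofmap, v, free) {
  fld <- ((free - 1L) %% dofmap$ndof_per_node) + 1L
  vapply(seq_along(dofmap$fields),
         function(k) sqrt(sum(v[free[fld == k]]^2)), numeric(1))
}

#' Advance the model one time step
#'
#' Backward-Euler step with the nested iteration of the growth framework:
#' every global Newton-Raphson iteration first updates the growth stretch
#' element-by-element at fixed total deformation (exactly for the
#' time-linear law, by a bracketed local Newton for the nonlinear laws),
#' then re-assembles stresses, fluxes and sources and performs one global
#' solve. Convergence requires each primary block's residual to drop below
#' `tol_r` relative to its initial value, or the increment to fall below
#' `tol_p`.
#'
#' @param model A `gmphets_model`.
#' @param state A `gmphets_state` (converged at time `t_n`).
#' @param bc A `gmphets_bc`.
#' @param dt Time step (s).
#' @param load_factor Scale in `[0, 1]` applied to ramped boundary data.
#' @param growth_active Is the growth law evolving during this step?
#' @param control List overriding `tol_r`, `tol_p`, `maxit`.
#' @return The converged `gmphets_state` at `t_n + dt`, carrying the
#'   iteration count and final residual norm as attributes-like fields
#'   `iterations`, `resnorm`.
#' @export
time_step <- function(model, state, bc, dt, load_factor = 1,
                      growth_active = FALSE, control = list()) {
  ctl <- default_control(control)
  fe <- model$fe; dm <- model$dofmap
  bct <- bc_tables(model, bc)
  p <- state$p
  vals <- bct$value * ifelse(bct$ramped, load_factor, 1)
  p[bct$fixed] <- vals
  free <- bct$free
  th_n <- state$theta
  hist <- list(J = state$J, c = state$c)
  th <- th_n
  ref <- NULL
  it <- 0L
  inc_small <- FALSE
  bn_prev <- NULL
  stalled <- 0L
  repeat {
    it <- it + 1L
    if (growth_active) {
      ef <- element_fields(fe, p, model$tp)
      th <- update_growth(model, ef, th_n, dt, ctl)
    }
    asm <- assemble_core(fe, model$mat, model$tp, model$rho_bar_s,
                         p, th, th_n, hist, dt, want_tangent = TRUE,
                         growth = list(gl = model$growth_law,
                                       active = growth_active))
    fext <- external_force(model, bc, p, load_factor)
    Psi <- scatter_residual(fe, asm$Rel) - fext
    bn <- block_norms(dm, Psi, free)
    # gross magnitude of the summed element contributions: the residual is
    # converged when it is tol_r below its own history or at the roundoff
    # floor of the assembly cancellation
    gross <- block_norms(dm, scatter_residual(fe, abs(asm$Rel)) + abs(fext),
                         free)
    ref <- if (is.null(ref)) pmax(bn, ctl$atol) else pmax(ref, bn)
    if (all(bn <= pmax(ctl$tol_r * ref, 1e-10 * gross, ctl$atol)) ||
        inc_small) break
    # a Newton iteration that stops contracting while already far below
    # its reference has reached the cancellation floor of the assembly
    if (!is.null(bn_prev) && all(bn >= 0.5 * bn_prev)) {
      stalled <- stalled + 1L
      if (stalled >= 2L && all(bn <= 1e-4 * ref)) break
    } else stalled <- 0L
    bn_prev <- bn
    if (it > ctl$maxit)
      gmphets_stop(sprintf(
        "global Newton did not converge in %d iterations (relative residual %.3e); the time step may be too large",
        ctl$maxit, max(bn / ref)), "step_failure_error")
    K <- scatter_tangent(fe, asm$Kel)
    Kf <- K[free, free, drop = FALSE]
    # symmetric diagonal equilibration guards the solve against the very
    # different scales of the displacement, fluid and species blocks
    d <- sqrt(abs(Matrix::diag(Kf)))
    d[d == 0 | !is.finite(d)] <- 1
    Dm <- Matrix::Diagonal(x = 1 / d)
    dp <- as.vector(Dm %*% Matrix::solve(Dm %*% Kf %*% Dm,
                                         as.vector(Dm %*% (-Psi[free]))))
    if (any(!is.finite(dp)))
      gmphets_stop("singular constrained system in the global solve",
                   "solver_error")
    if (model$mode == "MPHETS") {
      # the concentration is exponential in mu_c; clamp its Newton
      # increment to +-2 R theta per iteration to keep the recovery finite
      cap <- 2 * model$tp$Rbar * model$tp$theta
      is_mc <- ((free - 1L) %% dm$ndof_per_node) + 1L ==
        match("mu_c", dm$fields)
      dp[is_mc] <- pmin(pmax(dp[is_mc], -cap), cap)
    }
    p[free] <- p[free] + dp
    dfull <- numeric(dm$ndof); dfull[free] <- dp
    pfull <- numeric(dm$ndof); pfull[free] <- p[free]
    inc_bn <- block_norms(dm, dfull, free)
    p_bn <- block_norms(dm, pfull, free)
    # absolute increment scales: below these a primary change is
    # physically meaningless (metres, Pa, J/mol)
    abs_scale <- c(u_R = 1e-15, u_Z = 1e-15, mu_f = 1e-5, mu_c = 1e-6)
    nfld <- vapply(seq_along(dm$fields), function(k)
      sum(((free - 1L) %% dm$ndof_per_node) + 1L == k), numeric(1))
    floor_bn <- abs_scale[dm$fields] * sqrt(pmax(nfld, 1))
    inc_small <- all(inc_bn <= pmax(ctl$tol_p * p_bn, floor_bn))
  }
  finish_step(model, state, bc, p, th, asm, dt, it, max(bn / ref))
}

finish_step <- function(model, state, bc, p, th, asm, dt, it, resnorm) {
  aux <- asm$aux
  adm <- aux$n > 0 & aux$n < 1
  if (any(!adm)) {
    bad <- which(!adm)[1]
    bounds <- check_admissibility(aux$J[bad], th[bad], model$tp$n0,
                                  model$rho_bar_s)
    gmphets_stop(sprintf(
      "porosity left (0,1) in element %d (n = %.4f, theta = %.5f, bounds [%.5f, %.5f])",
      bad, aux$n[bad], th[bad], bounds$theta_lower, bounds$theta_upper),
      "porosity_admissibility_error")
  }
  structure(list(t = state$t + dt, p = p, theta = th, J = aux$J, c = aux$c,
                 n = aux$n, step = state$step + 1L, aux = aux,
                 iterations = it, resnorm = resnorm),
            class = "gmphets_state")
}

#' Assemble the global system at a given state
#'
#' Returns the global stiffness, the dissipation matrix (the part of the
#' time-discrete Jacobian that scales with `1/dt`, reported `dt`-scaled so
#' that the full Jacobian is `K_hat + C_hat / dt`), the primary residual
#' with Dirichlet rows eliminated, and the secondary residual `Psi_g`
#' (identically zero here: pore pressure and concentration are recovered in
#' closed form from the interpolated potentials at every Gauss point, so the
#' monitored secondary bookkeeping of the growth framework is exactly
#' satisfied).
#'
#' @param model A `gmphets_model`.
#' @param state A `gmphets_state`.
#' @param bc A `gmphets_bc`.
#' @param dt Time step (s) used for the rate terms.
#' @param load_factor Scale applied to ramped boundary data.
#' @return List with sparse `K_hat`, `C_hat`, residual `Psi` (free dofs),
#'   `Psi_g` (0), index vectors `free` and `fixed`, and the per-element
#'   auxiliary state `aux`.
#' @export
assemble <- function(model, state, bc, dt = Inf, load_factor = 1) {
  fe <- model$fe
  bct <- bc_tables(model, bc)
  p <- state$p
  p[bct$fixed] <- bct$value * ifelse(bct$ramped, load_factor, 1)
  hist <- list(J = state$J, c = state$c)
  a_dt  <- assemble_core(fe, model$mat, model$tp, model$rho_bar_s, p,
                         state$theta, state$theta, hist, dt)
  a_inf <- assemble_core(fe, model$mat, model$tp, model$rho_bar_s, p,
                         state$theta, state$theta, hist, Inf,
                         want_tangent = TRUE)
  K_inf <- scatter_tangent(fe, a_inf$Kel)
  K_dt  <- scatter_tangent(fe, a_dt$Kel)
  Psi <- scatter_residual(fe, a_dt$Rel) -
    external_force(model, bc, p, load_factor)
  list(K_hat = K_inf, C_hat = (K_dt - K_inf) * dt, Psi = Psi[bct$free],
       Psi_g = 0, free = bct$free, fixed = bct$fixed, aux = a_dt$aux)
}

# Build a one-element fe structure from corner coordinates.
single_element_fe <- function(coords, mode) {
  mesh <- structure(list(
    nodes = data.frame(id = 1:3, R = coords[, 1], Z = coords[, 2]),
    elements = matrix(1:3, 1, 3),
    ri = min(coords[, 1]), ro = max(coords[, 1]),
    strip_height = diff(range(coords[, 2]))
  ), class = "gmphets_mesh")
  geo <- element_geometry(coords)
  mesh$area <- geo$area; mesh$gauss_R <- geo$gauss_R
  dm <- dof_map(mesh, mode)
  list(fe = fe_precompute(mesh, dm), dofmap = dm)
}

# Pack nodal dof values of one element into a global-order vector.
pack_element_dofs <- function(dofmap, u, mu_f, mu_c) {
  p <- numeric(dofmap$ndof)
  p[dof_index(dofmap, 1:3, "u_R")] <- u[, 1]
  p[dof_index(dofmap, 1:3, "u_Z")] <- u[, 2]
  if ("mu_f" %in% dofmap$fields) p[dof_index(dofmap, 1:3, "mu_f")] <- mu_f
  if ("mu_c" %in% dofmap$fields) p[dof_index(dofmap, 1:3, "mu_c")] <- mu_c
  p
}

element_local_order <- function(mode) {
  switch(mode,
    HE = c("u_R1", "u_R2", "u_R3", "u_Z1", "u_Z2", "u_Z3"),
    PHE = c("u_R1", "u_R2", "u_R3", "u_Z1", "u_Z2", "u_Z3",
            "mu_f1", "mu_f2", "mu_f3"),
    MPHETS = c("u_R1", "u_R2", "u_R3", "u_Z1", "u_Z2", "u_Z3",
               "mu_f1", "mu_f2", "mu_f3", "mu_c1", "mu_c2", "mu_c3"))
}

#' Residual vector of a single element
#'
#' Galerkin residual of the momentum, fluid and species conservation
#' equations on one linear axisymmetric triangle with single-point
#' quadrature; rates are backward differences against the previous-step
#' values, and `dt = Inf` gives the rate-free (static) residual.
#'
#' @param coords 3 x 2 corner coordinates (R, Z), counter-clockwise.
#' @param u 3 x 2 nodal displacements (u_R, u_Z).
#' @param mu_f,mu_c Nodal fluid and chemical potentials (length 3).
#' @param mat,tp Material and transport parameter sets.
#' @param theta,theta_n Current and previous growth stretch of the element.
#' @param rho_bar_s Normalised solid growth density.
#' @param J_n,c_n Previous-step Jacobian and concentration at the Gauss
#'   point.
#' @param dt Time step (s).
#' @param mode `"MPHETS"`, `"PHE"` or `"HE"`.
#' @return Named residual vector in local dof order (u_R 1..3, u_Z 1..3,
#'   then potentials).
#' @export
element_residual <- function(coords, u, mu_f = numeric(3), mu_c = numeric(3),
                             mat = material_params(), tp = transport_params(),
                             theta = 1, theta_n = theta, rho_bar_s = 1,
                             J_n = 1, c_n = 0, dt = Inf, mode = "MPHETS") {
  se <- single_element_fe(coords, mode)
  p <- pack_element_dofs(se$dofmap, u, mu_f, mu_c)
  a <- assemble_core(se$fe, mat, tp, rho_bar_s, p, theta, theta_n,
                     list(J = J_n, c = c_n), dt, want_tangent = FALSE)
  stats::setNames(as.vector(a$Rel), element_local_order(mode))
}

#' Consistent tangent matrix of a single element
#'
#' Analytic linearisation of [element_residual()] with respect to the nodal
#' primaries at frozen growth stretch (the growth stretch is an internal
#' variable re-converged by the local update in every global iteration).
#' Verified against finite differences of the residual in the test suite.
#'
#' @inheritParams element_residual
#' @return Named square matrix in local dof order.
#' @export
element_tangent <- function(coords, u, mu_f = numeric(3), mu_c = numeric(3),
                            mat = material_params(), tp = transport_params(),
                            theta = 1, theta_n = theta, rho_bar_s = 1,
                            J_n = 1, c_n = 0, dt = Inf, mode = "MPHETS") {
  se <- single_element_fe(coords, mode)
  p <- pack_element_dofs(se$dofmap, u, mu_f, mu_c)
  a <- assemble_core(se$fe, mat, tp, rho_bar_s, p, theta, theta_n,
                     list(J = J_n, c = c_n), dt, want_tangent = TRUE)
  K <- matrix(a$Kel, se$fe$nl, se$fe$nl)
  dimnames(K) <- list(element_local_order(mode), element_local_order(mode))
  K
}

#' Net fluid volume flux across the boundary
#'
#' Discrete boundary influx computed from the converged fluid residual at
#' the constrained (Dirichlet) fluid nodes: at the solution the residual
#' vanishes on free dofs, so the reaction on the fixed dofs equals the
#' boundary flux. Used by the source/flux balance checks.
#'
#' @param model A `gmphets_model`.
#' @param state A converged `gmphets_state`.
#' @param state_prev The state at the start of the step (for the rates);
#'   defaults to `state`, which gives the rate-free balance.
#' @param dt Time step used for the rate terms.
#' @return List with `outflux` (m^3/s, positive out of the domain) and
#'   `source_total` (m^3/s, volume created by growth).
#' @export
fluid_balance <- function(model, state, state_prev = state, dt = Inf) {
  fe <- model$fe
  a <- assemble_core(fe, model$mat, model$tp, model$rho_bar_s, state$p,
                     state$theta, state_prev$theta,
                     list(J = state_prev$J, c = state_prev$c),
                     dt, want_tangent = FALSE)
  Psi <- scatter_residual(fe, a$Rel)
  dm <- model$dofmap
  fdofs <- dof_index(dm, model$mesh$nodes$id, "mu_f")
  vol <- 2 * pi * model$mesh$gauss_R * model$mesh$area
  # summing the fluid rows applies the unit test function: the interior
  # (free) rows vanish at the solution, so the sum is the reaction at the
  # Dirichlet nodes, i.e. minus the net boundary outflux
  list(outflux = -sum(Psi[fdofs]), source_total = sum(a$aux$src * vol))
}
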