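# Scenario presets reproducing the arterial test problems, the phase-driven
# run loop, configuration I/O and result tables.

#' Millimetres of mercury to pascal
#' @param x Pressure in mmHg.
#' @return Pressure in Pa (1 mmHg = 133.322 Pa).
#' @export
mmHg <- function(x) 133.322 * x

scenario_presets <- function() {
  base <- list(
    ri = 1e-3, ro = 1.25e-3, strip_height = 2.5e-5,
    Pi_mmHg = 100,
    C10 = 1e6, D1 = 5.5e-9,
    kff = 2e-14, bfc = 6e-4, dcc = 4.55e-14,
    n0 = 0.5, phi_c = 0, gamma_mat = 0.5,
    c_inner_bath = 6.40e-3, c_outer_bath = 6.40e-4, partition = 0.5,
    law = "none", alpha = 0.0008,
    tau_plus = 200, tau_minus = 200, gamma_plus = 2, gamma_minus = 3,
    theta_max = 1.2, theta_min = 0.8, c_thresh = 0.009185,
    growth_case = "solid_only", growth_start = "simultaneous",
    rigid = FALSE,
    n_load = 5, n_consol = 1, n_growth = 0, dt = 50,
    output_every = 10
  )
  list(
    `rigid-time` = utils::modifyList(base, list(
      model_mode = "PHE", n_radial = 60, rigid = TRUE,
      law = "time_linear", growth_start = "after-consolidation",
      n_load = 0, n_consol = 10, n_growth = 300, dt = 0.5,
      output_every = 10)),
    `stress-mphets` = utils::modifyList(base, list(
      model_mode = "MPHETS", n_radial = 160,
      law = "stress", tau_plus = 1e11, tau_minus = 1e11,
      n_load = 5, n_consol = 1, n_growth = 1000, dt = 50,
      output_every = 50)),
    `stress-he` = utils::modifyList(base, list(
      model_mode = "HE", n_radial = 160,
      law = "stress", tau_plus = 1e11, tau_minus = 1e11,
      n_load = 5, n_consol = 1, n_growth = 1000, dt = 50,
      output_every = 50)),
    `conc-largeP` = utils::modifyList(base, list(
      model_mode = "MPHETS", n_radial = 80,
      law = "concentration", dcc = 4.55e-14,
      n_load = 5, n_consol = 0, n_growth = 2000, dt = 50,
      output_every = 100)),
    `conc-smallP` = utils::modifyList(base, list(
      model_mode = "MPHETS", n_radial = 80,
      law = "concentration", dcc = 4.55e-12,
      n_load = 5, n_consol = 0, n_growth = 2000, dt = 50,
      output_every = 100))
  )
}

#' Scenario configuration
#'
#' Returns one of the preset arterial test configurations, optionally
#' overridden field by field. Presets: `"rigid-time"` (time-driven growth
#' of a rigid porohyperelastic cylinder), `"stress-mphets"` /
#' `"stress-he"` (stress-driven growth of the pressurised cylinder as a
#' porohyperelastic-with-transport vs a purely hyperelastic model), and
#' `"conc-largeP"` / `"conc-smallP"` (concentration-driven growth at the
#' two diffusivities, i.e. large and small Peclet-like number).
#'
#' @param scenario Preset name.
#' @param ... Field overrides (e.g. `n_radial = 20`, `n_growth = 100`).
#' @return A `gmphets_config` list.
#' @export
scenario_config <- function(scenario = c("rigid-time", "stress-mphets",
                                         "stress-he", "conc-largeP",
                                         "conc-smallP"), ...) {
  scenario <- match.arg(scenario)
  cfg <- scenario_presets()[[scenario]]
  cfg$scenario <- scenario
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(cfg), "model_mode"))
  if (length(unknown))
    gmphets_stop(paste("unknown config fields:", paste(unknown, collapse = ", ")),
                 "config_error")
  cfg <- utils::modifyList(cfg, dots)
  structure(cfg, class = "gmphets_config")
}

#' Peclet-like number of a configuration
#'
#' `beta = kff * bfc / dcc`, the ratio of convective to diffusive species
#' transport.
#'
#' @param config A `gmphets_config`.
#' @return Numeric `beta`.
#' @export
peclet_beta <- function(config) config$kff * config$bfc / config$dcc

config_to_model <- function(config) {
  mesh <- generate_strip_mesh(config$ri, config$ro, config$n_radial,
                              config$strip_height)
  c_in <- partition_concentration(config$c_inner_bath, config$partition)
  c_out <- partition_concentration(config$c_outer_bath, config$partition)
  tp <- transport_params(kff = config$kff, bfc = config$bfc, dcc = config$dcc,
                         n0 = config$n0, phi_c = config$phi_c,
                         gamma_mat = config$gamma_mat,
                         c_floor = 0.1 * min(c_in, c_out))
  gl <- if (identical(config$law, "none")) NULL else
    growth_law_params(config$law, alpha = config$alpha,
                      tau_plus = config$tau_plus, tau_minus = config$tau_minus,
                      gamma_plus = config$gamma_plus,
                      gamma_minus = config$gamma_minus,
                      theta_max = config$theta_max,
                      theta_min = config$theta_min,
                      c_thresh = config$c_thresh)
  model <- gmphets_model(mesh, mode = config$model_mode,
                         mat = material_params(config$C10, config$D1),
                         tp = tp, growth_law = gl,
                         growth_case = config$growth_case)
  Pi <- mmHg(config$Pi_mmHg)
  bc <- if (config$model_mode == "HE")
    boundary_conditions(pressure_inner = Pi, rigid = config$rigid)
  else if (config$model_mode == "PHE")
    boundary_conditions(pressure_inner = Pi, pf_inner = Pi, pf_outer = 0,
                        rigid = config$rigid)
  else
    boundary_conditions(pressure_inner = Pi, pf_inner = Pi, pf_outer = 0,
                        c_inner = c_in, c_outer = c_out, rigid = config$rigid)
  list(model = model, bc = bc, c_init = c_out)
}

phase_schedule <- function(config) {
  ph <- list()
  if (config$n_load > 0)
    ph$loading <- list(n = config$n_load, dt = config$dt, growth = FALSE,
                       ramp = TRUE)
  if (config$n_consol > 0)
    ph$consolidation <- list(n = config$n_consol, dt = config$dt,
                             growth = FALSE, ramp = FALSE)
  if (config$n_growth > 0)
    ph$growth <- list(n = config$n_growth, dt = config$dt, growth = TRUE,
                      ramp = FALSE)
  ph
}

nodal_snapshot <- function(model, state) {
  dm <- model$dofmap; nodes <- model$mesh$nodes
  uR <- state$p[dof_index(dm, nodes$id, "u_R")]
  uZ <- state$p[dof_index(dm, nodes$id, "u_Z")]
  out <- data.frame(`t [s]` = state$t, node = nodes$id, `R [m]` = nodes$R,
                    `Z [m]` = nodes$Z, `u_R [m]` = uR, `u_Z [m]` = uZ,
                    check.names = FALSE)
  if ("mu_f" %in% dm$fields)
    out$`mu_f [Pa]` <- state$p[dof_index(dm, nodes$id, "mu_f")]
  if ("mu_c" %in% dm$fields)
    out$`mu_c [J/mol]` <- state$p[dof_index(dm, nodes$id, "mu_c")]
  out
}

gauss_snapshot <- function(model, state) {
  a <- state$aux
  ne <- nrow(model$mesh$elements)
  data.frame(`t [s]` = state$t, element = seq_len(ne),
             `gauss_R [m]` = model$mesh$gauss_R,
             theta = state$theta, n = state$n,
             `pf [Pa]` = a$pf, `c [mol/m^3]` = state$c,
             `trM [Pa]` = a$trM,
             `Seff_RR [Pa]` = a$Seff11, `Seff_ZZ [Pa]` = a$Seff22,
             `Seff_hoop [Pa]` = a$Seff33,
             `sigma_hoop [Pa]` = a$sigma_hoop,
             `sigma_eff_hoop [Pa]` = a$sigma_eff_hoop,
             J = a$J, check.names = FALSE)
}

run_summary_row <- function(model, state, phase) {
  a <- state$aux
  mesh <- model$mesh; dm <- model$dofmap
  uR <- state$p[dof_index(dm, mesh$nodes$id, "u_R")]
  r_in <- mesh$ri + uR[mesh$boundary_sets$inner[1]]
  r_out <- mesh$ro + uR[mesh$boundary_sets$outer[1]]
  trM_nodal <- nodal_average(mesh, a$trM)
  data.frame(`t [s]` = state$t, step = state$step, phase = phase,
             iterations = state$iterations, resnorm = state$resnorm,
             `thickness [m]` = r_out - r_in, `r_outer [m]` = r_out,
             theta_min = min(state$theta), theta_max = max(state$theta),
             n_min = min(state$n), n_max = max(state$n),
             `pf_min [Pa]` = min(a$pf), `pf_max [Pa]` = max(a$pf),
             `trM_avg_min [Pa]` = min(trM_nodal),
             `trM_avg_max [Pa]` = max(trM_nodal),
             check.names = FALSE)
}

#' Run a preset or custom scenario
#'
#' Builds the model from the configuration and integrates the phase
#' schedule (pressure ramp over the loading steps, consolidation, then
#' growth), collecting a per-step summary and nodal/Gauss-point snapshots
#' at the output cadence.
#'
#' @param config A `gmphets_config` from [scenario_config()] (or a config
#'   file via [read_config()]).
#' @param control Solver control overrides for [time_step()].
#' @param verbose Print one log line per step (time, phase, iterations,
#'   residual, growth-stretch and porosity ranges).
#' @return A `gmphets_run`: list with `config`, `beta`, data.frames
#'   `summary`, `nodal`, `gauss`, the `mesh`, and the final
#'   `state`.
#' @export
run_scenario <- function(config, control = list(), verbose = FALSE) {
  cm <- config_to_model(config)
  model <- cm$model; bc <- cm$bc
  state <- initial_state(model, c_init = cm$c_init)
  ph <- phase_schedule(config)
  summaries <- list(); nodals <- list(); gausses <- list()
  total <- sum(vapply(ph, function(z) z$n, numeric(1)))
  done <- 0L
  for (phname in names(ph)) {
    pz <- ph[[phname]]
    for (i in seq_len(pz$n)) {
      lf <- if (pz$ramp) i / pz$n else 1
      state <- time_step(model, state, bc, pz$dt, load_factor = lf,
                         growth_active = pz$growth, control = control)
      done <- done + 1L
      summaries[[done]] <- run_summary_row(model, state, phname)
      if (verbose)
        message(sprintf(
          "t=%9.1fs  %-13s it=%d  res=%.2e  theta=[%.4f,%.4f]  n=[%.3f,%.3f]",
          state$t, phname, state$iterations, state$resnorm,
          min(state$theta), max(state$theta), min(state$n), max(state$n)))
      last_of_phase <- i == pz$n
      if (done %% config$output_every == 0 || last_of_phase || done == total) {
        nodals[[length(nodals) + 1L]] <- nodal_snapshot(model, state)
        gausses[[length(gausses) + 1L]] <- gauss_snapshot(model, state)
      }
    }
  }
  structure(list(config = config, beta = peclet_beta(config),
                 summary = do.call(rbind, summaries),
                 nodal = do.call(rbind, nodals),
                 gauss = do.call(rbind, gausses),
                 mesh = model$mesh, model = model, state = state),
            class = "gmphets_run")
}

#' @export
print.gmphets_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("gmphets run '%s' (%s, %d elements): %d steps to t = %g s\n",
              x$config$scenario, x$config$model_mode,
              nrow(x$mesh$elements), nrow(s), s$`t [s]`[nrow(s)]))
  cat(sprintf("  final: theta in [%.4f, %.4f], porosity in [%.3f, %.3f], thickness %.4g mm\n",
              s$theta_min[nrow(s)], s$theta_max[nrow(s)],
              s$n_min[nrow(s)], s$n_max[nrow(s)],
              1e3 * s$`thickness [m]`[nrow(s)]))
  invisible(x)
}

#' Write run outputs to disk
#'
#' CSV tables (`summary.csv`, `nodal.csv`, `gauss.csv`, RFC-4180 dialect,
#' units in the column headers) and optionally one legacy-VTK snapshot per
#' stored output time.
#'
#' @param run A `gmphets_run`.
#' @param dir Output directory (created if missing).
#' @param format Subset of `c("csv", "vtk")`.
#' @return Character vector of files written, invisibly.
#' @export
write_outputs <- function(run, dir, format = "csv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if ("csv" %in% format) {
    for (nm in c("summary", "nodal", "gauss")) {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(run[[nm]], f, row.names = FALSE)
      written <- c(written, f)
    }
    f <- file.path(dir, "config.txt")
    write_config(run$config, f)
    written <- c(written, f)
  }
  if ("vtk" %in% format) {
    ts <- unique(run$gauss$`t [s]`)
    for (i in seq_along(ts)) {
      g <- run$gauss[run$gauss$`t [s]` == ts[i], ]
      nd <- run$nodal[run$nodal$`t [s]` == ts[i], ]
      f <- file.path(dir, sprintf("snapshot_%04d.vtk", i))
      write_mesh_vtk(run$mesh, f,
                     point_data = list(u_R = nd$`u_R [m]`),
                     cell_data = list(theta = g$theta, porosity = g$n,
                                      pf = g$`pf [Pa]`, trM = g$`trM [Pa]`))
      written <- c(written, f)
    }
  }
  invisible(written)
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are
#' parsed as numerics where possible, otherwise kept as strings. The
#' `scenario` key selects the preset the remaining keys override.
#'
#' @param path File path.
#' @return A `gmphets_config`.
#' @export
read_config <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  kv <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", ln))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad))
    gmphets_stop(sprintf("cannot parse config line: '%s'", ln[bad][1]),
                 "config_error")
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- lapply(kv, function(z) {
    v <- trimws(z[3])
    if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- keys
  scen <- vals$scenario %||% "rigid-time"
  vals$scenario <- NULL
  do.call(scenario_config, c(list(scenario = scen), vals))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a configuration as a flat key = value file
#'
#' @param config A `gmphets_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  keys <- names(config)
  vals <- vapply(config, function(v)
    if (is.numeric(v)) format(v, digits = 17) else as.character(v),
    character(1))
  writeLines(sprintf("%s = %s", keys, vals), path)
  invisible(path)
}
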