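# Shared fixtures: small meshes, parameter sets and a cache for the
# full-scale scenario runs used by several acceptance checks.

table1_material <- function() material_params(C10 = 1e6, D1 = 5.5e-9)

# transport_params() defaults are the arterial test-problem values
table1_transport <- function(...) transport_params(...)

# a well-shaped triangle away from the axis
unit_triangle <- function() cbind(c(1e-3, 1.002e-3, 1.001e-3),
                                  c(0, 0, 2e-5))

random_spd3 <- function() {
  A <- matrix(stats::rnorm(9, sd = 0.15), 3, 3)
  diag(3) + crossprod(A)
}

# central finite differences of a vector-valued function
fd_jacobian <- function(f, x, h_rel = 1e-6, h_abs = 1e-9) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (k in seq_along(x)) {
    h <- max(h_rel * abs(x[k]), h_abs)
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    J[, k] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# cache expensive full-scale runs across test files within one session
run_cache <- new.env(parent = emptyenv())

cached_run <- function(name, config, ...) {
  if (is.null(run_cache[[name]]))
    run_cache[[name]] <- run_scenario(config, ...)
  run_cache[[name]]
}
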