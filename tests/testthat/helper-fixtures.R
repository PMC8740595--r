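# Shared, lazily computed fixtures.  testthat runs all files in one
# session, so expensive steady states are solved once and reused.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# Reference parameter sets: the defaults are a moderately spatial regime,
# `spatial_params()` sits deep in the strong-gradient regime near washout.
ref_params <- function() gut_parameters()
spatial_params <- function() gut_parameters(v = 0.181, D = 0.02)

ref_steady <- function(n_cells = 600) {
  fixture(sprintf("ref_steady_%d", n_cells),
          solve_steady_state(ref_params(),
                             build_grid(ref_params(), n_cells)))
}

spatial_steady <- function(n_cells = 600) {
  fixture(sprintf("spatial_steady_%d", n_cells),
          solve_steady_state(spatial_params(),
                             build_grid(spatial_params(), n_cells)))
}

# Tight-tolerance variants used when comparing two independent numerical
# methods against each other.
ref_steady_tight <- function(n_cells = 600) {
  fixture(sprintf("ref_steady_tight_%d", n_cells),
          solve_steady_state(ref_params(),
                             build_grid(ref_params(), n_cells),
                             tol = 1e-10, t_max = 8000))
}

spatial_steady_tight <- function(n_cells = 600) {
  fixture(sprintf("spatial_steady_tight_%d", n_cells),
          solve_steady_state(spatial_params(),
                             build_grid(spatial_params(), n_cells),
                             tol = 1e-10, t_max = 8000))
}
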