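# Shared fixtures: small grids and cached expensive states.  Everything is
# generated in code under fixed seeds.

# cache expensive objects across test files within one run
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# settled resting state of the default cell (5 s of quiescence)
settled_cell <- function(params = cell_params()) {
  key <- paste0("rest_", paste(signif(unlist(params), 6), collapse = "_"))
  fixture(key, function() {
    s <- cell_state_init(params)
    cell_simulate(s, params, duration = 5000, dt = 0.02, trace_dt = 0)$state
  })
}

# end-diastolic single-cell state at a cycle length
paced_cell <- function(cl, params = cell_params()) {
  key <- paste0("paced_", cl, "_", paste(signif(unlist(params), 6), collapse = "_"))
  fixture(key, function() pre_pace_cell(params, cl, max_beats = 150))
}

# deterministic linear "field" whose ordering is known exactly
ramp_field <- function(nx, ny) matrix(seq_len(nx * ny), nx, ny)

expect_within <- function(value, target, tol) {
  expect_true(is.finite(value) && abs(value - target) <= tol,
              label = sprintf("%.4f within %.4f of %.4f", value, tol, target))
}
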