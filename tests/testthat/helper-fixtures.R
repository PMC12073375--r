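# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, expr, envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# A non-overlapping stick mesh at the reference scale: the workhorse for
# recovery and identity checks.
fixture_mesh <- function() memo("mesh", {
  generate_mesh(mesh_spec(
    1024, 1024, um_per_px = 0.05, n_fibers = 80,
    law = diameter_law("lognormal", median_um = 0.48, sigma_log = 0.586),
    placement = "segment", fiber_length_um = c(4, 8),
    allow_overlap = FALSE, seed = 7))
})

fixture_bundle <- function() memo("bundle", {
  run_measure(fixture_mesh(), run_config(um_per_px = 0.05))
})

truth_diams <- function(truth) vapply(truth$fibers, `[[`, 0, "diameter_um")

# straight 1-px-wide pixel paths as logical matrices
line_mask <- function(H, W, rows, cols) {
  m <- matrix(FALSE, H, W)
  m[cbind(rows, cols)] <- TRUE
  m
}
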