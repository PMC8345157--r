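# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Small phantom for unit tests (coarser and smaller than the default
# study-scale phantom; the spec's scale_factor exists for exactly this).
small_phantom <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- build_phantom(
      phantom_spec(voxel_spacing_mm = 4, scale_factor = 0.35))
  }
  .fixture_env$small
}

small_plan <- function(seed = 11L, ...) {
  key <- paste0("plan_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.fixture_env[[key]])) {
    ph <- small_phantom()
    .fixture_env[[key]] <-
      simulate_plan(ph$structs, plan_sim_spec(seed = seed, ...))
  }
  .fixture_env[[key]]
}
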