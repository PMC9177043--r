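# Expensive shared artifacts, computed once per test session.
.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

default_run <- function() cached("default_run", {
  run_multipmd(multipmd_config(), seed = 1L)
})

mfep_windows <- list(inside = c(-0.45, 0.45), outside = c(-1.9, -1.0))

mfep_for <- function(mech) cached(paste0("mfep_", mech), {
  mfep_descent(potential_rotor_flip(), mech, theta_windows = mfep_windows)
})

quad_for <- function(name) cached(paste0("quad_", name), {
  reference_fes_quadrature(potential_rotor_flip(),
                           default_run()$paths[[name]]$path, check = FALSE)
})

profile_for <- function(name) cached(paste0("prof_", name), {
  cfg <- default_run()$config
  averaged_profile(default_run()$paths[[name]]$hills,
                   cfg$total_ps * 2 / 7, cfg$total_ps, cfg$total_ps / 70)
})
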