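#' Overdamped Langevin configuration
#'
#' Brownian dynamics on the CV-space potential: only configurational
#' sampling matters for validating the free-energy machinery, so the
#' propagator is first-order overdamped. The default kT of 0.596 kcal/mol
#' corresponds to a 300 K thermostat in the same energy units as the force
#' constants. One "ps" of the engine is 100 steps at dt = 0.01, so the
#' production pace values (1 ps hills and path updates, 20 ps steering)
#' map onto engine schedules at the same ratios.
#'
#' @param kT thermal energy, kcal/mol.
#' @param gamma friction coefficient.
#' @param dt timestep in ps.
#' @param n_steps default number of steps for runs.
#' @return An object of class `langevin_config`.
#' @export
langevin_config <- function(kT = 0.596, gamma = 1, dt = 0.01,
                            n_steps = 1000L) {
  if (dt <= 0) stop("dt must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  if (kT < 0) stop("kT must be non-negative")
  structure(list(kT = kT, gamma = gamma, dt = dt, n_steps = n_steps),
            class = "langevin_config")
}

#' Single overdamped Langevin step
#'
#' `x <- x - (grad V + grad V_bias) dt / gamma + sqrt(2 kT dt / gamma) eta`
#' with standard-normal `eta` per axis drawn from R's seeded generator.
#' Periodic axes of the potential are wrapped to [-pi, pi).
#'
#' @param pos current position (numeric vector).
#' @param potential an `analytic_potential`.
#' @param config a [langevin_config()].
#' @param bias_force additional force vector (defaults to zero).
#' @return The new position.
#' @export
langevin_step <- function(pos, potential, config, bias_force = 0) {
  g <- drop(potential$gradient(matrix(pos, nrow = 1L)))
  if (any(!is.finite(g))) stop("non-finite potential gradient")
  bias_force <- rep_len(bias_force, length(pos))
  if (any(!is.finite(bias_force))) stop("non-finite bias force")
  noise <- if (config$kT > 0)
    sqrt(2 * config$kT * config$dt / config$gamma) * rnorm(length(pos))
  else rep(0, length(pos))
  out <- pos + (-g + bias_force) * config$dt / config$gamma + noise
  wrap <- rep_len(potential$periodic, length(pos))
  out[wrap] <- wrap_angle(out[wrap])
  out
}

#' Run unbiased overdamped Langevin dynamics
#'
#' Uses the compiled propagator for the built-in potential families; runs
#' are bit-identical for equal seeds (set via [set.seed()] before calling).
#'
#' @param potential an `analytic_potential` with a `cpp_id`.
#' @param x0 starting position.
#' @param n_steps number of steps.
#' @param config a [langevin_config()].
#' @param record_every record every k-th step.
#' @return Matrix of recorded positions, one row per record.
#' @export
run_langevin <- function(potential, x0, n_steps,
                         config = langevin_config(), record_every = 1L) {
  cpp_run_langevin(as.numeric(x0), potential$cpp_id, potential$cpp_par,
                   as.integer(n_steps), config$dt, config$gamma, config$kT,
                   as.integer(record_every),
                   rep_len(potential$periodic, length(x0)))
}
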