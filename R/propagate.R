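#' Propagate one replica under its scaled Hamiltonian
#'
#' Advances coordinates at bath temperature `1/beta_0` under the scaled
#' potential with scaling parameter `beta_m`.  Two samplers are available:
#' `"langevin"` uses the BAOAB splitting of underdamped Langevin dynamics;
#' `"mc"` performs single-particle Gaussian-displacement Metropolis sweeps
#' (one attempt per atom per sweep), which is exact for any step size and is
#' used for the detailed-balance proofs.
#'
#' @inheritParams scaled_forces
#' @param n_steps number of integrator steps (Langevin) or sweeps (MC).
#' @param mode `"mc"` (default) or `"langevin"`.
#' @param dt Langevin time step (reduced units).
#' @param friction Langevin friction coefficient gamma.
#' @param step_sd MC per-coordinate Gaussian displacement s.d.
#' @param velocities n x 3 matrix; if `NULL` in Langevin mode, drawn from
#'   the Maxwell-Boltzmann distribution at the bath temperature using the
#'   current R RNG stream.
#' @param seed integer vector seeding the sampler's own counter-based
#'   stream (independent of R's RNG).
#' @return List with `x` (final coordinates), `velocities` (Langevin), and
#'   `mc_acceptance` (MC move acceptance fraction, MC mode).
#' @export
propagate <- function(system, sel, x = system$positions, beta_m = 1,
                      beta_0 = 1, n_steps = 1000,
                      mode = c("mc", "langevin"), dt = 0.01, friction = 2,
                      step_sd = 0.12, velocities = NULL, seed = 1L) {
  mode <- match.arg(mode)
  x <- .check_coords(system, x)
  if (beta_m <= 0 || beta_0 <= 0) stop("inverse temperatures must be positive")
  packed <- .pack_system(system, sel)
  # beta_m == beta_0 is the unscaled system even at beta -> Inf (T = 0)
  s <- if (beta_m == beta_0) 1 else beta_m / beta_0
  seed <- as.integer(seed)
  if (mode == "mc") {
    res <- cpp_mc_run(x, packed, s, beta_0, as.integer(n_steps), step_sd, seed)
    return(list(x = res$pos, velocities = NULL,
                mc_acceptance = res$accepted / max(res$attempted, 1)))
  }
  if (is.null(velocities))
    velocities <- .maxwell_boltzmann(system$masses, 1 / beta_0)
  res <- cpp_langevin_run(x, velocities, system$masses, packed, s, beta_0,
                          as.integer(n_steps), dt, friction, seed)
  list(x = res$pos, velocities = res$vel, mc_acceptance = NA_real_)
}

.maxwell_boltzmann <- function(masses, temperature) {
  n <- length(masses)
  if (temperature <= 0) return(matrix(0, n, 3))
  matrix(stats::rnorm(3 * n, sd = rep(sqrt(temperature / masses), 3)), n, 3)
}
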