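#' Langevin dynamics configuration
#'
#' Settings of the stochastic (Langevin-thermostatted) integrator. The
#' defaults are the thermostat settings used throughout the toolkit: a
#' 2 fs time step, 310 K, and a low friction of 1 ps^-1.
#'
#' @param dt Integration time step (ps). Default 0.002 (= 2 fs).
#' @param temperature Thermostat temperature (K). Default 310.
#' @param friction Langevin friction/damping (ps^-1). Default 1. Zero
#'   friction gives deterministic velocity-Verlet dynamics.
#' @param sample_stride Record one frame (and one supervision distance
#'   point) every `sample_stride` integrator steps. Default 50 (0.1 ps at
#'   the default dt).
#' @param seed Optional integer seed applied via `set.seed()` by the run
#'   functions before integrating.
#' @return An object of class `"dynamics_config"`.
#' @export
dynamics_config <- function(dt = 0.002, temperature = 310, friction = 1.0,
                            sample_stride = 50, seed = NULL) {
  stopifnot(dt > 0, temperature >= 0, friction >= 0, sample_stride >= 1)
  structure(list(dt = dt, temperature = temperature, friction = friction,
                 sample_stride = as.integer(sample_stride), seed = seed),
            class = "dynamics_config")
}

#' Instantaneous ligand state
#'
#' @param position Numeric vector (A).
#' @param velocity Numeric vector (A/ps); defaults to zero.
#' @param time Time stamp (ps), >= 0.
#' @return An object of class `"md_state"`.
#' @export
state <- function(position, velocity = NULL, time = 0) {
  position <- as.numeric(position)
  if (is.null(velocity)) velocity <- numeric(length(position))
  velocity <- as.numeric(velocity)
  stopifnot(length(velocity) == length(position), time >= 0)
  structure(list(position = position, velocity = velocity, time = time),
            class = "md_state")
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Each Cartesian component is drawn independently from a normal
#' distribution with variance kB*T/m (expressed in A^2/ps^2). Used to
#' reassign random velocities after a rejected supervision window and to
#' initialise runs.
#'
#' @param system A [toy_system()] (provides the ligand mass and dims).
#' @param temperature Temperature (K), >= 0. At 0 K the zero vector is
#'   returned.
#' @return Numeric velocity vector (A/ps) of length `system$dims`.
#' @export
sample_velocities <- function(system, temperature) {
  stopifnot(inherits(system, "toy_system"))
  if (length(temperature) != 1 || !is.finite(temperature) || temperature < 0)
    stop("temperature must be a single non-negative number")
  if (temperature == 0) return(numeric(system$dims))
  sdv <- sqrt(.KCAL_AMU * .kB * temperature / system$ligand_mass)
  rnorm(system$dims, sd = sdv)
}

new_segment <- function(raw) {
  structure(list(times = as.numeric(raw$times),
                 positions = raw$positions,
                 velocities = raw$velocities,
                 potential_energies = as.numeric(raw$potential_energies),
                 interaction_energies = as.numeric(raw$interaction_energies),
                 distances = as.numeric(raw$distances)),
            class = "trajectory_segment")
}

#' Run one unbiased Langevin dynamics segment
#'
#' Integrates BAOAB Langevin dynamics for `round(duration/dt)` steps and
#' records frames (time, position, velocity, potential and interaction
#' energy, and distance to the orthosteric center) every
#' `config$sample_stride` steps; the first recorded frame is the start
#' state and the final step is always recorded.
#'
#' @param system A [toy_system()].
#' @param start An [state()] valid for the system.
#' @param duration Segment length (ps); must be >= `config$dt`.
#' @param config A [dynamics_config()].
#' @return An object of class `"trajectory_segment"`.
#' @export
#' @examples
#' sys <- build_scenario("diffusive", dims = 2)
#' seg <- run_segment(sys, state(c(10, 0)), duration = 1,
#'                    dynamics_config(seed = 1))
#' range(seg$distances)
run_segment <- function(system, start, duration, config = dynamics_config()) {
  stopifnot(inherits(system, "toy_system"), inherits(start, "md_state"),
            inherits(config, "dynamics_config"))
  if (duration < config$dt)
    stop("duration (", duration, " ps) must be at least one time step")
  if (!is.null(config$seed)) set.seed(config$seed)
  nsteps <- max(1L, as.integer(round(duration / config$dt)))
  raw <- cpp_run_segment(sys_to_cpp(system), start$position, start$velocity,
                         start$time, nsteps, config$dt, config$temperature,
                         config$friction, config$sample_stride)
  new_segment(raw)
}

#' @export
print.trajectory_segment <- function(x, ...) {
  n <- length(x$times)
  cat("Trajectory segment: ", n, " frames, t = ",
      format(x$times[1]), " .. ", format(x$times[n]), " ps\n", sep = "")
  cat("  site distance: ", format(round(x$distances[1], 3)), " -> ",
      format(round(x$distances[n], 3)), " A (min ",
      format(round(min(x$distances), 3)), ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.trajectory_segment <- function(x, ...) {
  d <- ncol(x$positions)
  pos <- as.data.frame(x$positions)
  names(pos) <- paste0("x", seq_len(d))
  data.frame(time = x$times, pos,
             distance = x$distances,
             potential_energy = x$potential_energies,
             interaction_energy = x$interaction_energies)
}

## Final (position, velocity, time) of a segment as an md_state.
segment_end_state <- function(segment) {
  n <- length(segment$times)
  state(segment$positions[n, ], segment$velocities[n, ], segment$times[n])
}

#' Kinetic energy of recorded frames
#'
#' @param segment A `trajectory_segment`.
#' @param mass Particle mass (amu).
#' @return Numeric vector of per-frame kinetic energies (kcal/mol).
#' @export
kinetic_energy <- function(segment, mass) {
  0.5 * mass * rowSums(segment$velocities^2) / .KCAL_AMU
}

#' Random start state on a shell around the orthosteric site
#'
#' Places the ligand uniformly on a sphere (or circle / pair of points in
#' lower dimensions) of given radius about the orthosteric center, with
#' Maxwell-Boltzmann velocities. This emulates starting replicas from the
#' solvated far field of the receptor.
#'
#' @param system A [toy_system()].
#' @param distance Shell radius (A). Default 20.
#' @param temperature Temperature for the initial velocities (K).
#' @return An [state()].
#' @export
random_start <- function(system, distance = 20, temperature = 310) {
  stopifnot(inherits(system, "toy_system"), distance > 0)
  u <- rnorm(system$dims)
  nrm <- sqrt(sum(u^2))
  if (nrm < 1e-12) u <- c(1, numeric(system$dims - 1)) else u <- u / nrm
  state(system$orthosteric_center + distance * u,
        sample_velocities(system, temperature))
}
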