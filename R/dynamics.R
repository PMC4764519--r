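## Langevin dynamics: BAOAB splitting for flexible beads, rigid-body
## translation + rotation for the cargo (spherical inertia, Stokes-scaled
## rotational friction), deterministic given the seed.

#' Langevin dynamics parameters
#'
#' Defaults are the stated simulation conditions: 300 K, a 0.02 ps time step
#' and a friction coefficient of 50 ps^-1 (comparable to the collision
#' frequency of water). Equilibrium averages are independent of the friction;
#' umbrella campaigns may lower it to decorrelate faster.
#'
#' @param temperature kelvin.
#' @param timestep ps.
#' @param friction ps^-1.
#' @param seed integer RNG seed for the thermostat stream.
#' @return object of class `LangevinParams`.
#' @export
langevin_params <- function(temperature = 300, timestep = 0.02, friction = 50,
                            seed = 1) {
  if (timestep <= 0) stop("timestep must be positive")
  if (friction < 0) stop("friction must be >= 0")
  if (temperature < 0) stop("temperature must be >= 0")
  structure(list(temperature = temperature, timestep = timestep,
                 friction = friction, seed = as.numeric(seed), kB = .kB),
            class = "LangevinParams")
}

#' Harmonic bias on the cargo z coordinate
#' @param stiffness kJ/mol/nm^2.
#' @param z0 anchor value, nm.
#' @return restraint descriptor.
#' @export
restraint_bias_z <- function(stiffness, z0) {
  stopifnot(stiffness >= 0)
  list(type = 1L, p1 = stiffness, p2 = z0)
}

#' Harmonic lateral restraint holding the cargo on the pore axis
#' @param stiffness kJ/mol/nm^2 acting on the radial displacement.
#' @return restraint descriptor.
#' @export
restraint_lateral <- function(stiffness = 100) {
  stopifnot(stiffness >= 0)
  list(type = 2L, p1 = stiffness)
}

#' Radial bias at a fixed direction and height
#'
#' Biases the signed projection of the cargo center on the in-plane ray at
#' angle `theta` toward `r0`, restrains the perpendicular in-plane component
#' (the angular restraint), and holds z at `z_plane`.
#'
#' @param stiffness bias stiffness on the radial projection, kJ/mol/nm^2.
#' @param r0 window center along the ray, nm.
#' @param theta ray direction, degrees.
#' @param tangential_stiffness angular restraint, kJ/mol/nm^2.
#' @param z_stiffness stiffness holding z at `z_plane`.
#' @param z_plane height of the radial scan, nm.
#' @return list of restraint descriptors.
#' @export
restraint_radial <- function(stiffness, r0, theta = 0, tangential_stiffness = 100,
                             z_stiffness = 100, z_plane = 0) {
  list(list(type = 3L, p1 = stiffness, p2 = r0, p3 = theta * pi / 180,
            p4 = tangential_stiffness),
       list(type = 4L, p1 = z_stiffness, p2 = z_plane))
}

#' Isotropic harmonic trap on the tracked particle
#' @param stiffness kJ/mol/nm^2.
#' @param center trap center, nm.
#' @return restraint descriptor.
#' @export
restraint_harmonic3d <- function(stiffness, center = c(0, 0, 0)) {
  list(type = 5L, p1 = stiffness, p2 = center[1], p3 = center[2], p4 = center[3])
}

#' Analytic double-well external potential on z
#'
#' `U(z) = h (z^2 - 1)^2`, the reference potential used to validate the
#' umbrella sampling + WHAM pipeline end to end.
#'
#' @param h well height, kJ/mol.
#' @return external-potential descriptor.
#' @export
external_doublewell <- function(h = 5) list(type = 1L, p1 = h)

#' Propagate a system with Langevin dynamics
#'
#' Runs `n_steps` of BAOAB Langevin dynamics. Flexible beads are integrated
#' per bead; a rigid cargo is propagated on its 6 rigid-body degrees of
#' freedom (rotation frozen if the cargo was added with
#' `free_rotate = FALSE`); anchored beads and scaffold beads do not move.
#' Fully reproducible for a given seed.
#'
#' @param topology a `SystemTopology`.
#' @param params a [forcefield_params()] object.
#' @param ld a [langevin_params()] object.
#' @param restraints list of restraint descriptors (see [restraint_bias_z()]
#'   and friends) acting on the cargo center, or on bead `track_bead` if the
#'   system has no cargo.
#' @param external external potential descriptor (e.g.
#'   [external_doublewell()]) or NULL.
#' @param n_steps number of steps (0 returns the initial frame only).
#' @param sample_every stride for the tracked-coordinate/energy time series.
#' @param traj_every stride for trajectory frames (0 = no frames).
#' @param track_bead bead whose coordinate is recorded when there is no cargo.
#' @return a `DynamicsRun`: the updated topology plus the time series
#'   (`series`: time, x, y, z, r of the tracked object; `vseries`:
#'   velocities; `ke`: kinetic energy of flexible beads), `dof`, `bond_rms`
#'   and any frames.
#' @export
run_dynamics <- function(topology, params = forcefield_params(),
                         ld = langevin_params(), restraints = list(),
                         external = NULL, n_steps = 1000, sample_every = 10,
                         traj_every = 0, track_bead = 1) {
  if (n_steps < 0) stop("n_steps must be >= 0")
  if (!is.null(restraints) && length(restraints) && !is.null(restraints$type))
    restraints <- list(restraints)   # single restraint passed bare
  ## flatten nested restraint groups (restraint_radial returns a pair)
  flat <- list()
  for (r in restraints) {
    if (!is.null(r$type)) flat[[length(flat) + 1]] <- r
    else for (rr in r) flat[[length(flat) + 1]] <- rr
  }
  if (is.null(external)) external <- list(type = 0L)
  out <- .cpp_run(topo_for_cpp(topology), ff_for_cpp(params), ld, flat,
                  external, as.integer(n_steps), as.integer(sample_every),
                  as.integer(traj_every), as.integer(track_bead))
  topology$pos <- out$pos
  topology$vel <- out$vel
  if (!is.null(topology$cargo) && !is.null(out$cargo_state)) {
    topology$cargo$center <- out$cargo_state$center
    topology$cargo$quat <- out$cargo_state$quat
    topology$cargo$vel <- out$cargo_state$vel
    topology$cargo$angvel <- out$cargo_state$angvel
  }
  series <- as.data.frame(out$series)
  names(series) <- c("time", "x", "y", "z", "r")
  structure(list(topology = topology, series = series, vseries = out$vseries,
                 ke = out$ke_series, dof = out$dof, bond_rms = out$bond_rms,
                 frames = out$frames, ld = ld),
            class = "DynamicsRun")
}

#' Kinetic temperature of a run
#'
#' Mean instantaneous kinetic temperature `2 <KE> / (n_dof kB)` of the
#' flexible beads over the sampled time series.
#'
#' @param run a `DynamicsRun`.
#' @return temperature, K.
#' @export
kinetic_temperature <- function(run) {
  if (run$dof == 0 || !length(run$ke)) return(NA_real_)
  2 * mean(run$ke) / (run$dof * .kB)
}
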