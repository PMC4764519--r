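## Energies and forces of the coarse-grained model. Scalar pair potentials are
## implemented here in R (vectorised over r); the compiled engine evaluates the
## identical forms for whole systems, and the test suite cross-checks the two.

#' Hydrophobic pair energy
#'
#' Split Lennard-Jones interaction between two residue beads: a fixed
#' repulsive core of strength `eps_rep` and an attractive well of depth
#' `eps_ij` set by the hydrophobicities of the pair,
#' `eps_ij = eps_max * h_i * h_j` with phenylalanine at h = 1 so the F-F
#' (and binding-spot-F) well is `eps_max` = 5.2 kJ/mol. The energy is shifted
#' so it vanishes continuously at the cutoff; `eps_ij = 0` leaves a purely
#' repulsive interaction that is exactly zero beyond `2^(1/6) sigma`.
#'
#' @param r pair distance(s), nm.
#' @param eps_ij attractive well depth, kJ/mol.
#' @param sigma_ij pair diameter (sum of bead radii), nm.
#' @param cutoff interaction cutoff, nm.
#' @param eps_rep repulsive-core strength, kJ/mol.
#' @return list with `energy` (kJ/mol) and `force` (radial force -dU/dr,
#'   kJ/mol/nm; positive = repulsive), each the length of `r`.
#' @export
hydrophobic_pair_energy <- function(r, eps_ij, sigma_ij, cutoff = 2.5,
                                    eps_rep = 5.2) {
  stopifnot(all(r > 0))
  sc6 <- (sigma_ij / cutoff)^6
  shift <- 4 * eps_ij * (sc6^2 - sc6)
  rmin <- 2^(1 / 6) * sigma_ij
  rl <- 0.8 * sigma_ij
  e <- numeric(length(r)); dUdr <- numeric(length(r))
  out <- r >= cutoff
  outer <- !out & r >= rmin
  mid <- !out & r < rmin & r >= rl
  core <- !out & r < rl
  if (any(outer)) {
    sr6 <- (sigma_ij / r[outer])^6
    e[outer] <- 4 * eps_ij * (sr6^2 - sr6) - shift
    dUdr[outer] <- 4 * eps_ij * (-12 * sr6^2 + 6 * sr6) / r[outer]
  }
  if (any(mid)) {
    sr6 <- (sigma_ij / r[mid])^6
    e[mid] <- 4 * eps_rep * (sr6^2 - sr6) + eps_rep - eps_ij - shift
    dUdr[mid] <- 4 * eps_rep * (-12 * sr6^2 + 6 * sr6) / r[mid]
  }
  if (any(core)) {
    sr6 <- (sigma_ij / rl)^6
    d0 <- 4 * eps_rep * (-12 * sr6^2 + 6 * sr6) / rl
    u0 <- 4 * eps_rep * (sr6^2 - sr6) + eps_rep - eps_ij - shift
    e[core] <- u0 + d0 * (r[core] - rl)
    dUdr[core] <- d0
  }
  list(energy = e, force = -dUdr)
}

#' Screened electrostatic pair energy
#'
#' Debye-Hueckel interaction between two charged beads,
#' `U = C q_i q_j exp(-r/lambda) / (eps_r r)`, energy-shifted to zero at the
#' Coulomb cutoff. `C` is the Coulomb constant 138.935 kJ mol^-1 nm e^-2.
#'
#' @param r pair distance(s), nm.
#' @param q_i,q_j charges, elementary units.
#' @param params a [forcefield_params()] object (uses `debye_length`,
#'   `dielectric`, `coulomb_cutoff`).
#' @return list with `energy` and radial `force` as in
#'   [hydrophobic_pair_energy()].
#' @export
electrostatic_pair_energy <- function(r, q_i, q_j, params = forcefield_params()) {
  stopifnot(all(r > 0))
  C <- 138.935458 / params$dielectric
  lam <- params$debye_length
  rc <- params$coulomb_cutoff
  qq <- q_i * q_j
  e <- numeric(length(r)); f <- numeric(length(r))
  if (qq != 0) {
    inside <- r < rc
    u <- C * qq * exp(-r[inside] / lam) / r[inside]
    us <- C * qq * exp(-rc / lam) / rc
    e[inside] <- u - us
    f[inside] <- u * (1 / r[inside] + 1 / lam)
  }
  list(energy = e, force = f)
}

#' Excluded-volume (WCA) pair energy
#'
#' Purely repulsive shifted Lennard-Jones used for scaffold beads and inert
#' cargo surfaces: zero energy and force at and beyond the contact distance
#' `sigma_c`, steep continuous repulsion inside it.
#'
#' @param r pair distance(s), nm.
#' @param sigma_c contact distance, nm (e.g. `D/2 + r_b` for a cargo of
#'   diameter D against a residue bead of radius `r_b` = 0.3 nm).
#' @param eps repulsion energy scale, kJ/mol.
#' @return list with `energy` and radial `force`.
#' @export
excluded_volume_energy <- function(r, sigma_c, eps = 5.0) {
  stopifnot(sigma_c > 0, all(r > 0))
  sigma <- sigma_c / 2^(1 / 6)
  rl <- 0.8 * sigma
  e <- numeric(length(r)); dUdr <- numeric(length(r))
  mid <- r < sigma_c & r >= rl
  core <- r < rl
  if (any(mid)) {
    sr6 <- (sigma / r[mid])^6
    e[mid] <- 4 * eps * (sr6^2 - sr6) + eps
    dUdr[mid] <- 4 * eps * (-12 * sr6^2 + 6 * sr6) / r[mid]
  }
  if (any(core)) {
    sr6 <- (sigma / rl)^6
    d0 <- 4 * eps * (-12 * sr6^2 + 6 * sr6) / rl
    u0 <- 4 * eps * (sr6^2 - sr6) + eps
    e[core] <- u0 + d0 * (r[core] - rl)
    dUdr[core] <- d0
  }
  list(energy = e, force = -dUdr)
}

## assemble the list handed to the compiled engine
topo_for_cpp <- function(topology) {
  topology[c("pos", "kind", "hyd", "charge", "evr", "mass", "mobile",
             "bonds", "bond_k", "bond_r0", "angles", "dihedrals",
             "exclusions", "cargo", "vel")]
}

ff_for_cpp <- function(params, terms = 15L) {
  list(eps_max = params$eps_max, vdw_cutoff = params$vdw_cutoff,
       coulomb_cutoff = params$coulomb_cutoff, debye_length = params$debye_length,
       dielectric = params$dielectric, wca_eps = params$wca_eps,
       terms = as.integer(terms),
       bend_table = params$bend_table, torsion_table = params$torsion_table)
}

#' Total potential energy and forces of a system
#'
#' Evaluates all energy terms (bonds, bending, torsion, hydrophobic,
#' electrostatic, excluded volume) and the exact per-bead forces for a
#' [SystemTopology][graft_nups()].
#'
#' @param topology a `SystemTopology`.
#' @param params a [forcefield_params()] object.
#' @param terms integer bit mask selecting terms (1 bonds, 2 bending,
#'   4 torsion, 8 nonbonded); default all.
#' @return list with `total` (kJ/mol), named `components`, and an
#'   N x 3 `forces` matrix (kJ/mol/nm).
#' @export
compute_energy <- function(topology, params = forcefield_params(), terms = 15L) {
  .cpp_energy(topo_for_cpp(topology), ff_for_cpp(params, terms))
}

#' Harmonic bond energy of a bead chain
#'
#' `E = sum 0.5 k (r - r0)^2` over the given bonds, with exact forces.
#'
#' @param positions N x 3 coordinate matrix, nm.
#' @param bonds B x 2 integer matrix of bead index pairs (1-based).
#' @param params a [forcefield_params()] object (uses `bond_length`,
#'   `bond_stiffness`).
#' @return list with `energy` and N x 3 `forces`.
#' @export
bond_energy <- function(positions, bonds, params = forcefield_params()) {
  positions <- as.matrix(positions)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  n <- nrow(positions)
  if (any(bonds < 1) || any(bonds > n))
    stop("topology error: bond index out of range 1..", n)
  topo <- bare_topology(positions)
  topo$bonds <- bonds
  topo$bond_k <- rep(params$bond_stiffness, nrow(bonds))
  topo$bond_r0 <- rep(params$bond_length, nrow(bonds))
  res <- compute_energy(topo, params, terms = 1L)
  list(energy = res$total, forces = res$forces)
}

#' Backbone stiffness energy (bending + torsion)
#'
#' Sum of the tabulated bending (three-bead pseudo-angle) and torsion
#' (four-bead dihedral) terms along each chain, interpolated with a C1 cubic
#' Hermite scheme so forces are consistent with the interpolant gradient.
#' Angles outside the bending-table domain are clamped.
#'
#' @param positions N x 3 coordinate matrix, nm.
#' @param chains list of integer vectors, one per chain, giving consecutive
#'   bead indices (1-based).
#' @param params a [forcefield_params()] object.
#' @return list with `energy` and N x 3 `forces`.
#' @export
backbone_stiffness_energy <- function(positions, chains, params = forcefield_params()) {
  positions <- as.matrix(positions)
  topo <- bare_topology(positions)
  ang <- list(); dih <- list()
  for (ch in chains) {
    ch <- as.integer(ch)
    if (length(ch) >= 3)
      ang[[length(ang) + 1]] <- cbind(ch[1:(length(ch) - 2)], ch[2:(length(ch) - 1)],
                                      ch[3:length(ch)])
    if (length(ch) >= 4)
      dih[[length(dih) + 1]] <- cbind(ch[1:(length(ch) - 3)], ch[2:(length(ch) - 2)],
                                      ch[3:(length(ch) - 1)], ch[4:length(ch)])
  }
  if (length(ang)) topo$angles <- do.call(rbind, ang)
  if (length(dih)) topo$dihedrals <- do.call(rbind, dih)
  res <- compute_energy(topo, params, terms = 6L)
  list(energy = res$total, forces = res$forces)
}

## minimal topology skeleton around a coordinate matrix (no interactions)
bare_topology <- function(positions) {
  n <- nrow(positions)
  list(pos = positions,
       kind = rep(0L, n), hyd = rep(0, n), charge = rep(0, n),
       evr = rep(0.3, n), mass = rep(120, n), mobile = rep(1L, n),
       chain = rep(1L, n),
       bonds = matrix(integer(0), ncol = 2), bond_k = numeric(0),
       bond_r0 = numeric(0),
       angles = matrix(integer(0), ncol = 3),
       dihedrals = matrix(integer(0), ncol = 4),
       exclusions = matrix(integer(0), ncol = 2),
       cargo = NULL, vel = NULL)
}
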