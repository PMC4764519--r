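## Rigid model cargoes: inert spheres, composite spheres, Kap-cargo complexes.

## deterministic quasi-uniform directions on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

## effective repulsive radius of a composite body along unit directions `u`
## (distance from the center at which a residue bead first feels zero force)
composite_effective_radius <- function(directions, r_c, contact, u) {
  centers <- r_c * directions
  apply(u, 1, function(v) {
    proj <- centers %*% v
    perp2 <- rowSums(centers^2) - proj^2
    ok <- perp2 < contact^2
    if (!any(ok)) return(0)
    max(proj[ok] + sqrt(contact^2 - perp2[ok]))
  })
}

#' Construct an inert model cargo
#'
#' Cargoes up to 5.0 nm in diameter are a single neutral bead with repulsive
#' contact `sigma_c = D/2 + r_b` (`r_b` = 0.3 nm). Larger cargoes are rigid
#' composites of neutral beads, each with contact `sigma_c` = 2.5 nm, centred
#' at `r_c = D/2 - (sigma_c - r_b)` from the cargo center; sub-bead directions
#' are chosen so the effective repulsive surface deviates from a sphere of
#' diameter D by less than 5 percent.
#'
#' @param D cargo diameter, nm.
#' @param r_b residue bead radius, nm.
#' @return object of class `CargoSpec`.
#' @export
make_inert_cargo <- function(D, r_b = 0.3) {
  if (!is.numeric(D) || D <= 0) stop("cargo diameter D must be positive")
  if (D <= 5.0) {
    spec <- list(D = D, kind = "single", sigma_c = D / 2 + r_b, r_c = NA_real_,
                 directions = NULL, n_spots = 0L, spot_spacing = NA_real_,
                 spot_diameter = 0.6, spots = NULL)
    class(spec) <- "CargoSpec"
    return(spec)
  }
  sigma_c <- 2.5
  r_c <- D / 2 - (sigma_c - r_b)
  target <- D / 2 + r_b
  probe <- fibonacci_sphere(1500)
  n <- 32
  repeat {
    dirs <- fibonacci_sphere(n)
    eff <- composite_effective_radius(dirs, r_c, sigma_c, probe)
    if (max(abs(eff - target)) / target < 0.035 || n > 4000) break
    n <- ceiling(n * 1.4)
  }
  spec <- list(D = D, kind = "composite", sigma_c = sigma_c, r_c = r_c,
               directions = dirs, n_spots = 0L, spot_spacing = NA_real_,
               spot_diameter = 0.6, spots = NULL)
  class(spec) <- "CargoSpec"
  spec
}

#' Construct a Kap-cargo complex
#'
#' A rigid sphere of diameter `D` (composite body as in [make_inert_cargo()])
#' decorated with `n_spots` hydrophobic binding spots: Phe-like beads
#' (hydrophobicity 1, so the spot-F pair well is `eps_max` = 5.2 kJ/mol)
#' placed on the sphere surface along a great-circle stripe on the equator of
#' the cargo frame, at equal arc spacing `d`. With `n_spots = 0` the
#' repulsive surface is identical to the inert cargo of the same diameter.
#'
#' @param D diameter, nm (10 nm for the canonical complex).
#' @param n_spots number of binding spots.
#' @param d arc spacing between neighbouring spots, nm.
#' @param r_b residue bead radius, nm.
#' @return object of class `CargoSpec` with `kind = "kap"`.
#' @export
make_kap_complex <- function(D = 10, n_spots = 7L, d = 1.3, r_b = 0.3) {
  if (n_spots < 0) stop("n_spots must be >= 0")
  if (d <= 0) stop("spot spacing d must be positive")
  spec <- make_inert_cargo(D, r_b)
  spec$kind <- "kap"
  spec$n_spots <- as.integer(n_spots)
  spec$spot_spacing <- d
  if (n_spots > 0) {
    if (n_spots * d > pi * D)
      stop("stripe cannot hold ", n_spots, " spots at spacing ", d, " nm")
    R <- D / 2
    alpha <- (seq_len(n_spots) - (n_spots + 1) / 2) * d / R
    spec$spots <- cbind(R * cos(alpha), R * sin(alpha), 0)
  }
  spec
}

#' Attach a rigid cargo to a system
#'
#' Appends the cargo's beads to the topology and defines the rigid-body frame
#' (center, orientation quaternion, member beads). The cargo mass is the sum
#' of its member-bead masses (120 Da each) scaled by `mass_scale`, and the
#' inertia is that of a uniform sphere of diameter D; equilibrium sampling is
#' independent of both, so `mass_scale < 1` may be used to speed up
#' decorrelation in umbrella windows.
#'
#' @param topology a `SystemTopology`.
#' @param cargo a `CargoSpec`.
#' @param center initial cargo center, nm.
#' @param mass_scale multiplier on the inertial mass (equilibrium-neutral).
#' @param free_rotate logical; if FALSE the orientation is frozen.
#' @param params a [forcefield_params()] object.
#' @return the topology with the cargo attached.
#' @export
add_cargo <- function(topology, cargo, center = c(0, 0, 0), mass_scale = 1,
                      free_rotate = TRUE, params = forcefield_params()) {
  if (!is.null(topology$cargo)) stop("topology already has a cargo")
  r_b <- 0.3
  if (cargo$kind == "single") {
    ref <- matrix(0, 1, 3)
    evr_new <- cargo$sigma_c - r_b
    kind_new <- 3L
    hyd_new <- 0; q_new <- 0
  } else {
    ref <- cargo$r_c * cargo$directions
    evr_new <- rep(cargo$sigma_c - r_b, nrow(ref))
    kind_new <- rep(3L, nrow(ref))
    hyd_new <- rep(0, nrow(ref)); q_new <- rep(0, nrow(ref))
  }
  code_new <- rep("@", nrow(ref))
  if (!is.null(cargo$spots) && nrow(cargo$spots) > 0) {
    ref <- rbind(ref, cargo$spots)
    ## spots are embedded flush in the rigid surface: their own excluded
    ## volume is subsumed by the cargo's (evr 0), so only the hydrophobic
    ## well reaches outside -- a spot adds attraction, not surface roughness
    evr_new <- c(evr_new, rep(0, nrow(cargo$spots)))
    kind_new <- c(kind_new, rep(1L, nrow(cargo$spots)))
    hyd_new <- c(hyd_new, rep(1, nrow(cargo$spots)))
    q_new <- c(q_new, rep(0, nrow(cargo$spots)))
    code_new <- c(code_new, rep("J", nrow(cargo$spots)))
  }
  m <- nrow(ref)
  off <- nrow(topology$pos)
  pos_new <- sweep(ref, 2, center, "+")
  topology$pos <- rbind(topology$pos, pos_new)
  topology$kind <- c(topology$kind, kind_new)
  topology$hyd <- c(topology$hyd, hyd_new)
  topology$charge <- c(topology$charge, q_new)
  topology$evr <- c(topology$evr, evr_new)
  topology$mass <- c(topology$mass, rep(params$bead_mass, m))
  topology$mobile <- c(topology$mobile, rep(2L, m))
  topology$chain <- c(topology$chain, rep(-1L, m))
  topology$code <- c(topology$code, code_new)
  if (!is.null(topology$vel)) topology$vel <- rbind(topology$vel, matrix(0, m, 3))
  M <- m * params$bead_mass * mass_scale
  topology$cargo <- list(
    members = off + seq_len(m), ref = ref,
    center = as.numeric(center), quat = c(1, 0, 0, 0),
    mass = M, inertia = 0.4 * M * (cargo$D / 2)^2,
    free_rotate = isTRUE(free_rotate), spec = cargo)
  topology
}

## move the cargo rigid frame (and its beads) to a new center
move_cargo <- function(topology, center) {
  stopifnot(!is.null(topology$cargo))
  q <- topology$cargo$quat
  R <- quat_to_matrix(q)
  pos <- topology$cargo$ref %*% t(R)
  topology$pos[topology$cargo$members, ] <- sweep(pos, 2, center, "+")
  topology$cargo$center <- as.numeric(center)
  topology
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' @export
print.CargoSpec <- function(x, ...) {
  cat(sprintf("CargoSpec: D = %.2f nm, kind = %s", x$D, x$kind))
  if (x$kind == "single") cat(sprintf(", sigma_c = %.2f nm", x$sigma_c))
  else cat(sprintf(", %d sub-beads at r_c = %.2f nm", nrow(x$directions), x$r_c))
  if (x$n_spots > 0)
    cat(sprintf(", %d binding spots at d = %.2f nm", x$n_spots, x$spot_spacing))
  cat("\n")
  invisible(x)
}
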