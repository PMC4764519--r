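## System construction: eightfold-symmetric scaffold, grafted FG-Nup chains,
## inert and Kap-cargo particles.

#' Scaffold geometry
#'
#' Geometry of the rigid pore scaffold: an hourglass wall of hard-sphere
#' beads (diameter 5.0 nm) around the pore axis (z), with the central plane
#' at z = 0 and the cytoplasmic side at z > 0. Full scale is a pore diameter
#' of L = 60 nm and half-height 15.4 nm (the z where the cytoplasm begins);
#' fixtures use scaled-down values.
#'
#' @param pore_diameter inner pore diameter L at the central plane, nm.
#' @param pore_half_height half-height of the scaffold wall, nm.
#' @param scaffold_bead_diameter diameter of the scaffold beads, nm.
#' @param symmetry_order rotational symmetry about the pore axis.
#' @return object of class `ScaffoldGeometry`.
#' @export
scaffold_geometry <- function(pore_diameter = 60, pore_half_height = 15.4,
                              scaffold_bead_diameter = 5.0, symmetry_order = 8L) {
  if (symmetry_order < 1) stop("symmetry_order must be >= 1")
  if (pore_diameter <= scaffold_bead_diameter)
    stop("pore_diameter must exceed the scaffold bead diameter")
  structure(list(pore_diameter = pore_diameter,
                 pore_half_height = pore_half_height,
                 scaffold_bead_diameter = scaffold_bead_diameter,
                 symmetry_order = as.integer(symmetry_order)),
            class = "ScaffoldGeometry")
}

## inner wall radius of the hourglass at height z (narrowest at z = 0)
wall_radius <- function(geom, z) {
  geom$pore_diameter / 2 +
    0.08 * geom$pore_diameter * (z / geom$pore_half_height)^2
}

#' Build the scaffold bead set
#'
#' Tiles the hourglass wall with rings of scaffold beads and adds
#' nuclear-envelope discs at z = +/- pore_half_height extending radially
#' outward, so the grafted chains are confined to the pore conduit and the
#' two compartments. Each ring holds a multiple of `symmetry_order` beads,
#' so the set is exactly invariant under rotation by `2*pi/symmetry_order`
#' about the pore axis.
#'
#' @param geom a [scaffold_geometry()].
#' @param membrane_extent radial extent of the envelope discs beyond the
#'   pore mouth, nm.
#' @return matrix of bead centers (nm) of class `Scaffold`, with the geometry
#'   attached as attribute `geometry`.
#' @export
build_scaffold <- function(geom = scaffold_geometry(), membrane_extent = 10) {
  d <- geom$scaffold_bead_diameter
  H <- geom$pore_half_height
  s <- geom$symmetry_order
  zs <- seq(-H, H, by = 0.87 * d)
  rows <- vector("list", length(zs))
  ring <- function(R, z, i) {
    n <- s * max(1L, round(2 * pi * R / (d * s)))
    phi <- (i %% 2) * pi / n + 2 * pi * (seq_len(n) - 1) / n
    cbind(R * cos(phi), R * sin(phi), z)
  }
  for (i in seq_along(zs))
    rows[[i]] <- ring(wall_radius(geom, zs[i]) + d / 2, zs[i], i)
  ## nuclear-envelope discs
  R0 <- wall_radius(geom, H) + d / 2
  for (k in seq_len(max(0L, ceiling(membrane_extent / (0.87 * d))))) {
    R <- R0 + k * 0.87 * d
    rows[[length(rows) + 1]] <- ring(R, H + d / 2, k)
    rows[[length(rows) + 1]] <- ring(R, -H - d / 2, k)
  }
  out <- do.call(rbind, rows)
  colnames(out) <- c("x", "y", "z")
  structure(out, geometry = geom, class = c("Scaffold", class(out)))
}

#' Nup anchor table
#'
#' Builds/validates the anchor table describing where FG-Nup chains are
#' grafted: one row per Nup ring, with `copies` chains per ring placed at
#' equal angles (copies must be a multiple of the scaffold symmetry order).
#'
#' @param nup_name character, Nup identifier.
#' @param ring_z ring height, nm.
#' @param ring_radius radial grafting distance from the pore axis, nm.
#' @param copies chains in the ring.
#' @param sequence_id name of the sequence to graft (key into the FASTA set).
#' @return `data.frame` of class `NupAnchors`.
#' @export
nup_anchors <- function(nup_name, ring_z, ring_radius, copies, sequence_id) {
  out <- data.frame(nup_name = as.character(nup_name), ring_z = ring_z,
                    ring_radius = ring_radius, copies = as.integer(copies),
                    sequence_id = as.character(sequence_id),
                    stringsAsFactors = FALSE)
  class(out) <- c("NupAnchors", "data.frame")
  out
}

#' Remove the minimal-viable-pore Nup set from an anchor table
#'
#' The minimal viable pore lacks Nup42, Nup159, Nup1, Nup60, Nup100, Nsp1 and
#' Nup145; all copies of exactly those seven Nup types are dropped and all
#' other anchors are untouched. Listed names absent from the table are
#' ignored with a warning.
#'
#' @param anchors a [nup_anchors()] table.
#' @return the filtered anchor table.
#' @export
make_minimal_variant <- function(anchors) {
  removed <- c("Nup42", "Nup159", "Nup1", "Nup60", "Nup100", "Nsp1", "Nup145")
  present <- unique(anchors$nup_name)
  absent <- setdiff(removed, present)
  if (length(absent) && nrow(anchors) > 0)
    warning("not in anchor table (ignored): ", paste(absent, collapse = ", "))
  anchors[!(anchors$nup_name %in% removed), , drop = FALSE]
}

## expand an anchor table into per-chain grafting coordinates
anchor_sites <- function(anchors, symmetry_order = 8L) {
  if (nrow(anchors) == 0)
    return(data.frame(nup_name = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), sequence_id = character(0)))
  out <- vector("list", nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    if (a$copies %% symmetry_order != 0)
      stop("copies of ", a$nup_name, " must be a multiple of the symmetry order")
    phi <- 2 * pi * (seq_len(a$copies) - 1) / a$copies + (i - 1) * pi / 16
    out[[i]] <- data.frame(nup_name = a$nup_name,
                           x = a$ring_radius * cos(phi),
                           y = a$ring_radius * sin(phi),
                           z = a$ring_z, sequence_id = a$sequence_id,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Graft FG-Nup chains into a scaffold
#'
#' Creates one chain per anchor copy. The anchored (C-terminal) bead is fixed
#' at the grafting site; the rest of the chain is grown as a self-avoiding
#' random walk away from the wall, reproducibly for a given seed. Consecutive
#' beads are bonded at 0.38 nm; bending/torsion terms and 1-2/1-3 nonbonded
#' exclusions are generated along each chain.
#'
#' @param scaffold a [build_scaffold()] bead set (or NULL for no scaffold).
#' @param anchors a [nup_anchors()] table.
#' @param sequences named character vector (or `AAStringSet`) of amino-acid
#'   sequences, keyed by `sequence_id`.
#' @param seed integer seed for the initial conformations.
#' @param params a [forcefield_params()] object.
#' @param geom scaffold geometry; defaults to the geometry attached to
#'   `scaffold`.
#' @return object of class `SystemTopology`.
#' @export
graft_nups <- function(scaffold, anchors, sequences, seed = 1,
                       params = forcefield_params(), geom = NULL) {
  if (is.null(geom)) geom <- attr(scaffold, "geometry")
  if (is.null(geom)) geom <- scaffold_geometry()
  if (inherits(sequences, "AAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  sites <- anchor_sites(anchors, geom$symmetry_order)
  if (nrow(sites) > 1) {
    dd <- as.matrix(stats::dist(sites[, c("x", "y", "z")]))
    diag(dd) <- Inf
    if (min(dd) < 1e-6) stop("overlapping anchors")
  }
  res <- params$residues

  pos <- NULL; kind <- integer(0); hyd <- numeric(0); charge <- numeric(0)
  evr <- numeric(0); mass <- numeric(0); mobile <- integer(0)
  chain <- integer(0); code <- character(0)
  bonds <- list(); angles <- list(); dihedrals <- list(); excl <- list()

  if (!is.null(scaffold) && nrow(scaffold) > 0) {
    ns <- nrow(scaffold)
    pos <- unclass(scaffold)[, , drop = FALSE]
    attr(pos, "geometry") <- NULL
    kind <- rep(2L, ns); hyd <- rep(0, ns); charge <- rep(0, ns)
    evr <- rep(geom$scaffold_bead_diameter / 2, ns)
    mass <- rep(1e6, ns); mobile <- rep(0L, ns)
    chain <- rep(0L, ns); code <- rep("#", ns)
  }

  chain_table <- list()
  with_seed(seed, {
    for (ci in seq_len(nrow(sites))) {
      sq <- sequences[[sites$sequence_id[ci]]]
      if (is.null(sq) || is.na(sq)) stop("unknown sequence_id: ", sites$sequence_id[ci])
      letters_ <- strsplit(toupper(sq), "")[[1]]
      bad <- !letters_ %in% res$code
      if (any(bad))
        stop("sequence ", sites$sequence_id[ci], " has unknown residue at position ",
             which(bad)[1])
      L <- length(letters_)
      anchor <- c(sites$x[ci], sites$y[ci], sites$z[ci])
      ## bead 1 is a fixed grafting bead; the L sequence residues are mobile
      xyz <- grow_chain(anchor, L + 1, geom)
      off <- if (is.null(pos)) 0L else nrow(pos)
      idx <- off + seq_len(L + 1)
      pos <- rbind(pos, xyz)
      kind <- c(kind, rep(0L, L + 1))
      hyd <- c(hyd, 0, res[letters_, "hydrophobicity"])
      charge <- c(charge, 0, res[letters_, "charge"])
      evr <- c(evr, 0.3, res[letters_, "bead_radius"])
      mass <- c(mass, rep(params$bead_mass, L + 1))
      mobile <- c(mobile, c(0L, rep(1L, L)))
      chain <- c(chain, rep(ci, L + 1))
      code <- c(code, "^", letters_)
      nb <- L + 1
      bonds[[ci]] <- cbind(idx[-nb], idx[-1])
      if (nb >= 3) angles[[ci]] <- cbind(idx[1:(nb - 2)], idx[2:(nb - 1)], idx[3:nb])
      if (nb >= 4) dihedrals[[ci]] <- cbind(idx[1:(nb - 3)], idx[2:(nb - 2)],
                                            idx[3:(nb - 1)], idx[4:nb])
      ex12 <- cbind(idx[-nb], idx[-1])
      ex13 <- if (nb >= 3) cbind(idx[1:(nb - 2)], idx[3:nb]) else NULL
      excl[[ci]] <- rbind(ex12, ex13)
      chain_table[[ci]] <- data.frame(chain = ci, nup_name = sites$nup_name[ci],
                                      sequence_id = sites$sequence_id[ci],
                                      length = L, stringsAsFactors = FALSE)
    }
  })

  bonds <- if (length(bonds)) do.call(rbind, bonds) else matrix(integer(0), ncol = 2)
  topo <- list(
    pos = if (is.null(pos)) matrix(numeric(0), ncol = 3) else pos,
    kind = kind, hyd = hyd, charge = charge, evr = evr, mass = mass,
    mobile = mobile, chain = chain, code = code,
    bonds = bonds,
    bond_k = rep(params$bond_stiffness, nrow(bonds)),
    bond_r0 = rep(params$bond_length, nrow(bonds)),
    angles = if (length(angles)) do.call(rbind, angles) else matrix(integer(0), ncol = 3),
    dihedrals = if (length(dihedrals)) do.call(rbind, dihedrals) else matrix(integer(0), ncol = 4),
    exclusions = if (length(excl)) do.call(rbind, excl) else matrix(integer(0), ncol = 2),
    cargo = NULL, vel = NULL,
    geometry = geom, anchors = anchors,
    chains = if (length(chain_table)) do.call(rbind, chain_table) else NULL)
  class(topo) <- "SystemTopology"
  topo
}

## self-avoiding random walk from the anchor toward the pore interior
grow_chain <- function(anchor, n, geom, bond = 0.38) {
  xyz <- matrix(0, n, 3)
  xyz[1, ] <- anchor
  if (n == 1) return(xyz)
  rad <- sqrt(anchor[1]^2 + anchor[2]^2)
  dir <- if (rad > 1e-9) c(-anchor[1] / rad, -anchor[2] / rad, 0) else c(1, 0, 0)
  for (i in 2:n) {
    ok <- FALSE
    for (try in 1:30) {
      prop <- dir + rnorm(3, sd = 0.6)
      prop <- prop / sqrt(sum(prop^2))
      cand <- xyz[i - 1, ] + bond * prop
      r <- sqrt(cand[1]^2 + cand[2]^2)
      z <- cand[3]
      H <- geom$pore_half_height
      if (abs(z) <= H && r > wall_radius(geom, z) - 0.3) next
      if (abs(z) > H && r > wall_radius(geom, H) - 0.3) next  # envelope plane
      if (abs(z) > 2 * H + 2) next
      lo <- max(1, i - 12)
      d2 <- rowSums((xyz[lo:(i - 1), , drop = FALSE] -
                     matrix(cand, i - lo, 3, byrow = TRUE))^2)
      if (i - lo >= 2 && any(d2[seq_len(i - lo - 1)] < 0.36^2)) next
      ok <- TRUE
      break
    }
    if (!ok) {                      # fall back: straight continuation
      cand <- xyz[i - 1, ] + bond * dir
      prop <- dir
    }
    xyz[i, ] <- cand
    dir <- prop
  }
  xyz
}

#' @export
print.SystemTopology <- function(x, ...) {
  cat("SystemTopology:", nrow(x$pos), "beads\n")
  cat(sprintf("  FG residues: %d (mobile %d), scaffold: %d, cargo: %d, spots: %d\n",
              sum(x$kind == 0), sum(x$kind == 0 & x$mobile == 1),
              sum(x$kind == 2), sum(x$kind == 3), sum(x$kind == 1)))
  cat(sprintf("  bonds: %d, angles: %d, dihedrals: %d\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals)))
  if (!is.null(x$cargo))
    cat(sprintf("  cargo at (%.2f, %.2f, %.2f), %d member beads\n",
                x$cargo$center[1], x$cargo$center[2], x$cargo$center[3],
                length(x$cargo$members)))
  invisible(x)
}
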