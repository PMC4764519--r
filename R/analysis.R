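## Derived quantities: the energy-barrier statistic, circumferentially
## averaged density maps, and barrier-versus-diameter curves.

#' Energy barrier of a PMF profile
#'
#' The barrier is the difference between the mean PMF over the pore core
#' (default -5 nm < z < 5 nm) and the mean over the cytoplasmic reference
#' interval (default 20 nm < z < 27 nm): the work required to move the cargo
#' from the cytoplasm into the core. The dispersion is the root mean square
#' of the PMF standard deviations over the two intervals (the error bars of
#' the barrier-versus-diameter curve). Bins are weighted uniformly.
#'
#' @param pmf a `PMFProfile`.
#' @param core core interval, nm (scale with the pore for fixtures).
#' @param reference cytoplasmic reference interval, nm.
#' @return object of class `BarrierEstimate` with fields `G`, `dispersion`,
#'   `core`, `reference`.
#' @export
energy_barrier <- function(pmf, core = c(-5, 5), reference = c(20, 27)) {
  sel_core <- pmf$z >= min(core) & pmf$z <= max(core) & is.finite(pmf$G)
  sel_ref <- pmf$z >= min(reference) & pmf$z <= max(reference) & is.finite(pmf$G)
  missing <- c(if (!any(sel_core)) "core", if (!any(sel_ref)) "reference")
  if (length(missing))
    stop("PMF does not cover interval(s): ", paste(missing, collapse = ", "))
  g_core <- pmf$G[sel_core]; g_ref <- pmf$G[sel_ref]
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  structure(list(G = mean(g_core) - mean(g_ref),
                 dispersion = sqrt((sd0(g_core)^2 + sd0(g_ref)^2) / 2),
                 core = core, reference = reference),
            class = "BarrierEstimate")
}

#' @export
print.BarrierEstimate <- function(x, ...) {
  cat(sprintf("Energy barrier G = %.2f +/- %.2f kJ/mol (core [%g, %g] nm vs reference [%g, %g] nm)\n",
              x$G, x$dispersion, x$core[1], x$core[2], x$reference[1], x$reference[2]))
  invisible(x)
}

#' Circumferentially averaged FG-Nup density map
#'
#' Bins the mass of the mobile FG-Nup beads into annular (r, z) voxels and
#' averages over frames; voxel volumes `2 pi r dr dz` are accounted for, so
#' values are mass densities in Da/nm^3. Beads falling outside the grid are
#' accumulated in an overflow counter so total mass is conserved exactly.
#'
#' @param frames list of N x 3 coordinate matrices (from a trajectory or an
#'   [axial_pmf_campaign()] with `traj_every > 0`).
#' @param topology the matching `SystemTopology`.
#' @param dr,dz voxel sizes, nm.
#' @param r_max,z_range grid extent; defaults cover the scaffold geometry.
#' @return object of class `DensityMap`: `r`, `z` (bin centers), `density`
#'   (length(r) x length(z), Da/nm^3), `frame_count`, `overflow_mass`
#'   (Da, per frame average) and `total_mass` (Da, per frame).
#' @export
density_map <- function(frames, topology, dr = 0.5, dz = 0.5, r_max = NULL,
                        z_range = NULL) {
  if (!length(frames)) stop("trajectory is empty")
  geom <- topology$geometry
  if (is.null(r_max))
    r_max <- if (!is.null(geom)) wall_radius(geom, geom$pore_half_height) + 3 else 15
  if (is.null(z_range))
    z_range <- if (!is.null(geom)) c(-2, 2) * geom$pore_half_height else c(-15, 15)
  sel <- topology$kind == 0 & topology$mobile == 1
  m_bead <- topology$mass[sel]
  r_edges <- seq(0, r_max + dr, by = dr)
  z_edges <- seq(z_range[1], z_range[2] + dz, by = dz)
  nr <- length(r_edges) - 1; nz <- length(z_edges) - 1
  acc <- matrix(0, nr, nz)
  overflow <- 0
  for (fr in frames) {
    p <- fr[sel, , drop = FALSE]
    r <- sqrt(p[, 1]^2 + p[, 2]^2)
    ri <- findInterval(r, r_edges, rightmost.closed = TRUE)
    zi <- findInterval(p[, 3], z_edges, rightmost.closed = TRUE)
    ok <- ri >= 1 & ri <= nr & zi >= 1 & zi <= nz
    overflow <- overflow + sum(m_bead[!ok])
    if (any(ok)) {
      ii <- cbind(ri[ok], zi[ok])
      for (k in seq_len(nrow(ii))) acc[ii[k, 1], ii[k, 2]] <-
          acc[ii[k, 1], ii[k, 2]] + m_bead[ok][k]
    }
  }
  nf <- length(frames)
  r_centers <- r_edges[-length(r_edges)] + dr / 2
  z_centers <- z_edges[-length(z_edges)] + dz / 2
  vol <- outer(2 * pi * r_centers * dr * dz, rep(1, nz))
  structure(list(r = r_centers, z = z_centers, density = acc / (nf * vol),
                 frame_count = nf, overflow_mass = overflow / nf,
                 total_mass = sum(m_bead)),
            class = "DensityMap")
}

#' Integrated mass of a density map (per frame)
#' @param map a `DensityMap`.
#' @return mass in Da, including overflow.
#' @export
density_map_mass <- function(map) {
  dr <- diff(map$r[1:2]); dz <- diff(map$z[1:2])
  vol <- outer(2 * pi * map$r * dr * dz, rep(1, length(map$z)))
  sum(map$density * vol) + map$overflow_mass
}

#' Barrier versus cargo diameter
#'
#' Computes the energy barrier for each per-diameter PMF and locates the
#' size-selectivity threshold D*: the diameter where the interpolated
#' barrier crosses the soft transport limit kBT. All crossings are reported;
#' with no crossing D* is NA.
#'
#' @param pmfs named list of `PMFProfile`, names = cargo diameters in nm.
#' @param core,reference intervals passed to [energy_barrier()].
#' @param threshold crossing level, kJ/mol (default kBT at 300 K).
#' @return list with `table` (D, G, dispersion), `D_star`, `crossings` and
#'   `threshold`.
#' @export
barrier_curve <- function(pmfs, core = c(-5, 5), reference = c(20, 27),
                          threshold = kBT(300)) {
  if (length(pmfs) < 2) stop("need barriers for at least two diameters")
  D <- as.numeric(names(pmfs))
  if (any(is.na(D))) stop("pmfs must be named by cargo diameter")
  est <- lapply(pmfs, energy_barrier, core = core, reference = reference)
  tab <- data.frame(D = D,
                    G = vapply(est, function(e) e$G, numeric(1)),
                    dispersion = vapply(est, function(e) e$dispersion, numeric(1)))
  tab <- tab[order(tab$D), ]
  rownames(tab) <- NULL
  crossings <- numeric(0)
  for (i in seq_len(nrow(tab) - 1)) {
    g1 <- tab$G[i] - threshold; g2 <- tab$G[i + 1] - threshold
    if (g1 == 0) crossings <- c(crossings, tab$D[i])
    if (g1 * g2 < 0)
      crossings <- c(crossings, tab$D[i] + (tab$D[i + 1] - tab$D[i]) *
                       (-g1) / (g2 - g1))
  }
  if (nrow(tab) && tab$G[nrow(tab)] == threshold)
    crossings <- c(crossings, tab$D[nrow(tab)])
  D_star <- if (length(crossings)) crossings[1] else NA_real_
  if (length(crossings) > 1)
    message("barrier curve crosses the threshold more than once; reporting all crossings")
  list(table = tab, D_star = D_star, crossings = crossings, threshold = threshold)
}
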