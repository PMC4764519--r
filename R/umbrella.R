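## Umbrella-sampling campaign management and WHAM unbiasing.

#' Plan umbrella windows along a reaction coordinate
#'
#' Window centers run from `z_start` to `z_end` inclusive at spacing `dz`
#' (order is normalised; a spacing larger than the span yields a single
#' window). The default bias stiffness is chosen so the ideal-spring
#' positional SD `sqrt(kBT/k)` is about `dz/2`, i.e. `k = 4 kBT / dz^2`,
#' giving strong histogram overlap between neighbours.
#'
#' @param z_start,z_end ends of the scanned range, nm.
#' @param dz window spacing, nm.
#' @param stiffness bias stiffness override, kJ/mol/nm^2.
#' @param lateral_stiffness stiffness of the restraint holding the cargo on
#'   the axis (or at the scan height for radial scans), kJ/mol/nm^2.
#' @param n_steps dynamics steps per window.
#' @param equilibration fraction of `n_steps` discarded as equilibration.
#' @param temperature kelvin (sets the default stiffness).
#' @param seed base seed; window w uses `seed + w - 1`.
#' @return `data.frame` of class `UmbrellaWindows`, ordered along the
#'   coordinate.
#' @export
plan_windows <- function(z_start, z_end, dz, stiffness = NULL,
                         lateral_stiffness = 100, n_steps = 30000,
                         equilibration = 0.2, temperature = 300, seed = 1) {
  if (dz <= 0) stop("dz must be positive")
  lo <- min(z_start, z_end); hi <- max(z_start, z_end)
  centers <- seq(lo, hi, by = dz)
  if (hi - lo >= dz && hi - centers[length(centers)] > 1e-9)
    centers <- c(centers, hi)
  if (is.null(stiffness)) stiffness <- 4 * kBT(temperature) / dz^2
  out <- data.frame(center = centers, stiffness = stiffness,
                    lateral_stiffness = lateral_stiffness,
                    n_steps = as.integer(n_steps),
                    equilibration_steps = as.integer(round(equilibration * n_steps)),
                    seed = seed + seq_along(centers) - 1)
  class(out) <- c("UmbrellaWindows", "data.frame")
  attr(out, "dz") <- dz
  out
}

#' Run one umbrella window
#'
#' Simulates the system with the harmonic bias `0.5 k (z - z0)^2` on the
#' cargo center (plus the lateral restraint holding it on the axis; for
#' radial windows the roles of z and r swap and an angular restraint fixes
#' the direction), discards the equilibration segment and returns the
#' reaction-coordinate samples.
#'
#' @param topology a `SystemTopology` with a cargo (or a single tracked
#'   particle).
#' @param window one row of a [plan_windows()] table (or a list with the same
#'   fields).
#' @param params force-field parameters.
#' @param ld Langevin parameters; the window seed overrides `ld$seed`.
#' @param axis "z" for axial windows, "r" for radial windows.
#' @param theta ray angle for radial windows, degrees.
#' @param z_plane scan height for radial windows, nm.
#' @param external optional external potential.
#' @param sample_every sampling stride, steps.
#' @param place if TRUE (default) the cargo is moved to the window center
#'   before the run; FALSE keeps the warm-start position.
#' @param traj_every frame stride passed through to [run_dynamics()].
#' @return a `WindowSamples` list: post-equilibration `samples`, the full
#'   `series`, the updated `topology`, the window definition, and `flagged`
#'   (TRUE when the window mean drifted more than 3 SD from the center).
#' @export
run_window <- function(topology, window, params = forcefield_params(),
                       ld = langevin_params(), axis = c("z", "r"), theta = 0,
                       z_plane = 0, external = NULL, sample_every = 20,
                       place = TRUE, traj_every = 0) {
  axis <- match.arg(axis)
  w <- as.list(window)
  if (w$stiffness <= 0) stop("window stiffness must be positive")
  ld$seed <- as.numeric(w$seed)
  if (axis == "z") {
    if (place && !is.null(topology$cargo))
      topology <- move_cargo(topology, c(0, 0, w$center))
    restraints <- list(restraint_bias_z(w$stiffness, w$center),
                       restraint_lateral(w$lateral_stiffness))
  } else {
    th <- theta * pi / 180
    if (place && !is.null(topology$cargo))
      topology <- move_cargo(topology, c(w$center * cos(th), w$center * sin(th),
                                         z_plane))
    restraints <- restraint_radial(w$stiffness, w$center, theta,
                                   tangential_stiffness = w$lateral_stiffness,
                                   z_stiffness = w$lateral_stiffness,
                                   z_plane = z_plane)
  }
  run <- run_dynamics(topology, params, ld, restraints, external,
                      n_steps = w$n_steps, sample_every = sample_every,
                      traj_every = traj_every)
  coord <- if (axis == "z") run$series$z
           else run$series$x * cos(theta * pi / 180) +
                run$series$y * sin(theta * pi / 180)
  keep <- run$series$time > w$equilibration_steps * ld$timestep
  samples <- coord[keep]
  flagged <- length(samples) > 1 &&
    abs(mean(samples) - w$center) > 3 * stats::sd(samples)
  structure(list(samples = samples, series = run$series, topology = run$topology,
                 window = w, axis = axis, flagged = flagged,
                 frames = run$frames),
            class = "WindowSamples")
}

#' WHAM: recombine biased window histograms into a PMF
#'
#' Self-consistent weighted-histogram estimator. Window samples are binned on
#' a shared grid; the window free-energy constants are iterated until the
#' largest change falls below `tol`, and the unbiased probability is
#' converted to a free-energy profile `G = -kBT log P`, shifted so the mean
#' over the reference region is zero (or so the minimum is zero when no
#' reference is given). Per-bin uncertainties come from a block bootstrap
#' over time-decorrelated blocks.
#'
#' @param samples list of numeric sample vectors, one per window.
#' @param windows the [plan_windows()] table (uses `center` and `stiffness`).
#' @param bin_width histogram bin width, nm.
#' @param temperature kelvin.
#' @param tol convergence threshold on the window constants, kJ/mol.
#' @param max_iter maximum WHAM iterations.
#' @param reference_region length-2 numeric: shift so the mean PMF over this
#'   interval is zero (e.g. the cytoplasmic end), or NULL for min = 0.
#' @param n_blocks blocks per window for the bootstrap.
#' @param n_boot bootstrap replicates (0 disables uncertainties).
#' @param boot_seed seed for the bootstrap resampling.
#' @return a `PMFProfile` data.frame with columns `z` (bin centers, nm),
#'   `G` (kJ/mol) and `se` (kJ/mol).
#' @export
wham <- function(samples, windows, bin_width = 0.25, temperature = 300,
                 tol = 1e-6, max_iter = 20000, reference_region = NULL,
                 n_blocks = 50, n_boot = 20, boot_seed = 1) {
  stopifnot(length(samples) == nrow(windows))
  kT <- kBT(temperature)
  ord <- order(windows$center)
  windows <- windows[ord, ]
  samples <- samples[ord]
  all <- unlist(samples)
  if (!length(all)) stop("no samples")
  lo <- min(all) - bin_width / 2; hi <- max(all) + bin_width / 2
  edges <- seq(lo, hi + bin_width, by = bin_width)
  zb <- edges[-length(edges)] + bin_width / 2
  B <- length(zb); W <- length(samples)
  H <- matrix(0, W, B)
  for (w in seq_len(W)) {
    idx <- findInterval(samples[[w]], edges, rightmost.closed = TRUE)
    idx <- idx[idx >= 1 & idx <= B]
    H[w, ] <- tabulate(idx, nbins = B)
  }
  ## adjacent windows must share at least one populated bin
  for (w in seq_len(W - 1)) {
    if (!any(H[w, ] > 0 & H[w + 1, ] > 0))
      stop(sprintf("no histogram overlap between windows at %.3g and %.3g",
                   windows$center[w], windows$center[w + 1]))
  }
  U <- matrix(0, W, B)
  for (w in seq_len(W))
    U[w, ] <- 0.5 * windows$stiffness[w] * (zb - windows$center[w])^2

  solve_wham <- function(H, f0 = rep(0, W), max_iter_local = max_iter,
                         tol_local = tol) {
    N <- rowSums(H)
    C <- colSums(H)
    expU <- exp(-U / kT)                     # W x B
    f <- f0
    for (it in seq_len(max_iter_local)) {
      denom <- colSums(N * exp(f / kT) * expU)
      P <- ifelse(denom > 0, C / denom, 0)
      fn <- -kT * log(pmax(expU %*% P, 1e-300))
      fn <- fn - fn[1]
      delta <- max(abs(fn - f))
      f <- as.numeric(fn)
      if (delta < tol_local) {
        P <- P / sum(P * bin_width)
        return(list(f = f, P = P, iter = it, residual = delta))
      }
    }
    list(f = f, P = NULL, iter = max_iter_local, residual = delta)
  }
  sol <- solve_wham(H)
  if (is.null(sol$P))
    stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kJ/mol)",
                 max_iter, sol$residual))
  G <- -kT * log(ifelse(sol$P > 0, sol$P, NA))

  shift_profile <- function(G) {
    if (!is.null(reference_region)) {
      inref <- zb >= min(reference_region) & zb <= max(reference_region) & is.finite(G)
      if (!any(inref)) stop("reference region not covered by the profile")
      G - mean(G[inref])
    } else G - min(G, na.rm = TRUE)
  }
  Gs <- shift_profile(G)

  se <- rep(NA_real_, B)
  if (n_boot > 0) {
    reps <- matrix(NA_real_, n_boot, B)
    with_seed(boot_seed, {
      for (r in seq_len(n_boot)) {
        Hb <- matrix(0, W, B)
        for (w in seq_len(W)) {
          x <- samples[[w]]
          nb <- min(n_blocks, length(x))
          blk <- split(x, cut(seq_along(x), nb, labels = FALSE))
          pick <- sample.int(nb, nb, replace = TRUE)
          xb <- unlist(blk[pick], use.names = FALSE)
          idx <- findInterval(xb, edges, rightmost.closed = TRUE)
          idx <- idx[idx >= 1 & idx <= B]
          Hb[w, ] <- tabulate(idx, nbins = B)
        }
        ## looser tolerance for bootstrap replicates: the replicate noise
        ## dominates well before the last decimals of the constants converge
        sb <- solve_wham(Hb, f0 = sol$f, max_iter_local = 5000,
                         tol_local = max(tol, 1e-4))
        if (!is.null(sb$P)) {
          Gb <- -kT * log(ifelse(sb$P > 0, sb$P, NA))
          ok <- is.finite(Gb) & is.finite(G)
          reps[r, ] <- Gb - mean(Gb[ok]) + mean(G[ok])   # align to main solution
        }
      }
    })
    se <- apply(reps, 2, stats::sd, na.rm = TRUE)
  }
  out <- data.frame(z = zb, G = Gs, se = se)
  class(out) <- c("PMFProfile", "data.frame")
  attr(out, "temperature") <- temperature
  attr(out, "bin_width") <- bin_width
  attr(out, "reference_region") <- reference_region
  attr(out, "wham_iterations") <- sol$iter
  out
}

#' Construct a PMF profile from vectors
#'
#' @param z bin centers, nm.
#' @param G free energy, kJ/mol.
#' @param se per-bin uncertainty, kJ/mol.
#' @return a `PMFProfile`.
#' @export
pmf_profile <- function(z, G, se = 0) {
  out <- data.frame(z = z, G = G, se = se)
  class(out) <- c("PMFProfile", "data.frame")
  out
}

#' Draw samples from a biased Boltzmann distribution
#'
#' Inverse-CDF sampling of `exp(-(U(z) + 0.5 k (z - z0)^2)/kBT)` on a fine
#' grid: synthetic window data with no dynamics, used to exercise the WHAM
#' estimator in isolation from the sampler.
#'
#' @param pmf_fun vectorised function U(z), kJ/mol.
#' @param center,stiffness bias window parameters.
#' @param n number of samples.
#' @param zlim length-2 support of the distribution, nm.
#' @param temperature kelvin.
#' @param seed RNG seed.
#' @return numeric vector of samples.
#' @export
sample_biased_boltzmann <- function(pmf_fun, center, stiffness, n, zlim,
                                    temperature = 300, seed = 1) {
  kT <- kBT(temperature)
  grid <- seq(zlim[1], zlim[2], length.out = 4001)
  dgrid <- diff(grid[1:2])
  wgt <- exp(-(pmf_fun(grid) + 0.5 * stiffness * (grid - center)^2) / kT)
  wgt[!is.finite(wgt)] <- 0
  with_seed(seed, {
    grid[sample.int(length(grid), n, replace = TRUE, prob = wgt)] +
      runif(n, -dgrid / 2, dgrid / 2)
  })
}

#' Compare PMF profiles across sampling levels or window spacings
#'
#' Regrids all profiles onto the grid of the first (with a warning when grids
#' differ) and reports the per-bin and maximum absolute differences between
#' consecutive campaign variants.
#'
#' @param profiles named list of >= 2 `PMFProfile` objects (e.g. 1X, 2X, 3X
#'   sampling).
#' @return `data.frame` with one row per consecutive pair: `pair`,
#'   `max_abs_diff`, `mean_abs_diff`; per-bin differences are attached as
#'   attribute `per_bin`.
#' @export
convergence_report <- function(profiles) {
  if (length(profiles) < 2) stop("need at least two campaign variants")
  if (is.null(names(profiles)))
    names(profiles) <- paste0("variant", seq_along(profiles))
  ref <- profiles[[1]]
  vals <- matrix(NA_real_, length(ref$z), length(profiles))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    if (length(p$z) != length(ref$z) || any(abs(p$z - ref$z) > 1e-9)) {
      warning("profile grids differ; regridding onto the first profile's bins")
      vals[, i] <- approx(p$z, p$G, xout = ref$z, rule = 1)$y
    } else vals[, i] <- p$G
  }
  per_bin <- abs(vals[, -1, drop = FALSE] - vals[, -ncol(vals), drop = FALSE])
  out <- data.frame(
    pair = paste(names(profiles)[-length(profiles)], names(profiles)[-1],
                 sep = " vs "),
    max_abs_diff = apply(per_bin, 2, max, na.rm = TRUE),
    mean_abs_diff = apply(per_bin, 2, mean, na.rm = TRUE))
  attr(out, "per_bin") <- data.frame(z = ref$z, per_bin)
  out
}
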