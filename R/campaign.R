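## Umbrella campaigns: sequences of windows run with warm starts.

#' Run an axial umbrella campaign
#'
#' Runs every window of a [plan_windows()] table along the pore axis,
#' starting at the cytoplasmic end and warm-starting each window from the
#' final state of the previous one (the cargo is translated to the new
#' window center; the chains relax during the window's equilibration
#' segment).
#'
#' @param topology a `SystemTopology` with a cargo attached.
#' @param windows a [plan_windows()] table.
#' @param params force-field parameters.
#' @param ld Langevin parameters (per-window seeds come from the table).
#' @param external optional external potential.
#' @param sample_every sampling stride, steps.
#' @param traj_every frame stride (0 = keep no frames); frames feed
#'   [density_map()].
#' @param verbose print progress.
#' @return an `UmbrellaCampaign`: `samples` (list, one vector per window row),
#'   `windows`, `flagged`, `frames`, `final_topology`.
#' @export
axial_pmf_campaign <- function(topology, windows, params = forcefield_params(),
                               ld = langevin_params(), external = NULL,
                               sample_every = 20, traj_every = 0,
                               verbose = FALSE) {
  ord <- order(windows$center, decreasing = TRUE)   # cytoplasm first
  samples <- vector("list", nrow(windows))
  flagged <- logical(nrow(windows))
  frames <- list()
  topo <- topology
  for (k in ord) {
    ws <- run_window(topo, windows[k, ], params, ld, axis = "z",
                     external = external, sample_every = sample_every,
                     traj_every = traj_every)
    samples[[k]] <- ws$samples
    flagged[k] <- ws$flagged
    if (traj_every > 0) frames <- c(frames, ws$frames)
    topo <- ws$topology
    if (verbose)
      message(sprintf("window z0 = %6.2f nm: %d samples, mean %6.2f",
                      windows$center[k], length(ws$samples),
                      mean(ws$samples)))
  }
  structure(list(samples = samples, windows = windows, flagged = flagged,
                 frames = frames, final_topology = topo),
            class = "UmbrellaCampaign")
}

## bins samples as wham() does and returns indices of adjacent window pairs
## (by center order) that share no populated bin
find_window_gaps <- function(samples, windows, bin_width) {
  ord <- order(windows$center)
  all <- unlist(samples)
  edges <- seq(min(all) - bin_width / 2, max(all) + 1.5 * bin_width,
               by = bin_width)
  pop <- lapply(samples[ord], function(s) {
    idx <- findInterval(s, edges, rightmost.closed = TRUE)
    unique(idx[idx >= 1])
  })
  gaps <- list()
  for (w in seq_len(length(pop) - 1)) {
    if (!length(intersect(pop[[w]], pop[[w + 1]])))
      gaps[[length(gaps) + 1]] <- c(ord[w], ord[w + 1])
  }
  gaps
}

#' Run an axial campaign and WHAM it, bridging histogram gaps
#'
#' Runs [axial_pmf_campaign()] and attempts [wham()]. Where the mean force is
#' steep, adjacent windows can end up with disjoint histograms even at
#' generous spacing; this driver then inserts a bridging window at the
#' midpoint of each gap with twice the bias stiffness (halving the
#' force-induced displacement), samples it from the current warm-start
#' state, and retries, up to `max_refine` rounds.
#'
#' @param topology system with cargo attached.
#' @param windows initial [plan_windows()] table.
#' @param params,ld,external,sample_every as in [axial_pmf_campaign()].
#' @param bin_width,n_boot,boot_seed,reference_region passed to [wham()].
#' @param max_refine maximum bridging rounds.
#' @param verbose print progress.
#' @return list with `pmf` (a `PMFProfile`), the final `windows` and
#'   `samples`, and `refined` (number of windows added).
#' @export
campaign_pmf <- function(topology, windows, params = forcefield_params(),
                         ld = langevin_params(), external = NULL,
                         sample_every = 10, bin_width = 0.4, n_boot = 10,
                         boot_seed = 1, reference_region = NULL,
                         max_refine = 2, verbose = FALSE) {
  camp <- axial_pmf_campaign(topology, windows, params, ld, external,
                             sample_every = sample_every, verbose = verbose)
  samples <- camp$samples
  wins <- windows
  topo <- camp$final_topology
  added <- 0
  for (round in seq_len(max_refine + 1)) {
    gaps <- find_window_gaps(samples, wins, bin_width)
    if (!length(gaps) || round > max_refine) break
    for (g in gaps) {
      mid <- mean(wins$center[g])
      neww <- wins[g[1], ]
      neww$center <- mid
      neww$stiffness <- 2 * max(wins$stiffness[g])
      neww$seed <- max(wins$seed) + 1
      if (verbose) message(sprintf("bridging window at %.2f (k = %g)",
                                   mid, neww$stiffness))
      ws <- run_window(topo, neww, params, ld, axis = "z",
                       external = external, sample_every = sample_every)
      topo <- ws$topology
      wins <- rbind(wins, neww)
      samples[[length(samples) + 1]] <- ws$samples
      added <- added + 1
    }
  }
  pmf <- wham(samples, wins, bin_width = bin_width,
              temperature = ld$temperature, n_boot = n_boot,
              boot_seed = boot_seed, reference_region = reference_region)
  list(pmf = pmf, windows = wins, samples = samples, refined = added)
}

#' Radial PMF profiles in fixed directions
#'
#' Umbrella campaign along the radial coordinate at a fixed height
#' (`z_plane`, default -2.5 nm, near the axial PMF maximum) for each
#' direction in `angles`. Each profile is zero-referenced at r = 0.
#'
#' @param topology a `SystemTopology` with a cargo.
#' @param windows a [plan_windows()] table over the radial coordinate
#'   (centers >= 0).
#' @param z_plane scan height, nm.
#' @param angles directions in degrees (canonically 0, 90, 180, 270).
#' @param params,ld,sample_every,verbose as in [axial_pmf_campaign()].
#' @param bin_width,n_boot WHAM settings.
#' @return named list of `PMFProfile`, one per angle.
#' @export
radial_pmf_campaign <- function(topology, windows, z_plane = -2.5,
                                angles = c(0, 90, 180, 270),
                                params = forcefield_params(),
                                ld = langevin_params(), sample_every = 20,
                                bin_width = 0.25, n_boot = 10, verbose = FALSE) {
  out <- list()
  for (th in angles) {
    samples <- vector("list", nrow(windows))
    topo <- topology
    for (k in order(windows$center)) {          # axis outwards
      ws <- run_window(topo, windows[k, ], params, ld, axis = "r",
                       theta = th, z_plane = z_plane,
                       sample_every = sample_every)
      samples[[k]] <- ws$samples
      topo <- ws$topology
    }
    pmf <- wham(samples, windows, bin_width = bin_width,
                temperature = ld$temperature, n_boot = n_boot)
    pmf$G <- pmf$G - pmf$G[which.min(abs(pmf$z))]
    out[[as.character(th)]] <- pmf
    if (verbose) message("radial direction ", th, " deg done")
  }
  out
}
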