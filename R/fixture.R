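## Synthetic desk-scale fixtures: FG-like sequences (FSFG motifs separated by
## hydrophilic spacers) grafted in a scaled-down eightfold pore. These stand
## in for the real yeast Nup sequences and scaffold anchor coordinates, which
## are external inputs; fixtures emulate their statistics, not their identity.

#' Generate a synthetic desk-scale fixture
#'
#' Produces a scaled pore (diameter `60 * scale` nm, half-height
#' `15.4 * scale` nm), eightfold anchor rings and FG-like sequences built
#' from FSFG motifs separated by S/T/N/Q-rich spacer segments with balanced
#' charges. At the default scale of 1/3 the pore is L = 20 nm and chains are
#' 80 residues. Sequence statistics (FG-motif residue fraction, target
#' 10-15 percent; net charge, target 0) are returned alongside. The barrier
#' core/reference intervals scale with the pore and are included.
#'
#' @param scale pore scale factor in (0, 1].
#' @param seed RNG seed; the same seed yields identical fixtures.
#' @param n_chains number of grafted chains (multiple of 8; wildtype has 128
#'   FG-Nups, fixtures default to 16).
#' @return object of class `SyntheticFixture`: `geometry`, `anchors`,
#'   `sequences` (named character), `stats`, `core_interval`,
#'   `reference_interval`, `scale`, `seed`.
#' @export
generate_synthetic_fixture <- function(scale = 1 / 3, seed = 1, n_chains = 16) {
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  if (n_chains %% 8 != 0) stop("n_chains must be a multiple of 8")
  geom <- scaffold_geometry(pore_diameter = 60 * scale,
                            pore_half_height = 15.4 * scale)
  ## FSFG motif + 16 hydrophilic spacer residues per 20-residue repeat unit:
  ## FG-dimer residue fraction 2/20 = 10%, the dilute end of the declared
  ## 10-15% band. At higher FG fractions the 16-chain desk brush collapses
  ## into wall clumps whose quenched arrangement varies from realization to
  ## realization and washes out the size-selectivity signal.
  n_units <- max(2, round(240 * scale / 20))
  spacer_pool <- c("S", "T", "N", "Q", "G", "A", "S", "T", "N", "Q")
  seqs <- with_seed(seed, {
    out <- character(2)
    for (s in 1:2) {
      units <- character(n_units)
      for (u in seq_len(n_units)) {
        spacer <- sample(spacer_pool, 16, replace = TRUE)
        ## balanced charge pair every second unit
        if (u %% 2 == 0) {
          pos <- sample(16, 2)
          spacer[pos[1]] <- "K"; spacer[pos[2]] <- "D"
        }
        units[u] <- paste0("FSFG", paste(spacer, collapse = ""))
      }
      out[s] <- paste(units, collapse = "")
    }
    names(out) <- c("synFG1", "synFG2")
    out
  })
  rings <- n_chains / 8
  ring_z <- if (rings == 1) 0 else
    seq(-0.25, 0.25, length.out = rings) * geom$pore_half_height
  anchors <- nup_anchors(
    nup_name = paste0("synNup", seq_len(rings)),
    ring_z = ring_z,
    ring_radius = wall_radius(geom, ring_z),
    copies = rep(8L, rings),
    sequence_id = rep(names(seqs), length.out = rings))
  fg_res <- vapply(seqs, function(s) {
    2 * lengths(regmatches(s, gregexpr("FG", s))) / nchar(s)
  }, numeric(1))
  charges <- vapply(seqs, function(s) {
    l <- strsplit(s, "")[[1]]
    sum(l %in% c("K", "R")) - sum(l %in% c("D", "E"))
  }, numeric(1))
  structure(list(geometry = geom, anchors = anchors, sequences = seqs,
                 stats = list(fg_fraction = fg_res, net_charge = charges,
                              chain_length = nchar(seqs)),
                 core_interval = scale * c(-5, 5),
                 reference_interval = scale * c(20, 27),
                 scale = scale, seed = seed),
            class = "SyntheticFixture")
}

#' Build the simulated system for a fixture
#'
#' Convenience wrapper: scaffold + grafted chains from a
#' [generate_synthetic_fixture()] bundle.
#'
#' @param fixture a `SyntheticFixture`.
#' @param seed seed for the initial chain conformations (defaults to the
#'   fixture seed).
#' @param params force-field parameters.
#' @return a `SystemTopology`.
#' @export
build_fixture_system <- function(fixture, seed = fixture$seed,
                                 params = forcefield_params()) {
  scaffold <- build_scaffold(fixture$geometry)
  graft_nups(scaffold, fixture$anchors, fixture$sequences, seed = seed,
             params = params)
}

#' @export
print.SyntheticFixture <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("SyntheticFixture: scale %.3g, L = %.1f nm, half-height %.1f nm\n",
              x$scale, g$pore_diameter, g$pore_half_height))
  cat(sprintf("  %d chains of %s residues; FG fraction %s; net charge %s\n",
              sum(x$anchors$copies),
              paste(unique(x$stats$chain_length), collapse = "/"),
              paste(sprintf("%.3f", x$stats$fg_fraction), collapse = "/"),
              paste(x$stats$net_charge, collapse = "/")))
  invisible(x)
}
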