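## Force-field parameterisation: residue table, angle tables, global constants.

#' Load a residue-parameter table
#'
#' Reads a delimited table with columns `code`, `hydrophobicity`, `charge` and
#' `bead_radius` describing the one-bead-per-residue parameters of the model:
#' a dimensionless hydrophobicity in \[0, 1\] (phenylalanine is the scale
#' maximum, 1.0), a charge in elementary units and the bead radius in nm
#' (default 0.3 nm). The table must cover the 20 amino acids plus the
#' binding-spot pseudo-residue `J`, a Phe-like hydrophobic bead used on the
#' surface of Kap-cargo complexes.
#'
#' @param path path to a delimited text file; default is the table shipped
#'   with the package.
#' @return a `data.frame` of class `ResidueParams`.
#' @export
load_residue_table <- function(path = system.file("extdata", "residue_params.tsv",
                                                  package = "npcbarrier")) {
  tab <- utils::read.table(path, header = TRUE, sep = "", stringsAsFactors = FALSE)
  need <- c("code", "hydrophobicity", "charge", "bead_radius")
  if (!all(need %in% names(tab)))
    stop("residue table must have columns: ", paste(need, collapse = ", "))
  required <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "J")
  missing <- setdiff(required, tab$code)
  if (length(missing))
    stop("residue table is missing residues: ", paste(missing, collapse = ", "))
  if (any(tab$bead_radius <= 0)) stop("bead_radius must be positive")
  if (any(tab$hydrophobicity < 0 | tab$hydrophobicity > 1))
    stop("hydrophobicity must lie in [0, 1]")
  hF <- tab$hydrophobicity[tab$code == "F"]
  if (hF != max(tab$hydrophobicity))
    stop("hydrophobicity of F must be the scale maximum")
  rownames(tab) <- tab$code
  class(tab) <- c("ResidueParams", "data.frame")
  tab
}

#' Load a tabulated angle potential
#'
#' Two-column delimited text: angle (radians) on a uniform grid, energy
#' (kJ/mol). Bending tables span \[0, pi\]; torsion tables span one period
#' \[-pi, pi) and are treated as periodic.
#'
#' @param path file path.
#' @return list with numeric vectors `x` (rad) and `y` (kJ/mol).
#' @export
load_angle_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "")
  if (ncol(tab) < 2) stop("angle table must have two columns (angle, energy)")
  dx <- diff(tab[[1]])
  if (any(abs(dx - dx[1]) > 1e-6)) stop("angle grid must be uniform")
  list(x = tab[[1]], y = tab[[2]])
}

#' Force-field parameters
#'
#' Bundles the parameters of the coarse-grained model: the 0.38 nm backbone
#' bond with a stiff harmonic spring, tabulated bending/torsion potentials,
#' the hydrophobic pair interaction whose most hydrophobic (Phe-Phe) well
#' depth is `eps_max` = 5.2 kJ/mol, Debye-screened electrostatics, and the
#' purely repulsive (WCA) excluded-volume term used for scaffold and cargo
#' surfaces. Pair energies are shifted so they vanish continuously at their
#' cutoffs (2.5 nm hydrophobic, 5.0 nm electrostatic).
#'
#' @param bond_length backbone bond length, nm.
#' @param bond_stiffness harmonic bond constant, kJ/mol/nm^2. Not a printed
#'   model constant; the default keeps RMS bond fluctuations below 0.02 nm
#'   at 300 K.
#' @param eps_max depth of the most hydrophobic pair well, kJ/mol.
#' @param vdw_cutoff hydrophobic cutoff, nm.
#' @param coulomb_cutoff electrostatic cutoff, nm.
#' @param debye_length Debye screening length, nm.
#' @param dielectric relative dielectric constant of the solvent.
#' @param bead_mass mass per residue bead, Da.
#' @param wca_eps energy scale of the excluded-volume repulsion, kJ/mol.
#' @param bend_table,torsion_table tabulated angle potentials
#'   (see [load_angle_table()]); defaults are the shipped tables.
#' @param residues residue-parameter table (see [load_residue_table()]).
#' @return object of class `ForceFieldParams`.
#' @export
forcefield_params <- function(bond_length = 0.38,
                              bond_stiffness = 8000,
                              eps_max = 5.2,
                              vdw_cutoff = 2.5,
                              coulomb_cutoff = 5.0,
                              debye_length = 0.8,
                              dielectric = 80,
                              bead_mass = 120,
                              wca_eps = 5.0,
                              bend_table = NULL,
                              torsion_table = NULL,
                              residues = NULL) {
  if (vdw_cutoff <= 0 || coulomb_cutoff <= 0) stop("cutoffs must be positive")
  if (coulomb_cutoff < vdw_cutoff) stop("coulomb_cutoff must be >= vdw_cutoff")
  if (eps_max <= 0) stop("eps_max must be positive")
  if (is.null(bend_table))
    bend_table <- load_angle_table(system.file("extdata", "bending_table.tsv",
                                               package = "npcbarrier"))
  if (is.null(torsion_table))
    torsion_table <- load_angle_table(system.file("extdata", "torsion_table.tsv",
                                                  package = "npcbarrier"))
  if (is.null(residues)) residues <- load_residue_table()
  structure(list(
    bond_length = bond_length, bond_stiffness = bond_stiffness,
    eps_max = eps_max, vdw_cutoff = vdw_cutoff, coulomb_cutoff = coulomb_cutoff,
    debye_length = debye_length, dielectric = dielectric, bead_mass = bead_mass,
    wca_eps = wca_eps, bend_table = bend_table, torsion_table = torsion_table,
    residues = residues, terms = 15L), class = "ForceFieldParams")
}

#' @export
print.ForceFieldParams <- function(x, ...) {
  cat("Coarse-grained force field\n")
  cat(sprintf("  bond: r0 = %.2f nm, k = %g kJ/mol/nm^2\n", x$bond_length, x$bond_stiffness))
  cat(sprintf("  hydrophobic: eps_max = %.1f kJ/mol, cutoff %.1f nm\n",
              x$eps_max, x$vdw_cutoff))
  cat(sprintf("  electrostatic: Debye %.2f nm, eps_r = %g, cutoff %.1f nm\n",
              x$debye_length, x$dielectric, x$coulomb_cutoff))
  cat(sprintf("  residues: %d types\n", nrow(x$residues)))
  invisible(x)
}
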