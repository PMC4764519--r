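## File formats: FASTA sequences, PDB structures, sample/PMF tables,
## key-value configs. Internal units are nm/ps/kJ/mol; PDB export converts
## to Angstrom at the boundary.

#' Read FG-Nup sequences from FASTA
#'
#' Sequences are validated against the 20-letter amino-acid alphabet;
#' lowercase letters are uppercased with a warning, duplicate record IDs and
#' invalid residues (with their position) are errors.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate sequence IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  if (any(grepl("[a-z]", seqs))) {
    warning("lowercase residues uppercased")
    seqs <- toupper(seqs)
  }
  alphabet <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (i in seq_along(seqs)) {
    l <- strsplit(seqs[i], "")[[1]]
    bad <- which(!l %in% alphabet)
    if (length(bad))
      stop(sprintf("invalid residue '%s' in record '%s' at position %d",
                   l[bad[1]], ids[i], bad[1]))
  }
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#' @param sequences named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta_sequences <- function(sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(sequences)) {
    writeLines(paste0(">", id), con)
    writeLines(strsplit(gsub("(.{60})", "\\1\n", sequences[[id]]), "\n")[[1]], con)
  }
  invisible(path)
}

#' Export a system as PDB
#'
#' One ATOM record per bead, coordinates converted from nm to Angstrom.
#' Chain identifiers cycle per Nup copy; residue names distinguish FG
#' residues (the residue one-letter code, e.g. "F  "), scaffold beads
#' ("SCF"), cargo beads ("CRG") and binding spots ("SPT"). Bead serial
#' numbers wrap at 99999 (PDB fixed-width limit).
#'
#' @param topology a `SystemTopology`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("REMARK   coarse-grained pore model, coordinates in Angstrom", con)
  n <- nrow(topology$pos)
  if (n > 0) {
    chain_ids <- c(LETTERS, letters, 0:9)
    resname <- ifelse(topology$kind == 2, "SCF",
                ifelse(topology$kind == 3, "CRG",
                 ifelse(topology$kind == 1, "SPT",
                        sprintf("%-3s", topology$code))))
    lines <- character(n)
    for (i in seq_len(n)) {
      ch <- if (topology$chain[i] > 0)
        chain_ids[(topology$chain[i] - 1) %% length(chain_ids) + 1] else "z"
      lines[i] <- sprintf(
        "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        (i - 1) %% 99999 + 1, resname[i], ch, (i - 1) %% 9999 + 1,
        topology$pos[i, 1] * 10, topology$pos[i, 2] * 10, topology$pos[i, 3] * 10)
    }
    writeLines(lines, con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read bead coordinates back from a PDB file
#' @param path PDB file written by [write_structure()].
#' @return N x 3 matrix of coordinates in nm.
#' @export
read_structure_coords <- function(path) {
  lines <- readLines(path)
  at <- lines[startsWith(lines, "ATOM")]
  out <- matrix(NA_real_, length(at), 3)
  out[, 1] <- as.numeric(substr(at, 31, 38))
  out[, 2] <- as.numeric(substr(at, 39, 46))
  out[, 3] <- as.numeric(substr(at, 47, 54))
  out / 10
}

## internal: full ATOM table (coords in nm + residue names) from a PDB
read_structure_table <- function(path) {
  lines <- readLines(path)
  at <- lines[startsWith(lines, "ATOM")]
  coords <- matrix(NA_real_, length(at), 3)
  coords[, 1] <- as.numeric(substr(at, 31, 38))
  coords[, 2] <- as.numeric(substr(at, 39, 46))
  coords[, 3] <- as.numeric(substr(at, 47, 54))
  list(coords = coords / 10, resname = trimws(substr(at, 18, 20)))
}

#' Write/read an XYZ coordinate trajectory
#'
#' Plain XYZ: per frame a bead count line, a comment line, then one
#' `EL x y z` row per bead (coordinates in nm).
#'
#' @param frames list of N x 3 matrices.
#' @param path file path.
#' @return `path` (writer) or the list of frames (reader).
#' @export
write_xyz <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    writeLines(c(as.character(nrow(fr)), paste("frame", k)), con)
    writeLines(sprintf("C %.4f %.4f %.4f", fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    rows <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "\\s+")
    frames[[length(frames) + 1]] <-
      matrix(as.numeric(unlist(lapply(rows, `[`, 2:4))), n, 3, byrow = TRUE)
    i <- i + 2 + n
  }
  frames
}

#' Write/read window sample series
#'
#' Two-column delimited text (time ps, coordinate nm), one file per window.
#' @param series data.frame with `time` and a coordinate column.
#' @param path output file.
#' @param coord name of the coordinate column.
#' @return `path`, invisibly.
#' @export
write_window_samples <- function(series, path, coord = "z") {
  utils::write.table(data.frame(time = series$time, value = series[[coord]]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_samples
#' @return for the reader: the data.frame.
#' @export
read_window_samples <- function(path) {
  utils::read.table(path, header = TRUE, sep = "")
}

#' Write a PMF profile as delimited text (z, G, se)
#' @param pmf a `PMFProfile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pmf <- function(pmf, path) {
  utils::write.table(as.data.frame(pmf), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "")
  pmf_profile(tab$z, tab$G, if (!is.null(tab$se)) tab$se else 0)
}

## ---- run configuration ----------------------------------------------------

default_config <- function() {
  list(
    # force field
    bond_length = 0.38, bond_stiffness = 8000, eps_max = 5.2,
    vdw_cutoff = 2.5, coulomb_cutoff = 5.0, debye_length = 0.8,
    dielectric = 80, bead_mass = 120, wca_eps = 5.0,
    # geometry
    pore_diameter = 60, pore_half_height = 15.4,
    scaffold_bead_diameter = 5.0, symmetry_order = 8,
    # dynamics
    temperature = 300, timestep = 0.02, friction = 50,
    # umbrella
    window_dz = 2.0, lateral_stiffness = 100, window_steps = 30000,
    equilibration_fraction = 0.2, sample_every = 20, bin_width = 0.25,
    n_blocks = 50, n_boot = 20,
    # analysis
    core_lo = -5, core_hi = 5, reference_lo = 20, reference_hi = 27,
    density_dr = 0.5, density_dz = 0.5,
    # transport model
    model_L = 60, spot_diameter = 0.6, constrain_b0_zero = FALSE,
    # misc
    seed = 1)
}

#' Read a key-value run configuration
#'
#' Plain `key = value` text (one per line, `#` comments). Unknown keys are
#' rejected; missing keys take the package defaults, which equal the stated
#' model values.
#'
#' @param path config file, or NULL for pure defaults.
#' @return named list of class `RunConfig`.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("malformed config line: ", ln)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% names(cfg)) stop("unknown config key: ", key)
      cfg[[key]] <- if (val %in% c("TRUE", "FALSE")) as.logical(val)
                    else as.numeric(val)
    }
  }
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' Write a fully resolved configuration next to a run's outputs
#' @param cfg a `RunConfig`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) paste(k, "=", format(cfg[[k]])),
                  character(1))
  writeLines(c("# resolved run configuration", lines), path)
  invisible(path)
}
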