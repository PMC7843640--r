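#' mdfluct: comparative residue-fluctuation analysis of MD trajectories
#'
#' Compare the structural rigidity of homologous proteins from molecular
#' dynamics trajectories: superposition and RMSD/RMSF, cross-homolog residue
#' mapping via sequence alignment, RMSF-difference region calling, and
#' salt-bridge / hydrogen-bond occupancy analysis, plus a synthetic-trajectory
#' generator with planted structure for validation.
#'
#' @keywords internal
"_PACKAGE"

## Coarse-topology side-chain "tip" atoms: one named distal heavy atom per
## residue type, with an approximate CA-to-tip extent in Angstrom. GLY has no
## side-chain heavy atom and is excluded from the synthetic alphabet.
.TIP_ATOM <- c(
  ALA = "CB",  ARG = "NH1", ASN = "ND2", ASP = "OD1", CYS = "SG",
  GLN = "NE2", GLU = "OE1", HIS = "NE2", ILE = "CD1", LEU = "CD1",
  LYS = "NZ",  MET = "SD",  PHE = "CZ",  PRO = "CG",  SER = "OG",
  THR = "OG1", TRP = "NE1", TYR = "OH",  VAL = "CG1")

.TIP_LENGTH <- c(
  ALA = 1.5, ARG = 7.0, ASN = 3.5, ASP = 3.6, CYS = 2.8,
  GLN = 4.5, GLU = 4.9, HIS = 4.5, ILE = 3.9, LEU = 3.9,
  LYS = 6.4, MET = 4.4, PHE = 5.1, PRO = 2.4, SER = 2.4,
  THR = 2.6, TRP = 5.2, TYR = 6.5, VAL = 2.5)

.STANDARD_AA3 <- c(names(.TIP_ATOM), "GLY")
.STANDARD_AA1 <- "ACDEFGHIKLMNPQRSTVWY"

.element_of <- function(atom_name) {
  ## First alphabetic character of the atom name is the element for the
  ## standard protein heavy atoms used here (C, N, O, S).
  substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", atom_name)), 1, 1)
}

#' Protein structure with a fixed atom topology
#'
#' A structure is an ordered atom table: one row per atom with chain id,
#' author residue number (1-based, kept as read), 3-letter residue name,
#' atom name, element and Cartesian position in Angstrom.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z` and optionally `element` (derived from `elety` if absent).
#' @param name label for the structure.
#' @return An object of class `md_structure` (a data.frame of atoms with a
#'   `name` attribute).
#' @export
md_structure <- function(atoms, name = "structure") {
  required <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$element)) atoms$element <- .element_of(atoms$elety)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue_number, atom_name): ",
         key[duplicated(key)][1])
  nonstd <- setdiff(unique(atoms$resid), .STANDARD_AA3)
  attr(atoms, "nonstandard_residues") <- nonstd
  attr(atoms, "name") <- name
  rownames(atoms) <- NULL
  class(atoms) <- c("md_structure", "data.frame")
  atoms
}

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf("md_structure '%s': %d atoms, %d residues, chain(s) %s\n",
              attr(x, "name"), nrow(x), n_residues(x),
              paste(unique(x$chain), collapse = ",")))
  invisible(x)
}

#' Number of residues in a structure
#' @param structure an `md_structure`.
#' @return integer count of distinct (chain, residue number) pairs.
#' @export
n_residues <- function(structure) {
  length(unique(paste(structure$chain, structure$resno)))
}

#' Coordinates of a structure as an n x 3 matrix
#' @param structure an `md_structure`.
#' @return numeric matrix with one row per atom (Angstrom).
#' @export
coords <- function(structure) {
  cbind(x = structure$x, y = structure$y, z = structure$z)
}

#' One-letter sequence implied by a structure's residues
#'
#' Residues are taken in file order (one per distinct chain/residue number);
#' used for the structure-to-FASTA consistency check in the pipeline.
#'
#' @param structure an `md_structure`.
#' @return single character string of 1-letter codes.
#' @export
structure_sequence <- function(structure) {
  keep <- !duplicated(paste(structure$chain, structure$resno))
  paste(bio3d::aa321(structure$resid[keep]), collapse = "")
}

#' Molecular dynamics trajectory over a fixed topology
#'
#' @param topology `md_structure` giving atom identities and the reference
#'   coordinates.
#' @param coords numeric array `n_atoms x 3 x n_frames` of frame coordinates
#'   (Angstrom), atom order identical to the topology.
#' @param frame_interval time between saved frames in picoseconds (not stored
#'   in PDB; supplied via argument/config, default 400 ps).
#' @param temperature simulation temperature label in kelvin (metadata only).
#' @return object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, coords, frame_interval = 400,
                          temperature = NA_real_) {
  stopifnot(inherits(topology, "md_structure"))
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1] != nrow(topology))
    stop("frame atom count (", dim(coords)[1],
         ") does not match topology (", nrow(topology), ")")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0 ps")
  structure(
    list(topology = topology, coords = coords,
         frame_interval = frame_interval, temperature = temperature),
    class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf(paste0("md_trajectory '%s': %d frames x %d atoms, ",
                     "interval %g ps (%.3f ns total)%s\n"),
              attr(x$topology, "name"), n_frames(x), nrow(x$topology),
              x$frame_interval, n_frames(x) * x$frame_interval / 1000,
              if (is.na(x$temperature)) ""
              else sprintf(", T = %g K", x$temperature)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Frame times in picoseconds
#'
#' Frames are scheduled at t = i * frame_interval for i = 1..n (the initial
#' configuration at t = 0 is not a saved frame), so a 400 ns run saved every
#' 400 ps gives times 400, 800, ..., 400000 ps.
#'
#' @param traj an `md_trajectory`.
#' @return numeric vector of times (ps).
#' @export
frame_times <- function(traj) seq_len(n_frames(traj)) * traj$frame_interval

#' Number of frames saved over a simulation of given duration
#'
#' @param duration_ns simulation length in nanoseconds.
#' @param frame_interval_ps saving interval in picoseconds (default 400).
#' @return integer frame count; errors if the duration is not a whole number
#'   of intervals.
#' @examples
#' frames_for_duration(400, 400) # 1000
#' @export
frames_for_duration <- function(duration_ns, frame_interval_ps = 400) {
  stopifnot(duration_ns > 0, frame_interval_ps > 0)
  n <- duration_ns * 1000 / frame_interval_ps
  if (abs(n - round(n)) > 1e-9)
    stop("duration is not a whole number of frame intervals")
  as.integer(round(n))
}
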