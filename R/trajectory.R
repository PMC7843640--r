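## Per-frame RMSD and per-residue RMSF over a trajectory.

#' Select atoms of a structure by atom name
#'
#' @param structure an `md_structure`.
#' @param atom_names character vector of atom names (default `"CA"`).
#' @return integer row indices into the atom table; errors when empty.
#' @export
select_atoms <- function(structure, atom_names = "CA") {
  idx <- which(structure$elety %in% atom_names)
  if (!length(idx))
    stop("atom selection (", paste(atom_names, collapse = ","),
         ") matches no atoms")
  idx
}

#' Per-frame RMSD after optimal superposition
#'
#' Each frame is independently superposed onto the reference (Kabsch, on the
#' selected atoms) and the RMSD over those atoms recorded. The default
#' selection is the CA trace.
#'
#' @param traj an `md_trajectory`.
#' @param reference reference coordinates: an `md_structure`, an n x 3
#'   matrix over the selection, or `NULL` for the trajectory topology.
#' @param atom_selection atom names used both for fitting and measurement.
#' @param burn_in_frames number of initial frames to discard (default 0).
#' @return data.frame of class `rmsd_series` with columns `frame_time_ps`
#'   and `rmsd_A`, plus attributes `protein` and `atom_selection`.
#' @export
trajectory_rmsd <- function(traj, reference = NULL, atom_selection = "CA",
                            burn_in_frames = 0) {
  stopifnot(inherits(traj, "md_trajectory"))
  sel <- select_atoms(traj$topology, atom_selection)
  if (is.null(reference)) reference <- traj$topology
  ref <- if (inherits(reference, "md_structure"))
    coords(reference)[select_atoms(reference, atom_selection), , drop = FALSE]
  else as.matrix(reference)
  if (nrow(ref) != length(sel))
    stop("reference selection has ", nrow(ref), " atoms; trajectory has ",
         length(sel))
  frames <- seq_len(n_frames(traj))
  if (burn_in_frames > 0) frames <- frames[-seq_len(burn_in_frames)]
  vals <- vapply(frames, function(f)
    .kabsch_core(traj$coords[sel, , f], ref)$rmsd, numeric(1))
  out <- data.frame(frame_time_ps = frames * traj$frame_interval,
                    rmsd_A = vals)
  attr(out, "protein") <- attr(traj$topology, "name")
  attr(out, "atom_selection") <- atom_selection
  class(out) <- c("rmsd_series", "data.frame")
  out
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf("rmsd_series '%s': %d frames, mean %.3f A (sel: %s)\n",
              attr(x, "protein"), nrow(x), mean(x$rmsd_A),
              paste(attr(x, "atom_selection"), collapse = ",")))
  invisible(x)
}

#' Per-residue RMSF about the iterated mean structure
#'
#' Two fixed passes: frames are superposed onto the first frame and averaged,
#' then re-superposed onto that mean and averaged again; the RMSF of residue
#' i is the root of the mean squared displacement of its selected atom from
#' the final mean. The selection must resolve to exactly one atom per
#' residue (default CA).
#'
#' @param traj an `md_trajectory` with at least 2 frames.
#' @param atom_selection atom names; one atom per residue.
#' @param burn_in_frames initial frames to discard.
#' @return data.frame of class `rmsf_profile` with columns `residue_number`
#'   and `rmsf_A`, plus `protein`/`atom_selection` attributes.
#' @export
rmsf <- function(traj, atom_selection = "CA", burn_in_frames = 0) {
  stopifnot(inherits(traj, "md_trajectory"))
  sel <- select_atoms(traj$topology, atom_selection)
  res_key <- paste(traj$topology$chain[sel], traj$topology$resno[sel])
  if (anyDuplicated(res_key))
    stop("selection resolves to more than one atom in residue ",
         res_key[duplicated(res_key)][1], "; RMSF is per-residue")
  frames <- seq_len(n_frames(traj))
  if (burn_in_frames > 0) frames <- frames[-seq_len(burn_in_frames)]
  if (length(frames) < 2) stop("at least 2 frames are required")
  X <- traj$coords[sel, , frames, drop = FALSE]
  nf <- length(frames)
  align_to <- function(ref) {
    out <- array(NA_real_, dim = dim(X))
    for (f in seq_len(nf)) {
      tr <- .kabsch_core(X[, , f], ref)
      out[, , f] <- apply_transform(X[, , f], tr)
    }
    out
  }
  aligned <- align_to(X[, , 1])
  m1 <- apply(aligned, c(1, 2), mean)
  aligned <- align_to(m1)
  m2 <- apply(aligned, c(1, 2), mean)
  dev2 <- (aligned - as.vector(m2))^2        # recycles m2 over frames
  msd <- apply(dev2, 1, sum) / nf            # sum over xyz, mean over frames
  out <- data.frame(residue_number = traj$topology$resno[sel],
                    rmsf_A = sqrt(msd))
  attr(out, "protein") <- attr(traj$topology, "name")
  attr(out, "atom_selection") <- atom_selection
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf("rmsf_profile '%s': %d residues, mean %.3f A, max %.3f A\n",
              attr(x, "protein"), nrow(x), mean(x$rmsf_A), max(x$rmsf_A)))
  invisible(x)
}

#' @method plot rmsf_profile
#' @export
plot.rmsf_profile <- function(x, ...) {
  graphics::plot(x$residue_number, x$rmsf_A, type = "l",
                 xlab = "residue number", ylab = "RMSF (A)",
                 main = attr(x, "protein"), ...)
  invisible(x)
}
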