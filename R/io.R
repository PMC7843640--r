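## PDB and FASTA input/output. Parsing of the fixed-column PDB layout is
## delegated to bio3d; a line-level pre-scan enforces the stricter contracts
## needed here (congruent atom counts across models, no altLocs or insertion
## codes, parseable coordinates) with informative positions in the messages.

.prescan_pdb <- function(lines) {
  is_atom <- startsWith(lines, "ATOM  ")
  is_model <- startsWith(lines, "MODEL")
  is_endmdl <- startsWith(lines, "ENDMDL")
  atom_lines <- which(is_atom)
  if (!length(atom_lines)) stop("no ATOM records found")
  for (ln in atom_lines) {
    rec <- lines[ln]
    if (nchar(rec) < 54)
      stop("unparseable ATOM line ", ln, ": record shorter than 54 columns")
    alt <- substr(rec, 17, 17)
    if (alt != " ")
      stop("ATOM line ", ln, ": alternate location indicator '", alt,
           "' not supported")
    ins <- substr(rec, 27, 27)
    if (ins != " ")
      stop("ATOM line ", ln, ": insertion code '", ins, "' not supported")
    xyz <- suppressWarnings(as.numeric(
      c(substr(rec, 31, 38), substr(rec, 39, 46), substr(rec, 47, 54))))
    if (anyNA(xyz))
      stop("unparseable ATOM line ", ln, ": bad coordinate field")
  }
  ## atom counts per MODEL block (whole file = one block when no MODEL)
  if (any(is_model)) {
    model_id <- cumsum(is_model)
    if (any(is_atom & model_id == 0))
      stop("ATOM records found outside MODEL/ENDMDL blocks")
    counts <- tapply(is_atom, model_id, sum)
    counts <- as.integer(counts[names(counts) != "0"]) # drop pre-MODEL part
    if (length(unique(counts)) > 1) {
      ref <- counts[1]
      bad <- which(counts != ref)[1]
      stop("model ", bad, " has ", counts[bad], " atoms; expected ", ref)
    }
    n_models <- sum(is_model)
  } else {
    n_models <- 0L
  }
  list(n_models = n_models)
}

#' Read a PDB file as a structure or trajectory
#'
#' Single-model files (no MODEL records) yield an [md_structure]; files with
#' MODEL/ENDMDL blocks yield an [md_trajectory] whose frames are the models
#' in file order. HETATM records are ignored. Alternate locations and
#' insertion codes are rejected. The frame interval is not representable in
#' PDB and is supplied by the caller (default 400 ps).
#'
#' @param path PDB file path.
#' @param frame_interval frame spacing in ps for multi-model files.
#' @param temperature temperature label in kelvin (metadata only).
#' @param name structure name (default: file base name).
#' @return an `md_structure` or `md_trajectory`.
#' @export
read_pdb <- function(path, frame_interval = 400, temperature = NA_real_,
                     name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(name)) name <- sub("\\.pdb$", "", basename(path))
  scan <- .prescan_pdb(readLines(path, warn = FALSE))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  keep <- which(pdb$atom$type == "ATOM")
  at <- pdb$atom[keep, , drop = FALSE]
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(elesy == ""))
    elesy <- .element_of(at$elety)
  topo_xyz <- matrix(pdb$xyz[1, bio3d::atom2xyz(keep)], ncol = 3, byrow = TRUE)
  topo <- md_structure(
    data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
               elety = at$elety, element = elesy,
               x = topo_xyz[, 1], y = topo_xyz[, 2], z = topo_xyz[, 3],
               stringsAsFactors = FALSE),
    name = name)
  if (scan$n_models == 0L) return(topo)
  nf <- nrow(pdb$xyz)
  arr <- array(NA_real_, dim = c(nrow(topo), 3, nf))
  cols <- bio3d::atom2xyz(keep)
  for (f in seq_len(nf))
    arr[, , f] <- matrix(pdb$xyz[f, cols], ncol = 3, byrow = TRUE)
  md_trajectory(topo, arr, frame_interval = frame_interval,
                temperature = temperature)
}

#' Write a structure or trajectory as (multi-model) PDB
#'
#' Round trip: reading a written file reproduces atom identities exactly and
#' coordinates to 3 decimals (PDB field precision). Coordinates outside the
#' `%8.3f` field (beyond -999.999 .. 9999.999) are an error.
#'
#' @param x an `md_structure` or `md_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "md_trajectory")) {
    topo <- x$topology
    nf <- n_frames(x)
    xyz <- matrix(NA_real_, nrow = nf, ncol = 3 * nrow(topo))
    for (f in seq_len(nf))
      xyz[f, ] <- as.vector(t(x$coords[, , f]))
  } else if (inherits(x, "md_structure")) {
    topo <- x
    xyz <- matrix(as.vector(t(coords(x))), nrow = 1)
  } else stop("x must be an md_structure or md_trajectory")
  if (any(xyz > 9999.999 | xyz < -999.999))
    stop("coordinate exceeds the 8.3 PDB field width")
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   resno = topo$resno, resid = topo$resid,
                   eleno = seq_len(nrow(topo)), elety = topo$elety,
                   chain = topo$chain, elesy = topo$element,
                   end = TRUE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' Records are returned in file order as a named character vector of
#' upper-case 1-letter sequences; ids are the first whitespace-delimited
#' token of each header. Only the 20 standard letters plus X are accepted.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) stop("no FASTA records in ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  if (any(!nzchar(seqs)))
    stop("empty sequence under header '",
         names(seqs)[!nzchar(seqs)][1], "'")
  ok <- paste0(.STANDARD_AA1, "X")
  for (i in seq_along(seqs)) {
    bad <- setdiff(strsplit(seqs[[i]], "")[[1]], strsplit(ok, "")[[1]])
    if (length(bad))
      stop("record '", names(seqs)[i], "' contains non-standard letter(s): ",
           paste(bad, collapse = ""))
  }
  seqs
}

#' Write sequences (or gapped alignment rows) as FASTA
#'
#' @param seqs named character vector; `-` gap characters are allowed so that
#'   alignments can be written with the same function.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Lengths of locally cached GenBank protein records
#'
#' Reads a FASTA copy of GenBank records (for example fetched once with
#' `efetch`) and reports the sequence length per accession. The package does
#' not download anything itself; `path` defaults to the package's cached copy
#' under `inst/extdata/genbank/` when present.
#'
#' @param path FASTA file of GenBank protein records.
#' @return named integer vector of sequence lengths.
#' @export
genbank_sequence_lengths <- function(path = system.file(
    "extdata", "genbank", "mgs_genbank.fasta", package = "mdfluct")) {
  if (is.null(path) || !nzchar(path) || !file.exists(path))
    stop("no local GenBank FASTA found; fetch the records and pass its path")
  seqs <- read_fasta(path)
  vapply(seqs, nchar, integer(1))
}
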