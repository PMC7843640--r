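## Salt-bridge and hydrogen-bond analysis: candidate pair search on the
## reference geometry, per-frame distance series with occupancy, and the
## cross-homolog SB / HB / NI comparison table.

.BASIC_ATOMS <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                     HIS = c("ND1", "NE2"))
.ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

## default contact cutoffs (heavy-atom distances, Angstrom)
.CONTACT_CUTOFF <- c(salt_bridge = 4.0, hydrogen_bond = 3.5)

.residue_table <- function(structure) {
  keep <- !duplicated(paste(structure$chain, structure$resno))
  data.frame(chain = structure$chain[keep], resno = structure$resno[keep],
             resid = structure$resid[keep], stringsAsFactors = FALSE)
}

.atoms_of <- function(structure, chain, resno, atom_names) {
  which(structure$chain == chain & structure$resno == resno &
          structure$elety %in% atom_names)
}

.new_pair <- function(kind, res_a, atoms_a, res_b, atoms_b,
                      ref_distance = NA_real_) {
  structure(list(kind = kind, res_a = res_a, atoms_a = atoms_a,
                 res_b = res_b, atoms_b = atoms_b,
                 cutoff = .CONTACT_CUTOFF[[kind]],
                 ref_distance = ref_distance),
            class = "interaction_pair")
}

#' @export
print.interaction_pair <- function(x, ...) {
  cat(sprintf("%s %s%d(%s) -- %s%d(%s): ref %.2f A, cutoff %.1f A\n",
              x$kind, x$res_a$resid, x$res_a$resno,
              paste(x$atoms_a, collapse = "/"),
              x$res_b$resid, x$res_b$resno,
              paste(x$atoms_b, collapse = "/"),
              x$ref_distance, x$cutoff))
  invisible(x)
}

.min_pair_distance <- function(xyz, ia, ib) {
  d <- Inf
  for (i in ia) for (j in ib)
    d <- min(d, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
  d
}

#' Search a structure for salt-bridge or hydrogen-bond candidates
#'
#' Salt bridges: every basic side-chain group (Lys NZ; Arg NH1/NH2/NE; His
#' ND1/NE2) against every acidic group (Asp OD1/OD2; Glu OE1/OE2) whose
#' minimum heavy-atom distance in the reference geometry is within
#' `search_cutoff`. Hydrogen bonds: all N/O heavy-atom pairs (side-chain and
#' backbone) within the cutoff, excluding pairs within one residue and
#' backbone-backbone pairs of sequence-adjacent residues. Criteria are
#' distance-only (no donor-H-acceptor angle; the coarse topology carries no
#' hydrogens). Residues with unrecognised chemistry are skipped with a
#' warning. Pairs are reported once, in canonical (chain, residue) order.
#'
#' @param structure an `md_structure` (reference geometry).
#' @param kind `"salt_bridge"` or `"hydrogen_bond"`.
#' @param search_cutoff candidate search radius in Angstrom (default 6).
#' @return list of `interaction_pair` objects.
#' @export
candidate_pairs <- function(structure, kind = c("salt_bridge",
                                                "hydrogen_bond"),
                            search_cutoff = 6.0) {
  kind <- match.arg(kind)
  xyz <- coords(structure)
  res <- .residue_table(structure)
  unknown <- setdiff(unique(res$resid), .STANDARD_AA3)
  if (length(unknown)) {
    warning("skipping residue(s) with unknown chemistry: ",
            paste(unknown, collapse = ","))
    res <- res[!res$resid %in% unknown, ]
  }
  pairs <- list()
  add <- function(i, j, atoms_i, atoms_j) {
    ia <- .atoms_of(structure, res$chain[i], res$resno[i], atoms_i)
    ib <- .atoms_of(structure, res$chain[j], res$resno[j], atoms_j)
    if (!length(ia) || !length(ib)) return()
    d <- .min_pair_distance(xyz, ia, ib)
    if (d > search_cutoff) return()
    ## canonical order: lower (chain, resno) first
    if (res$chain[j] < res$chain[i] ||
        (res$chain[j] == res$chain[i] && res$resno[j] < res$resno[i])) {
      tmp <- i; i <- j; j <- tmp
      tmpa <- atoms_i; atoms_i <- atoms_j; atoms_j <- tmpa
    }
    pairs[[length(pairs) + 1]] <<- .new_pair(
      kind,
      list(chain = res$chain[i], resno = res$resno[i], resid = res$resid[i]),
      structure$elety[.atoms_of(structure, res$chain[i], res$resno[i],
                                atoms_i)],
      list(chain = res$chain[j], resno = res$resno[j], resid = res$resid[j]),
      structure$elety[.atoms_of(structure, res$chain[j], res$resno[j],
                                atoms_j)],
      d)
  }
  if (kind == "salt_bridge") {
    basics <- which(res$resid %in% names(.BASIC_ATOMS))
    acidics <- which(res$resid %in% names(.ACIDIC_ATOMS))
    for (i in basics) for (j in acidics)
      add(i, j, .BASIC_ATOMS[[res$resid[i]]], .ACIDIC_ATOMS[[res$resid[j]]])
  } else {
    no_idx <- which(structure$element %in% c("N", "O") &
                      paste(structure$chain, structure$resno) %in%
                        paste(res$chain, res$resno))
    if (length(no_idx) > 1) {
      for (u in seq_along(no_idx)) for (v in seq_along(no_idx)) {
        if (u >= v) next
        i <- no_idx[u]; j <- no_idx[v]
        same_res <- structure$chain[i] == structure$chain[j] &&
          structure$resno[i] == structure$resno[j]
        if (same_res) next
        adjacent_bb <- structure$chain[i] == structure$chain[j] &&
          abs(structure$resno[i] - structure$resno[j]) <= 1 &&
          structure$elety[i] %in% .BACKBONE_ATOMS &&
          structure$elety[j] %in% .BACKBONE_ATOMS
        if (adjacent_bb) next
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (d > search_cutoff) next
        ri <- which(res$chain == structure$chain[i] &
                      res$resno == structure$resno[i])
        rj <- which(res$chain == structure$chain[j] &
                      res$resno == structure$resno[j])
        if (structure$chain[j] < structure$chain[i] ||
            (structure$chain[j] == structure$chain[i] &&
               structure$resno[j] < structure$resno[i])) {
          tmp <- i; i <- j; j <- tmp
          tmpr <- ri; ri <- rj; rj <- tmpr
        }
        pairs[[length(pairs) + 1]] <- .new_pair(
          "hydrogen_bond",
          list(chain = res$chain[ri], resno = res$resno[ri],
               resid = res$resid[ri]),
          structure$elety[i],
          list(chain = res$chain[rj], resno = res$resno[rj],
               resid = res$resid[rj]),
          structure$elety[j],
          d)
      }
    }
  }
  ## de-duplicate residue pairs (keep the closest atom combination record)
  if (length(pairs) > 1) {
    key <- vapply(pairs, function(p)
      paste(p$res_a$chain, p$res_a$resno, p$res_b$chain, p$res_b$resno),
      "")
    ord <- order(key, vapply(pairs, function(p) p$ref_distance, 0))
    pairs <- pairs[ord][!duplicated(sort(key))]
    ## merge atom lists of duplicates is unnecessary for the coarse topology
  }
  pairs
}

#' Per-frame distance series and occupancy for an interaction pair
#'
#' The per-frame distance is the minimum over the listed equivalent atoms
#' (e.g. Asp OD1/OD2); occupancy is the fraction of frames at or below the
#' contact cutoff (salt bridge 4.0 A, hydrogen bond 3.5 A by default).
#' Distances need no superposition: they are invariant under the rigid
#' motion of each frame.
#'
#' @param traj an `md_trajectory`.
#' @param pair an `interaction_pair` (see [candidate_pairs]).
#' @param cutoff contact cutoff override (A).
#' @return object of class `interaction_series`: list with `pair`,
#'   `distances` (per frame, A), `frame_times` (ps), `cutoff`, `occupancy`.
#' @export
distance_series <- function(traj, pair, cutoff = NULL) {
  stopifnot(inherits(traj, "md_trajectory"),
            inherits(pair, "interaction_pair"))
  if (is.null(cutoff)) cutoff <- pair$cutoff
  topo <- traj$topology
  ia <- .atoms_of(topo, pair$res_a$chain, pair$res_a$resno, pair$atoms_a)
  ib <- .atoms_of(topo, pair$res_b$chain, pair$res_b$resno, pair$atoms_b)
  if (!length(ia))
    stop("atom(s) ", paste(pair$atoms_a, collapse = "/"), " of residue ",
         pair$res_a$resno, " not in topology")
  if (!length(ib))
    stop("atom(s) ", paste(pair$atoms_b, collapse = "/"), " of residue ",
         pair$res_b$resno, " not in topology")
  nf <- n_frames(traj)
  d <- rep(Inf, nf)
  for (i in ia) for (j in ib) {
    dif <- traj$coords[i, , , drop = TRUE] - traj$coords[j, , , drop = TRUE]
    if (nf == 1) dif <- matrix(dif, ncol = 1)
    d <- pmin(d, sqrt(colSums(dif^2)))
  }
  structure(list(pair = pair, distances = d, frame_times = frame_times(traj),
                 cutoff = cutoff, occupancy = mean(d <= cutoff)),
            class = "interaction_series")
}

#' @export
print.interaction_series <- function(x, ...) {
  cat(sprintf("interaction_series (%s %d-%d): %d frames, occupancy %.3f\n",
              x$pair$kind, x$pair$res_a$resno, x$pair$res_b$resno,
              length(x$distances), x$occupancy))
  invisible(x)
}

.chem_compatible <- function(kind, resid_a, resid_b) {
  if (kind == "salt_bridge") {
    (resid_a %in% names(.BASIC_ATOMS) && resid_b %in% names(.ACIDIC_ATOMS)) ||
      (resid_b %in% names(.BASIC_ATOMS) && resid_a %in% names(.ACIDIC_ATOMS))
  } else {
    has_no <- function(r) {
      tip <- .TIP_ATOM[r]
      !is.na(tip) && .element_of(tip) %in% c("N", "O")
    }
    has_no(resid_a) && has_no(resid_b)
  }
}

#' Compare interaction occupancies across homologs
#'
#' Joins measured interaction series from several proteins on common column
#' pairs (via the alignment map) and classifies each protein at each pair:
#' `SB` or `HB` (by the pair's kind) when the occupancy reaches
#' `presence_threshold`, `NI` when the interaction is essentially never
#' formed or when the aligned residue cannot chemically form it (for a salt
#' bridge, e.g. the basic partner replaced by a methionine). Rows whose
#' residues fall in gap columns are flagged, not dropped.
#'
#' @param series_by_protein named list (per protein id) of lists of
#'   `interaction_series`.
#' @param alignment_map an [build_map] result covering the proteins.
#' @param structures optional named list of `md_structure`, used to name the
#'   aligned residues of proteins for which a pair was not measured.
#' @param presence_threshold minimum occupancy for calling an interaction
#'   formed (default 0.1).
#' @return data.frame with one row per (common pair, protein): columns
#'   `common_pair`, `kind`, `protein`, `resno_a`, `resid_a`, `resno_b`,
#'   `resid_b`, `occupancy`, `classification`, `note`.
#' @export
compare_across_homologs <- function(series_by_protein, alignment_map,
                                    structures = NULL,
                                    presence_threshold = 0.1) {
  stopifnot(is.list(series_by_protein), !is.null(names(series_by_protein)))
  key_of <- function(id, s) {
    ca <- alignment_map$res2col[[id]][s$pair$res_a$resno]
    cb <- alignment_map$res2col[[id]][s$pair$res_b$resno]
    if (is.na(ca) || is.na(cb)) return(NA_character_)
    paste0("c", min(ca, cb), "-c", max(ca, cb), ":", s$pair$kind)
  }
  ## index measured series by (protein, key)
  measured <- list()
  unmapped <- list()
  for (id in names(series_by_protein)) {
    for (s in series_by_protein[[id]]) {
      k <- key_of(id, s)
      if (is.na(k)) {
        unmapped[[length(unmapped) + 1]] <- list(id = id, s = s)
      } else measured[[paste(id, k)]] <- s
    }
  }
  keys <- sort(unique(vapply(
    strsplit(names(measured), " ", fixed = TRUE), `[`, "", 2)))
  rows <- list()
  for (k in keys) {
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    kind <- parts[2]
    cols <- as.integer(sub("c", "", strsplit(parts[1], "-")[[1]]))
    for (id in names(series_by_protein)) {
      s <- measured[[paste(id, k)]]
      if (!is.null(s)) {
        occ <- s$occupancy
        cls <- if (occ >= presence_threshold)
          c(salt_bridge = "SB", hydrogen_bond = "HB")[[kind]] else "NI"
        rows[[length(rows) + 1]] <- data.frame(
          common_pair = parts[1], kind = kind, protein = id,
          resno_a = s$pair$res_a$resno, resid_a = s$pair$res_a$resid,
          resno_b = s$pair$res_b$resno, resid_b = s$pair$res_b$resid,
          occupancy = occ, classification = cls, note = "")
      } else {
        ra <- alignment_map$col2res[[id]][cols[1]]
        rb <- alignment_map$col2res[[id]][cols[2]]
        resid_a <- resid_b <- NA_character_
        if (!is.null(structures[[id]])) {
          rt <- .residue_table(structures[[id]])
          if (!is.na(ra)) resid_a <- rt$resid[match(ra, rt$resno)]
          if (!is.na(rb)) resid_b <- rt$resid[match(rb, rt$resno)]
        }
        note <- if (is.na(ra) || is.na(rb)) "gap_column"
        else if (!is.na(resid_a) && !is.na(resid_b) &&
                   !.chem_compatible(kind, resid_a, resid_b))
          "incompatible_residue"
        else "not_measured"
        rows[[length(rows) + 1]] <- data.frame(
          common_pair = parts[1], kind = kind, protein = id,
          resno_a = ra, resid_a = resid_a, resno_b = rb, resid_b = resid_b,
          occupancy = NA_real_, classification = "NI", note = note)
      }
    }
  }
  for (u in unmapped)
    rows[[length(rows) + 1]] <- data.frame(
      common_pair = NA_character_, kind = u$s$pair$kind, protein = u$id,
      resno_a = u$s$pair$res_a$resno, resid_a = u$s$pair$res_a$resid,
      resno_b = u$s$pair$res_b$resno, resid_b = u$s$pair$res_b$resid,
      occupancy = u$s$occupancy, classification = "NI",
      note = "unmapped_residue")
  if (!length(rows))
    return(data.frame(common_pair = character(0), kind = character(0),
                      protein = character(0), resno_a = integer(0),
                      resid_a = character(0), resno_b = integer(0),
                      resid_b = character(0), occupancy = numeric(0),
                      classification = character(0), note = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
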