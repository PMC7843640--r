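## Synthetic reference structures, trajectories with planted per-residue
## fluctuation amplitudes and planted two-state contacts, and homologous
## sequence sets with ground-truth residue correspondence. These emulate the
## inputs of a comparative thermostability MD study at a scale where every
## downstream quantity has a known expectation.

.sample_sequence <- function(n_residues) {
  ## letters with a defined side-chain tip atom (no GLY), mildly enriched in
  ## charged/polar residues so interaction analyses have material to work on
  aa <- bio3d::aa321(names(.TIP_ATOM))
  w <- rep(1, length(aa))
  w[aa %in% c("K", "R", "D", "E", "T", "S")] <- 2
  paste(sample(aa, n_residues, replace = TRUE, prob = w / sum(w)),
        collapse = "")
}

#' Coarse reference structure on a helical self-avoiding curve
#'
#' Builds a two-atoms-per-residue model: CA atoms on a wide helix with 3.8 A
#' consecutive spacing, plus one named side-chain tip atom per residue (NZ
#' for Lys, OD1 for Asp, OG1 for Thr, ...) placed radially outward at an
#' approximate side-chain extent. The assigned sequence is drawn from the
#' 19 residue types that have a side-chain heavy atom (GLY excluded), or
#' supplied explicitly.
#'
#' @param n_residues number of residues (>= 2); ignored when `sequence` is
#'   given.
#' @param sequence optional 1-letter sequence to realise.
#' @param seed RNG seed for the sequence draw.
#' @param chain chain identifier.
#' @param name structure name.
#' @return an `md_structure` with `2 * n_residues` atoms.
#' @export
make_reference_structure <- function(n_residues = NULL, sequence = NULL,
                                     seed = 1, chain = "A",
                                     name = "synthetic") {
  if (is.null(sequence)) {
    if (is.null(n_residues) || n_residues < 2)
      stop("n_residues must be >= 2")
    set.seed(seed)
    sequence <- .sample_sequence(n_residues)
  }
  aa1 <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa1)
  if (n < 2) stop("n_residues must be >= 2")
  aa3 <- bio3d::aa123(aa1)
  bad <- setdiff(unique(aa3), names(.TIP_ATOM))
  if (length(bad))
    stop("sequence contains residue(s) without a defined tip atom: ",
         paste(bad, collapse = ","))
  radius <- 12; rise <- 1.5
  chord <- sqrt(3.8^2 - rise^2)
  theta <- 2 * asin(chord / (2 * radius))
  i <- seq_len(n)
  ca <- cbind(radius * cos(i * theta), radius * sin(i * theta), i * rise)
  radial <- cbind(cos(i * theta), sin(i * theta), 0)
  tip <- ca + radial * .TIP_LENGTH[aa3]
  atoms <- data.frame(
    chain = chain,
    resno = rep(i, each = 2),
    resid = rep(aa3, each = 2),
    elety = as.vector(rbind("CA", .TIP_ATOM[aa3])),
    x = as.vector(rbind(ca[, 1], tip[, 1])),
    y = as.vector(rbind(ca[, 2], tip[, 2])),
    z = as.vector(rbind(ca[, 3], tip[, 3])),
    stringsAsFactors = FALSE)
  md_structure(atoms, name = name)
}

#' Per-residue fluctuation specification for the trajectory generator
#'
#' @param n_residues residue count, matching the reference structure.
#' @param base_sigma baseline per-axis Gaussian displacement SD (Angstrom).
#' @param regions optional data.frame with columns `start`, `end`, `sigma`
#'   overriding the baseline over residue spans (the planted
#'   high-fluctuation regions).
#' @param rigid_max_rot_deg,rigid_max_trans per-frame rigid-body noise: a
#'   random rotation up to this angle (degrees) and a random translation with
#'   components up to this magnitude (Angstrom) applied to the whole frame.
#' @param seed RNG seed used by [make_trajectory].
#' @return object of class `fluctuation_spec`.
#' @export
fluctuation_spec <- function(n_residues, base_sigma = 0.3, regions = NULL,
                             rigid_max_rot_deg = 0, rigid_max_trans = 0,
                             seed = 1) {
  sigma <- rep(base_sigma, n_residues)
  if (!is.null(regions)) {
    regions <- as.data.frame(regions)
    stopifnot(all(c("start", "end", "sigma") %in% names(regions)))
    if (any(regions$start < 1 | regions$end > n_residues |
            regions$start > regions$end))
      stop("region spans must lie within [1, n_residues]")
    for (r in seq_len(nrow(regions)))
      sigma[regions$start[r]:regions$end[r]] <- regions$sigma[r]
  }
  if (any(sigma < 0)) stop("sigmas must be >= 0")
  structure(list(n_residues = n_residues, sigma = sigma, regions = regions,
                 rigid_max_rot_deg = rigid_max_rot_deg,
                 rigid_max_trans = rigid_max_trans, seed = seed),
            class = "fluctuation_spec")
}

#' Planted two-state residue-pair interaction
#'
#' In each generated frame the named atom pair is set (by moving the second
#' atom along the pair axis) to `bound_distance` with probability `occupancy`
#' and `unbound_distance` otherwise, plus Gaussian jitter — an idealised
#' forming/breaking salt bridge or hydrogen bond with known occupancy.
#'
#' @param res_a,res_b residue numbers of the anchor and partner residue.
#' @param atom_a,atom_b atom names; default: the residue's side-chain tip.
#' @param bound_distance,unbound_distance contact / broken distances (A),
#'   `bound_distance < unbound_distance`.
#' @param occupancy Bernoulli probability of the bound state per frame.
#' @param jitter_sigma SD of the distance jitter (A).
#' @return object of class `interaction_plan`.
#' @export
interaction_plan <- function(res_a, res_b, atom_a = NULL, atom_b = NULL,
                             bound_distance = 3.0, unbound_distance = 8.0,
                             occupancy = 1, jitter_sigma = 0.1) {
  if (!(bound_distance < unbound_distance))
    stop("bound_distance must be < unbound_distance")
  if (occupancy < 0 || occupancy > 1) stop("occupancy must be in [0, 1]")
  structure(list(res_a = res_a, res_b = res_b, atom_a = atom_a,
                 atom_b = atom_b, bound_distance = bound_distance,
                 unbound_distance = unbound_distance, occupancy = occupancy,
                 jitter_sigma = jitter_sigma),
            class = "interaction_plan")
}

.resolve_plan_atom <- function(topology, resno, atom_name, what) {
  rows <- which(topology$resno == resno)
  if (!length(rows)) stop("interaction plan references missing residue ",
                          resno)
  if (is.null(atom_name)) {
    ## default to the side-chain tip (the non-CA atom of the residue)
    rows <- rows[topology$elety[rows] != "CA"]
    if (!length(rows)) stop("residue ", resno, " has no side-chain atom")
    return(rows[1])
  }
  hit <- rows[topology$elety[rows] == atom_name]
  if (!length(hit))
    stop("interaction plan references missing atom ", atom_name,
         " of residue ", resno, " (", what, ")")
  hit[1]
}

#' Place planted contacts in a reference structure
#'
#' Moves each plan's partner tip atom next to the anchor tip so that the
#' reference geometry reflects the planted contact (and distance-based
#' candidate searches can find it), at `bound_distance` when the plan's
#' occupancy is positive, else at `unbound_distance`.
#'
#' @param reference an `md_structure`.
#' @param plans list of [interaction_plan] objects.
#' @return the modified `md_structure`.
#' @export
plant_reference_contacts <- function(reference, plans) {
  xyz <- coords(reference)
  for (p in plans) {
    ia <- .resolve_plan_atom(reference, p$res_a, p$atom_a, "anchor")
    ib <- .resolve_plan_atom(reference, p$res_b, p$atom_b, "partner")
    ca_a <- which(reference$resno == reference$resno[ia] &
                    reference$elety == "CA")[1]
    u <- xyz[ia, ] - xyz[ca_a, ]
    nu <- sqrt(sum(u^2))
    u <- if (nu > 1e-9) u / nu else c(1, 0, 0)
    d <- if (p$occupancy > 0) p$bound_distance else p$unbound_distance
    xyz[ib, ] <- xyz[ia, ] + u * d
  }
  reference$x <- xyz[, 1]; reference$y <- xyz[, 2]; reference$z <- xyz[, 3]
  reference
}

.random_rotation <- function(max_deg) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ## scale a unit draw rather than runif(1, 0, 0): the draw is consumed even
  ## when max_deg = 0, keeping paired runs with the same seed in lockstep
  ang <- stats::runif(1) * max_deg * pi / 180
  .quat_to_rot(c(cos(ang / 2), sin(ang / 2) * ax))
}

#' Generate a trajectory with planted fluctuations and contacts
#'
#' Each frame is the reference plus independent per-atom Gaussian
#' displacements with that residue's sigma; planted interactions then
#' override the pair distance (two-state Bernoulli draw with the plan's
#' occupancy, moving only the partner atom along the pair axis); finally a
#' random rigid-body rotation/translation of the whole frame is applied so
#' that downstream superposition has real work to do. Deterministic given
#' `spec$seed`.
#'
#' @param reference an `md_structure` (see [make_reference_structure]).
#' @param spec a [fluctuation_spec]; `spec$n_residues` must match.
#' @param plans list of [interaction_plan] objects.
#' @param n_frames number of frames to generate.
#' @param frame_interval frame spacing (ps).
#' @param temperature temperature label (K, metadata only).
#' @return an `md_trajectory`; the planted per-frame bound states are kept
#'   in attribute `ground_truth` (list with `seed` and logical matrix
#'   `bound_states`, frames x plans).
#' @export
make_trajectory <- function(reference, spec, plans = list(), n_frames,
                            frame_interval = 400, temperature = 358) {
  stopifnot(inherits(reference, "md_structure"),
            inherits(spec, "fluctuation_spec"))
  if (spec$n_residues != n_residues(reference))
    stop("spec is for ", spec$n_residues, " residues but reference has ",
         n_residues(reference))
  if (inherits(plans, "interaction_plan")) plans <- list(plans)
  ia <- ib <- integer(length(plans))
  for (k in seq_along(plans)) {
    ia[k] <- .resolve_plan_atom(reference, plans[[k]]$res_a,
                                plans[[k]]$atom_a, "anchor")
    ib[k] <- .resolve_plan_atom(reference, plans[[k]]$res_b,
                                plans[[k]]$atom_b, "partner")
  }
  ref <- coords(reference)
  natoms <- nrow(ref)
  res_key <- paste(reference$chain, reference$resno)
  sigma_atom <- spec$sigma[match(res_key, unique(res_key))]
  rigid <- spec$rigid_max_rot_deg > 0 || spec$rigid_max_trans > 0
  arr <- array(NA_real_, dim = c(natoms, 3, n_frames))
  bound <- matrix(NA, n_frames, length(plans))
  set.seed(spec$seed)
  for (f in seq_len(n_frames)) {
    C <- ref + matrix(stats::rnorm(natoms * 3), natoms, 3) * sigma_atom
    for (k in seq_along(plans)) {
      p <- plans[[k]]
      u <- C[ib[k], ] - C[ia[k], ]
      nu <- sqrt(sum(u^2))
      u <- if (nu > 1e-9) u / nu else c(1, 0, 0)
      bound[f, k] <- stats::runif(1) < p$occupancy
      d <- (if (bound[f, k]) p$bound_distance else p$unbound_distance) +
        stats::rnorm(1, 0, p$jitter_sigma)
      C[ib[k], ] <- C[ia[k], ] + u * max(d, 0.5)
    }
    ## rigid-noise draws are consumed even when disabled so that runs with
    ## the same seed differ only by the applied rigid motion (paired tests)
    R <- .random_rotation(spec$rigid_max_rot_deg)
    tv <- (2 * stats::runif(3) - 1) * spec$rigid_max_trans
    if (rigid) C <- sweep(C %*% t(R), 2, tv, `+`)
    arr[, , f] <- C
  }
  traj <- md_trajectory(reference, arr, frame_interval = frame_interval,
                        temperature = temperature)
  attr(traj, "ground_truth") <- list(seed = spec$seed, bound_states = bound)
  traj
}

#' Generate a homologous sequence set with ground-truth correspondence
#'
#' Variants of a base sequence by independent per-site substitution and
#' occasional single-residue indels. The returned correspondence gives, for
#' each variant, the variant position of every base residue (NA where
#' deleted) — the ground truth for alignment-mapping tests.
#'
#' @param base_sequence 1-letter base sequence (non-empty).
#' @param n_variants number of variants.
#' @param substitution_rate per-site substitution probability in `[0, 1)`.
#' @param indel_rate per-site probability of a single-residue indel (split
#'   evenly between deletion and insertion) in `[0, 1)`.
#' @param seed RNG seed.
#' @param ids variant ids (default `v1`, `v2`, ...).
#' @param forced_residues optional named list (per variant id) of named
#'   character vectors `c("12" = "M", ...)` forcing the residue at a *base*
#'   position (applied after mutation, via the correspondence).
#' @return list with `sequences` (named character vector) and
#'   `correspondence` (named list of integer vectors, length = base length).
#' @export
make_homolog_set <- function(base_sequence, n_variants = 2,
                             substitution_rate = 0.1, indel_rate = 0.01,
                             seed = 1, ids = NULL, forced_residues = NULL) {
  if (!nzchar(base_sequence)) stop("base sequence is empty")
  if (substitution_rate < 0 || substitution_rate >= 1 ||
      indel_rate < 0 || indel_rate >= 1)
    stop("rates must be in [0, 1)")
  if (is.null(ids)) ids <- paste0("v", seq_len(n_variants))
  alphabet <- bio3d::aa321(names(.TIP_ATOM))
  base <- strsplit(toupper(base_sequence), "")[[1]]
  set.seed(seed)
  seqs <- character(n_variants); names(seqs) <- ids
  corr <- vector("list", n_variants); names(corr) <- ids
  for (v in seq_len(n_variants)) {
    out <- character(0)
    map <- rep(NA_integer_, length(base))
    for (i in seq_along(base)) {
      if (stats::runif(1) < indel_rate / 2) {
        ## deletion: base residue i absent from this variant
      } else {
        ch <- base[i]
        if (stats::runif(1) < substitution_rate)
          ch <- sample(setdiff(alphabet, ch), 1)
        out <- c(out, ch)
        map[i] <- length(out)
      }
      if (stats::runif(1) < indel_rate / 2)
        out <- c(out, sample(alphabet, 1))
    }
    forced <- forced_residues[[ids[v]]]
    if (!is.null(forced)) {
      pos <- as.integer(names(forced))
      for (j in seq_along(pos)) {
        vp <- map[pos[j]]
        if (!is.na(vp)) out[vp] <- forced[[j]]
      }
    }
    seqs[v] <- paste(out, collapse = "")
    corr[[v]] <- map
  }
  list(sequences = seqs, correspondence = corr)
}
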