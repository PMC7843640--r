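## Config-driven orchestration: load inputs, check structure/sequence
## consistency, align and map residues, per-protein RMSD/RMSF, RMSF-difference
## regions, interaction occupancy comparison, tidy CSV outputs. Also the
## synthetic fixture generator that stands in for real MD trajectories.

#' Build a run configuration
#'
#' @param proteins list of per-protein entries, each a list with `id`,
#'   `role` (`"mesophile"` or `"thermophile"`), `structure` (PDB path),
#'   `trajectory` (multi-model PDB path) and `sequence` (FASTA path).
#' @param frame_interval frame spacing of the trajectories (ps).
#' @param output_dir where [run_pipeline] writes its CSVs.
#' @param atom_selection atom names for RMSD/RMSF (default CA).
#' @param burn_in_frames initial frames discarded from each trajectory.
#' @param search_cutoff candidate search radius (A).
#' @param sb_cutoff,hb_cutoff contact cutoffs (A).
#' @param presence_threshold occupancy needed to call an interaction formed.
#' @param min_region_length,region_gap_tolerance region-calling parameters.
#' @param temperature trajectory temperature label (K, metadata only).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(proteins, frame_interval = 400, output_dir = ".",
                       atom_selection = "CA", burn_in_frames = 0,
                       search_cutoff = 6.0, sb_cutoff = 4.0,
                       hb_cutoff = 3.5, presence_threshold = 0.1,
                       min_region_length = 3, region_gap_tolerance = 2,
                       temperature = NA_real_) {
  cfg <- structure(list(
    proteins = proteins, frame_interval = frame_interval,
    output_dir = output_dir, atom_selection = atom_selection,
    burn_in_frames = burn_in_frames, search_cutoff = search_cutoff,
    sb_cutoff = sb_cutoff, hb_cutoff = hb_cutoff,
    presence_threshold = presence_threshold,
    min_region_length = min_region_length,
    region_gap_tolerance = region_gap_tolerance,
    temperature = temperature), class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Relative paths inside the file are resolved against its directory.
#'
#' @param path YAML file with the fields of [run_config].
#' @return validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$proteins)) stop("config validation: missing 'proteins'")
  base <- dirname(normalizePath(path))
  y$proteins <- lapply(y$proteins, function(p) {
    for (f in c("structure", "trajectory", "sequence"))
      if (!is.null(p[[f]]) && !grepl("^/", p[[f]]))
        p[[f]] <- file.path(base, p[[f]])
    p
  })
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}

#' Validate a run configuration
#'
#' Checks the schema before any computation: at least two proteins with
#' unique ids, exactly one mesophile and at least one thermophile, and all
#' referenced files present.
#'
#' @param cfg a `run_config`.
#' @return `cfg`, invisibly; errors on violation.
#' @export
validate_run_config <- function(cfg) {
  p <- cfg$proteins
  if (length(p) < 2)
    stop("config validation: at least 2 proteins are required")
  ids <- vapply(p, function(x) x$id %||% stop(
    "config validation: protein entry without id"), "")
  if (anyDuplicated(ids)) stop("config validation: duplicate protein ids")
  roles <- vapply(p, function(x) x$role %||% "", "")
  if (!all(roles %in% c("mesophile", "thermophile")))
    stop("config validation: role must be 'mesophile' or 'thermophile'")
  if (sum(roles == "mesophile") != 1)
    stop("config validation: exactly one mesophile is required")
  if (sum(roles == "thermophile") < 1)
    stop("config validation: at least one thermophile is required")
  for (x in p) for (f in c("structure", "trajectory", "sequence")) {
    if (is.null(x[[f]]))
      stop("config validation: protein '", x$id, "' lacks ", f)
    if (!file.exists(x[[f]]))
      stop("config validation: missing file for '", x$id, "': ", x[[f]])
  }
  if (cfg$frame_interval <= 0)
    stop("config validation: frame_interval must be > 0")
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("[mdfluct] stage '%s' done in %.1f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full comparative analysis
#'
#' Stages, in order: load inputs; structure/sequence consistency check;
#' progressive alignment and residue map; per-protein RMSD and RMSF;
#' RMSF-difference profile and region detection; interaction candidate
#' search, distance series and cross-homolog comparison; CSV/FASTA outputs
#' plus a YAML report. A failure in any stage aborts with the stage name.
#'
#' @param config a `run_config` (or path to a YAML config).
#' @param output_dir overrides `config$output_dir`.
#' @return object of class `run_report`: list with `rmsd`, `rmsf`,
#'   `alignment`, `map`, `delta`, `regions`, `region_spans`,
#'   `interactions`, `warnings`, `config`, `files`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  out_dir <- output_dir %||% config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(config$proteins, `[[`, "", "id")
  roles <- vapply(config$proteins, `[[`, "", "role")
  collected_warnings <- character(0)
  withCallingHandlers({

  loaded <- .stage("load", {
    lapply(config$proteins, function(p) {
      list(structure = read_pdb(p$structure, name = p$id),
           trajectory = read_pdb(p$trajectory,
                                 frame_interval = config$frame_interval,
                                 temperature = config$temperature,
                                 name = p$id),
           sequence = read_fasta(p$sequence)[[1]])
    })
  })
  names(loaded) <- ids
  .stage("consistency_check", {
    for (id in ids) {
      s <- structure_sequence(loaded[[id]]$structure)
      if (s != loaded[[id]]$sequence)
        stop("structure residues of '", id,
             "' do not match its FASTA sequence")
      if (!inherits(loaded[[id]]$trajectory, "md_trajectory"))
        stop("trajectory file of '", id, "' has a single model")
    }
  })
  alignment <- .stage("alignment", {
    seqs <- vapply(loaded, `[[`, "", "sequence")
    names(seqs) <- ids
    align_many(seqs)
  })
  amap <- build_map(alignment)
  analysis <- .stage("rmsd_rmsf", {
    lapply(ids, function(id) list(
      rmsd = trajectory_rmsd(loaded[[id]]$trajectory,
                             atom_selection = config$atom_selection,
                             burn_in_frames = config$burn_in_frames),
      rmsf = rmsf(loaded[[id]]$trajectory,
                  atom_selection = config$atom_selection,
                  burn_in_frames = config$burn_in_frames)))
  })
  names(analysis) <- ids
  regions_out <- .stage("region_detection", {
    dp <- delta_profile(lapply(analysis, `[[`, "rmsf"), amap,
                        mesophile_id = ids[roles == "mesophile"],
                        thermophile_ids = ids[roles == "thermophile"])
    regs <- detect_regions(dp, min_length = config$min_region_length,
                           gap_tolerance = config$region_gap_tolerance)
    list(delta = dp, regions = regs,
         spans = map_regions_to_proteins(regs, amap))
  })
  interactions_out <- .stage("interactions", {
    series <- list()
    for (id in ids) {
      topo <- loaded[[id]]$structure
      cand <- c(candidate_pairs(topo, "salt_bridge", config$search_cutoff),
                candidate_pairs(topo, "hydrogen_bond", config$search_cutoff))
      series[[id]] <- lapply(cand, function(p) {
        cutoff <- if (p$kind == "salt_bridge") config$sb_cutoff
        else config$hb_cutoff
        distance_series(loaded[[id]]$trajectory, p, cutoff = cutoff)
      })
    }
    table <- compare_across_homologs(
      series, amap,
      structures = lapply(loaded, `[[`, "structure"),
      presence_threshold = config$presence_threshold)
    list(series = series, table = table)
  })
  files <- .stage("write_outputs", {
    w <- function(df, f) {
      path <- file.path(out_dir, f)
      utils::write.csv(df, path, row.names = FALSE)
      path
    }
    rmsd_df <- do.call(rbind, lapply(ids, function(id)
      cbind(protein = id, as.data.frame(analysis[[id]]$rmsd))))
    rmsf_df <- do.call(rbind, lapply(ids, function(id)
      cbind(protein = id, as.data.frame(analysis[[id]]$rmsf))))
    dist_df <- do.call(rbind, lapply(ids, function(id)
      do.call(rbind, lapply(interactions_out$series[[id]], function(s)
        data.frame(protein = id,
                   pair = sprintf("%s%d-%s%d:%s", s$pair$res_a$resid,
                                  s$pair$res_a$resno, s$pair$res_b$resid,
                                  s$pair$res_b$resno, s$pair$kind),
                   frame_time_ps = s$frame_times,
                   distance_A = s$distances)))))
    delta_df <- as.data.frame(regions_out$delta)
    delta_df$mean_delta <- attr(regions_out$delta, "mean_delta")
    paths <- c(
      rmsd = w(rmsd_df, "rmsd.csv"),
      rmsf = w(rmsf_df, "rmsf.csv"),
      map = w(as.data.frame(amap), "alignment_map.csv"),
      delta = w(delta_df, "delta_profile.csv"),
      regions = w(as.data.frame(regions_out$regions), "regions.csv"),
      region_spans = w(regions_out$spans, "region_spans.csv"),
      interactions = w(interactions_out$table, "interactions.csv"),
      distances = w(dist_df, "distances.csv"))
    af <- file.path(out_dir, "alignment.fasta")
    write_fasta(alignment$rows, af)
    paths <- c(paths, alignment = af)
    ## 1-based inclusive intervals over the common numbering
    iv <- file.path(out_dir, "regions.intervals.txt")
    writeLines(c("# common_numbering\tstart\tend\tlabel",
                 sprintf("common\t%d\t%d\t%s",
                         regions_out$regions$start_column,
                         regions_out$regions$end_column,
                         regions_out$regions$label)), iv)
    paths <- c(paths, intervals = iv)
    rep_path <- file.path(out_dir, "report.yaml")
    yaml::write_yaml(list(
      package = "mdfluct",
      version = as.character(utils::packageVersion("mdfluct")),
      timestamp = format(Sys.time(), tz = "UTC"),
      config = unclass(config),
      atom_selection = config$atom_selection,
      mean_delta = attr(regions_out$delta, "mean_delta"),
      n_regions = nrow(regions_out$regions),
      warnings = as.list(collected_warnings)), rep_path)
    c(paths, report = rep_path)
  })

  report <- structure(list(
    rmsd = lapply(analysis, `[[`, "rmsd"),
    rmsf = lapply(analysis, `[[`, "rmsf"),
    alignment = alignment, map = amap,
    delta = regions_out$delta, regions = regions_out$regions,
    region_spans = regions_out$spans,
    interactions = interactions_out$table,
    warnings = collected_warnings,
    config = config, files = files), class = "run_report")
  report
  }, warning = function(w) {
    collected_warnings <<- c(collected_warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
}

#' @export
print.run_report <- function(x, ...) {
  ids <- names(x$rmsd)
  cat("mdfluct run report\n")
  for (id in ids)
    cat(sprintf("  %-12s mean RMSD %.3f A, mean RMSF %.3f A\n", id,
                mean(x$rmsd[[id]]$rmsd_A), mean(x$rmsf[[id]]$rmsf_A)))
  cat(sprintf("  regions above mean delta: %d (threshold %.3f A)\n",
              nrow(x$regions), attr(x$delta, "mean_delta")))
  formed <- x$interactions$classification %in% c("SB", "HB")
  cat(sprintf("  interaction rows: %d (%d formed)\n",
              nrow(x$interactions), sum(formed)))
  invisible(x)
}

#' Default synthetic-study generator configuration
#'
#' Emulates the study conditions of a three-homolog thermostability
#' comparison: one mesophile whose trajectory carries four planted
#' high-fluctuation regions, two thermophiles with flat profiles, planted
#' salt bridges / hydrogen bonds with distinct occupancies (including a
#' basic residue replaced by methionine in the mesophile, which therefore
#' cannot form the bridge), 1,000 frames per trajectory at 400 ps intervals
#' (400 ns), and global rigid-body frame noise.
#'
#' @param seed master seed; all per-protein seeds derive from it.
#' @param n_residues base sequence length.
#' @param n_frames frames per trajectory.
#' @return list of class `generator_config`.
#' @export
default_generator_config <- function(seed = 42, n_residues = 130,
                                     n_frames = frames_for_duration(400,
                                                                    400)) {
  structure(list(
    seed = seed, n_residues = n_residues, n_frames = n_frames,
    frame_interval = 400, temperature = 358,
    base_sigma = 0.4, region_sigma = 0.9,
    regions = data.frame(start = c(15, 45, 72, 105),
                         end = c(30, 55, 85, 118)),
    substitution_rate = c(thermo2 = 0.12, meso = 0.2),
    indel_rate = c(thermo2 = 0.005, meso = 0.015),
    rigid_max_rot_deg = 5, rigid_max_trans = 1.0,
    ## planted sites in base numbering (mirroring a Lys-Asp bridge, an
    ## adjacent Arg-Glu bridge, a Thr-Thr hydrogen bond and an Arg-Glu
    ## bridge between a loop and a helix)
    sites = c("12" = "K", "25" = "R", "26" = "E", "36" = "T", "39" = "T",
              "81" = "R", "82" = "D", "90" = "E"),
    meso_forced = c("12" = "M"),
    ## occupancies per protein per planted pair (0 = not planted)
    plans = list(
      list(a = 12, b = 82, kind = "salt_bridge",
           occupancy = c(thermo1 = 0.85, thermo2 = 0.8, meso = 0)),
      list(a = 25, b = 26, kind = "salt_bridge",
           occupancy = c(thermo1 = 0.9, thermo2 = 0.4, meso = 0.15)),
      list(a = 36, b = 39, kind = "hydrogen_bond",
           occupancy = c(thermo1 = 0.9, thermo2 = 0.3, meso = 0.05)),
      list(a = 81, b = 90, kind = "salt_bridge",
           occupancy = c(thermo1 = 0.85, thermo2 = 0, meso = 0.6)))),
    class = "generator_config")
}

#' Generate a synthetic three-homolog fixture set on disk
#'
#' Writes, per protein, a reference PDB, a multi-model trajectory PDB and a
#' FASTA record, plus a combined `sequences.fasta`, a ground-truth YAML
#' sidecar (planted sigmas, regions, occupancies, residue correspondences)
#' and a ready-to-run `analyze_config.yaml`. Deterministic for a given
#' config seed.
#'
#' @param config a [default_generator_config] style list.
#' @param out_dir output directory (created if needed).
#' @return the path of the written analysis config, invisibly.
#' @export
generate_fixtures <- function(config = default_generator_config(),
                              out_dir) {
  if (missing(out_dir)) stop("out_dir is required")
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output dir: ", out_dir)
  cfg <- config
  set.seed(cfg$seed)
  base <- .sample_sequence(cfg$n_residues)
  bb <- strsplit(base, "")[[1]]
  bb[as.integer(names(cfg$sites))] <- cfg$sites
  base <- paste(bb, collapse = "")
  ## variants with planted sites preserved (mesophile gets the Met swap)
  keep_sites <- as.character(names(cfg$sites))
  forced <- list(
    thermo2 = stats::setNames(cfg$sites, keep_sites),
    meso = stats::setNames(
      replace(cfg$sites, match(names(cfg$meso_forced), names(cfg$sites)),
              cfg$meso_forced), keep_sites))
  hs_t2 <- make_homolog_set(
    base, n_variants = 1,
    substitution_rate = cfg$substitution_rate[["thermo2"]],
    indel_rate = cfg$indel_rate[["thermo2"]],
    seed = cfg$seed + 1, ids = "thermo2",
    forced_residues = forced["thermo2"])
  hs_me <- make_homolog_set(
    base, n_variants = 1,
    substitution_rate = cfg$substitution_rate[["meso"]],
    indel_rate = cfg$indel_rate[["meso"]],
    seed = cfg$seed + 2, ids = "meso",
    forced_residues = forced["meso"])
  seqs <- c(thermo1 = base, hs_t2$sequences, hs_me$sequences)
  corr <- c(list(thermo1 = seq_len(nchar(base))),
            hs_t2$correspondence, hs_me$correspondence)
  roles <- c(thermo1 = "thermophile", thermo2 = "thermophile",
             meso = "mesophile")
  analyze_proteins <- list()
  truth <- list(seed = cfg$seed, base_sequence = base,
                regions_base_numbering = cfg$regions,
                proteins = list())
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    ref <- make_reference_structure(sequence = seqs[[id]], name = id)
    map <- corr[[id]]
    plans <- list()
    plan_occ <- numeric(0)
    for (p in cfg$plans) {
      occ <- p$occupancy[[id]]
      a <- map[p$a]; b <- map[p$b]
      if (occ > 0 && !is.na(a) && !is.na(b)) {
        bound <- if (p$kind == "salt_bridge") 3.0 else 2.8
        plans[[length(plans) + 1]] <- interaction_plan(
          a, b, bound_distance = bound, unbound_distance = 8.0,
          occupancy = occ, jitter_sigma = 0.15)
        plan_occ <- c(plan_occ, stats::setNames(
          occ, sprintf("%d-%d:%s", p$a, p$b, p$kind)))
      }
    }
    ref <- plant_reference_contacts(ref, plans)
    if (roles[[id]] == "mesophile") {
      reg <- cfg$regions
      reg$start <- map[reg$start]; reg$end <- map[reg$end]
      ## a span could in principle lose its endpoints to a deletion; fall
      ## back to the nearest mapped base position
      for (r in seq_len(nrow(reg))) {
        if (is.na(reg$start[r]))
          reg$start[r] <- min(map[cfg$regions$start[r]:cfg$regions$end[r]],
                              na.rm = TRUE)
        if (is.na(reg$end[r]))
          reg$end[r] <- max(map[cfg$regions$start[r]:cfg$regions$end[r]],
                            na.rm = TRUE)
      }
      reg$sigma <- cfg$region_sigma
    } else reg <- NULL
    spec <- fluctuation_spec(
      nchar(seqs[[id]]), base_sigma = cfg$base_sigma, regions = reg,
      rigid_max_rot_deg = cfg$rigid_max_rot_deg,
      rigid_max_trans = cfg$rigid_max_trans,
      seed = cfg$seed + 10 + i)
    traj <- make_trajectory(ref, spec, plans, n_frames = cfg$n_frames,
                            frame_interval = cfg$frame_interval,
                            temperature = cfg$temperature)
    write_pdb(ref, file.path(out_dir, paste0(id, ".pdb")))
    write_pdb(traj, file.path(out_dir, paste0(id, "_traj.pdb")))
    write_fasta(seqs[id], file.path(out_dir, paste0(id, ".fasta")))
    analyze_proteins[[length(analyze_proteins) + 1]] <- list(
      id = id, role = roles[[id]],
      structure = paste0(id, ".pdb"),
      trajectory = paste0(id, "_traj.pdb"),
      sequence = paste0(id, ".fasta"))
    truth$proteins[[id]] <- list(
      role = roles[[id]], sigma = spec$sigma, seed = spec$seed,
      regions = if (is.null(reg)) NULL else reg,
      planted_occupancy = as.list(plan_occ),
      correspondence_to_base = as.integer(corr[[id]]))
  }
  write_fasta(seqs, file.path(out_dir, "sequences.fasta"))
  yaml::write_yaml(truth, file.path(out_dir, "ground_truth.yaml"))
  cfg_path <- file.path(out_dir, "analyze_config.yaml")
  yaml::write_yaml(list(
    proteins = analyze_proteins,
    frame_interval = cfg$frame_interval,
    temperature = cfg$temperature,
    output_dir = "results"), cfg_path)
  invisible(cfg_path)
}
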