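## The comparative statistic at the centre of the package: per-common-column
## RMSF difference between a mesophilic protein and the mean of its
## thermophilic homologs, thresholded at the average difference and merged
## into contiguous high-fluctuation regions.

#' Cross-homolog RMSF difference profile
#'
#' For every common column at which the mesophile and all thermophiles are
#' aligned without a gap, the difference
#' `RMSF(mesophile) - mean(RMSF(thermophiles))` is computed; columns with a
#' gap in any contributing protein are dropped. The average difference over
#' the retained columns is stored alongside (it is the region-calling
#' threshold).
#'
#' @param rmsf_profiles named list of [rmsf] results, one per protein id.
#' @param alignment_map an [build_map] result covering all ids.
#' @param mesophile_id id of the mesophilic protein.
#' @param thermophile_ids ids of the thermophilic proteins (averaged).
#' @return data.frame of class `delta_profile` with columns `common_column`
#'   and `delta` (Angstrom), and attributes `mean_delta`, `mesophile_id`,
#'   `thermophile_ids`.
#' @export
delta_profile <- function(rmsf_profiles, alignment_map, mesophile_id,
                          thermophile_ids) {
  ids <- c(mesophile_id, thermophile_ids)
  for (id in ids) {
    if (is.null(rmsf_profiles[[id]]))
      stop("no RMSF profile for protein '", id, "'")
    if (!id %in% alignment_map$ids)
      stop("protein '", id, "' is not in the alignment map")
  }
  ## per-protein RMSF indexed by common column
  by_col <- sapply(ids, function(id) {
    prof <- rmsf_profiles[[id]]
    v <- rep(NA_real_, alignment_map$n_columns)
    cols <- alignment_map$res2col[[id]][prof$residue_number]
    v[cols] <- prof$rmsf_A
    v
  })
  keep <- rowSums(is.na(by_col)) == 0
  delta <- by_col[, 1] - rowMeans(by_col[, -1, drop = FALSE])
  out <- data.frame(common_column = which(keep), delta = delta[keep])
  attr(out, "mean_delta") <- mean(out$delta)
  attr(out, "mesophile_id") <- mesophile_id
  attr(out, "thermophile_ids") <- thermophile_ids
  class(out) <- c("delta_profile", "data.frame")
  out
}

#' @export
print.delta_profile <- function(x, ...) {
  cat(sprintf(
    "delta_profile: %s - mean(%s), %d columns, mean delta %.3f A\n",
    attr(x, "mesophile_id"), paste(attr(x, "thermophile_ids"),
                                   collapse = ","),
    nrow(x), attr(x, "mean_delta")))
  invisible(x)
}

#' @method plot delta_profile
#' @export
plot.delta_profile <- function(x, regions = NULL, ...) {
  graphics::plot(x$common_column, x$delta, type = "h",
                 xlab = "common residue number", ylab = "delta RMSF (A)",
                 ...)
  graphics::abline(h = attr(x, "mean_delta"), lty = 2)
  if (!is.null(regions) && nrow(regions))
    graphics::rect(regions$start_column, graphics::par("usr")[3],
                   regions$end_column, graphics::par("usr")[4],
                   col = grDevices::adjustcolor("orange", 0.25), border = NA)
  invisible(x)
}

#' Call contiguous high-fluctuation regions
#'
#' Columns whose delta is strictly greater than the profile's average delta
#' are flagged; flagged columns are merged into runs, tolerating up to
#' `gap_tolerance` consecutive unflagged columns inside a run; runs spanning
#' fewer than `min_length` columns are discarded; survivors are labelled
#' I, II, ... in sequence order.
#'
#' @param dp a [delta_profile].
#' @param min_length minimum region span in columns (default 3).
#' @param gap_tolerance unflagged columns tolerated inside a run (default 2).
#' @return data.frame of class `fluct_regions` with columns `label`,
#'   `start_column`, `end_column`, `length`, `mean_delta_in_region`;
#'   zero rows when nothing exceeds the threshold.
#' @export
detect_regions <- function(dp, min_length = 3, gap_tolerance = 2) {
  stopifnot(inherits(dp, "delta_profile"))
  empty <- data.frame(label = character(0), start_column = integer(0),
                      end_column = integer(0), length = integer(0),
                      mean_delta_in_region = numeric(0))
  class(empty) <- c("fluct_regions", "data.frame")
  if (!nrow(dp)) return(empty)
  thr <- attr(dp, "mean_delta")
  flagged <- dp$common_column[dp$delta > thr]
  if (!length(flagged)) return(empty)
  ## merge flagged columns whose separation (in common numbering) leaves at
  ## most gap_tolerance unflagged columns between them
  breaks <- which(diff(flagged) > gap_tolerance + 1)
  starts <- flagged[c(1, breaks + 1)]
  ends <- flagged[c(breaks, length(flagged))]
  len <- ends - starts + 1L
  keep <- len >= min_length
  out <- data.frame(label = as.character(utils::as.roman(seq_len(sum(keep)))),
                    start_column = starts[keep], end_column = ends[keep],
                    length = len[keep],
                    mean_delta_in_region = NA_real_)
  for (r in seq_len(nrow(out)))
    out$mean_delta_in_region[r] <- mean(
      dp$delta[dp$common_column >= out$start_column[r] &
                 dp$common_column <= out$end_column[r]])
  attr(out, "threshold") <- thr
  class(out) <- c("fluct_regions", "data.frame")
  out
}

#' Translate regions from common numbering to each protein's own numbering
#'
#' @param regions a [detect_regions] result (common numbering).
#' @param alignment_map an [build_map] result.
#' @return data.frame with one row per region x protein: `label`, `protein`,
#'   `start_residue`, `end_residue`, `n_residues`, `empty` (TRUE when the
#'   region lies entirely in that protein's gap columns).
#' @export
map_regions_to_proteins <- function(regions, alignment_map) {
  rows <- list()
  for (r in seq_len(nrow(regions))) {
    cols <- regions$start_column[r]:regions$end_column[r]
    for (id in alignment_map$ids) {
      res <- alignment_map$col2res[[id]][cols]
      res <- res[!is.na(res)]
      rows[[length(rows) + 1]] <- data.frame(
        label = regions$label[r], protein = id,
        start_residue = if (length(res)) min(res) else NA_integer_,
        end_residue = if (length(res)) max(res) else NA_integer_,
        n_residues = length(res), empty = !length(res))
    }
  }
  if (!length(rows))
    return(data.frame(label = character(0), protein = character(0),
                      start_residue = integer(0), end_residue = integer(0),
                      n_residues = integer(0), empty = logical(0)))
  do.call(rbind, rows)
}
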