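## Global protein sequence alignment (Needleman-Wunsch with affine gaps,
## Gotoh three-state recurrence), progressive multiple alignment against a
## growing profile, percent identity, and the residue-to-common-column map
## that lets per-residue quantities be compared across homologs.

.blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

## Gotoh DP. Scores are maximized; a gap of length L costs
## gap_open + L * gap_extend. `b_cols` may be a character vector (sequence)
## or a character matrix (profile rows x columns) scored by the mean
## substitution score over non-gap characters in the column.
.gotoh <- function(a_chars, b_cols, sub, gap_open, gap_extend) {
  n <- length(a_chars)
  is_prof <- is.matrix(b_cols)
  m <- if (is_prof) ncol(b_cols) else length(b_cols)
  col_score <- function(j, ch) {
    if (!is_prof) return(sub[ch, b_cols[j]])
    cc <- b_cols[, j]
    cc <- cc[cc != "-"]
    if (!length(cc)) return(0)
    mean(sub[ch, cc])
  }
  NEG <- -1e9
  ## state matrices: M diag, GA gap in A's row (B column unmatched),
  ## GB gap in B's row (A residue unmatched)
  M <- GA <- GB <- matrix(NEG, n + 1, m + 1)
  pM <- pGA <- pGB <- matrix(0L, n + 1, m + 1)  # 1=M, 2=GA, 3=GB
  M[1, 1] <- 0
  for (j in seq_len(m) + 1) {
    GA[1, j] <- -(gap_open + (j - 1) * gap_extend)
    pGA[1, j] <- 2L
  }
  GA[1, 2] <- -(gap_open + gap_extend); pGA[1, 2] <- 1L
  for (i in seq_len(n) + 1) {
    GB[i, 1] <- -(gap_open + (i - 1) * gap_extend)
    pGB[i, 1] <- 3L
  }
  GB[2, 1] <- -(gap_open + gap_extend); pGB[2, 1] <- 1L
  pick <- function(vals) {
    ## deterministic tie rule: prefer M, then GA, then GB
    k <- which(vals == max(vals))[1]
    c(vals[k], k)
  }
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- col_score(j - 1, a_chars[i - 1])
      r <- pick(c(M[i - 1, j - 1], GA[i - 1, j - 1], GB[i - 1, j - 1]))
      M[i, j] <- r[1] + s; pM[i, j] <- r[2]
      r <- pick(c(M[i, j - 1] - gap_open - gap_extend,
                  GA[i, j - 1] - gap_extend,
                  GB[i, j - 1] - gap_open - gap_extend))
      GA[i, j] <- r[1]; pGA[i, j] <- r[2]
      r <- pick(c(M[i - 1, j] - gap_open - gap_extend,
                  GA[i - 1, j] - gap_open - gap_extend,
                  GB[i - 1, j] - gap_extend))
      GB[i, j] <- r[1]; pGB[i, j] <- r[2]
    }
  }
  finals <- c(M[n + 1, m + 1], GA[n + 1, m + 1], GB[n + 1, m + 1])
  r <- pick(finals)
  score <- r[1]; state <- r[2]
  ## traceback: ops as 'D' (a_i~b_j), 'A' (gap in A), 'B' (gap in B)
  i <- n + 1; j <- m + 1; ops <- character(0)
  while (i > 1 || j > 1) {
    if (state == 1L) {
      ops <- c("D", ops); prev <- pM[i, j]; i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      ops <- c("A", ops); prev <- pGA[i, j]; j <- j - 1
    } else {
      ops <- c("B", ops); prev <- pGB[i, j]; i <- i - 1
    }
    state <- prev
  }
  list(score = score, ops = ops)
}

.new_alignment <- function(rows, score) {
  stopifnot(length(unique(nchar(rows))) == 1)
  structure(list(ids = names(rows), rows = rows, score = score),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("protein_alignment: %d sequences, %d columns, score %.1f\n",
              length(x$rows), nchar(x$rows[1]), x$score))
  for (id in x$ids) {
    s <- x$rows[[id]]
    cat(sprintf("  %-12s %s%s\n", id, substr(s, 1, 60),
                if (nchar(s) > 60) "..." else ""))
  }
  invisible(x)
}

#' Global pairwise protein alignment (affine gaps)
#'
#' Needleman-Wunsch dynamic programming with a substitution matrix and
#' affine gap penalties (a gap of length L costs
#' `gap_open + L * gap_extend`). Ties are broken deterministically: residue
#' pairing is preferred over a gap in the first sequence, which is preferred
#' over a gap in the second.
#'
#' @param seq_a,seq_b 1-letter sequences (non-empty).
#' @param ids labels for the two rows.
#' @param substitution substitution matrix (default BLOSUM62 from
#'   Biostrings).
#' @param gap_open,gap_extend gap penalties (positive; defaults 10 and 1).
#' @return object of class `protein_alignment`: `ids`, `rows` (equal-length
#'   gapped strings) and `score`.
#' @export
align_pair <- function(seq_a, seq_b, ids = c("a", "b"), substitution = NULL,
                       gap_open = 10, gap_extend = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  if (is.null(substitution)) substitution <- .blosum62()
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  g <- .gotoh(a, b, substitution, gap_open, gap_extend)
  ra <- rb <- character(length(g$ops))
  i <- j <- 0
  for (k in seq_along(g$ops)) {
    op <- g$ops[k]
    if (op == "D") { i <- i + 1; j <- j + 1; ra[k] <- a[i]; rb[k] <- b[j] }
    else if (op == "A") { j <- j + 1; ra[k] <- "-"; rb[k] <- b[j] }
    else { i <- i + 1; ra[k] <- a[i]; rb[k] <- "-" }
  }
  rows <- c(paste(ra, collapse = ""), paste(rb, collapse = ""))
  names(rows) <- ids
  .new_alignment(rows, g$score)
}

.align_seq_to_profile <- function(profile_rows, seq, id, substitution,
                                  gap_open, gap_extend) {
  prof <- do.call(rbind, strsplit(profile_rows, ""))
  rownames(prof) <- names(profile_rows)
  a <- strsplit(toupper(seq), "")[[1]]
  g <- .gotoh(a, prof, substitution, gap_open, gap_extend)
  new_prof <- matrix("-", nrow(prof) + 1, length(g$ops))
  i <- j <- 0
  for (k in seq_along(g$ops)) {
    op <- g$ops[k]
    if (op == "D") {
      i <- i + 1; j <- j + 1
      new_prof[seq_len(nrow(prof)), k] <- prof[, j]
      new_prof[nrow(prof) + 1, k] <- a[i]
    } else if (op == "A") {
      j <- j + 1
      new_prof[seq_len(nrow(prof)), k] <- prof[, j]
    } else {
      i <- i + 1
      new_prof[nrow(prof) + 1, k] <- a[i]
    }
  }
  rows <- apply(new_prof, 1, paste, collapse = "")
  names(rows) <- c(names(profile_rows), id)
  list(rows = rows, score = g$score)
}

#' Progressive multiple alignment
#'
#' The closest pair by pairwise percent identity is aligned first; remaining
#' sequences are then added one at a time (each time the sequence with the
#' highest identity to any already-aligned sequence) against the growing
#' profile, scored by the column-average substitution score. Deterministic:
#' ties are broken by lexicographic id.
#'
#' @param seqs named character vector of >= 2 sequences.
#' @inheritParams align_pair
#' @return a `protein_alignment` over all input sequences (score = sum of
#'   the progressive alignment step scores).
#' @export
align_many <- function(seqs, substitution = NULL, gap_open = 10,
                       gap_extend = 1) {
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  if (is.null(substitution)) substitution <- .blosum62()
  ids <- names(seqs)
  if (length(seqs) == 2)
    return(align_pair(seqs[[1]], seqs[[2]], ids = ids,
                      substitution = substitution, gap_open = gap_open,
                      gap_extend = gap_extend))
  ## pairwise identities
  pid <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) for (j in seq_along(ids)) if (i < j) {
    al <- align_pair(seqs[[i]], seqs[[j]], ids = ids[c(i, j)],
                     substitution = substitution, gap_open = gap_open,
                     gap_extend = gap_extend)
    pid[i, j] <- pid[j, i] <- percent_identity(al, ids[i], ids[j])
  }
  ## seed pair: maximum identity, ties by lexicographic id pair
  best <- -Inf; pair <- NULL
  for (i in order(ids)) for (j in order(ids)) if (ids[i] < ids[j]) {
    if (pid[i, j] > best) { best <- pid[i, j]; pair <- c(i, j) }
  }
  al <- align_pair(seqs[[pair[1]]], seqs[[pair[2]]], ids = ids[pair],
                   substitution = substitution, gap_open = gap_open,
                   gap_extend = gap_extend)
  rows <- al$rows
  total <- al$score
  remaining <- setdiff(ids, ids[pair])
  while (length(remaining)) {
    affinity <- vapply(remaining, function(id)
      max(pid[id, names(rows)]), numeric(1))
    nxt <- remaining[order(-affinity, remaining)][1]
    step <- .align_seq_to_profile(rows, seqs[[nxt]], nxt, substitution,
                                  gap_open, gap_extend)
    rows <- step$rows
    total <- total + step$score
    remaining <- setdiff(remaining, nxt)
  }
  rows <- rows[ids]  # restore input order
  .new_alignment(rows, total)
}

#' Percent identity between two aligned sequences
#'
#' Identical-residue columns divided by the aligned columns in which neither
#' sequence has a gap (gap columns excluded from the denominator), as a
#' percentage to 1 decimal.
#'
#' @param alignment a `protein_alignment`.
#' @param id_a,id_b row ids.
#' @return numeric percentage (e.g. `75.0`).
#' @export
percent_identity <- function(alignment, id_a, id_b) {
  stopifnot(inherits(alignment, "protein_alignment"))
  for (id in c(id_a, id_b))
    if (!id %in% alignment$ids) stop("unknown sequence id: ", id)
  a <- strsplit(alignment$rows[[id_a]], "")[[1]]
  b <- strsplit(alignment$rows[[id_b]], "")[[1]]
  keep <- a != "-" & b != "-"
  if (!sum(keep)) return(NaN)
  round(100 * mean(a[keep] == b[keep]), 1)
}

#' Residue-number to common-column map from an alignment
#'
#' Assigns every alignment column a common residue number (its 1-based
#' column index) and records, per protein, the mapping between its own
#' residue numbering and the common numbering, with gap columns flagged.
#'
#' @param alignment a `protein_alignment`.
#' @return object of class `alignment_map`: list with `ids`, `n_columns`,
#'   `res2col` (per id: integer vector, residue i -> column), `col2res`
#'   (per id: integer vector, column -> residue or NA at gaps).
#' @export
build_map <- function(alignment) {
  stopifnot(inherits(alignment, "protein_alignment"))
  res2col <- col2res <- list()
  for (id in alignment$ids) {
    chars <- strsplit(alignment$rows[[id]], "")[[1]]
    nongap <- which(chars != "-")
    res2col[[id]] <- nongap
    c2r <- rep(NA_integer_, length(chars))
    c2r[nongap] <- seq_along(nongap)
    col2res[[id]] <- c2r
  }
  structure(list(ids = alignment$ids,
                 n_columns = nchar(alignment$rows[[1]]),
                 res2col = res2col, col2res = col2res),
            class = "alignment_map")
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf("alignment_map: %d proteins over %d common columns\n",
              length(x$ids), x$n_columns))
  invisible(x)
}

#' @describeIn build_map long-format data.frame (protein, common_column,
#'   residue_number, is_gap_column) suitable for CSV export.
#' @param x an `alignment_map`.
#' @param ... unused.
#' @method as.data.frame alignment_map
#' @export
as.data.frame.alignment_map <- function(x, ...) {
  do.call(rbind, lapply(x$ids, function(id)
    data.frame(protein = id, common_column = seq_len(x$n_columns),
               residue_number = x$col2res[[id]],
               is_gap_column = is.na(x$col2res[[id]]))))
}
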