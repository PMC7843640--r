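# Independent oracles and small fixture builders used across the suite.

# Exhaustive global-alignment score: enumerate every alignment of two short
# sequences with affine gap accounting (gap of length L costs
# open + L * extend), independent of the DP implementation.
enumerate_align_score <- function(a, b, sub, open = 10, extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i <= length(A) && j <= length(B))
      rec(i + 1, j + 1, "D", sc + sub[A[i], B[j]])
    if (j <= length(B))
      rec(i, j + 1, "A", sc - extend - if (prev == "A") 0 else open)
    if (i <= length(A))
      rec(i + 1, j, "B", sc - extend - if (prev == "B") 0 else open)
  }
  rec(1, 1, "", 0)
  best
}

random_aa <- function(n) {
  paste(sample(strsplit("ACDEFHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Fixed-column PDB ATOM line.
pdb_atom_line <- function(eleno, elety, resid, chain, resno, x, y, z,
                          element = substr(elety, 1, 1)) {
  sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          eleno, elety, resid, chain, resno, x, y, z, element)
}

# Multi-model PDB text from a list of n x 3 coordinate matrices.
pdb_text <- function(models, resid = "ALA", elety = "CA", chain = "A") {
  out <- character(0)
  for (m in seq_along(models)) {
    xyz <- models[[m]]
    n <- nrow(xyz)
    out <- c(out, sprintf("MODEL     %4d", m),
             vapply(seq_len(n), function(i)
               pdb_atom_line(i, rep_len(elety, n)[i], rep_len(resid, n)[i],
                             chain, i, xyz[i, 1], xyz[i, 2], xyz[i, 3]),
               ""),
             "ENDMDL")
  }
  c(out, "END")
}

write_tmp_pdb <- function(lines) {
  f <- withr::local_tempfile(fileext = ".pdb",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# A small two-residue structure with a Lys NZ / Asp OD1 pair at a given
# tip-tip distance, for interaction tests.
lys_asp_structure <- function(tip_distance, resno = c(1, 10)) {
  md_structure(data.frame(
    chain = "A",
    resno = rep(resno, each = 2),
    resid = rep(c("LYS", "ASP"), each = 2),
    elety = c("CA", "NZ", "CA", "OD1"),
    x = c(0, 2, 30, 2 + tip_distance),
    y = 0, z = 0), name = "toy")
}

rigid_rotate_traj <- function(traj, angle = 1.1, axis = c(1, 2, 3),
                              shift = c(3, -2, 7)) {
  ax <- axis / sqrt(sum(axis^2))
  q <- c(cos(angle / 2), sin(angle / 2) * ax)
  R <- mdfluct:::.quat_to_rot(q)
  for (f in seq_len(n_frames(traj)))
    traj$coords[, , f] <- sweep(traj$coords[, , f] %*% t(R), 2, shift, `+`)
  traj
}
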