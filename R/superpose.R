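## Optimal rigid-body superposition. The closed-form Kabsch solution (SVD of
## the weighted covariance, reflection suppressed) is the workhorse; a slow
## quaternion-grid minimizer is kept as an independent brute-force reference.

.kabsch_core <- function(mobile, reference, weights = NULL) {
  n <- nrow(mobile)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  H <- crossprod(P * w, Q)                     # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)   # q ~ R %*% p
  fitted <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd)
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares rotation and translation mapping `mobile` onto `reference`,
#' with the reflection branch suppressed (rotation determinant forced to +1).
#'
#' @param mobile,reference n x 3 coordinate matrices (Angstrom), n >= 3 and
#'   not collinear.
#' @param weights optional non-negative per-point weights (default uniform).
#' @return list of class `superposition` with elements `rotation` (3 x 3
#'   proper orthonormal matrix), `translation` (length-3 vector, Angstrom)
#'   and `rmsd` (Angstrom, after applying the transform).
#' @examples
#' ref <- matrix(rnorm(12), 4, 3)
#' fit <- kabsch_superpose(ref, ref)
#' fit$rmsd # 0
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3 || ncol(reference) != 3)
    stop("coordinates must be n x 3 matrices")
  if (nrow(mobile) != nrow(reference))
    stop("point counts differ (", nrow(mobile), " vs ", nrow(reference), ")")
  if (nrow(mobile) < 3) stop("at least 3 points are required")
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(mobile), all(weights >= 0),
              sum(weights) > 0)
  }
  for (m in list(reference, mobile)) {
    s <- svd(sweep(m, 2, colMeans(m)), nu = 0, nv = 0)$d
    if (s[2] < 1e-8 * max(s[1], 1))
      stop("degenerate (collinear) point set")
  }
  res <- .kabsch_core(mobile, reference, weights)
  class(res) <- "superposition"
  res
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd = %.4f A, rotation det = %+.3f\n",
              x$rmsd, det(x$rotation)))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param transform a `superposition` (or list with `rotation`/`translation`).
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  sweep(as.matrix(xyz) %*% t(transform$rotation), 2, transform$translation,
        `+`)
}

.quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Brute-force minimum RMSD by quaternion-grid search
#'
#' Independent reference for [kabsch_superpose]: rotations are parameterized
#' by unit quaternions; a broad random sample is refined by repeatedly
#' perturbing the best quaternion with shrinking step sizes. Translation is
#' handled exactly by centroid matching. Orders of magnitude slower than the
#' closed form; intended for validation on small point sets only. Consumes
#' the R random number stream.
#'
#' @param mobile,reference n x 3 coordinate matrices.
#' @param n_start size of the initial random quaternion sample.
#' @param n_refine refinement rounds.
#' @param n_local candidates per refinement round.
#' @return minimum RMSD found (Angstrom).
#' @export
rmsd_quaternion_grid <- function(mobile, reference, n_start = 600,
                                 n_refine = 45, n_local = 80) {
  P <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  Q <- sweep(as.matrix(reference), 2, colMeans(reference))
  score <- function(q) {
    R <- .quat_to_rot(q)
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  qs <- rbind(c(1, 0, 0, 0),
              matrix(stats::rnorm(4 * n_start), ncol = 4))
  vals <- apply(qs, 1, score)
  best_q <- qs[which.min(vals), ]
  best <- min(vals)
  step <- 1
  for (k in seq_len(n_refine)) {
    cand <- matrix(stats::rnorm(4 * n_local, sd = step), ncol = 4)
    cand <- sweep(cand, 2, best_q, `+`)
    v <- apply(cand, 1, score)
    if (min(v) < best) {
      best <- min(v)
      best_q <- cand[which.min(v), ]
    }
    step <- step * 0.7
  }
  best
}
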