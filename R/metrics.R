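#' Least RMSD between two paired point sets
#'
#' RMSD after optimal rigid-body superposition (Kabsch, restricted to proper
#' rotations; reflections are rejected by flipping the sign of the smallest
#' singular value).  Atoms are paired by row index with uniform weights.
#'
#' @param A,B Numeric matrices (m x 3), m >= 3, Angstrom.
#' @return lRMSD in Angstrom (scalar, >= 0).
#' @examples
#' A <- matrix(rnorm(12), 4, 3)
#' lrmsd(A, A)  # 0
#' @export
lrmsd <- function(A, B) {
  if (!is.matrix(A) || !is.matrix(B) || ncol(A) != 3 || ncol(B) != 3)
    stop("coordinate sets must be m x 3 matrices")
  if (nrow(A) != nrow(B)) stop("atom counts differ")
  if (nrow(A) < 3) stop("at least 3 atoms required")
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  H <- crossprod(Bc, Ac)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  # explicit rotation + residuals rather than the trace identity: the
  # residual form stays accurate near zero where the trace form cancels
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sqrt(mean(rowSums((Bc %*% t(R) - Ac)^2)))
}

#' Optimal proper-rotation superposition of B onto A
#'
#' @param A,B Numeric m x 3 matrices, paired by row.
#' @return B after superposition onto A (m x 3 matrix).
#' @export
superpose <- function(A, B) {
  if (nrow(A) != nrow(B)) stop("atom counts differ")
  muA <- colMeans(A); muB <- colMeans(B)
  Ac <- sweep(A, 2, muA); Bc <- sweep(B, 2, muB)
  H <- crossprod(Bc, Ac)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(Bc %*% t(R), 2, muA, `+`)
}

#' Ultrafast-shape-recognition (USR) features of a point set
#'
#' Three rotation/translation-invariant shape coordinates: the mean atom
#' distance from the centroid (ctd), from the atom farthest from the
#' centroid (fct), and from the atom farthest from fct (ftf).  Ties for the
#' farthest atom are broken by lowest atom index so the projection is
#' deterministic.
#'
#' @param xyz Numeric m x 3 matrix, m >= 2.
#' @return Named numeric vector \code{c(ctd, fct, ftf)} in Angstrom, with an
#'   attribute \code{degenerate = TRUE} when all atoms coincide.
#' @export
usr_features <- function(xyz) {
  if (!is.matrix(xyz) || ncol(xyz) != 3) stop("xyz must be m x 3")
  if (nrow(xyz) < 2) stop("at least 2 atoms required")
  dist_to <- function(p) sqrt(rowSums(sweep(xyz, 2, p)^2))
  d_ctd <- dist_to(colMeans(xyz))
  if (all(d_ctd == 0)) {
    out <- c(ctd = 0, fct = 0, ftf = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  i_fct <- which.max(d_ctd)           # which.max takes the first maximum
  d_fct <- dist_to(xyz[i_fct, ])
  i_ftf <- which.max(d_fct)
  d_ftf <- dist_to(xyz[i_ftf, ])
  c(ctd = mean(d_ctd), fct = mean(d_fct), ftf = mean(d_ftf))
}

#' Progress-coordinate level of a conformation
#'
#' The 1-D progress grid discretizes lRMSD-to-goal into integer levels of
#' 1 Angstrom spacing on [0, D]; values beyond D map to the D level.
#'
#' @param lrmsd_to_goal lRMSD to the goal structure (Angstrom, >= 0).
#' @param D Grid upper bound (Angstrom, positive integer).
#' @param spacing Level spacing in Angstrom (default 1).
#' @return Integer level in [0, D/spacing].
#' @export
progress_level <- function(lrmsd_to_goal, D, spacing = 1) {
  if (any(lrmsd_to_goal < 0) || D <= 0) stop("inputs must be non-negative")
  as.integer(pmin(floor(lrmsd_to_goal / spacing),
                  as.integer(round(D / spacing))))
}

#' Delta-R transition coordinate
#'
#' lRMSD to reference A minus lRMSD to reference B: a 1-D coordinate along
#' a transition between two end states, negative near A and positive near
#' B (at the end states themselves it equals -/+ the inter-reference
#' lRMSD).
#'
#' @param xyz Coordinates of the conformation (m x 3).
#' @param refA,refB Reference coordinate sets (m x 3 each).
#' @return Signed Angstrom value; antisymmetric under swapping the refs.
#' @export
delta_r <- function(xyz, refA, refB) lrmsd(xyz, refA) - lrmsd(xyz, refB)
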