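#' Extract root-to-goal paths from a tree
#'
#' One path per goal-region node (lRMSD-to-goal <= tol), each traced back
#' through parent links to the root, ordered by terminal lRMSD ascending.
#'
#' @param result A \code{planner_result} (or a tree environment plus
#'   explicit \code{tol}).
#' @param tol Goal-region radius; defaults to the run configuration's.
#' @return List of paths; each path is a list with \code{nodes} (integer
#'   indices root..goal), \code{lrmsd_goal}, \code{energy}.
#' @export
extract_paths <- function(result, tol = NULL) {
  tr <- result$tree
  if (is.null(tol)) tol <- result$config$tol
  nseq <- seq_len(tr$n)
  hits <- nseq[tr$lrmsd_goal[nseq] <= tol]
  hits <- hits[order(tr$lrmsd_goal[hits])]
  lapply(hits, function(h) {
    nodes <- h
    while (tr$parent[nodes[1]] != 0L) nodes <- c(tr$parent[nodes[1]], nodes)
    list(nodes = nodes,
         lrmsd_goal = tr$lrmsd_goal[nodes],
         energy = tr$energy[nodes])
  })
}

#' Tree depth: lowest lRMSD-to-goal over all nodes
#'
#' @param result A \code{planner_result}.
#' @return Angstrom.
#' @export
tree_depth <- function(result) {
  tr <- result$tree
  min(tr$lrmsd_goal[seq_len(tr$n)])
}

#' Breadth of the successful-path ensemble
#'
#' Paths are aligned by distance-from-goal index i = 0..h-1, where h is the
#' node count of the shortest successful path; paths longer than h
#' contribute their h nodes nearest the goal end.  d_i is the maximum
#' pairwise lRMSD among the conformations occupying index i across paths,
#' and b = sum_{i=0}^{h-1} (i+1) d_i / h, down-weighting differences close
#' to the goal.
#'
#' @param result A \code{planner_result}.
#' @param paths Optionally, precomputed \code{\link{extract_paths}} output.
#' @param geo Geometry parameters.
#' @return List of class \code{breadth_report}: \code{b} (Angstrom),
#'   \code{h}, and the per-index \code{d} vector (index i = 0 first).
#' @export
path_breadth <- function(result, paths = extract_paths(result),
                         geo = geometry_params()) {
  if (length(paths) == 0) stop("breadth undefined: no successful paths")
  tr <- result$tree
  h <- min(vapply(paths, function(p) length(p$nodes), integer(1)))
  d <- numeric(h)
  for (i in seq_len(h) - 1L) {            # i = 0 at the goal end
    members <- vapply(paths, function(p) p$nodes[length(p$nodes) - i],
                      integer(1))
    uniq <- unique(members)
    if (length(uniq) > 1) {
      xyz <- lapply(uniq, function(k) forward_kinematics(tr$conf[[k]], geo))
      dm <- 0
      for (a in seq_along(uniq)[-length(uniq)])
        for (b2 in (a + 1):length(uniq))
          dm <- max(dm, lrmsd(xyz[[a]], xyz[[b2]]))
      d[i + 1L] <- dm
    }
  }
  b <- sum((seq_len(h)) * d) / h          # (i+1) * d_i with i = 0..h-1
  structure(list(b = b, h = h, d = d), class = "breadth_report")
}

#' @export
print.breadth_report <- function(x, ...) {
  cat(sprintf("breadth b = %.3f A over shortest-path length h = %d\n",
              x$b, x$h))
  invisible(x)
}

#' Lowest lRMSD to reference structures over qualifying paths
#'
#' For each reference structure, the minimum lRMSD over every conformation
#' on paths whose terminal node reaches the goal within \code{qualify_tol}.
#'
#' @param result A \code{planner_result}.
#' @param references List of reference coordinate matrices (4n x 3) or
#'   \code{conformation}s.
#' @param qualify_tol Path qualification radius (Angstrom); defaults to the
#'   run tolerance.
#' @param geo Geometry parameters.
#' @return Numeric vector, one minimum lRMSD per reference (named if the
#'   reference list is named); all NA with attribute
#'   \code{no_qualifying_paths = TRUE} when no path qualifies.
#' @export
reference_proximity <- function(result, references, qualify_tol = NULL,
                                geo = geometry_params()) {
  if (is.null(qualify_tol)) qualify_tol <- result$config$tol
  paths <- extract_paths(result, tol = qualify_tol)
  refs <- lapply(references, function(r)
    if (inherits(r, "conformation")) forward_kinematics(r, geo) else r)
  out <- rep(NA_real_, length(refs))
  names(out) <- names(references)
  if (length(paths) == 0) {
    attr(out, "no_qualifying_paths") <- TRUE
    return(out)
  }
  tr <- result$tree
  nodes <- sort(unique(unlist(lapply(paths, `[[`, "nodes"))))
  xyz <- lapply(nodes, function(k) forward_kinematics(tr$conf[[k]], geo))
  for (j in seq_along(refs))
    out[j] <- min(vapply(xyz, function(x) lrmsd(x, refs[[j]]), numeric(1)))
  out
}

#' Pseudo-free-energy profile from samples of a 1-D coordinate
#'
#' Single-ensemble Boltzmann histogram estimator: per-bin
#' F = -kB T ln(count/total), shifted so the minimum is 0.  Empty bins are
#' reported as +Inf.  The profile is defined up to an additive constant and
#' carries no statistical reweighting across sampling windows.
#'
#' @param values Numeric samples of the coordinate (e.g. delta-R, Angstrom).
#' @param bins Number of bins, >= 2.
#' @param T Temperature in Kelvin.
#' @param kB Boltzmann constant in kcal/(mol K).
#' @return Data frame with bin \code{mid}, \code{count}, and free energy
#'   \code{F} in kcal/mol; attribute \code{degenerate = TRUE} when all
#'   samples fall in one bin.
#' @export
pseudo_free_energy <- function(values, bins = 20, T = 300, kB = KB_KCAL) {
  if (length(values) < 1) stop("at least one sample required")
  if (bins < 2) stop("at least 2 bins required")
  rng <- range(values)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  cnt <- tabulate(pmin(findInterval(values, edges, rightmost.closed = TRUE),
                       bins), nbins = bins)
  p <- cnt / sum(cnt)
  F <- ifelse(p > 0, -kB * T * log(p), Inf)
  F <- F - min(F)
  out <- data.frame(mid = (edges[-1] + edges[-(bins + 1)]) / 2,
                    count = cnt, F = F)
  if (sum(cnt > 0) == 1) attr(out, "degenerate") <- TRUE
  out
}

#' Delta-R samples of every node on the successful paths
#'
#' Convenience for profiling a transition along the delta-R coordinate
#' (lRMSD to reference A minus lRMSD to reference B).
#'
#' @param result A \code{planner_result}.
#' @param refA,refB Reference \code{conformation}s or coordinate matrices;
#'   default to the run's start and goal.
#' @param paths Precomputed paths (default: extract at the run tolerance).
#' @param geo Geometry parameters.
#' @return Numeric vector of delta-R values (Angstrom).
#' @export
path_delta_r <- function(result, refA = result$start, refB = result$goal,
                         paths = extract_paths(result),
                         geo = geometry_params()) {
  A <- if (inherits(refA, "conformation")) forward_kinematics(refA, geo) else refA
  B <- if (inherits(refB, "conformation")) forward_kinematics(refB, geo) else refB
  tr <- result$tree
  nodes <- sort(unique(unlist(lapply(paths, `[[`, "nodes"))))
  vapply(nodes, function(k)
    delta_r(forward_kinematics(tr$conf[[k]], geo), A, B), numeric(1))
}
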