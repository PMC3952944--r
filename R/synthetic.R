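#' Generate a toy transition with known reachability
#'
#' Builds a self-contained test instance: a random goal conformation, a
#' start obtained from the goal by overwriting every trimer window with a
#' random decoy configuration, and a fragment library that contains, for
#' every window, the goal's own configuration plus \code{decoys_per_window}
#' random configurations.  By construction the goal is reachable from the
#' start by at most n-2 library moves (one per window), so planner tests
#' never depend on luck for existence of a solution.  Optionally the
#' designated energy model carries a Gaussian barrier of
#' \code{barrier_height} kcal/mol centred at delta-R = 0 between start and
#' goal on top of the goal-funnel toy energy.
#'
#' @param n Chain length in residues, >= 4.
#' @param decoys_per_window Random decoy configurations per window
#'   (default 0).
#' @param barrier_height Barrier height in kcal/mol (default 0 = plain
#'   funnel).
#' @param barrier_width Gaussian width on the delta-R axis (Angstrom,
#'   default 0.5).
#' @param funnel_scale Funnel slope, kcal/mol per Angstrom of lRMSD.
#' @param decoy_jitter NULL (default) draws decoy configurations uniformly
#'   at random over angle space, giving large conformational jumps per
#'   move.  A positive value in degrees instead makes every decoy the
#'   goal's own window configuration perturbed by uniform noise of that
#'   half-width, producing a small-step transition regime in which an
#'   energy barrier on the delta-R axis must actually be climbed move by
#'   move rather than leapt over.
#' @param seed Integer seed; the instance is a deterministic function of
#'   the arguments.
#' @param geo Geometry parameters.
#' @return Object of class \code{toy_transition}: \code{n}, \code{start},
#'   \code{goal}, \code{lib}, \code{model}, \code{seed}, plus the knobs.
#' @export
make_toy_transition <- function(n, decoys_per_window = 0, barrier_height = 0,
                                barrier_width = 0.5, funnel_scale = 1,
                                decoy_jitter = NULL, seed = 1,
                                geo = geometry_params()) {
  if (n < 4) stop("toy transitions require n >= 4")
  set.seed(seed)
  seqn <- rep("A", n)
  rand_angles <- function() stats::runif(n, -180, 180)
  repeat {
    goal <- conformation(seqn, rand_angles(), rand_angles())
    goal_tri <- excise_trimers(forward_kinematics(goal, geo), "goal")
    decoy_angles <- function(i) {
      if (is.null(decoy_jitter))
        wrap_angle(stats::runif(6, -180, 180))
      else {
        a <- goal_tri[[i]]$angles
        j <- stats::runif(6, -decoy_jitter, decoy_jitter)
        ifelse(a == ANGLE_UNDEF, a, wrap_angle(a + j))
      }
    }
    start <- goal
    for (i in seq_len(n - 2))
      start <- apply_move(start, i,
                          fragment_config(decoy_angles(i),
                                          sprintf("decoy_start:%d", i)))
    d0 <- lrmsd(forward_kinematics(start, geo), forward_kinematics(goal, geo))
    if (d0 > 0) break   # regenerate on the (rare) exact collision
  }
  windows <- vector("list", n - 2)
  for (i in seq_len(n - 2)) {
    ent <- list(goal_tri[[i]])
    if (decoys_per_window > 0)
      for (k in seq_len(decoys_per_window))
        ent <- c(ent, list(fragment_config(decoy_angles(i),
                                           sprintf("decoy:%d:%d", i, k))))
    windows[[i]] <- ent
  }
  lib <- new_fragment_library(n, windows, "position-specific")
  model <- if (barrier_height > 0)
    energy_barrier(start, goal, height = barrier_height,
                   width = barrier_width, scale = funnel_scale, geo = geo)
  else energy_goal_funnel(goal, scale = funnel_scale, geo = geo)
  structure(list(n = n, start = start, goal = goal, lib = lib, model = model,
                 seed = seed, decoys_per_window = decoys_per_window,
                 barrier_height = barrier_height),
            class = "toy_transition")
}

#' @export
print.toy_transition <- function(x, ...) {
  cat("toy_transition: n =", x$n, ", decoys/window =", x$decoys_per_window,
      ", barrier =", x$barrier_height, "kcal/mol\n")
  invisible(x)
}

#' Ordered move list certifying goal reachability
#'
#' Returns the sequence of (window, configuration) moves — the goal's own
#' trimer configuration at each window, in order — whose application
#' transforms the toy start into the goal exactly (lRMSD 0).
#'
#' @param toy A \code{toy_transition}.
#' @return List of moves, each a list with \code{window} and \code{config};
#'   length <= n - 2.
#' @export
reachability_certificate <- function(toy) {
  stopifnot(inherits(toy, "toy_transition"))
  moves <- list()
  cur <- toy$start
  for (i in seq_len(toy$n - 2)) {
    cfg <- toy$lib$windows[[i]][[1]]   # the goal configuration by construction
    nxt <- apply_move(cur, i, cfg)
    if (!identical(c(nxt$phi, nxt$psi), c(cur$phi, cur$psi)))
      moves[[length(moves) + 1L]] <- list(window = i, config = cfg)
    cur <- nxt
  }
  moves
}
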