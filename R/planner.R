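#' Planner configuration
#'
#' @param tol Goal-region radius in Angstrom: a tree node within \code{tol}
#'   lRMSD of the goal terminates a path.
#' @param max_nodes Number of conformations to add to the tree (root not
#'   counted).
#' @param m Candidates that must pass the Metropolis criterion per expansion
#'   (default 10).
#' @param l Maximum fragment moves attempted per expansion (default 100).
#'   Reactive-temperature runs benefit from a larger candidate budget
#'   (e.g. m = 25, l = 250), since hotter expansions scatter more widely.
#' @param scheme Global bias scheme over the progress grid: one of
#'   \code{"QUAD"}, \code{"LINEAR"}, \code{"UNIFORM"}, \code{"COMBINE"}.
#' @param epsilon Additive floor in the QUAD/LINEAR weights so distant
#'   levels stay selectable (default 1e-6).
#' @param combine_p Probability COMBINE uses UNIFORM on a given draw
#'   (default 0.9, i.e. a 90/10 UNIFORM/QUAD mixture).
#' @param local_bias If TRUE, a chosen candidate is added only when its
#'   lRMSD-to-goal does not exceed the parent's.
#' @param step_control If TRUE, the candidate is chosen by the Gaussian
#'   step-size rule instead of lowest lRMSD-to-goal.
#' @param use_shape_grid If TRUE, a 3-D USR projection grid biases selection
#'   away from over-sampled shape cells.
#' @param shape_cell_size Cell edge per USR feature in Angstrom
#'   (default 0.25).
#' @param reactive If TRUE, the window-based reactive temperature controller
#'   drives the temperature index; otherwise \code{temp_index} is fixed.
#' @param reactive_cfg A \code{\link{reactive_config}}.
#' @param temp_index Fixed temperature index on the 0..14 schedule
#'   (default 9, the medium temperature).
#' @param seed Integer seed for the single RNG stream driving every
#'   stochastic choice; NULL leaves the RNG state untouched.
#' @param stop_on_goal If TRUE the loop stops at the first node entering
#'   the goal region instead of growing the full \code{max_nodes} tree;
#'   convenient for hit-rate experiments (default FALSE).
#' @param max_iter_factor Hard cap on total iterations as a multiple of
#'   \code{max_nodes}, guaranteeing termination when expansions keep
#'   failing (default 50).
#' @return Object of class \code{planner_config}.
#' @export
planner_config <- function(tol, max_nodes, m = 10, l = 100,
                           scheme = c("QUAD", "LINEAR", "UNIFORM", "COMBINE"),
                           epsilon = 1e-6, combine_p = 0.9,
                           local_bias = FALSE, step_control = FALSE,
                           use_shape_grid = FALSE, shape_cell_size = 0.25,
                           reactive = FALSE, reactive_cfg = reactive_config(),
                           temp_index = 9, seed = NULL,
                           max_iter_factor = 50, stop_on_goal = FALSE) {
  scheme <- match.arg(scheme)
  if (tol <= 0) stop("tol must be positive")
  if (max_nodes < 0) stop("max_nodes must be >= 0")
  if (!(m >= 1 && m <= l)) stop("require 1 <= m <= l")
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (combine_p < 0 || combine_p > 1) stop("combine_p must be in [0, 1]")
  if (temp_index < 0 || temp_index > 14) stop("temp_index must be in 0..14")
  structure(list(tol = tol, max_nodes = as.integer(max_nodes), m = as.integer(m),
                 l = as.integer(l), scheme = scheme, epsilon = epsilon,
                 combine_p = combine_p, local_bias = local_bias,
                 step_control = step_control, use_shape_grid = use_shape_grid,
                 shape_cell_size = shape_cell_size, reactive = reactive,
                 reactive_cfg = reactive_cfg, temp_index = as.integer(temp_index),
                 seed = seed, max_iter_factor = max_iter_factor,
                 stop_on_goal = stop_on_goal),
            class = "planner_config")
}

#' Progress-level selection weight
#'
#' QUAD: 1/(1+l^2) + epsilon; LINEAR: 1/(1+l) + epsilon; UNIFORM:
#' 1/n_levels.  COMBINE has no weight of its own — each draw resolves to
#' UNIFORM or QUAD first.
#'
#' @param scheme One of "QUAD", "LINEAR", "UNIFORM".
#' @param level Integer level(s) >= 0.
#' @param epsilon Additive floor for QUAD/LINEAR.
#' @param n_levels Number of levels (needed by UNIFORM).
#' @return Numeric weight(s).
#' @export
level_weight <- function(scheme, level, epsilon = 1e-6, n_levels = NULL) {
  if (any(level < 0)) stop("levels must be >= 0")
  switch(scheme,
         QUAD = 1 / (1 + level^2) + epsilon,
         LINEAR = 1 / (1 + level) + epsilon,
         UNIFORM = {
           if (is.null(n_levels)) stop("UNIFORM requires n_levels")
           rep(1 / n_levels, length(level))
         },
         stop("unknown bias scheme: ", scheme))
}

# USR cell key at the configured granularity
shape_cell_key <- function(feats, cell_size) {
  paste(floor(feats / cell_size), collapse = ",")
}

# empty tree container (environment: grown in place)
new_tree <- function(cap, D) {
  tr <- new.env(parent = emptyenv())
  tr$conf <- vector("list", cap)
  tr$parent <- integer(cap)
  tr$lrmsd_goal <- numeric(cap)
  tr$level <- integer(cap)
  tr$cell <- character(cap)
  tr$energy <- numeric(cap)
  tr$iter <- integer(cap)
  tr$temp_idx <- integer(cap)
  tr$n <- 0L
  tr$D <- D
  tr$levels <- replicate(D + 1, integer(0), simplify = FALSE)
  tr$cells <- new.env(parent = emptyenv())  # key -> list(nsel, nodes)
  tr
}

tree_insert <- function(tr, conf, parent, lr, level, cell, energy, iter,
                        temp_idx) {
  i <- tr$n + 1L
  tr$conf[[i]] <- conf
  tr$parent[i] <- parent
  tr$lrmsd_goal[i] <- lr
  tr$level[i] <- level
  tr$cell[i] <- cell
  tr$energy[i] <- energy
  tr$iter[i] <- iter
  tr$temp_idx[i] <- temp_idx
  tr$n <- i
  tr$levels[[level + 1L]] <- c(tr$levels[[level + 1L]], i)
  if (nzchar(cell)) {
    rec <- get0(cell, envir = tr$cells, ifnotfound = NULL)
    if (is.null(rec)) rec <- list(nsel = 0L, nodes = integer(0))
    rec$nodes <- c(rec$nodes, i)
    assign(cell, rec, envir = tr$cells)
  }
  i
}

#' Select a parent node for expansion
#'
#' Draws a progress level over the occupied levels with probability
#' proportional to the scheme weight (renormalized over occupied levels;
#' under COMBINE each draw first resolves to UNIFORM with probability
#' \code{combine_p}, else QUAD).  If the shape grid is enabled, a 3-D cell
#' is then drawn among cells holding that level's nodes with probability
#' proportional to 1/((1 + nsel) * nconfs), and that cell's nsel counter is
#' incremented.  The node is finally drawn uniformly from the resulting
#' pool.
#'
#' @param tree Tree environment from \code{\link{run_planner}}.
#' @param config A \code{\link{planner_config}}.
#' @return List: \code{node} (index), \code{level}, \code{cell} (key or NA).
#' @export
select_parent <- function(tree, config) {
  occ <- which(vapply(tree$levels, length, integer(1)) > 0) - 1L
  if (length(occ) == 0) stop("empty tree")
  scheme <- config$scheme
  if (scheme == "COMBINE")
    scheme <- if (stats::runif(1) < config$combine_p) "UNIFORM" else "QUAD"
  w <- level_weight(scheme, occ, config$epsilon, n_levels = length(occ))
  lv <- if (length(occ) == 1) occ else occ[sample.int(length(occ), 1, prob = w)]
  pool <- tree$levels[[lv + 1L]]
  cell <- NA_character_
  if (config$use_shape_grid) {
    keys <- unique(tree$cell[pool])
    cw <- vapply(keys, function(k) {
      rec <- get(k, envir = tree$cells)
      1.0 / ((1.0 + rec$nsel) * length(rec$nodes))
    }, numeric(1))
    cell <- if (length(keys) == 1) keys else keys[sample.int(length(keys), 1, prob = cw)]
    rec <- get(cell, envir = tree$cells)
    rec$nsel <- rec$nsel + 1L
    assign(cell, rec, envir = tree$cells)
    pool <- intersect(pool, rec$nodes)
  }
  node <- if (length(pool) == 1) pool else pool[sample.int(length(pool), 1)]
  list(node = node, level = lv, cell = cell)
}

#' Gaussian step-size candidate selection
#'
#' Computes the mean and standard deviation of the candidates' lRMSDs to
#' the parent, draws one value from the Gaussian with those parameters, and
#' returns the candidate whose parent-distance is closest to the draw (ties
#' to the lowest index).  With a single candidate or zero spread the draw
#' degenerates to the mean.
#'
#' @param dists_to_parent Numeric vector of candidate lRMSDs to the parent
#'   (Angstrom), length >= 1.
#' @return Integer index of the chosen candidate.
#' @export
step_size_select <- function(dists_to_parent) {
  k <- length(dists_to_parent)
  if (k == 0) stop("no candidates")
  if (k == 1) return(1L)
  mu <- mean(dists_to_parent)
  s <- stats::sd(dists_to_parent)
  g <- if (is.na(s) || s == 0) mu else stats::rnorm(1, mu, s)
  which.min(abs(dists_to_parent - g))
}

#' Expand a tree node with fragment-replacement moves
#'
#' Proposes up to \code{l} fragment moves from the parent; each proposed
#' conformation is screened by the Metropolis criterion at temperature
#' \code{T}.  Proposals stop as soon as \code{m} candidates pass.  The
#' candidate with the lowest lRMSD to the goal is chosen (or, with step
#' control, the one selected by the Gaussian step-size rule).  Under local
#' bias the chosen candidate is returned only if its lRMSD-to-goal does not
#' exceed the parent's.  A failed expansion (no surviving candidate) is a
#' normal outcome.
#'
#' @param parent_conf Parent \code{conformation}.
#' @param parent_energy Parent energy in kcal/mol.
#' @param parent_lrmsd Parent lRMSD-to-goal in Angstrom.
#' @param lib Fragment library.
#' @param model Energy model.
#' @param goal_xyz Goal backbone coordinates (4n x 3).
#' @param T Temperature in Kelvin.
#' @param config A \code{\link{planner_config}}.
#' @param geo Geometry parameters.
#' @return A list with \code{conf} (the accepted child \code{conformation},
#'   or NULL when the expansion fails), \code{energy}, \code{lrmsd},
#'   \code{attempts}, \code{n_candidates}, \code{deltaE}.
#' @export
expand_node <- function(parent_conf, parent_energy, parent_lrmsd, lib, model,
                        goal_xyz, T, config, geo = geometry_params()) {
  cand <- list()
  attempts <- 0L
  while (attempts < config$l && length(cand) < config$m) {
    attempts <- attempts + 1L
    mv <- sample_move(lib)
    child <- apply_move(parent_conf, mv$window, mv$config)
    cxyz <- forward_kinematics(child, geo)
    e <- energy_total_xyz(model, child, cxyz, geo)
    if (!metropolis_accept(e - parent_energy, T)) next
    cand[[length(cand) + 1L]] <-
      list(conf = child, energy = e,
           lrmsd = lrmsd(cxyz, goal_xyz), xyz = cxyz)
  }
  fail <- list(conf = NULL, energy = NA_real_, lrmsd = NA_real_,
               attempts = attempts, n_candidates = length(cand),
               deltaE = NA_real_)
  if (length(cand) == 0) return(fail)
  if (config$step_control) {
    pxyz <- forward_kinematics(parent_conf, geo)
    dp <- vapply(cand, function(cc) lrmsd(cc$xyz, pxyz), numeric(1))
    pick <- step_size_select(dp)
  } else {
    pick <- which.min(vapply(cand, `[[`, numeric(1), "lrmsd"))
  }
  ch <- cand[[pick]]
  if (config$local_bias && ch$lrmsd > parent_lrmsd) return(fail)
  list(conf = ch$conf, energy = ch$energy, lrmsd = ch$lrmsd,
       attempts = attempts, n_candidates = length(cand),
       deltaE = ch$energy - parent_energy)
}

#' Grow a conformational tree from start toward goal
#'
#' The main loop: select a parent over the discretization layer(s), expand
#' it with fragment moves under Metropolis screening, and insert any
#' resulting child into the progress grid (and shape grid, if enabled).
#' The loop runs until \code{max_nodes} conformations have been added or a
#' hard iteration cap (\code{max_iter_factor * max_nodes}) is hit.  When the
#' reactive controller is enabled, the temperature index is re-evaluated
#' after every window of \code{w} added nodes from the window's best
#' lRMSD-to-goal.  A single RNG stream (seeded from \code{config$seed})
#' drives all stochastic choices in a fixed order, so identical seed and
#' configuration reproduce the tree exactly.
#'
#' @param start,goal \code{conformation}s of equal length.
#' @param lib Fragment library matching the chain length.
#' @param model Energy model.
#' @param config A \code{\link{planner_config}}.
#' @param geo Geometry parameters.
#' @return Object of class \code{planner_result}: the tree environment
#'   (\code{tree}), \code{goal_nodes} (indices within tol of the goal),
#'   \code{depth_trace} (min lRMSD-to-goal after each added node),
#'   \code{window_best} and \code{temp_trace} (per-window statistics and
#'   temperature indices), \code{log} (one data.frame row per iteration),
#'   plus \code{start}, \code{goal}, \code{goal_xyz}, \code{config},
#'   \code{schedule}, \code{D}.
#' @export
run_planner <- function(start, goal, lib, model, config,
                        geo = geometry_params()) {
  stopifnot(inherits(start, "conformation"), inherits(goal, "conformation"),
            inherits(config, "planner_config"))
  if (n_residues(start) != n_residues(goal))
    stop("start and goal chain lengths differ")
  if (lib$n != n_residues(start))
    stop("fragment library chain length does not match the structures")
  if (!is.null(config$seed)) set.seed(config$seed)

  sched <- temperature_schedule()
  start_xyz <- forward_kinematics(start, geo)
  goal_xyz <- forward_kinematics(goal, geo)
  d0 <- lrmsd(start_xyz, goal_xyz)
  D <- max(1L, as.integer(ceiling(d0)))

  tr <- new_tree(config$max_nodes + 1L, D)
  cell0 <- if (config$use_shape_grid)
    shape_cell_key(usr_features(start_xyz), config$shape_cell_size) else ""
  temp_idx <- if (config$reactive) config$reactive_cfg$start_index
              else config$temp_index
  tree_insert(tr, start, 0L, d0, progress_level(d0, D), cell0,
              evaluate_energy(model, start, geo)$total, 0L, temp_idx)

  goal_nodes <- if (d0 <= config$tol) 1L else integer(0)
  depth <- d0
  depth_trace <- numeric(config$max_nodes)
  max_iter <- config$max_iter_factor * max(config$max_nodes, 1L)
  w <- config$reactive_cfg$w
  window_best <- numeric(0)
  temp_trace <- temp_idx
  cur_window_best <- Inf

  log_iter <- integer(max_iter); log_level <- integer(max_iter)
  log_cell <- character(max_iter); log_attempts <- integer(max_iter)
  log_added <- logical(max_iter); log_lrmsd <- rep(NA_real_, max_iter)
  log_tidx <- integer(max_iter)

  added <- 0L; it <- 0L
  while (added < config$max_nodes && it < max_iter) {
    it <- it + 1L
    sel <- select_parent(tr, config)
    p <- sel$node
    res <- expand_node(tr$conf[[p]], tr$energy[p], tr$lrmsd_goal[p], lib,
                       model, goal_xyz, sched$temps[temp_idx + 1L], config,
                       geo)
    log_iter[it] <- it; log_level[it] <- sel$level
    log_cell[it] <- if (is.na(sel$cell)) "" else sel$cell
    log_tidx[it] <- temp_idx
    if (is.null(res$conf)) {
      log_attempts[it] <- res$attempts; log_added[it] <- FALSE
      next
    }
    added <- added + 1L
    cell <- if (config$use_shape_grid)
      shape_cell_key(usr_features(forward_kinematics(res$conf, geo)),
                     config$shape_cell_size) else ""
    tree_insert(tr, res$conf, p, res$lrmsd, progress_level(res$lrmsd, D),
                cell, res$energy, it, temp_idx)
    if (res$lrmsd <= config$tol) goal_nodes <- c(goal_nodes, tr$n)
    depth <- min(depth, res$lrmsd)
    depth_trace[added] <- depth
    log_attempts[it] <- res$attempts; log_added[it] <- TRUE
    log_lrmsd[it] <- res$lrmsd
    cur_window_best <- min(cur_window_best, res$lrmsd)
    if (config$stop_on_goal && res$lrmsd <= config$tol) break
    if (added %% w == 0L) {
      if (config$reactive && length(window_best) > 0)
        temp_idx <- reactive_update(cur_window_best,
                                    window_best[length(window_best)],
                                    temp_idx, config$reactive_cfg)
      window_best <- c(window_best, cur_window_best)
      temp_trace <- c(temp_trace, temp_idx)
      cur_window_best <- Inf
    }
  }

  keep <- seq_len(it)
  structure(list(
    tree = tr,
    goal_nodes = goal_nodes,
    depth_trace = depth_trace[seq_len(added)],
    window_best = window_best,
    temp_trace = temp_trace,
    log = data.frame(iter = log_iter[keep], level = log_level[keep],
                     cell = log_cell[keep], attempts = log_attempts[keep],
                     added = log_added[keep], child_lrmsd = log_lrmsd[keep],
                     temp_index = log_tidx[keep],
                     stringsAsFactors = FALSE),
    start = start, goal = goal, goal_xyz = goal_xyz,
    config = config, schedule = sched, D = D),
    class = "planner_result")
}

#' @export
print.planner_result <- function(x, ...) {
  cat("planner_result:", x$tree$n, "nodes (root included),",
      length(x$goal_nodes), "goal-region nodes, depth =",
      sprintf("%.3f", min(x$tree$lrmsd_goal[seq_len(x$tree$n)])), "A\n")
  invisible(x)
}
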