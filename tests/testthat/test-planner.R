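test_that("level weights implement the published weighting functions", {
  expect_equal(level_weight("QUAD", 0, epsilon = 0), 1)
  expect_equal(level_weight("QUAD", 3, epsilon = 0), 0.1)
  expect_equal(level_weight("LINEAR", 1, epsilon = 0), 0.5)
  expect_equal(level_weight("UNIFORM", 0:4, n_levels = 5), rep(0.2, 5))
  expect_equal(level_weight("QUAD", 2, epsilon = 0.01), 1 / 5 + 0.01)
  expect_error(level_weight("CUBIC", 1), "unknown")
  expect_error(level_weight("UNIFORM", 1), "n_levels")
})

# build a small tree by hand through the internal container
make_manual_tree <- function(confs, lrmsds, parents, D, cells = NULL) {
  tr <- pathtree:::new_tree(length(confs), D)
  for (i in seq_along(confs))
    pathtree:::tree_insert(tr, confs[[i]], parents[i], lrmsds[i],
                           progress_level(lrmsds[i], D),
                           if (is.null(cells)) "" else cells[i],
                           0, i - 1L, 9L)
  tr
}

test_that("parent selection follows the level distribution", {
  set.seed(41)
  confs <- replicate(4, rand_conformation(4), simplify = FALSE)
  # two occupied levels: 0 (one node) and 3 (three nodes)
  tr <- make_manual_tree(confs, c(0.5, 3.2, 3.5, 3.9), c(0L, 1L, 1L, 2L), 5)
  cfg <- planner_config(tol = 0.1, max_nodes = 1, scheme = "QUAD",
                        epsilon = 0.01)
  draws <- replicate(10000, select_parent(tr, cfg)$level)
  w <- c(1 + 0.01, 1 / 10 + 0.01)           # QUAD weights at levels 0, 3
  counts <- c(sum(draws == 0), sum(draws == 3))
  expect_equal(sum(counts), 10000)
  expect_gt(chisq_p(counts, w), 0.01)
  # nodes within the chosen level are uniform
  picks <- replicate(5000, select_parent(tr, cfg)$node)
  tab <- tabulate(picks, 4)[2:4]
  expect_gt(chisq_p(tab, rep(1, 3)), 0.01)
  # single-node tree: the root is forced
  tr1 <- make_manual_tree(confs[1], 2.0, 0L, 5)
  expect_equal(select_parent(tr1, cfg)$node, 1L)
})

test_that("shape-grid cells are drawn by the 1/((1+nsel)nconfs) rule", {
  set.seed(42)
  confs <- replicate(3, rand_conformation(4), simplify = FALSE)
  tr <- make_manual_tree(confs, c(2.1, 2.2, 2.3), c(0L, 1L, 1L), 5,
                         cells = c("cellA", "cellB", "cellB"))
  rec <- get("cellB", envir = tr$cells); rec$nsel <- 3L
  assign("cellB", rec, envir = tr$cells)
  cfg <- planner_config(tol = 0.1, max_nodes = 1, scheme = "UNIFORM",
                        use_shape_grid = TRUE)
  # weights: cellA 1/((1+0)*1) = 1, cellB 1/((1+3)*2) = 0.125 -> 8:1
  # sample without mutating the counters we are testing against
  draws <- replicate(3000, {
    recA <- get("cellA", envir = tr$cells); recB <- get("cellB", envir = tr$cells)
    out <- select_parent(tr, cfg)$cell
    assign("cellA", recA, envir = tr$cells)
    assign("cellB", recB, envir = tr$cells)
    out
  })
  counts <- c(sum(draws == "cellA"), sum(draws == "cellB"))
  expect_gt(chisq_p(counts, c(1, 0.125)), 0.01)
  # nsel increments on selection
  before <- get("cellA", envir = tr$cells)$nsel
  repeat if (select_parent(tr, cfg)$cell == "cellA") break
  expect_equal(get("cellA", envir = tr$cells)$nsel, before + 1L)
})

test_that("expansion picks the lowest-lRMSD candidate and honours local bias", {
  set.seed(43)
  toy <- make_toy_transition(6, decoys_per_window = 2, seed = 77)
  goal_xyz <- forward_kinematics(toy$goal)
  cfg <- planner_config(tol = 0.5, max_nodes = 10, m = 3, l = 50)
  parent_lr <- lrmsd(forward_kinematics(toy$start), goal_xyz)
  res <- expand_node(toy$start, 0, parent_lr, toy$lib, energy_zero(),
                     goal_xyz, 300, cfg)
  expect_false(is.null(res$conf))
  expect_equal(res$n_candidates, 3)          # zero energy accepts everything
  expect_lte(res$attempts, 3)
  expect_equal(res$lrmsd, lrmsd(forward_kinematics(res$conf), goal_xyz),
               tolerance = 1e-12)
  # rejecting model: exhausts exactly l attempts and returns no child
  res2 <- expand_node(toy$start, 0, parent_lr, toy$lib, energy_reject_all(),
                      goal_xyz, 300, cfg)
  expect_null(res2$conf)
  expect_equal(res2$attempts, cfg$l)
  expect_equal(res2$n_candidates, 0)
  # local bias: when every candidate is farther from the goal than the
  # parent (parent = goal, decoy-only library), nothing is added
  cfg_lb <- planner_config(tol = 0.5, max_nodes = 10, m = 3, l = 50,
                           local_bias = TRUE)
  decoy_lib <- build_library(list(rand_conformation(6)), n = 6)
  res3 <- expand_node(toy$goal, 0, 0, decoy_lib, energy_zero(), goal_xyz,
                      300, cfg_lb)
  expect_null(res3$conf)                     # parent is already at lRMSD 0
})

test_that("step-size selection picks the candidate nearest the Gaussian draw", {
  expect_equal(step_size_select(2.7), 1L)
  expect_equal(step_size_select(c(1, 1, 1)), 1L)   # zero spread, tie to first
  d <- c(1, 2, 3)
  set.seed(7)
  g <- rnorm(1, mean(d), sd(d))                    # replicate the draw
  set.seed(7)
  expect_equal(step_size_select(d), which.min(abs(d - g)))
  expect_error(step_size_select(numeric(0)), "no candidates")
  # over many draws the selection concentrates on the candidate nearest the
  # mean: P(middle) = Phi(0.5) - Phi(-0.5), the largest of the three
  set.seed(8)
  picks <- tabulate(replicate(4000, step_size_select(d)), 3)
  expect_gt(picks[2], picks[1])
  expect_gt(picks[2], picks[3])
})

test_that("zero-budget runs return just the root", {
  toy <- make_toy_transition(6, seed = 5)
  cfg <- planner_config(tol = 0.5, max_nodes = 0, seed = 1)
  res <- run_planner(toy$start, toy$goal, toy$lib, energy_zero(), cfg)
  expect_equal(res$tree$n, 1L)
  expect_length(res$goal_nodes, 0)
})

test_that("identical seeds reproduce the tree exactly", {
  toy <- make_toy_transition(8, decoys_per_window = 1, seed = 11)
  cfg <- planner_config(tol = 0.3, max_nodes = 150, scheme = "COMBINE",
                        use_shape_grid = TRUE, seed = 99)
  a <- run_planner(toy$start, toy$goal, toy$lib, toy$model, cfg)
  b <- run_planner(toy$start, toy$goal, toy$lib, toy$model, cfg)
  expect_identical(a$tree$n, b$tree$n)
  expect_identical(a$tree$parent[seq_len(a$tree$n)],
                   b$tree$parent[seq_len(b$tree$n)])
  expect_identical(a$tree$lrmsd_goal[seq_len(a$tree$n)],
                   b$tree$lrmsd_goal[seq_len(b$tree$n)])
  expect_identical(a$depth_trace, b$depth_trace)
  expect_identical(a$log, b$log)
})

test_that("tree bookkeeping stays consistent and depth is monotone", {
  toy <- make_toy_transition(8, decoys_per_window = 2, seed = 12)
  cfg <- planner_config(tol = 0.3, max_nodes = 300, scheme = "QUAD",
                        use_shape_grid = TRUE, seed = 3)
  res <- run_planner(toy$start, toy$goal, toy$lib, toy$model, cfg)
  tr <- res$tree
  n <- tr$n
  # each node sits in exactly one level list, matching its stored level
  member_of <- integer(n)
  for (lv in seq_along(tr$levels)) {
    for (k in tr$levels[[lv]]) {
      expect_equal(member_of[k], 0L)
      member_of[k] <- lv - 1L
    }
  }
  expect_identical(member_of, tr$level[seq_len(n)])
  # stored lRMSD and level agree with recomputation from the conformation
  for (k in sample(seq_len(n), 25)) {
    lr <- lrmsd(forward_kinematics(tr$conf[[k]]), res$goal_xyz)
    expect_equal(lr, tr$lrmsd_goal[k], tolerance = 1e-9)
    expect_equal(progress_level(lr, res$D), tr$level[k])
    # stored energies recompute from the stored conformations (the toy
    # model is the unit-slope goal funnel), so every edge's Metropolis
    # decision is re-checkable from the tree alone
    expect_equal(tr$energy[k], evaluate_energy(toy$model, tr$conf[[k]])$total,
                 tolerance = 1e-9)
  }
  # shape-grid memberships partition the nodes
  cells <- ls(tr$cells)
  counted <- unlist(lapply(cells, function(k) get(k, envir = tr$cells)$nodes))
  expect_setequal(counted, seq_len(n))
  expect_equal(length(counted), n)
  # parent links precede children; root is the start structure
  expect_equal(tr$parent[1], 0L)
  expect_true(all(tr$parent[2:n] >= 1 & tr$parent[2:n] < 2:n))
  # depth trace non-increasing
  expect_true(all(diff(res$depth_trace) <= 0))
  expect_equal(min(tr$lrmsd_goal[seq_len(n)]), tree_depth(res))
})

test_that("local bias makes root-to-leaf lRMSD sequences non-increasing", {
  toy <- make_toy_transition(8, decoys_per_window = 2, seed = 13)
  cfg <- planner_config(tol = 0.3, max_nodes = 200, scheme = "QUAD",
                        local_bias = TRUE, seed = 4)
  res <- run_planner(toy$start, toy$goal, toy$lib, toy$model, cfg)
  tr <- res$tree
  for (k in seq_len(tr$n)[-1])
    expect_lte(tr$lrmsd_goal[k], tr$lrmsd_goal[tr$parent[k]] + 1e-12)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(planner_config(tol = 0, max_nodes = 1), "tol")
  expect_error(planner_config(tol = 1, max_nodes = 1, m = 20, l = 10), "m <= l")
  expect_error(planner_config(tol = 1, max_nodes = 1, temp_index = 15),
               "temp_index")
  toy <- make_toy_transition(6, seed = 2)
  short <- make_toy_transition(5, seed = 2)
  cfg <- planner_config(tol = 1, max_nodes = 1)
  expect_error(run_planner(toy$start, short$goal, toy$lib, energy_zero(), cfg),
               "lengths differ")
  expect_error(run_planner(short$start, short$goal, toy$lib, energy_zero(),
                           cfg), "library")
})
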