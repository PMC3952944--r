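# adjust one interior psi angle by bisection until lrmsd(base, out) = target
tune_to_lrmsd <- function(base, target, slot = 3) {
  bx <- forward_kinematics(base)
  f <- function(t) {
    cf <- base; cf$psi[slot] <- cf$psi[slot] + t
    lrmsd(bx, forward_kinematics(cf))
  }
  hi <- 10
  while (f(hi) < target) hi <- hi * 2
  lo <- 0
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) lo <- mid else hi <- mid
  }
  cf <- base; cf$psi[slot] <- cf$psi[slot] + (lo + hi) / 2
  cf
}

fake_result <- function(tr, goal, tol, geo = geometry_params()) {
  structure(list(tree = tr, config = list(tol = tol),
                 goal_xyz = forward_kinematics(goal, geo), D = tr$D),
            class = "planner_result")
}

test_that("path extraction returns parent-chains ending in the goal region", {
  set.seed(51)
  confs <- replicate(5, rand_conformation(5), simplify = FALSE)
  goal <- confs[[5]]
  gx <- forward_kinematics(goal)
  lr <- vapply(confs, function(cf) lrmsd(forward_kinematics(cf), gx),
               numeric(1))
  tr <- pathtree:::new_tree(5, 10)
  for (i in 1:5)
    pathtree:::tree_insert(tr, confs[[i]], i - 1L, lr[i],
                           progress_level(lr[i], 10), "", 0, i, 9L)
  res <- fake_result(tr, goal, tol = 0.5)
  paths <- extract_paths(res)
  expect_length(paths, 1)                    # only the leaf is within tol
  expect_equal(paths[[1]]$nodes, 1:5)
  expect_equal(paths[[1]]$lrmsd_goal[5], 0)
  # nothing within a tiny tolerance -> empty list
  tr2 <- pathtree:::new_tree(2, 10)
  pathtree:::tree_insert(tr2, confs[[1]], 0L, 3, 3L, "", 0, 0L, 9L)
  expect_length(extract_paths(fake_result(tr2, goal, 0.1)), 0)
  # two goal-region leaves share their prefix
  pathtree:::tree_insert(tr, tune_to_lrmsd(goal, 0.2), 3L, 0.2, 0L, "",
                         0, 6L, 9L)
  paths2 <- extract_paths(fake_result(tr, goal, tol = 0.5))
  expect_length(paths2, 2)
  expect_equal(paths2[[1]]$nodes[1:3], paths2[[2]]$nodes[1:3])
})

test_that("depth is the tree minimum and shrinks with insertions", {
  set.seed(52)
  start <- rand_conformation(5); goal <- rand_conformation(5)
  d0 <- lrmsd(forward_kinematics(start), forward_kinematics(goal))
  tr <- pathtree:::new_tree(2, 10)
  pathtree:::tree_insert(tr, start, 0L, d0, progress_level(d0, 10), "",
                         0, 0L, 9L)
  res <- fake_result(tr, goal, 0.5)
  expect_equal(tree_depth(res), d0)
  pathtree:::tree_insert(tr, goal, 1L, 0, 0L, "", 0, 1L, 9L)
  expect_equal(tree_depth(res), 0)
})

test_that("breadth equals the hand-computed value on a two-path fixture", {
  set.seed(53)
  root <- rand_conformation(6)
  mid <- tune_to_lrmsd(root, 2)              # lrmsd(root, mid) = 2 exactly
  goal <- rand_conformation(6)
  leaf2 <- tune_to_lrmsd(goal, 1)            # lrmsd(goal, leaf2) = 1 exactly
  gx <- forward_kinematics(goal)
  lr <- function(cf) lrmsd(forward_kinematics(cf), gx)
  expect_gt(lr(root), 1.2); expect_gt(lr(mid), 1.2)  # fixture sanity
  tr <- pathtree:::new_tree(4, 12)
  D <- 12
  pathtree:::tree_insert(tr, root, 0L, lr(root), progress_level(lr(root), D),
                         "", 0, 0L, 9L)
  pathtree:::tree_insert(tr, goal, 1L, 0, 0L, "", 0, 1L, 9L)      # leaf 1
  pathtree:::tree_insert(tr, mid, 1L, lr(mid), progress_level(lr(mid), D),
                         "", 0, 2L, 9L)
  pathtree:::tree_insert(tr, leaf2, 3L, lr(leaf2),
                         progress_level(lr(leaf2), D), "", 0, 3L, 9L)
  res <- fake_result(tr, goal, tol = 1.2)
  paths <- extract_paths(res)
  expect_length(paths, 2)
  rep_ <- path_breadth(res, paths)
  # h = 2; d_0 = lrmsd(leaf1, leaf2) = 1, d_1 = lrmsd(root, mid) = 2
  # b = (1*1 + 2*2)/2 = 2.5
  expect_equal(rep_$h, 2)
  expect_equal(rep_$d, c(1, 2), tolerance = 1e-6)
  expect_equal(rep_$b, 2.5, tolerance = 1e-6)
  # permuting the path list leaves b unchanged
  expect_equal(path_breadth(res, rev(paths))$b, rep_$b, tolerance = 1e-12)
  # identical paths give zero breadth
  expect_equal(path_breadth(res, paths[c(1, 1)])$b, 0)
  expect_error(path_breadth(res, list()), "no successful paths")
})

test_that("reference proximity is exact for on-path references", {
  toy <- make_toy_transition(8, decoys_per_window = 1, seed = 54)
  cfg <- planner_config(tol = 0.5, max_nodes = 200, scheme = "QUAD", seed = 6)
  res <- run_planner(toy$start, toy$goal, toy$lib, energy_zero(), cfg)
  paths <- extract_paths(res)
  expect_gt(length(paths), 0)
  midnode <- paths[[1]]$nodes[max(1, length(paths[[1]]$nodes) - 1)]
  prox <- reference_proximity(res, list(start = toy$start, goal = toy$goal,
                                        mid = res$tree$conf[[midnode]]))
  expect_lt(unname(prox["start"]), 1e-9)
  expect_lte(prox["goal"], res$config$tol)
  expect_lt(unname(prox["mid"]), 1e-9)
  # no qualifying path: flagged, all values absent
  prox2 <- reference_proximity(res, list(toy$goal), qualify_tol = -1)
  expect_true(all(is.na(prox2)))
  expect_true(isTRUE(attr(prox2, "no_qualifying_paths")))
})

test_that("pseudo-free-energy profiles follow the Boltzmann histogram", {
  vals <- rep(c(0.5, 1.5, 2.5, 3.5), each = 100)
  prof <- pseudo_free_energy(vals, bins = 4, T = 300)
  expect_equal(prof$count, rep(100, 4))
  expect_equal(prof$F, rep(0, 4))            # flat profile, shifted to 0
  # doubling every count leaves the shifted profile unchanged
  prof2 <- pseudo_free_energy(rep(vals, 2), bins = 4, T = 300)
  expect_equal(prof2$F, prof$F)
  # Gaussian samples give a single-minimum, near-quadratic profile
  set.seed(55)
  g <- rnorm(30000)
  pg <- pseudo_free_energy(g, bins = 21, T = 300)
  finite <- is.finite(pg$F) & pg$count > 30
  expect_lt(abs(pg$mid[which.min(pg$F)]), 0.5)
  expect_gt(cor(pg$F[finite], pg$mid[finite]^2), 0.97)
  # analytic check: F ~ kB T x^2 / 2 up to an additive constant
  kBT <- KB_KCAL * 300
  pred <- kBT * pg$mid[finite]^2 / 2
  expect_lt(max(abs((pg$F[finite] - min(pg$F[finite])) - (pred - min(pred)))),
            0.25 * kBT)
  # degenerate: all samples in one bin
  pd <- pseudo_free_energy(rep(1, 10), bins = 3)
  expect_true(isTRUE(attr(pd, "degenerate")))
  expect_error(pseudo_free_energy(numeric(0)), "at least one")
})
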