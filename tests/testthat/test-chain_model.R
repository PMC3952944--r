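test_that("single-residue chain follows the documented anchor convention", {
  cf <- conformation("A", ANGLE_UNDEF, ANGLE_UNDEF)
  geo <- geometry_params()
  xyz <- forward_kinematics(cf, geo)
  expect_equal(nrow(xyz), 4)
  expect_equal(xyz[1, ], c(0, 0, 0))                       # N at origin
  expect_equal(xyz[2, ], c(geo$b_n_ca, 0, 0))              # CA on +x
  expect_equal(xyz[3, 3], 0)                               # C in xy-plane
  expect_gt(xyz[3, 2], 0)                                  # ... positive y
  th <- geo$a_n_ca_c * pi / 180
  expect_equal(sqrt(sum((xyz[3, ] - xyz[2, ])^2)), geo$b_ca_c,
               tolerance = 1e-12)
  expect_equal(xyz[3, 1], geo$b_n_ca - geo$b_ca_c * cos(th),
               tolerance = 1e-12)
})

test_that("forward kinematics and dihedral measurement are mutual inverses", {
  n <- 9
  # canonical helix angles
  cf <- conformation(rep("A", n), rep(-57, n), rep(-47, n))
  ang <- measure_dihedrals(forward_kinematics(cf))
  expect_equal(ang$phi[-1], cf$phi[-1], tolerance = 1e-6)
  expect_equal(ang$psi[-n], cf$psi[-n], tolerance = 1e-6)
  expect_equal(ang$phi[1], ANGLE_UNDEF)
  expect_equal(ang$psi[n], ANGLE_UNDEF)
  # random angles, several seeds
  for (s in 1:5) {
    set.seed(s)
    cf <- rand_conformation(6)
    ang <- measure_dihedrals(forward_kinematics(cf))
    expect_equal(ang$phi[-1], cf$phi[-1], tolerance = 1e-6)
    expect_equal(ang$psi[-6], cf$psi[-6], tolerance = 1e-6)
  }
})

test_that("idealized geometry is conserved for arbitrary dihedrals", {
  geo <- geometry_params()
  for (s in 1:3) {
    set.seed(10 + s)
    xyz <- forward_kinematics(rand_conformation(7), geo)
    g <- measure_geometry(xyz)
    expect_equal(g$n_ca, rep(geo$b_n_ca, 7), tolerance = 1e-6)
    expect_equal(g$ca_c, rep(geo$b_ca_c, 7), tolerance = 1e-6)
    expect_equal(g$c_n, rep(geo$b_c_n, 6), tolerance = 1e-6)
    expect_equal(g$c_o, rep(geo$b_c_o, 7), tolerance = 1e-6)
    expect_equal(g$n_ca_c, rep(geo$a_n_ca_c, 7), tolerance = 1e-6)
    expect_equal(g$ca_c_n, rep(geo$a_ca_c_n, 6), tolerance = 1e-6)
    expect_equal(g$c_n_ca, rep(geo$a_c_n_ca, 6), tolerance = 1e-6)
    expect_equal(g$ca_c_o, rep(geo$a_ca_c_o, 7), tolerance = 1e-6)
  }
})

test_that("coordinates are a pure function of the angles", {
  set.seed(7)
  phi <- runif(5, -180, 180); psi <- runif(5, -180, 180)
  a <- forward_kinematics(conformation(rep("A", 5), phi, psi))
  b <- forward_kinematics(conformation(rep("G", 5), phi, psi))
  expect_identical(as.vector(dist(a)), as.vector(dist(b)))
  expect_identical(a, forward_kinematics(conformation(rep("A", 5), phi, psi)))
})

test_that("torsion sign follows the standard convention", {
  # planar cis arrangement -> 0; trans -> +/-180
  expect_equal(torsion_angle(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, 1, 0)),
               0)
  expect_equal(abs(torsion_angle(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0),
                                 c(-1, -1, 0))), 180)
  # hand-built chiral quadruple vs the independent atan2 formula
  set.seed(99)
  for (k in 1:20) {
    p <- lapply(1:4, function(i) rnorm(3))
    expect_equal(torsion_angle(p[[1]], p[[2]], p[[3]], p[[4]]),
                 torsion_reference(p[[1]], p[[2]], p[[3]], p[[4]]),
                 tolerance = 1e-9)
  }
  # explicit chirality: fourth atom above the plane gives +90
  expect_equal(torsion_angle(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.3, 0),
                             c(2.2, 1.3, 1)), 90, tolerance = 1e-9)
})

test_that("phi/psi agree with an independent structural-biology library", {
  skip_if_not_installed("bio3d")
  set.seed(21)
  cf <- rand_conformation(6)
  xyz <- forward_kinematics(cf)
  # psi_2 = N2-CA2-C2-N3
  v <- bio3d::torsion.xyz(as.vector(t(xyz[c(5, 6, 7, 9), ])))
  expect_equal(unname(v), cf$psi[2], tolerance = 1e-6)
  # phi_2 = C1-N2-CA2-C2
  v <- bio3d::torsion.xyz(as.vector(t(xyz[c(3, 5, 6, 7), ])))
  expect_equal(unname(v), cf$phi[2], tolerance = 1e-6)
})

test_that("missing atoms yield per-residue sentinels, not errors", {
  set.seed(3)
  xyz <- forward_kinematics(rand_conformation(4))
  xyz[6, ] <- NA  # CA of residue 2
  ang <- measure_dihedrals(xyz)
  expect_equal(ang$phi[2], ANGLE_UNDEF)
  expect_equal(ang$psi[2], ANGLE_UNDEF)
  expect_false(ang$phi[4] == ANGLE_UNDEF)  # unaffected residues still defined
})

test_that("invalid inputs are rejected", {
  expect_error(conformation(rep("A", 3), c(999, NaN, 10), c(1, 2, 999)),
               "non-finite")
  cf <- rand_conformation(4)
  cf$phi[3] <- ANGLE_UNDEF
  expect_error(forward_kinematics(cf), "undefined")
  expect_error(measure_dihedrals(matrix(0, 5, 3)))
  expect_error(geometry_params(b_n_ca = -1))
  expect_error(geometry_params(a_n_ca_c = 181))
})
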