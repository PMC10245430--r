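test_that("dihedral angle matches analytic construction and conventions", {
  # planar cis (same side) -> 0; planar trans -> pi
  cis <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(dihedral_angle(cis, 1, 2, 3, 4), 0, tolerance = 1e-12)
  trans <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(-1, 0, 0))
  expect_equal(dihedral_angle(trans, 1, 2, 3, 4), pi, tolerance = 1e-12)

  for (phi_deg in c(60, -60, 175, -120, 1)) {
    X <- butane_coords_with_dihedral(phi_deg * pi / 180)
    expect_equal(dihedral_angle(X, 1, 2, 3, 4), phi_deg * pi / 180,
                 tolerance = 1e-6)
  }

  # collinear reference atom leaves the plane undefined
  bad <- rbind(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0), c(-1, 1, 0))
  expect_error(dihedral_angle(bad, 1, 2, 3, 4), "degenerate|collinear")
})

test_that("dihedral is invariant under proper rigid motion", {
  X <- butane_coords_with_dihedral(1.1)
  set.seed(7)
  for (k in 1:5) {
    Y <- random_rigid_motion(X)
    expect_equal(dihedral_angle(Y, 1, 2, 3, 4), dihedral_angle(X, 1, 2, 3, 4),
                 tolerance = 1e-9)
  }
})

test_that("normalized torsion reduces to the dihedral for a single pair", {
  g <- fix_graph("CCCCC")
  specs <- find_rotatable_bonds(g)
  init <- fix_init("CCCCC")
  for (s in specs) {
    expect_length(s$a_group, 1)
    expect_length(s$b_group, 1)
    expect_equal(normalized_torsion(init$coords, s),
                 dihedral_angle(init$coords, s$a_group, s$i, s$j, s$b_group),
                 tolerance = 1e-12)
  }
})

test_that("normalized torsion shifts by exactly the applied bond rotation", {
  set.seed(11)
  for (smi in c("CCCC", "CCC(F)(F)F", "c1ccccc1CCc1ccccc1")) {
    g <- fix_graph(smi)
    init <- fix_init(smi)
    for (s in find_rotatable_bonds(g)) {
      a0 <- normalized_torsion(init$coords, s)
      for (gamma in runif(5, -pi, pi)) {
        idx <- jside_oracle(g$adjacency, s$i, s$j)
        rot <- rotate_fragment_oracle(init$coords, s$i, s$j, idx, gamma)
        expect_equal(angle_diff(normalized_torsion(rot, s), a0 + gamma), 0,
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("normalized torsion is SE(3)-invariant and flips under reflection", {
  g <- fix_graph("CCC(F)(F)F")
  s <- find_rotatable_bonds(g)[[1]]
  X <- fix_init("CCC(F)(F)F")$coords
  a0 <- normalized_torsion(X, s)
  set.seed(3)
  for (k in 1:5) {
    expect_equal(normalized_torsion(random_rigid_motion(X), s), a0,
                 tolerance = 1e-9)
  }
  Xr <- X; Xr[, 3] <- -Xr[, 3]  # improper transformation
  expect_equal(angle_diff(normalized_torsion(Xr, s), -a0), 0,
               tolerance = 1e-9)
})

test_that("CF3-like symmetric groups do not cancel the weighted sum", {
  g <- fix_graph("CCC(F)(F)F")
  s <- find_rotatable_bonds(g)[[1]]
  init <- fix_init("CCC(F)(F)F")
  set.seed(5)
  for (target in runif(25, -pi, pi)) {
    conf <- set_torsion(init, g, s, target)
    expect_equal(angle_diff(normalized_torsion(conf$coords, s), target), 0,
                 tolerance = 1e-6)
  }
  # degenerate weights (all equal) DO cancel for a symmetric terminal group:
  # the default scheme must not
  w_bad <- matrix(1, length(s$a_group), length(s$b_group))
  w_def <- default_pair_weights(s)
  expect_true(all(w_def > 0))
  expect_gt(length(unique(as.numeric(w_def))), 1)
  expect_silent(normalized_torsion(init$coords, s, w_def))
  expect_true(is.finite(normalized_torsion(init$coords, s)))
  rm(w_bad)
})

test_that("set_torsion hits its target and preserves rigid fragments", {
  g <- fix_graph("CCCC")
  s <- find_rotatable_bonds(g)[[1]]
  init <- fix_init("CCCC")

  same <- set_torsion(init, g, s, normalized_torsion(init$coords, s))
  expect_equal(same$coords, init$coords, tolerance = 1e-9)

  set.seed(17)
  side_j <- jside_oracle(g$adjacency, s$i, s$j)
  side_i <- setdiff(seq_len(g$n), side_j)
  for (target in runif(100, -pi, pi)) {
    conf <- set_torsion(init, g, s, target)
    expect_equal(angle_diff(normalized_torsion(conf$coords, s), target), 0,
                 tolerance = 1e-6)
    for (side in list(side_i, side_j)) {
      d0 <- dist(init$coords[side, , drop = FALSE])
      d1 <- dist(conf$coords[side, , drop = FALSE])
      expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
    }
  }
})

test_that("sequential torsion sets on different bonds commute", {
  g <- fix_graph("CCCCC")
  specs <- find_rotatable_bonds(g)
  init <- fix_init("CCCCC")
  set.seed(23)
  for (k in 1:10) {
    t1 <- runif(1, -pi, pi); t2 <- runif(1, -pi, pi)
    c12 <- set_torsion(set_torsion(init, g, specs[[1]], t1), g, specs[[2]], t2)
    c21 <- set_torsion(set_torsion(init, g, specs[[2]], t2), g, specs[[1]], t1)
    for (conf in list(c12, c21)) {
      expect_equal(angle_diff(normalized_torsion(conf$coords, specs[[1]]), t1),
                   0, tolerance = 1e-6)
      expect_equal(angle_diff(normalized_torsion(conf$coords, specs[[2]]), t2),
                   0, tolerance = 1e-6)
    }
  }
})

test_that("rotating a ring bond is refused", {
  g <- fix_graph("c1ccccc1")
  bd <- g$bond_df[1, ]
  fake <- structure(list(i = bd$i, j = bd$j,
                         a_group = setdiff(which(g$adjacency[bd$i, ] == 1),
                                           bd$j),
                         b_group = setdiff(which(g$adjacency[bd$j, ] == 1),
                                           bd$i),
                         sequence_index = 0L), class = "tc_torsion")
  init <- fix_init("c1ccccc1")
  expect_error(set_torsion(init, g, fake, 1), "bridge|ring")
})

test_that("apply_torsion_sequence round-trips and is idempotent", {
  g <- fix_graph("CCCCC")
  specs <- find_rotatable_bonds(g)
  init <- fix_init("CCCCC")

  expect_identical(apply_torsion_sequence(init, g, list(), numeric(0))$coords,
                   init$coords)

  targets <- c(60, 180) * pi / 180
  c1 <- apply_torsion_sequence(init, g, specs, targets)
  expect_equal(angle_diff(measure_torsions(c1, specs), targets),
               rep(0, 2), tolerance = 1e-5, ignore_attr = TRUE)
  c2 <- apply_torsion_sequence(c1, g, specs, targets)
  expect_equal(c2$coords, c1$coords, tolerance = 1e-6)

  # angles measured from a reference conformer reproduce its geometry up to
  # the (zero, here: same initial) bond-length/angle residual
  ref <- apply_torsion_sequence(init, g, specs, c(-1.2, 0.7))
  back <- apply_torsion_sequence(init, g, specs, measure_torsions(ref, specs))
  expect_equal(conf_rmsd(ref, back, g, symmetry = FALSE), 0,
               tolerance = 1e-6)
})
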