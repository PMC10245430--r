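test_that("heavy-atom RMSD obeys identity, rotation and symmetry contracts", {
  g <- fix_graph("CCCCC")
  init <- fix_init("CCCCC")
  expect_equal(conf_rmsd(init, init, g), 0, tolerance = 1e-12)

  set.seed(12)
  moved <- random_rigid_motion(init$coords)
  expect_equal(conf_rmsd(init$coords, moved, g), 0, tolerance = 1e-6)

  specs <- find_rotatable_bonds(g)
  other <- apply_torsion_sequence(init, g, specs, c(1, -2))
  expect_equal(conf_rmsd(init, other, g), conf_rmsd(other, init, g),
               tolerance = 1e-9)
  expect_error(conf_rmsd(init$coords, init$coords[1:3, ], g), "atom count")
})

test_that("automorphism minimization recognizes relabeled symmetric
           structures", {
  benz <- fix_graph("c1ccccc1")
  binit <- fix_init("c1ccccc1")
  rotated <- binit$coords[c(2:6, 1), ]  # ring-rotation relabeling
  expect_equal(conf_rmsd(binit$coords, rotated, benz, symmetry = TRUE), 0,
               tolerance = 1e-6)

  # flipping one phenyl of 1,2-diphenylethane by pi maps the ring onto
  # itself only through the ortho/meta swap automorphism
  dpe <- fix_graph("c1ccccc1CCc1ccccc1")
  dinit <- fix_init("c1ccccc1CCc1ccccc1")
  specs <- find_rotatable_bonds(dpe)
  phenyl <- specs[[which.max(vapply(specs, function(s)
    max(length(s$a_group), length(s$b_group)), numeric(1)))]]
  cur <- normalized_torsion(dinit$coords, phenyl)
  flipped <- set_torsion(dinit, dpe, phenyl, wrap_angle(cur + pi))
  plain <- conf_rmsd(dinit, flipped, dpe, symmetry = FALSE)
  sym <- conf_rmsd(dinit, flipped, dpe, symmetry = TRUE)
  expect_lt(sym, 0.1)
  expect_gt(plain, sym)
})

test_that("coverage/matching matches the brute-force oracle", {
  g <- fix_graph("CCCCC")
  specs <- find_rotatable_bonds(g)
  init <- fix_init("CCCCC")
  set.seed(99)
  for (trial in 1:20) {
    Sg <- random_pentane_ensemble(sample(1:10, 1), g, specs, init)
    Sr <- random_pentane_ensemble(sample(1:10, 1), g, specs, init)
    delta <- runif(1, 0.2, 2)
    m <- coverage_matching(Sg, Sr, g, delta = delta, symmetry = FALSE)
    o_r <- cov_mat_oracle(Sg, Sr, delta)
    o_p <- cov_mat_oracle(Sr, Sg, delta)
    expect_equal(m$cov_r, o_r$cov, tolerance = 1e-9)
    expect_equal(m$mat_r, o_r$mat, tolerance = 1e-9)
    expect_equal(m$cov_p, o_p$cov, tolerance = 1e-9)
    expect_equal(m$mat_p, o_p$mat, tolerance = 1e-9)
  }
})

test_that("identical ensembles give perfect coverage and zero matching", {
  g <- fix_graph("CCCC")
  init <- fix_init("CCCC")
  specs <- find_rotatable_bonds(g)
  S <- lapply(c(-1, 0.5, 2), function(t)
    apply_torsion_sequence(init, g, specs, t)$coords)
  m <- coverage_matching(S, S, g)
  expect_equal(m$cov_r, 100)
  expect_equal(m$cov_p, 100)
  expect_equal(m$mat_r, 0, tolerance = 1e-9)
  expect_equal(m$mat_p, 0, tolerance = 1e-9)
})

test_that("a single distant generated conformer yields zero coverage and
           its RMSD as matching", {
  g <- fix_graph("CCCC")
  init <- fix_init("CCCC")
  specs <- find_rotatable_bonds(g)
  ref <- apply_torsion_sequence(init, g, specs, pi)
  gen <- apply_torsion_sequence(init, g, specs, 0)
  r0 <- conf_rmsd(ref, gen, g)
  m <- coverage_matching(list(gen), list(ref), g, delta = min(1.25, r0 / 2))
  expect_equal(m$cov_r, 0)
  expect_equal(m$mat_r, r0, tolerance = 1e-12)
})

test_that("coverage is monotone in delta and in ensemble growth", {
  g <- fix_graph("CCCCC")
  specs <- find_rotatable_bonds(g)
  init <- fix_init("CCCCC")
  set.seed(5)
  Sg <- random_pentane_ensemble(5, g, specs, init)
  Sr <- random_pentane_ensemble(6, g, specs, init)
  deltas <- c(0.1, 0.5, 1, 1.5, 3)
  covs <- vapply(deltas, function(d)
    coverage_matching(Sg, Sr, g, delta = d)$cov_r, numeric(1))
  expect_true(all(diff(covs) >= 0))
  mats <- vapply(deltas, function(d)
    coverage_matching(Sg, Sr, g, delta = d)$mat_r, numeric(1))
  expect_equal(max(mats) - min(mats), 0, tolerance = 1e-12)

  extra <- random_pentane_ensemble(1, g, specs, init)
  m0 <- coverage_matching(Sg, Sr, g)
  m1 <- coverage_matching(c(Sg, extra), Sr, g)
  expect_gte(m1$cov_r, m0$cov_r)
  expect_lte(m1$mat_r, m0$mat_r)

  expect_error(coverage_matching(list(), Sr, g), "non-empty")
})

test_that("the SVD superposition agrees with an external reference
           implementation", {
  skip_if_not_installed("bio3d")
  g <- fix_graph("CCCCC")
  specs <- find_rotatable_bonds(g)
  init <- fix_init("CCCCC")
  set.seed(41)
  for (k in 1:10) {
    A <- apply_torsion_sequence(init, g, specs, runif(2, -pi, pi))$coords
    B <- apply_torsion_sequence(init, g, specs, runif(2, -pi, pi))$coords
    ours <- conf_rmsd(A, B, g, symmetry = FALSE)
    ref <- bio3d::rmsd(as.numeric(t(A)), as.numeric(t(B)), fit = TRUE)
    # bio3d rounds its result to 3 decimals
    expect_equal(ours, ref, tolerance = 2e-3)
  }
})
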