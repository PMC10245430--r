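test_that("atomic self-attention updates have the expected shape and
           attention rows normalize", {
  m <- tiny_model("full")
  g <- fix_graph("CCCC")
  H <- update_atoms(m, g)
  expect_equal(dim(H), c(4, m$config$hidden))
  expect_true(all(is.finite(H)))

  preds <- model_predict(m, g, energy = 0.5, n_samples = 1, seed = 1,
                         keep_attention = TRUE)
  attn <- attr(preds, "attention")
  expect_gt(length(attn), 0)
  for (A in attn) {
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
  }
})

test_that("unmasked self-attention is permutation-equivariant", {
  # position mode "none": representations depend only on atom features, so
  # the update must commute with any row permutation
  m <- tiny_model("none")
  g <- fix_graph("c1ccccc1CCc1ccccc1")
  H <- update_atoms(m, g)
  set.seed(9)
  perm <- sample(g$n)
  g2 <- g
  g2$atom_features <- g$atom_features[perm, , drop = FALSE]
  H2 <- update_atoms(m, g2)
  expect_equal(H2, H[perm, , drop = FALSE], tolerance = 1e-5)
})

test_that("torsion readout averages terminal groups correctly", {
  m <- tiny_model("full")
  g <- fix_graph("CCC(F)(F)F")
  specs <- find_rotatable_bonds(g)
  tau0 <- readout_torsions(m, g, specs)
  expect_equal(dim(tau0), c(1, m$config$hidden))

  # the three fluorines are automorphic AND share identical adjacency rows,
  # so their updated representations coincide: the b-group mean equals any
  # single member's representation
  H <- update_atoms(m, g)
  f_idx <- which(g$elements == "F")
  expect_length(f_idx, 3)
  expect_equal(H[f_idx[1], ], H[f_idx[2], ], tolerance = 1e-10)
  expect_equal(colMeans(H[f_idx, , drop = FALSE]), H[f_idx[1], ],
               tolerance = 1e-10)

  but <- fix_graph("CCCC")
  tb <- readout_torsions(m, but, find_rotatable_bonds(but))
  expect_equal(dim(tb), c(1, m$config$hidden))
})

test_that("encoder noise is seed-deterministic and optional", {
  m <- tiny_model("full")
  g <- fix_graph("CCCCC")
  tau0 <- readout_torsions(m, g, find_rotatable_bonds(g))
  e1 <- model_encode(m, tau0, noise_std = 0)
  e2 <- model_encode(m, tau0, noise_std = 0)
  expect_identical(e1, e2)
  n1 <- model_encode(m, tau0, noise_std = 5, seed = 4)
  n2 <- model_encode(m, tau0, noise_std = 5, seed = 4)
  n3 <- model_encode(m, tau0, noise_std = 5, seed = 5)
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
})

test_that("decoder output is causal, unit-norm and wrapped", {
  m <- tiny_model("full")
  g <- fix_graph("c1ccccc1CCc1ccccc1")
  specs <- find_rotatable_bonds(g)
  L <- length(specs)
  expect_equal(L, 3)
  tau0 <- readout_torsions(m, g, specs)
  mem <- model_encode(m, tau0, noise_std = 0)

  teacher <- c(0.5, -2.0, 2.5)
  dec <- decode_autoregressive(m, mem, 1.0, teacher)
  expect_length(dec$angles, L)
  expect_true(all(dec$angles > -pi & dec$angles <= pi))
  expect_equal(rowSums(dec$sincos^2), rep(1, L), tolerance = 1e-6)

  set.seed(31)
  for (p in 1:(L - 1)) {
    for (r in 1:10) {
      pert <- teacher
      pert[(p + 1):L] <- runif(L - p, -pi, pi)
      dec_p <- decode_autoregressive(m, mem, 1.0, pert)
      expect_identical(dec_p$angles[1:p], dec$angles[1:p])
    }
  }
  expect_error(decode_autoregressive(m, mem, 1.0, c(1, 2)), "length")
})

test_that("prediction is seed-reproducible and graph-only", {
  m <- model_init(tiny_config(noise_std = 5))
  g <- fix_graph("CCCCC")
  p1 <- model_predict(m, g, energy = 1, n_samples = 3, seed = 11)
  p2 <- model_predict(m, g, energy = 1, n_samples = 3, seed = 11)
  expect_identical(p1, p2)
  p3 <- model_predict(m, g, energy = 1, n_samples = 3, seed = 12)
  expect_false(identical(p1, p3))
  # samples differ among themselves only through the encoder noise
  expect_false(identical(p1[[1]], p1[[2]]))

  # predictions are a function of the 2D graph only: a graph rebuilt from a
  # rigidly transformed conformer record gives bitwise-equal output
  init <- fix_init("CCCCC")
  set.seed(2)
  moved <- conformer(random_rigid_motion(init$coords), 0, "reference")
  tmp <- tempfile(fileext = ".sdf")
  write_conformer_sdf(g, list(moved), tmp)
  g2 <- read_conformer_sdf(tmp)$graph
  p4 <- model_predict(m, g2, energy = 1, n_samples = 3, seed = 11)
  expect_identical(p1, p4)
  unlink(tmp)
})

test_that("rigid molecules give empty predictions with a warning", {
  m <- tiny_model("full")
  g <- fix_graph("c1ccccc1")
  expect_warning(p <- model_predict(m, g, energy = 0, n_samples = 2),
                 "no rotatable")
  expect_length(p, 2)
  expect_identical(p[[1]], numeric(0))
})

test_that("checkpoints round-trip through disk", {
  m <- tiny_model("full")
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  g <- fix_graph("CCCC")
  expect_identical(model_predict(m, g, energy = 0.3, seed = 5),
                   model_predict(m2, g, energy = 0.3, seed = 5))
  unlink(path)
})
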