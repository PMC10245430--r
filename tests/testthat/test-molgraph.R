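test_that("SMILES parsing yields the expected heavy-atom graphs", {
  but <- fix_graph("CCCC")
  expect_equal(but$n, 4)
  expect_equal(nrow(but$bond_df), 3)
  expect_equal(but$nH, c(3, 2, 2, 3))

  benz <- fix_graph("c1ccccc1")
  expect_equal(benz$n, 6)
  expect_true(all(benz$aromatic_atoms))
  expect_true(all(benz$bond_df$aromatic))
  expect_true(all(benz$bond_df$ring))

  ac <- fix_graph("CC(=O)O")
  expect_equal(rowSums(ac$adjacency), ac$degree)
  expect_equal(max(ac$degree), 3)  # central carbon
})

test_that("adjacency is symmetric with zero diagonal, features fixed-width", {
  for (smi in fixture_suite()$smiles) {
    g <- fix_graph(smi)
    expect_identical(g$adjacency, t(g$adjacency))
    expect_true(all(diag(g$adjacency) == 0))
    expect_equal(ncol(g$atom_features), 40)
    if (nrow(g$bond_df) > 0) expect_equal(ncol(g$bond_features), 10)
  }
})

test_that("atom featurization encodes aromaticity, symmetry and H counts", {
  benz <- fix_graph("c1ccccc1")
  # all six carbons identical, aromatic bit set
  expect_equal(unique(round(benz$atom_features, 10)),
               benz$atom_features[1, , drop = FALSE], ignore_attr = TRUE)
  f <- featurize_atom(list(element = "C", degree = 2, charge = 0,
                           hybridization = "sp2", aromatic = TRUE, nH = 1,
                           in_ring = TRUE))
  expect_equal(f, benz$atom_features[1, ], ignore_attr = TRUE)

  px <- fix_graph("Cc1ccc(C)cc1")
  methyls <- which(px$degree == 1)
  expect_length(methyls, 2)
  expect_equal(px$atom_features[methyls[1], ], px$atom_features[methyls[2], ])

  # methane carbon: degree-0 heavy-neighbor slot and 4 attached hydrogens
  fm <- featurize_atom(list(element = "C", degree = 0, charge = 0,
                            hybridization = "sp3", aromatic = FALSE,
                            nH = 4, in_ring = FALSE))
  expect_equal(fm[17], 1)        # degree one-hot, position 0
  expect_equal(fm[36], 1)        # attached-H one-hot, position 4
  f_el <- featurize_atom(list(element = "Xx", degree = 1, charge = 0,
                              hybridization = "sp3", aromatic = FALSE,
                              nH = 0, in_ring = FALSE))
  expect_equal(f_el[16], 1)  # unknown element maps to "other"
})

test_that("rotatable-bond enumeration matches the non-ring single-bond rule", {
  expect_length(find_rotatable_bonds(fix_graph("CCCC")), 1)
  expect_length(find_rotatable_bonds(fix_graph("c1ccccc1")), 0)

  pent <- find_rotatable_bonds(fix_graph("CCCCC"))
  expect_length(pent, 2)
  expect_equal(vapply(pent, `[[`, integer(1), "sequence_index"), 0:1)
  # hand enumeration: the two interior C-C bonds (2-3) and (3-4)
  bonds <- lapply(pent, function(s) sort(c(s$i, s$j)))
  expect_setequal(vapply(bonds, paste, character(1), collapse = "-"),
                  c("2-3", "3-4"))

  for (s in find_rotatable_bonds(fix_graph("c1ccccc1CCc1ccccc1"))) {
    expect_gt(length(s$a_group), 0)
    expect_gt(length(s$b_group), 0)
  }
})

test_that("every torsion bond is a bridge", {
  for (smi in flexible_suite()$smiles) {
    g <- fix_graph(smi)
    for (s in find_rotatable_bonds(g)) {
      adj <- g$adjacency
      adj[s$i, s$j] <- adj[s$j, s$i] <- 0L
      reach <- jside_oracle(adj, 0, s$j)  # plain BFS from j
      expect_false(s$i %in% reach)
      expect_equal(sort(c(reach, jside_oracle(adj, 0, s$i))), seq_len(g$n))
    }
  }
})

test_that("canonical torsion ordering is independent of atom numbering", {
  g1 <- fix_graph("CCCCC")
  # same molecule written with a different atom order
  g2 <- read_molecule("C(CC)CC")
  t1 <- find_rotatable_bonds(g1)
  t2 <- find_rotatable_bonds(g2)
  expect_equal(length(t1), length(t2))
  # match atoms between the two numberings through canonical rank keys
  key1 <- g1$rank_keys; key2 <- g2$rank_keys
  expect_setequal(key1, key2)
  for (k in seq_along(t1)) {
    expect_equal(sort(key1[c(t1[[k]]$i, t1[[k]]$j)]),
                 sort(key2[c(t2[[k]]$i, t2[[k]]$j)]))
  }
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(read_molecule("CC.CC"), "fragment")
  expect_error(read_molecule("this-is-not-a-molecule["), "parse|invalid")
})
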