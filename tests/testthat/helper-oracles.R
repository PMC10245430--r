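# Independent oracles shared by the evaluation and acceptance tests.

# Independent RMSD oracle: Horn's quaternion method for optimal proper
# superposition (different algorithm from the package's SVD route).
quaternion_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  M <- crossprod(B, A)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(0, msd))
}

# Brute-force coverage/matching oracle: explicit double loops.
cov_mat_oracle <- function(Sg, Sr, delta) {
  nr <- length(Sr); ng <- length(Sg)
  covered <- 0; mat_sum <- 0
  for (r in seq_len(nr)) {
    best <- Inf
    for (g in seq_len(ng)) {
      d <- quaternion_rmsd(Sr[[r]], Sg[[g]])
      if (d < best) best <- d
    }
    if (best < delta) covered <- covered + 1
    mat_sum <- mat_sum + best
  }
  list(cov = 100 * covered / nr, mat = mat_sum / nr)
}

random_pentane_ensemble <- function(n, g, specs, init) {
  lapply(seq_len(n), function(k) {
    apply_torsion_sequence(init, g, specs, runif(2, -pi, pi))$coords
  })
}

write_tiny_train_config <- function(path, extra = list()) {
  cfg <- c(list(hidden = 16, heads = 2, atom_layers = 1, encoder_layers = 1,
                decoder_layers = 1, noise_std = 0, epochs = 3, lr = 1e-3,
                train_noise_std = 0), extra)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE)
  path
}
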