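# Shared fixtures: memoized graphs/embeddings and small independent oracles.

.graph_cache <- new.env(parent = emptyenv())

fix_graph <- function(smiles) {
  g <- .graph_cache[[smiles]]
  if (is.null(g)) {
    g <- read_molecule(smiles)
    .graph_cache[[smiles]] <- g
  }
  g
}

fix_init <- function(smiles, seed = 1) embed_initial(smiles, seed)

tiny_config <- function(...) {
  args <- list(hidden = 16, heads = 2, atom_layers = 1, encoder_layers = 1,
               decoder_layers = 1, noise_std = 0, seed = 42)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(model_config, args)
}

.tiny_model_cache <- new.env(parent = emptyenv())
tiny_model <- function(pos_mode = "full") {
  m <- .tiny_model_cache[[pos_mode]]
  if (is.null(m)) {
    m <- model_init(tiny_config(pos_mode = pos_mode))
    .tiny_model_cache[[pos_mode]] <- m
  }
  m
}

# Independent z-matrix style placement: position atom d given three
# reference atoms (a, b, c), a bond length r(c-d), angle theta(b-c-d) and
# dihedral phi(a-b-c-d). Used to construct coordinates with known dihedrals
# without any package geometry code.
zmat_place <- function(a, b, c, r, theta, phi) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-r * cos(theta), r * cos(phi) * sin(theta),
          r * sin(phi) * sin(theta))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Four-carbon chain with prescribed central dihedral phi (radians).
butane_coords_with_dihedral <- function(phi, r = 1.54, theta = 111 * pi / 180) {
  p1 <- c(0, 0, 0)
  p2 <- c(r, 0, 0)
  p3 <- p2 + c(-r * cos(theta), r * sin(theta), 0)
  p4 <- zmat_place(p1, p2, p3, r, theta, phi)
  rbind(p1, p2, p3, p4)
}

# Independent fragment rotation (used by the equivariance checks): rotate
# the atoms in `idx` by gamma about the axis from atom i to atom j,
# using an explicit axis-angle matrix written out here.
rotate_fragment_oracle <- function(coords, i, j, idx, gamma) {
  u <- coords[j, ] - coords[i, ]
  u <- u / sqrt(sum(u^2))
  cg <- cos(gamma); sg <- sin(gamma)
  R <- matrix(c(
    cg + u[1]^2 * (1 - cg), u[1] * u[2] * (1 - cg) - u[3] * sg,
    u[1] * u[3] * (1 - cg) + u[2] * sg,
    u[2] * u[1] * (1 - cg) + u[3] * sg, cg + u[2]^2 * (1 - cg),
    u[2] * u[3] * (1 - cg) - u[1] * sg,
    u[3] * u[1] * (1 - cg) - u[2] * sg,
    u[3] * u[2] * (1 - cg) + u[1] * sg, cg + u[3]^2 * (1 - cg)),
    3, 3, byrow = TRUE)
  anchor <- coords[i, ]
  coords[idx, ] <- sweep(sweep(coords[idx, , drop = FALSE], 2, anchor) %*%
                           t(R), 2, anchor, `+`)
  coords
}

# j-side fragment of a bridge bond, by BFS on the adjacency matrix
# (independent of the package's fragment code).
jside_oracle <- function(adj, i, j) {
  n <- nrow(adj)
  seen <- rep(FALSE, n); seen[j] <- TRUE
  queue <- j
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(adj[v, ] == 1)
    if (v == j) nb <- setdiff(nb, i)
    for (w in nb) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  which(seen)
}

# Flexible fixture molecules (>= 1 rotatable bond)
flexible_suite <- function() {
  s <- fixture_suite()
  s[s$n_torsions > 0, ]
}
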