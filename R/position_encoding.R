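# Graph position encodings for atoms. Conventional message passing cannot
# separate symmetric nodes more than a few hops apart, so each atom carries a
# three-part position vector
#     pos = pos_wl || pos_d || pos_a
# built from (1) a learned embedding of its Weisfeiler-Lehman label,
# (2) a learned embedding of its degree, and (3) a learned linear projection
# of its (zero-padded) adjacency row. The vector is concatenated in front of
# the self-attention stack, replacing the sequence-position scalar of a
# text transformer. Three ablation modes are supported: "none" (no position
# vector), "learnable" (a plain index-based embedding), and "full".

#' Weisfeiler-Lehman node labels
#'
#' Standard 1-WL color refinement seeded by (element, degree). After each
#' iteration a node's color is the hash of its previous color and the sorted
#' multiset of its neighbors' colors. Hashing is a stable polynomial string
#' hash, so labels are identical across runs and platforms.
#'
#' @param graph `tc_molgraph`.
#' @param iterations number of refinement rounds (>= 1). Three rounds cover
#'   symmetry radii beyond the reach of ordinary message passing.
#' @return integer vector of per-node labels (hash values); nodes with the
#'   same topological environment share a label.
#' @export
wl_labels <- function(graph, iterations = 3) {
  stopifnot(iterations >= 1)
  color <- sprintf("%s|%d", graph$elements, graph$degree)
  for (it in seq_len(iterations)) {
    color <- vapply(seq_len(graph$n), function(v) {
      paste0(color[v], "{",
             paste(sort(color[graph$adj_list[[v]]]), collapse = ";"), "}")
    }, character(1))
  }
  as.integer(stable_hash(color))
}

wl_buckets <- function(graph, iterations, n_buckets) {
  (wl_labels(graph, iterations) %% n_buckets) + 1L
}

padded_adjacency <- function(graph, max_atoms) {
  if (graph$n > max_atoms) {
    stop("molecule has ", graph$n, " heavy atoms; the position encoder is ",
         "configured for at most ", max_atoms,
         " (raise max_atoms in the model config)")
  }
  out <- matrix(0, graph$n, max_atoms)
  out[, seq_len(graph$n)] <- graph$adjacency
  out
}

pos_width <- function(config) {
  switch(config$pos_mode,
         none = 0L,
         learnable = as.integer(config$d_wl + config$d_deg + config$d_adj),
         full = as.integer(config$d_wl + config$d_deg + config$d_adj))
}

# Plain-numeric position matrix (n x P) given a parameter list; the training
# path goes through the autodiff equivalent in network.R.
#' Build the position vectors for every atom
#'
#' @param graph `tc_molgraph`.
#' @param model a `tc_model` (provides the learned tables and config).
#' @return numeric matrix n x P (P = 0 in the `"none"` ablation mode).
#' @export
build_position_matrix <- function(graph, model) {
  config <- model$config
  p <- model$params
  mode <- config$pos_mode
  if (mode == "none") return(matrix(0, graph$n, 0))
  if (mode == "learnable") {
    if (graph$n > config$max_atoms) {
      stop("molecule exceeds max_atoms = ", config$max_atoms)
    }
    return(p$E_idx[seq_len(graph$n), , drop = FALSE])
  }
  wb <- wl_buckets(graph, config$wl_iterations, config$wl_buckets)
  pos_wl <- p$E_wl[wb, , drop = FALSE]
  pos_d <- p$E_deg[pmin(graph$degree, 6) + 1L, , drop = FALSE]
  pos_a <- padded_adjacency(graph, config$max_atoms) %*% p$W_adj
  cbind(pos_wl, pos_d, pos_a)
}

#' Initial atom representation: features with position vector appended
#'
#' @param graph `tc_molgraph`.
#' @param model a `tc_model`.
#' @return numeric matrix n x (F_a + P).
#' @export
initial_atom_representation <- function(graph, model) {
  cbind(graph$atom_features, build_position_matrix(graph, model))
}

# Sinusoidal encoding of sequence positions (used for decoder angle tokens).
sinusoidal_encoding <- function(positions, d) {
  out <- matrix(0, length(positions), d)
  for (k in seq_len(d)) {
    i <- (k - 1) %/% 2
    rate <- 1 / 10000^(2 * i / d)
    out[, k] <- if (k %% 2 == 1) sin(positions * rate) else
      cos(positions * rate)
  }
  out
}
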