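# Ensemble evaluation: heavy-atom best-fit RMSD minimized over graph
# automorphisms, and the coverage/matching (COV/MAT) metrics over generated
# vs. reference conformer sets.

graph_automorphisms <- function(graph, max_automorphisms = 10000) {
  g <- molgraph_igraph(graph)
  colors <- match(graph$elements, unique(graph$elements))
  maps <- igraph::graph.get.isomorphisms.vf2(
    g, g, vertex.color1 = colors, vertex.color2 = colors)
  perms <- lapply(maps, function(m) as.integer(m))
  if (length(perms) > max_automorphisms) {
    warning("molecule has ", length(perms), " automorphisms; using the ",
            "first ", max_automorphisms)
    perms <- perms[seq_len(max_automorphisms)]
  }
  perms
}

#' Heavy-atom RMSD between two conformers
#'
#' Root-mean-square deviation after optimal (Kabsch) superposition, by
#' default minimized over the graph automorphisms of the molecule (colored
#' by element), so topologically equivalent atoms — a flipped phenyl ring, a
#' rotated CF3 — do not inflate the deviation.
#'
#' @param conf_a,conf_b `tc_conformer` or coordinate matrices (same atom
#'   count and order as `graph`).
#' @param graph `tc_molgraph`; required for `symmetry = TRUE`.
#' @param symmetry minimize over graph automorphisms (default TRUE).
#' @param max_automorphisms cap on enumerated automorphisms.
#' @return RMSD in Angstrom.
#' @export
conf_rmsd <- function(conf_a, conf_b, graph = NULL, symmetry = TRUE,
                      max_automorphisms = 10000) {
  A <- if (inherits(conf_a, "tc_conformer")) conf_a$coords else conf_a
  B <- if (inherits(conf_b, "tc_conformer")) conf_b$coords else conf_b
  if (nrow(A) != nrow(B)) {
    stop("conformers have different atom counts: ", nrow(A), " vs ", nrow(B))
  }
  if (!symmetry || is.null(graph)) return(kabsch_rmsd(A, B))
  stopifnot(nrow(A) == graph$n)
  perms <- graph_automorphisms(graph, max_automorphisms)
  min(vapply(perms, function(p) kabsch_rmsd(A, B[p, , drop = FALSE]),
             numeric(1)))
}

#' Coverage and matching metrics for a generated ensemble
#'
#' Recall-side scores: COV-R is the percentage of reference conformers whose
#' minimum RMSD to the generated set is strictly below `delta`; MAT-R is the
#' mean over references of that minimum RMSD. The precision-side duals COV-P
#' and MAT-P are the same quantities with the two sets swapped.
#'
#' @param S_g list of generated conformers (`tc_conformer`/matrices).
#' @param S_r list of reference conformers.
#' @param graph `tc_molgraph` of the molecule.
#' @param delta coverage threshold in Angstrom (default 1.25).
#' @param symmetry use symmetry-aware RMSD (default TRUE).
#' @return object of class `tc_metrics`: `cov_r`, `mat_r`, `cov_p`, `mat_p`,
#'   `delta`, and the |S_r| x |S_g| `pairwise_rmsd` matrix.
#' @export
coverage_matching <- function(S_g, S_r, graph, delta = 1.25,
                              symmetry = TRUE) {
  if (length(S_g) == 0 || length(S_r) == 0) {
    stop("both conformer sets must be non-empty")
  }
  M <- matrix(0, length(S_r), length(S_g))
  for (r in seq_along(S_r)) {
    for (g in seq_along(S_g)) {
      M[r, g] <- conf_rmsd(S_r[[r]], S_g[[g]], graph, symmetry)
    }
  }
  min_r <- apply(M, 1, min)   # per reference
  min_g <- apply(M, 2, min)   # per generated
  structure(list(
    cov_r = 100 * mean(min_r < delta),
    mat_r = mean(min_r),
    cov_p = 100 * mean(min_g < delta),
    mat_p = mean(min_g),
    delta = delta,
    symmetry = symmetry,
    pairwise_rmsd = M
  ), class = "tc_metrics")
}

#' @export
print.tc_metrics <- function(x, ...) {
  cat(sprintf(paste0("<tc_metrics> delta = %.2f A\n",
                     "  COV-R %6.2f %%   MAT-R %.4f A\n",
                     "  COV-P %6.2f %%   MAT-P %.4f A\n"),
              x$delta, x$cov_r, x$mat_r, x$cov_p, x$mat_p))
  invisible(x)
}
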