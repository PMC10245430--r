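# 3D torsion geometry: dihedral measurement, the normalized torsion angle
# (a terminal-atom-independent summary of all dihedrals around one rotatable
# bond), dihedral resetting by rigid fragment rotation, and conformer
# reconstruction from a predicted angle sequence.

#' Construct a conformer object
#'
#' @param coords numeric matrix (heavy atoms x 3), Angstrom.
#' @param relative_energy relative energy in kcal/mol (0 = lowest-energy
#'   member of its ensemble).
#' @param source_tag one of `"reference"`, `"initial"`, `"generated"`.
#' @return object of class `tc_conformer`.
#' @export
conformer <- function(coords, relative_energy = 0,
                      source_tag = c("reference", "initial", "generated")) {
  source_tag <- match.arg(source_tag)
  stopifnot(is.matrix(coords), ncol(coords) == 3, relative_energy >= 0)
  structure(list(coords = unname(coords),
                 relative_energy = relative_energy,
                 source_tag = source_tag),
            class = "tc_conformer")
}

#' @export
print.tc_conformer <- function(x, ...) {
  cat(sprintf("<tc_conformer:%s> %d atoms, dE = %.3f kcal/mol\n",
              x$source_tag, nrow(x$coords), x$relative_energy))
  invisible(x)
}

#' Signed dihedral angle
#'
#' IUPAC sign convention: looking down the i->j axis, the angle is positive
#' when the far bond j->b is rotated clockwise from the near bond i->a.
#' Cis (eclipsed, same side) is 0; trans is \eqn{\pi}.
#'
#' @param coords n x 3 coordinate matrix.
#' @param a,i,j,b atom indices; a-i, i-j, j-b must be bonded in the caller's
#'   graph (not checked here).
#' @return signed dihedral in \eqn{(-\pi, \pi]}, radians.
#' @export
dihedral_angle <- function(coords, a, i, j, b) {
  stopifnot(length(unique(c(a, i, j, b))) == 4)
  b0 <- coords[a, ] - coords[i, ]
  b1 <- coords[j, ] - coords[i, ]
  b2 <- coords[b, ] - coords[j, ]
  nb1 <- sqrt(sum(b1^2))
  if (nb1 < 1e-9) stop("degenerate geometry: i and j coincide")
  b1u <- b1 / nb1
  v <- b0 - sum(b0 * b1u) * b1u
  w <- b2 - sum(b2 * b1u) * b1u
  if (sqrt(sum(v^2)) < 1e-9 || sqrt(sum(w^2)) < 1e-9) {
    stop("degenerate geometry: collinear atoms leave the dihedral undefined")
  }
  x <- sum(v * w)
  y <- sum(crossprod_vec(b1u, v) * w)
  wrap_angle(atan2(y, x))
}

crossprod_vec <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Default terminal-pair weights for the normalized torsion angle
#'
#' One strictly positive weight per terminal-atom pair \eqn{(a_m, b_n)}.
#' Distinct deterministic weights \eqn{c_{mn} = 2^{-(m+n)}} (with m, n the
#' 1-based positions within the canonically ranked terminal groups) prevent
#' the per-pair \eqn{(\cos, \sin)} vectors from cancelling under symmetric
#' geometries such as CF3 groups, which a single shared constant cannot.
#'
#' @param spec a `tc_torsion`.
#' @return matrix |a_group| x |b_group| of weights.
#' @export
default_pair_weights <- function(spec) {
  m <- length(spec$a_group); n <- length(spec$b_group)
  outer(seq_len(m), seq_len(n), function(mm, nn) 2^-(mm + nn))
}

#' Normalized torsion angle of a rotatable bond
#'
#' Summarizes every dihedral \eqn{\Delta_{a_m b_n}} around bond (i, j) into a
#' single angle: each terminal pair contributes a unit vector
#' \eqn{(\cos\Delta, \sin\Delta)}, the vectors are combined in a weighted sum
#' s, and the angle of s is returned. Rotating the bond by \eqn{\gamma}
#' rotates the result by exactly \eqn{\gamma}; the value is independent of
#' which single terminal pair one might have picked.
#'
#' @param coords n x 3 coordinates.
#' @param spec a `tc_torsion`.
#' @param weights optional |a| x |b| positive weight matrix; defaults to
#'   [default_pair_weights()].
#' @return normalized angle in \eqn{(-\pi, \pi]}, radians.
#' @export
normalized_torsion <- function(coords, spec, weights = NULL) {
  if (is.null(weights)) weights <- default_pair_weights(spec)
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == length(spec$a_group),
            ncol(weights) == length(spec$b_group),
            all(weights > 0))
  s <- c(0, 0)
  for (m in seq_along(spec$a_group)) {
    for (n in seq_along(spec$b_group)) {
      d <- dihedral_angle(coords, spec$a_group[m], spec$i, spec$j,
                          spec$b_group[n])
      s <- s + weights[m, n] * c(cos(d), sin(d))
    }
  }
  ns <- sqrt(sum(s^2))
  if (ns < 1e-12) {
    stop("degenerate normalized torsion: weighted (cos, sin) sum has zero ",
         "norm for bond ", spec$i, "-", spec$j)
  }
  wrap_angle(atan2(s[2], s[1]))
}

# Atoms on the j side of bridge bond (i, j): BFS from j with edge (i, j)
# removed. Errors if (i, j) is not a bridge.
fragment_beyond <- function(graph, i, j) {
  n <- graph$n
  visited <- rep(FALSE, n)
  visited[j] <- TRUE
  queue <- j
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in graph$adj_list[[v]]) {
      if ((v == j && w == i) || (v == i && w == j)) next
      if (v == i) next
      if (!visited[w]) {
        visited[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  if (visited[i]) {
    stop("bond ", i, "-", j, " is not a bridge; cannot rotate a ring bond")
  }
  which(visited)
}

#' Set the normalized torsion of one rotatable bond
#'
#' Rigidly rotates one of the two fragments about the i->j axis so that the
#' bond's normalized torsion equals `target`. The smaller fragment moves
#' (ties: the fragment containing j); bond lengths and angles within each
#' fragment are untouched.
#'
#' @param conf a `tc_conformer` (or bare coordinate matrix).
#' @param graph the molecule's `tc_molgraph`.
#' @param spec a `tc_torsion` for a bridge (non-ring) bond.
#' @param target target normalized angle, radians.
#' @param weights optional weight matrix passed to [normalized_torsion()].
#' @return a `tc_conformer` with updated coordinates.
#' @export
set_torsion <- function(conf, graph, spec, target, weights = NULL) {
  coords <- if (inherits(conf, "tc_conformer")) conf$coords else conf
  stopifnot(is.finite(target))
  current <- normalized_torsion(coords, spec, weights)
  delta <- angle_diff(target, current)

  side_j <- fragment_beyond(graph, spec$i, spec$j)
  side_i <- setdiff(seq_len(graph$n), side_j)
  move_j <- length(side_j) <= length(side_i)
  moving <- if (move_j) side_j else side_i

  axis <- coords[spec$j, ] - coords[spec$i, ]
  # rotating the j-side fragment by +gamma about the i->j axis (right-hand
  # rule) advances every dihedral, and hence the normalized angle, by +gamma;
  # moving the i side instead requires the opposite rotation
  gamma <- if (move_j) delta else -delta
  R <- rotation_about_axis(axis, gamma)
  anchor <- coords[spec$i, ]
  shifted <- sweep(coords[moving, , drop = FALSE], 2, anchor)
  coords[moving, ] <- sweep(shifted %*% t(R), 2, anchor, `+`)

  out <- if (inherits(conf, "tc_conformer")) conf else conformer(coords)
  out$coords <- coords
  out
}

#' Apply a sequence of torsion targets to an initial conformer
#'
#' Applies [set_torsion()] spec by spec in canonical order. Because each
#' rotation moves a rigid fragment about a distinct bridge bond, earlier
#' bonds' normalized angles are preserved and every spec's final measured
#' angle equals its target.
#'
#' @param initial a `tc_conformer`.
#' @param graph the molecule's `tc_molgraph`.
#' @param specs list of `tc_torsion` (canonical order).
#' @param angles numeric vector of target normalized angles, radians,
#'   `length(angles) == length(specs)`.
#' @param relative_energy optional energy tag for the resulting conformer.
#' @return a `tc_conformer` tagged `"generated"`.
#' @export
apply_torsion_sequence <- function(initial, graph, specs, angles,
                                   relative_energy = NULL) {
  stopifnot(length(angles) == length(specs))
  conf <- initial
  for (k in seq_along(specs)) {
    conf <- set_torsion(conf, graph, specs[[k]], angles[k])
  }
  out <- conformer(conf$coords,
                   relative_energy %||% initial$relative_energy,
                   source_tag = "generated")
  out
}

#' Measure the normalized torsion sequence of a conformer
#'
#' @param conf `tc_conformer` or coordinate matrix.
#' @param specs list of `tc_torsion`.
#' @return numeric vector of normalized angles, radians.
#' @export
measure_torsions <- function(conf, specs) {
  coords <- if (inherits(conf, "tc_conformer")) conf$coords else conf
  vapply(specs, function(s) normalized_torsion(coords, s), numeric(1))
}
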