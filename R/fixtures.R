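# Synthetic conformer-ensemble generator. Emulates GEOM-style records
# (molecular graph, conformer ensemble, relative energy per conformer with
# 0 kcal/mol for the lowest-energy member) from nothing but a SMILES string:
# conformers are enumerated on a torsion grid and scored with independent
# per-bond 3-fold cosine potentials, so the whole energy landscape is
# closed-form and test oracles can be evaluated by hand.

find_python <- function() {
  for (cand in c(Sys.getenv("TORSIONCONF_PYTHON"), "python", "python3")) {
    if (nzchar(cand) && nzchar(Sys.which(cand))) return(Sys.which(cand))
  }
  stop("no python interpreter found (needed for distance-geometry embedding)")
}

#' Embed an initial 3D conformer for a SMILES string
#'
#' Runs a seeded distance-geometry embedding (ETKDGv3 followed by MMFF94
#' relaxation, through the system RDKit) and returns the heavy-atom
#' conformer. Deterministic for a given (SMILES, seed) pair.
#'
#' @param smiles SMILES string.
#' @param seed integer random seed for the embedder.
#' @return `tc_conformer` tagged `"initial"`, heavy atoms only, in the same
#'   atom order as [read_molecule()] on the same SMILES.
#' @export
embed_initial <- function(smiles, seed = 1) {
  key <- paste0(smiles, "|", seed)
  cached <- .embed_cache[[key]]
  if (!is.null(cached)) {
    return(conformer(cached, 0, "initial"))
  }
  py <- find_python()
  script <- system.file("python", "embed_etkdg.py", package = "torsionconf")
  if (!nzchar(script)) {
    # during in-source testing the package may not be installed
    script <- file.path("inst", "python", "embed_etkdg.py")
  }
  out <- suppressWarnings(
    system2(py, c(shQuote(script), shQuote(smiles), as.integer(seed)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0
  if (status != 0) {
    stop("embedding failed for '", smiles, "' (seed ", seed,
         "); retry with a different seed", call. = FALSE)
  }
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  writeLines(out, tmp)
  set <- ChemmineR::read.SDFset(tmp)
  st <- strip_hydrogens_sdf(set[[1]])
  ab <- ChemmineR::atomblock(st$sdf)
  coords <- unname(ab[, 1:3, drop = FALSE])
  .embed_cache[[key]] <- coords
  conformer(coords, 0, "initial")
}

# Embedding is deterministic per (SMILES, seed), so results are memoized for
# the lifetime of the session.
.embed_cache <- new.env(parent = emptyenv())

#' Specification for a synthetic conformer ensemble
#'
#' @param smiles SMILES string (must have at least one rotatable bond for
#'   [make_ensemble()]).
#' @param resolution torsion grid resolution in degrees; must divide 360.
#' @param barriers per-bond 3-fold barrier heights V_l in kcal/mol (recycled
#'   over rotatable bonds). The grid energy is
#'   \eqn{E(\theta) = \sum_l V_l (1 + \cos 3\theta_l)/2}.
#' @param n_keep number of lowest-energy grid points kept.
#' @param distinct_energies keep at most one conformer per distinct energy
#'   level (makes the (graph, energy) -> angles map single-valued, which the
#'   energy-conditioned training fixtures require).
#' @param seed embedding seed.
#' @return object of class `tc_fixture_spec`.
#' @export
fixture_spec <- function(smiles, resolution = 60, barriers = 1.0,
                         n_keep = 8, distinct_energies = FALSE, seed = 1) {
  stopifnot(360 %% resolution == 0, all(barriers >= 0), n_keep >= 1)
  structure(list(smiles = smiles, resolution = resolution,
                 barriers = barriers, n_keep = n_keep,
                 distinct_energies = distinct_energies, seed = seed),
            class = "tc_fixture_spec")
}

#' One training record: graph, torsion specs, conformer, angle sequence
#'
#' @param graph `tc_molgraph`.
#' @param specs list of `tc_torsion` for the graph.
#' @param conf `tc_conformer` (reference geometry + relative energy).
#' @return object of class `tc_record`; `angles` holds the normalized
#'   torsion sequence measured from the coordinates.
#' @export
training_record <- function(graph, specs, conf) {
  structure(list(graph = graph, specs = specs, conformer = conf,
                 angles = measure_torsions(conf, specs),
                 energy = conf$relative_energy),
            class = "tc_record")
}

#' Generate a synthetic conformer ensemble on a torsion grid
#'
#' Enumerates all combinations of grid torsion values (grid anchored at the
#' anti conformation, 180 degrees), scores each combination with the
#' independent per-bond 3-fold potential of the [fixture_spec()], rebuilds
#' the kept low-energy conformers from a seeded initial embedding, and
#' shifts energies so the minimum kept energy is exactly 0 kcal/mol.
#'
#' @param spec a `tc_fixture_spec` (or SMILES string, with defaults).
#' @return list of `tc_record`, ordered by increasing relative energy.
#' @export
make_ensemble <- function(spec) {
  if (is.character(spec)) spec <- fixture_spec(spec)
  graph <- read_molecule(spec$smiles)
  specs <- find_rotatable_bonds(graph)
  L <- length(specs)
  if (L == 0) {
    stop("molecule '", spec$smiles, "' has no rotatable bonds; ",
         "use embed_initial() alone for rigid molecules")
  }
  V <- rep_len(spec$barriers, L)
  res_rad <- spec$resolution * pi / 180
  npts <- as.integer(360 / spec$resolution)
  grid_1d <- wrap_angle(pi + (seq_len(npts) - 1) * res_rad)
  combos <- as.matrix(expand.grid(rep(list(grid_1d), L)))
  energies <- as.numeric(
    (1 + cos(3 * combos)) %*% matrix(V / 2, ncol = 1))
  ord <- order(energies, seq_along(energies))
  combos <- combos[ord, , drop = FALSE]
  energies <- energies[ord]
  if (spec$distinct_energies) {
    keep <- !duplicated(round(energies, 9))
    combos <- combos[keep, , drop = FALSE]
    energies <- energies[keep]
  }
  k <- min(spec$n_keep, length(energies))
  combos <- combos[seq_len(k), , drop = FALSE]
  energies <- energies[seq_len(k)] - energies[1]

  init <- embed_initial(spec$smiles, spec$seed)
  stopifnot(nrow(init$coords) == graph$n)
  lapply(seq_len(k), function(r) {
    conf <- apply_torsion_sequence(init, graph, specs, combos[r, ],
                                   relative_energy = energies[r])
    conf$source_tag <- "reference"
    training_record(graph, specs, conf)
  })
}

#' The standing fixture molecule set
#'
#' Small molecules covering the cases the test suite needs: a single-torsion
#' chain (butane), a two-torsion chain (n-pentane), a three-torsion molecule
#' (1,2-diphenylethane), a symmetric aromatic for topological-equivalence
#' tests (para-xylene), a rigid molecule (benzene), and a symmetric CF3
#' terminal group (1,1,1-trifluoropropane) exercising the terminal-pair
#' weighting of the normalized torsion.
#'
#' @return data.frame with columns `name`, `smiles`, `n_torsions`.
#' @export
fixture_suite <- function() {
  data.frame(
    name = c("butane", "pentane", "diphenylethane", "para_xylene",
             "benzene", "trifluoropropane"),
    smiles = c("CCCC", "CCCCC", "c1ccccc1CCc1ccccc1", "Cc1ccc(C)cc1",
               "c1ccccc1", "CCC(F)(F)F"),
    n_torsions = c(1L, 2L, 3L, 0L, 0L, 1L),
    stringsAsFactors = FALSE)
}

#' The deduplicated-energy fixture training set
#'
#' Ensembles for butane, n-pentane (two distinct barriers) and
#' 1,1,1-trifluoropropane with `distinct_energies = TRUE`: every conformer
#' of a molecule has a distinct relative energy, so the
#' (graph, energy) -> angle-sequence map the model is asked to learn is
#' single-valued.
#'
#' @param seed embedding seed.
#' @param n_keep conformers kept per molecule (before deduplication cap).
#' @return list of `tc_record`.
#' @export
fixture_training_set <- function(seed = 1, n_keep = 4) {
  sets <- list(
    butane = fixture_spec("CCCC", resolution = 60, barriers = 1.0,
                          n_keep = n_keep, distinct_energies = TRUE,
                          seed = seed),
    pentane = fixture_spec("CCCCC", resolution = 60,
                           barriers = c(1.0, 2.5), n_keep = n_keep,
                           distinct_energies = TRUE, seed = seed),
    trifluoropropane = fixture_spec("CCC(F)(F)F", resolution = 60,
                                    barriers = 1.8,
                                    n_keep = n_keep,
                                    distinct_energies = TRUE, seed = seed))
  unlist(lapply(sets, make_ensemble), recursive = FALSE)
}
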