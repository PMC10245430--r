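#' @importFrom stats rnorm runif
#' @importFrom utils head tail
NULL

ELEMENT_VOCAB <- c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "As",
                   "Se", "Br", "Te", "I", "At", "other")

DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                     S = 2, Cl = 1, As = 3, Se = 2, Br = 1, Te = 2,
                     I = 1, At = 1)

# Atom feature layout (width F_a = 40), AttentiveFP-style:
#   element one-hot (16) | heavy-degree one-hot 0..5 (6) | formal charge (1) |
#   radical electrons (1) | hybridization one-hot sp/sp2/sp3/sp3d/sp3d2/other
#   (6) | aromatic (1) | attached-H one-hot 0..4 (5) | in-ring (1) |
#   chirality flag (1) | chirality type R/S (2)
# Radical and stereo slots are reserved and zero under this parser.
ATOM_FEATURE_WIDTH <- 40L

# Bond feature layout (width F_b = 10):
#   type one-hot single/double/triple/aromatic (4) | conjugated (1) |
#   in-ring (1) | stereo one-hot (4, reserved)
BOND_FEATURE_WIDTH <- 10L

element_of <- function(rowname) sub("_\\d+$", "", rowname)

# ---- SDF helpers -----------------------------------------------------------

sdf_elements <- function(sdf) element_of(rownames(ChemmineR::atomblock(sdf)))

sdf_charges <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  code <- if (ncol(ab) >= 5) ab[, 5] else rep(0, nrow(ab))
  # MDL charge codes: 0 none, 1:+3, 2:+2, 3:+1, 4 radical, 5:-1, 6:-2, 7:-3
  map <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
           `6` = -2, `7` = -3)
  unname(map[as.character(code)])
}

strip_hydrogens_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- element_of(rownames(ab))
  heavy <- which(el != "H")
  if (length(heavy) == nrow(ab)) {
    return(list(sdf = sdf, explicit_h = rep(0L, nrow(ab))))
  }
  idx_map <- integer(nrow(ab)); idx_map[heavy] <- seq_along(heavy)
  bb <- as.matrix(bb)
  keep_bond <- el[bb[, 1]] != "H" & el[bb[, 2]] != "H"
  exp_h <- integer(length(heavy))
  for (r in which(!keep_bond)) {
    ij <- bb[r, 1:2]
    hv <- ij[el[ij] != "H"]
    if (length(hv) == 1) exp_h[idx_map[hv]] <- exp_h[idx_map[hv]] + 1L
  }
  ab2 <- ab[heavy, , drop = FALSE]
  bb2 <- bb[keep_bond, , drop = FALSE]
  bb2[, 1] <- idx_map[bb2[, 1]]
  bb2[, 2] <- idx_map[bb2[, 2]]
  rownames(ab2) <- paste(el[heavy], seq_along(heavy), sep = "_")
  rownames(bb2) <- seq_len(nrow(bb2))
  h <- sdf@header
  h["Counts_Line"] <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                              nrow(ab2), nrow(bb2))
  out <- methods::new("SDF", header = h, atomblock = ab2, bondblock = bb2,
                      datablock = sdf@datablock)
  list(sdf = out, explicit_h = exp_h)
}

aromatic_perception <- function(sdf, n) {
  arom_atoms <- rep(FALSE, n)
  arom_bonds <- character(0)
  rings <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, upper = 12, type = "all",
                                      arom = TRUE)),
    error = function(e) NULL)
  if (!is.null(rings) && length(rings$RINGS) > 0) {
    for (k in seq_along(rings$RINGS)) {
      if (!isTRUE(rings$AROMATIC[[k]])) next
      idx <- as.integer(sub("^.*_", "", rings$RINGS[[k]]))
      arom_atoms[idx] <- TRUE
      m <- length(idx)
      for (p in seq_len(m)) {
        q <- if (p == m) 1 else p + 1
        arom_bonds <- c(arom_bonds,
                        paste(sort(c(idx[p], idx[q])), collapse = "-"))
      }
    }
  }
  list(atoms = arom_atoms, bonds = unique(arom_bonds))
}

# ---- canonical ranks (Morgan/WL-style refinement) --------------------------

# Iterative neighborhood refinement with full color-history keys; ranks are
# dense ranks of the lexicographically sorted keys, so they are deterministic
# and invariant under input atom permutation. Automorphic atoms tie.
canonical_rank_keys <- function(elements, charges, nH, aromatic, adj_list) {
  key <- sprintf("%s|%d|%d|%d|%d", elements, charges, nH,
                 as.integer(aromatic), lengths(adj_list))
  n <- length(key)
  n_classes <- length(unique(key))
  for (iter in seq_len(n)) {
    nbr <- vapply(seq_len(n), function(v)
      paste(sort(key[adj_list[[v]]]), collapse = ","), character(1))
    key <- paste0(key, "(", nbr, ")")
    nc <- length(unique(key))
    if (nc == n_classes) break
    n_classes <- nc
  }
  key
}

canonical_ranks_from_keys <- function(keys) {
  match(keys, sort(unique(keys)))
}

# ---- public API ------------------------------------------------------------

#' Read a molecule into a featurized graph
#'
#' Parses a SMILES string or an SDF record into the package's molecular-graph
#' container: per-atom and per-bond feature vectors (AttentiveFP-style
#' vocabulary), a binary adjacency matrix over heavy atoms, and
#' permutation-invariant canonical atom ranks. Hydrogens are folded into an
#' attached-H count feature; graph nodes are heavy atoms only.
#'
#' @param source a SMILES string, a path to an SDF file (first record used),
#'   or a `ChemmineR::SDF` object.
#' @return an object of class `tc_molgraph` with elements `n`, `elements`,
#'   `atom_features` (n x 40), `bond_df`, `bond_features`, `adjacency`,
#'   `degree`, `nH`, `canonical_ranks`, `coords` (template coordinates, may be
#'   2D), and `sdf` (heavy-atom template used for SDF output).
#' @examples
#' \dontrun{
#' g <- read_molecule("CCCC")
#' g$n  # 4 heavy atoms
#' }
#' @export
read_molecule <- function(source) {
  sdf <- NULL
  smiles <- NA_character_
  if (inherits(source, "SDF")) {
    sdf <- source
  } else if (is.character(source) && length(source) == 1) {
    if (file.exists(source) || grepl("\\.sdf$", source, ignore.case = TRUE)) {
      if (!file.exists(source)) stop("SDF file not found: ", source)
      set <- ChemmineR::read.SDFset(source)
      sdf <- set[[1]]
    } else {
      smiles <- source
      set <- tryCatch(ChemmineR::smiles2sdf(stats::setNames(source, "mol")),
                      error = function(e) {
                        stop("cannot parse SMILES '", source, "': ",
                             conditionMessage(e))
                      })
      sdf <- set[[1]]
    }
  } else {
    stop("source must be a SMILES string, an SDF path, or an SDF object")
  }
  ab <- tryCatch(ChemmineR::atomblock(sdf), error = function(e) NULL)
  if (is.null(ab) || nrow(ab) == 0) {
    stop("invalid or unparsable molecule record")
  }
  if (nrow(ChemmineR::bondblock(sdf)) > 0 &&
      !suppressWarnings(ChemmineR::validSDF(methods::as(sdf, "SDFset")))) {
    stop("invalid or unparsable molecule record")
  }
  build_molgraph(sdf, smiles = smiles)
}

build_molgraph <- function(sdf_full, smiles = NA_character_) {
  st <- strip_hydrogens_sdf(sdf_full)
  sdf <- st$sdf
  ab <- ChemmineR::atomblock(sdf)
  bb <- as.matrix(ChemmineR::bondblock(sdf))
  n <- nrow(ab)
  if (n == 0) stop("molecule has no heavy atoms")
  elements <- sdf_elements(sdf)
  charges <- sdf_charges(sdf)

  bond_i <- as.integer(bb[, 1]); bond_j <- as.integer(bb[, 2])
  order <- as.integer(bb[, 3])
  nb <- length(bond_i)

  adj <- matrix(0L, n, n)
  for (r in seq_len(nb)) {
    adj[bond_i[r], bond_j[r]] <- 1L
    adj[bond_j[r], bond_i[r]] <- 1L
  }
  adj_list <- lapply(seq_len(n), function(v) which(adj[v, ] == 1L))
  degree <- vapply(adj_list, length, integer(1))

  g <- igraph::graph_from_data_frame(
    data.frame(from = bond_i, to = bond_j),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  if (igraph::components(g)$no > 1) {
    stop("disconnected multi-fragment input is not supported; ",
         "supply a single connected molecule")
  }
  bridge_eids <- igraph::bridges(g)
  in_ring_bond <- rep(TRUE, nb)
  in_ring_bond[as.integer(bridge_eids)] <- FALSE
  ring_atoms <- rep(FALSE, n)
  for (r in which(in_ring_bond)) {
    ring_atoms[c(bond_i[r], bond_j[r])] <- TRUE
  }

  arom <- aromatic_perception(sdf, n)
  bond_key <- paste(pmin(bond_i, bond_j), pmax(bond_i, bond_j), sep = "-")
  arom_bond <- bond_key %in% arom$bonds

  # implicit hydrogens from default valence (kekulized bond orders)
  bondsum <- numeric(n)
  for (r in seq_len(nb)) {
    bondsum[bond_i[r]] <- bondsum[bond_i[r]] + order[r]
    bondsum[bond_j[r]] <- bondsum[bond_j[r]] + order[r]
  }
  defval <- unname(DEFAULT_VALENCE[elements])
  defval[is.na(defval)] <- 0
  eff <- defval + ifelse(elements %in% c("N", "O", "P", "S"), charges,
                         -abs(charges))
  nH <- pmax(0L, as.integer(round(eff - bondsum))) + st$explicit_h

  # hybridization from kekulized orders + aromaticity
  hyb <- vapply(seq_len(n), function(v) {
    rows <- which(bond_i == v | bond_j == v)
    os <- order[rows]
    tot_deg <- degree[v] + nH[v]
    if (tot_deg >= 6) return("sp3d2")
    if (tot_deg == 5) return("sp3d")
    if (any(os == 3) || sum(os == 2) >= 2) return("sp")
    if (any(os == 2) || arom$atoms[v]) return("sp2")
    "sp3"
  }, character(1))

  atom_features <- t(vapply(seq_len(n), function(v) {
    featurize_atom(list(element = elements[v], degree = degree[v],
                        charge = charges[v], hybridization = hyb[v],
                        aromatic = arom$atoms[v], nH = nH[v],
                        in_ring = ring_atoms[v]))
  }, numeric(ATOM_FEATURE_WIDTH)))

  conj <- vapply(seq_len(nb), function(r) {
    unsat <- function(v) arom$atoms[v] || hyb[v] %in% c("sp", "sp2")
    unsat(bond_i[r]) && unsat(bond_j[r])
  }, logical(1))
  bond_features <- t(vapply(seq_len(nb), function(r) {
    type <- if (arom_bond[r]) "aromatic" else
      c("single", "double", "triple")[min(order[r], 3)]
    featurize_bond(type, conj[r], in_ring_bond[r])
  }, numeric(BOND_FEATURE_WIDTH)))

  keys <- canonical_rank_keys(elements, charges, nH, arom$atoms, adj_list)
  ranks <- canonical_ranks_from_keys(keys)

  bond_df <- data.frame(i = bond_i, j = bond_j, order = order,
                        aromatic = arom_bond, ring = in_ring_bond,
                        conjugated = conj)

  structure(list(
    n = n, elements = elements, charges = charges, nH = nH,
    atom_features = atom_features,
    bond_df = bond_df, bond_features = bond_features,
    adjacency = adj, adj_list = adj_list, degree = degree,
    aromatic_atoms = arom$atoms, ring_atoms = ring_atoms,
    canonical_ranks = ranks, rank_keys = keys,
    coords = unname(ab[, 1:3, drop = FALSE]),
    sdf = sdf, smiles = smiles,
    heavy_atom_count = n
  ), class = "tc_molgraph")
}

#' @export
print.tc_molgraph <- function(x, ...) {
  cat(sprintf("<tc_molgraph> %d heavy atoms, %d bonds, %d rotatable bonds\n",
              x$n, nrow(x$bond_df), length(find_rotatable_bonds(x))))
  invisible(x)
}

#' Featurize one atom descriptor
#'
#' @param atom a list with `element`, `degree` (heavy-atom degree), `charge`,
#'   `hybridization` (one of sp/sp2/sp3/sp3d/sp3d2/other), `aromatic`, `nH`
#'   (attached hydrogens), `in_ring`.
#' @return numeric feature vector of width 40. Elements outside the supported
#'   vocabulary map to the trailing "other" slot.
#' @export
featurize_atom <- function(atom) {
  el <- ifelse(atom$element %in% ELEMENT_VOCAB[1:15], atom$element, "other")
  e1 <- as.numeric(ELEMENT_VOCAB == el)
  d1 <- as.numeric(0:5 == min(atom$degree, 5))
  hybs <- c("sp", "sp2", "sp3", "sp3d", "sp3d2", "other")
  h1 <- as.numeric(hybs == (if (atom$hybridization %in% hybs)
    atom$hybridization else "other"))
  nh1 <- as.numeric(0:4 == min(atom$nH, 4))
  c(e1, d1, atom$charge, 0,
    h1, as.numeric(isTRUE(atom$aromatic)), nh1,
    as.numeric(isTRUE(atom$in_ring)), 0, 0, 0)
}

featurize_bond <- function(type, conjugated, in_ring) {
  t1 <- as.numeric(c("single", "double", "triple", "aromatic") == type)
  c(t1, as.numeric(isTRUE(conjugated)), as.numeric(isTRUE(in_ring)),
    0, 0, 0, 0)
}

bond_feature_of <- function(graph, i, j) {
  key <- paste(pmin(i, j), pmax(i, j), sep = "-")
  all_keys <- paste(pmin(graph$bond_df$i, graph$bond_df$j),
                    pmax(graph$bond_df$i, graph$bond_df$j), sep = "-")
  row <- match(key, all_keys)
  if (is.na(row)) stop("no bond between atoms ", i, " and ", j)
  graph$bond_features[row, ]
}

#' Enumerate rotatable bonds with their torsion terminal groups
#'
#' A bond is rotatable when it is a non-ring single bond between two heavy
#' atoms that each carry at least one further heavy neighbor. Amide and other
#' conjugated single bonds are included by default (`amide = "include"`).
#' The returned specs are ordered canonically: sorted by the smaller, then the
#' larger, canonical rank of the two bond atoms; within each spec the terminal
#' groups are sorted by canonical rank, so the ordering is independent of the
#' input atom numbering.
#'
#' @param graph a `tc_molgraph`.
#' @param amide `"include"` (default) or `"exclude"` amide-like conjugated
#'   single bonds.
#' @return a list of `tc_torsion` specs, each with `i`, `j`, `a_group`,
#'   `b_group`, `sequence_index` (0-based). Rigid molecules give `list()`.
#' @export
find_rotatable_bonds <- function(graph, amide = c("include", "exclude")) {
  amide <- match.arg(amide)
  bd <- graph$bond_df
  cand <- which(bd$order == 1 & !bd$ring & !bd$aromatic &
                  graph$degree[bd$i] >= 2 & graph$degree[bd$j] >= 2)
  if (amide == "exclude") {
    cand <- cand[!bd$conjugated[cand]]
  }
  specs <- lapply(cand, function(r) {
    i <- bd$i[r]; j <- bd$j[r]
    # orient so that i has the smaller canonical rank (ties keep input order)
    if (graph$canonical_ranks[j] < graph$canonical_ranks[i]) {
      tmp <- i; i <- j; j <- tmp
    }
    a <- setdiff(graph$adj_list[[i]], j)
    b <- setdiff(graph$adj_list[[j]], i)
    a <- a[order(graph$canonical_ranks[a], a)]
    b <- b[order(graph$canonical_ranks[b], b)]
    structure(list(i = i, j = j, a_group = a, b_group = b,
                   sequence_index = NA_integer_), class = "tc_torsion")
  })
  if (length(specs) == 0) return(list())
  rmin <- vapply(specs, function(s)
    min(graph$canonical_ranks[c(s$i, s$j)]), numeric(1))
  rmax <- vapply(specs, function(s)
    max(graph$canonical_ranks[c(s$i, s$j)]), numeric(1))
  ord <- order(rmin, rmax, vapply(specs, function(s) min(s$i, s$j),
                                  numeric(1)))
  specs <- specs[ord]
  for (k in seq_along(specs)) specs[[k]]$sequence_index <- k - 1L
  specs
}

#' @export
print.tc_torsion <- function(x, ...) {
  cat(sprintf("<tc_torsion %d> bond %d-%d, a={%s}, b={%s}\n",
              x$sequence_index, x$i, x$j,
              paste(x$a_group, collapse = ","),
              paste(x$b_group, collapse = ",")))
  invisible(x)
}

molgraph_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$bond_df[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = seq_len(graph$n)))
}
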