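# Multi-conformer SDF I/O. One molecule, many conformer records; the
# per-conformer relative energy travels in the SDF data field
# REL_ENERGY_KCAL (kcal/mol), the source tag in SOURCE_TAG.

#' Write a conformer ensemble to a multi-record SDF file
#'
#' @param graph `tc_molgraph` providing the heavy-atom template (bonds,
#'   elements).
#' @param conformers list of `tc_conformer`.
#' @param file output path.
#' @param title record title prefix.
#' @return `file`, invisibly.
#' @export
write_conformer_sdf <- function(graph, conformers, file, title = "mol") {
  stopifnot(length(conformers) > 0)
  records <- lapply(seq_along(conformers), function(k) {
    cf <- conformers[[k]]
    stopifnot(nrow(cf$coords) == graph$n)
    tmpl <- graph$sdf
    ab <- ChemmineR::atomblock(tmpl)
    ab[, 1:3] <- round(cf$coords, 4)
    h <- tmpl@header
    h["Molecule_Name"] <- sprintf("%s_%d", title, k)
    h["Source"] <- "  torsionconf"
    h["Comment"] <- ""
    methods::new("SDF", header = h, atomblock = ab,
                 bondblock = ChemmineR::bondblock(tmpl),
                 datablock = c(
                   REL_ENERGY_KCAL = sprintf("%.6f", cf$relative_energy),
                   SOURCE_TAG = cf$source_tag))
  })
  set <- methods::as(records[[1]], "SDFset")
  if (length(records) > 1) {
    # concatenation temporarily duplicates the default CMP id
    suppressWarnings(
      for (k in 2:length(records)) {
        set <- c(set, methods::as(records[[k]], "SDFset"))
      })
  }
  ChemmineR::cid(set) <- sprintf("%s_%d", title, seq_along(records))
  ChemmineR::write.SDF(set, file)
  invisible(file)
}

#' Read a conformer ensemble from a multi-record SDF file
#'
#' All records must describe the same molecule (same heavy-atom graph).
#'
#' @param file SDF path.
#' @return list with `graph` (`tc_molgraph` from the first record) and
#'   `conformers` (list of `tc_conformer`; relative energies taken from the
#'   REL_ENERGY_KCAL data field, defaulting to 0).
#' @export
read_conformer_sdf <- function(file) {
  set <- ChemmineR::read.SDFset(file)
  graph <- build_molgraph(set[[1]])
  confs <- lapply(seq_along(ChemmineR::cid(set)), function(k) {
    sdf <- set[[k]]
    st <- strip_hydrogens_sdf(sdf)
    ab <- ChemmineR::atomblock(st$sdf)
    db <- ChemmineR::datablock(sdf)
    en <- suppressWarnings(as.numeric(db["REL_ENERGY_KCAL"]))
    if (length(en) == 0 || is.na(en)) en <- 0
    tag <- db["SOURCE_TAG"]
    if (is.null(tag) || is.na(tag) ||
        !tag %in% c("reference", "initial", "generated")) tag <- "reference"
    conformer(unname(ab[, 1:3, drop = FALSE]), en, tag)
  })
  els <- lapply(seq_along(ChemmineR::cid(set)), function(k)
    sdf_elements(strip_hydrogens_sdf(set[[k]])$sdf))
  if (!all(vapply(els, identical, logical(1), els[[1]]))) {
    stop("SDF records describe different molecules")
  }
  list(graph = graph, conformers = confs)
}
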