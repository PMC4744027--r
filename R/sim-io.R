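#' Specimen metadata table
#'
#' Flattens a \code{\linkS4class{CommunityTruth}} (and optionally a
#' morphospecies partition) into the per-specimen metadata table used by the
#' richness and turnover machinery: specimen id, true species, morphospecies
#' label, sampling unit, elevational level and collection method.
#'
#' @param truth A \code{CommunityTruth}.
#' @param morphospecies Optional \code{\linkS4class{Partition}} of
#'   morphospecies labels over the same specimens.
#' @return A \code{data.frame} with columns \code{specimen_id},
#'   \code{true_species}, \code{morphospecies}, \code{sampling_unit},
#'   \code{level}, \code{method}.
#' @export
specimenTable <- function(truth, morphospecies = NULL) {
  stopifnot(is(truth, "CommunityTruth"))
  ids <- specimens(truth@truePartition)
  morpho <- if (is.null(morphospecies)) truth@truePartition@groups[ids] else
    groupOf(morphospecies)[ids]
  data.frame(
    specimen_id = ids,
    true_species = truth@truePartition@groups[ids],
    morphospecies = unname(morpho),
    sampling_unit = unname(truth@unitOfSpecimen[ids]),
    level = unname(truth@levelOfSpecimen[ids]),
    method = unname(truth@methodOfSpecimen[ids]),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a simulated data set to disk
#'
#' Emits the standard text artefacts of one simulation: aligned FASTA,
#' newick truth genealogy, TSV specimen metadata and a JSON truth summary.
#'
#' @param truth A \code{CommunityTruth}.
#' @param tree The genealogy from \code{\link{simulateGenealogy}}.
#' @param aln The alignment from \code{\link{simulateSequences}}.
#' @param morphospecies Morphospecies \code{Partition} (from
#'   \code{\link{corruptMorphospecies}}).
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
writeSimulation <- function(truth, tree, aln, morphospecies, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(dir, "alignment.fasta"),
    tree = file.path(dir, "genealogy.nwk"),
    meta = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.json"))
  writeAlignment(aln, paths[["fasta"]])
  ape::write.tree(tree, file = paths[["tree"]], digits = 14)
  utils::write.table(specimenTable(truth, morphospecies), paths[["meta"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    species_count = truth@speciesCount,
    n_specimens = sum(truth@abundances),
    singleton_fraction = mean(truth@abundances == 1L),
    abundances = as.integer(truth@abundances),
    seed = truth@seed
  ), paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a specimen metadata TSV
#'
#' @param path TSV with at least columns \code{specimen_id},
#'   \code{morphospecies}, \code{sampling_unit}, \code{level}, \code{method}.
#' @return A validated \code{data.frame}.
#' @export
readMetadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "morphospecies", "sampling_unit", "level", "method")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$specimen_id)) stop("duplicate specimen ids in metadata")
  meta
}
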