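#' Read and validate an aligned FASTA file
#'
#' Reads one DNA sequence per specimen, upper-cases the residues, and
#' validates that the records form a proper alignment: equal lengths and
#' unique specimen ids.  Characters outside the IUPAC DNA alphabet
#' (plus \code{-} and \code{N}) are rejected by the underlying parser.
#'
#' @param path Path to a FASTA file.
#' @return A named \code{\link[Biostrings]{DNAStringSet}}, one record per
#'   specimen.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "ACGA"), tf)
#' readAlignment(tf)
#' @export
readAlignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  # keep only the id token of each header
  names(x) <- vapply(strsplit(names(x), "[ \t]"), `[`, "", 1L)
  validateAlignment(x)
}

#' Validate an alignment held in memory
#'
#' @param x A named \code{DNAStringSet} (or named character vector of
#'   sequences).
#' @return The validated, upper-cased \code{DNAStringSet}.
#' @export
validateAlignment <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (length(x) == 0L) stop("alignment has no records")
  ids <- names(x)
  if (is.null(ids) || any(ids == "")) stop("all records must carry an id")
  if (anyDuplicated(ids))
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  w <- Biostrings::width(x)
  if (length(unique(w)) > 1L) {
    bad <- ids[w != stats::median(w)]
    stop("ragged alignment; records of deviating length: ",
         paste(bad, collapse = ", "))
  }
  if (w[1L] < 1L) stop("zero-length sequences")
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Write an alignment to FASTA
#'
#' @param x A named \code{DNAStringSet}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeAlignment <- function(x, path) {
  Biostrings::writeXStringSet(x, filepath = path, width = 70L)
  invisible(path)
}

# character matrix (specimens x sites) from an alignment
.alnMatrix <- function(x) {
  m <- do.call(rbind, strsplit(as.character(x), ""))
  rownames(m) <- names(x)
  m
}

#' Pairwise mismatch and comparable-site counts
#'
#' For every pair of records counts the sites at which both sequences carry
#' an unambiguous base (A/C/G/T) and, of those, the sites at which they
#' differ.  Sites with a gap, \code{N} or any IUPAC ambiguity code in either
#' sequence are excluded pairwise.
#'
#' @param x A named \code{DNAStringSet}.
#' @return List with integer matrices \code{steps} (mismatches) and
#'   \code{comparable} (sites compared), both with specimen ids as dimnames.
#' @export
mismatchMatrix <- function(x) {
  x <- validateAlignment(x)
  m <- .alnMatrix(x)
  bases <- c("A", "C", "G", "T")
  ind <- lapply(bases, function(b) (m == b) * 1)
  valid <- Reduce(`+`, ind)
  matches <- Reduce(`+`, lapply(ind, tcrossprod))
  comparable <- tcrossprod(valid)
  steps <- round(comparable - matches)
  storage.mode(steps) <- "integer"
  storage.mode(comparable) <- "integer"
  dimnames(steps) <- dimnames(comparable) <- list(names(x), names(x))
  list(steps = steps, comparable = comparable)
}

#' Pairwise uncorrected distance matrix
#'
#' Uncorrected (p) distances: mismatches divided by comparable sites.  Under
#' the default \code{"pairwise"} policy, sites with a gap or ambiguity code
#' in either member of a pair are excluded for that pair only; under
#' \code{"complete"}, columns containing any gap or ambiguity in any record
#' are removed before all comparisons.  A pair with zero comparable sites is
#' assigned distance 0 with a warning.
#'
#' @param x A named \code{DNAStringSet} with at least 2 records.
#' @param policy \code{"pairwise"} (default) or \code{"complete"} deletion.
#' @return Symmetric numeric matrix of distances in \code{[0, 1]} with zero
#'   diagonal; comparable-site counts are attached as attribute
#'   \code{"comparable"}.
#' @examples
#' aln <- Biostrings::DNAStringSet(c(a = "ACGT", b = "ACGA"))
#' pDistanceMatrix(aln)
#' @export
pDistanceMatrix <- function(x, policy = c("pairwise", "complete")) {
  policy <- match.arg(policy)
  x <- validateAlignment(x)
  if (length(x) < 2L) stop("need at least 2 records for a distance matrix")
  if (policy == "complete") {
    m <- .alnMatrix(x)
    ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
    keep <- colSums(!ok) == 0L
    if (!any(keep)) stop("complete deletion removed every site")
    s <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
    x <- Biostrings::DNAStringSet(stats::setNames(s, names(x)))
  }
  mm <- mismatchMatrix(x)
  if (any(mm$comparable[upper.tri(mm$comparable)] == 0L))
    warning("pair(s) with no comparable sites assigned distance 0")
  d <- mm$steps / pmax(mm$comparable, 1L)
  diag(d) <- 0
  attr(d, "comparable") <- mm$comparable
  d
}

#' Collapse specimens into haplotypes
#'
#' Specimens are grouped by strict string identity of their aligned
#' sequences: records differing only at gap/ambiguity sites are kept apart.
#' Haplotype indices are assigned in lexicographic sequence order, so they
#' do not depend on record order.
#'
#' @param x A named \code{DNAStringSet}.
#' @return A list of class \code{HaplotypeTable} with elements
#'   \code{haplotypeOfSpecimen} (named integer), \code{representatives}
#'   (\code{DNAStringSet} named \code{H1..Hk}, one per haplotype) and
#'   \code{nHaplotypes}.
#' @export
collapseHaplotypes <- function(x) {
  x <- validateAlignment(x)
  s <- as.character(x)
  uniq <- sort(unique(s))
  idx <- match(s, uniq)
  reps <- Biostrings::DNAStringSet(uniq)
  names(reps) <- paste0("H", seq_along(uniq))
  structure(list(
    haplotypeOfSpecimen = stats::setNames(idx, names(x)),
    representatives = reps,
    nHaplotypes = length(uniq)
  ), class = "HaplotypeTable")
}

#' @export
print.HaplotypeTable <- function(x, ...) {
  cat("HaplotypeTable:", length(x$haplotypeOfSpecimen), "specimens in",
      x$nHaplotypes, "haplotypes\n")
  invisible(x)
}

#' Specimen partition induced by haplotype membership
#'
#' @param ht A \code{HaplotypeTable} from \code{\link{collapseHaplotypes}}.
#' @return A \code{\linkS4class{Partition}} grouping specimens that share a
#'   haplotype.
#' @export
haplotypePartition <- function(ht) {
  Partition(stats::setNames(paste0("H", ht$haplotypeOfSpecimen),
                            names(ht$haplotypeOfSpecimen)))
}

#' Export a distance matrix as square TSV
#'
#' @param d Symmetric matrix with id dimnames.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeDistanceMatrix <- function(d, path) {
  df <- data.frame(id = rownames(d), as.data.frame(unclass(d)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
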