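#' Threshold clustering of pairwise distances
#'
#' Groups specimens into MOTUs by single-linkage transitive closure: the
#' partition is the set of connected components of the graph that joins
#' every pair with uncorrected distance strictly below the threshold.
#' Common barcoding presets are 0.03, 0.05 and 0.075.
#'
#' @param d Symmetric distance matrix with specimen ids as dimnames
#'   (see \code{\link{pDistanceMatrix}}).
#' @param threshold Distance threshold in (0, 1); pairs with
#'   \code{d < threshold} are linked.
#' @return A \code{\linkS4class{Partition}}; component labels are the
#'   smallest contained specimen id, so output is deterministic.
#' @examples
#' d <- matrix(c(0, .02, .1, .02, 0, .02, .1, .02, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' blocks(clusterByThreshold(d, 0.03))
#' @export
clusterByThreshold <- function(d, threshold) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), threshold > 0, threshold < 1)
  ids <- rownames(d)
  if (is.null(ids)) stop("distance matrix must carry specimen ids")
  pairs <- which(d < threshold & upper.tri(d), arr.ind = TRUE)
  .componentsPartition(ids, pairs)
}

#' Statistical-parsimony connection limit
#'
#' Computes the largest number of mutational steps at which two haplotypes
#' can be connected while the connection remains non-homoplasious with the
#' stated confidence.  The probability that a connection of \code{j}
#' observed differences is parsimonious is taken as the probability that
#' \code{j} mutations placed uniformly and independently over
#' \code{seqLength} sites all strike distinct sites,
#' \deqn{P(j) = \prod_{i=0}^{j-1} (1 - i/L),}
#' the no-superimposed-change term of the classical parsimony-probability
#' argument; the limit is the largest \code{j} with \code{P(j) >=}
#' \code{confidence}.  A fixed \code{maxSteps} override is accepted for
#' compatibility with externally computed limits.
#'
#' @param seqLength Alignment length in sites (>= 1).
#' @param confidence Required parsimony probability, in (0, 1); default 0.95.
#' @param maxSteps Optional fixed override of the computed limit.
#' @return A \code{\linkS4class{ConnectionLimit}}.
#' @examples
#' connectionLimit(658)
#' @export
connectionLimit <- function(seqLength, confidence = 0.95, maxSteps = NULL) {
  seqLength <- as.integer(seqLength)
  if (is.na(seqLength) || seqLength < 1L) stop("seqLength must be >= 1")
  stopifnot(confidence > 0, confidence < 1)
  if (!is.null(maxSteps)) {
    stopifnot(maxSteps >= 0)
    j <- as.integer(maxSteps)
    return(new("ConnectionLimit", maxSteps = j, confidence = confidence,
               seqLength = seqLength,
               probability = parsimonyProbability(j, seqLength)))
  }
  j <- 0L
  while (j < seqLength &&
         parsimonyProbability(j + 1L, seqLength) >= confidence)
    j <- j + 1L
  new("ConnectionLimit", maxSteps = j, confidence = confidence,
      seqLength = seqLength,
      probability = parsimonyProbability(j, seqLength))
}

#' Probability that j uniformly placed mutations are homoplasy-free
#'
#' @param j Number of mutational steps.
#' @param seqLength Number of sites.
#' @return \code{prod(1 - (0:(j-1))/seqLength)}.
#' @export
parsimonyProbability <- function(j, seqLength) {
  if (j <= 0L) return(1)
  if (j > seqLength) return(0)
  prod(1 - (seq_len(j) - 1) / seqLength)
}

#' Group haplotypes into statistical-parsimony networks
#'
#' Haplotypes are joined whenever they lie at most \code{maxSteps} mutational
#' steps apart; networks are the connected components of that graph, and the
#' specimen-level partition is obtained by mapping each specimen through its
#' haplotype.  Isolated haplotypes form singleton networks.
#'
#' @param ht A \code{HaplotypeTable} from \code{\link{collapseHaplotypes}}.
#' @param stepsH Integer matrix of mutational steps (mismatch counts) between
#'   haplotype representatives, with haplotype names as dimnames.
#' @param limit A \code{\linkS4class{ConnectionLimit}}.
#' @return A specimen-level \code{\linkS4class{Partition}}.
#' @export
parsimonyNetworks <- function(ht, stepsH, limit) {
  stopifnot(inherits(ht, "HaplotypeTable"), is(limit, "ConnectionLimit"))
  if (!is.matrix(stepsH) || !is.numeric(stepsH))
    stop("stepsH must be a numeric matrix of step counts")
  if (any(abs(stepsH - round(stepsH)) > 1e-9))
    stop("stepsH must contain integer mutational step counts")
  hNames <- names(ht$representatives)
  stepsH <- stepsH[hNames, hNames, drop = FALSE]
  pairs <- which(stepsH <= limit@maxSteps & upper.tri(stepsH), arr.ind = TRUE)
  hapPart <- .componentsPartition(hNames, pairs)
  netOfHap <- groupOf(hapPart)
  spHap <- hNames[ht$haplotypeOfSpecimen]
  Partition(stats::setNames(netOfHap[spHap], names(ht$haplotypeOfSpecimen)))
}

#' Haplotype step matrix for parsimony networks
#'
#' Convenience wrapper: collapses an alignment to haplotypes and counts raw
#' pairwise mismatches (pairwise deletion of gap/ambiguity sites) between
#' the haplotype representatives.
#'
#' @param aln A named \code{DNAStringSet}.
#' @return List with \code{haplotypes} (a \code{HaplotypeTable}) and
#'   \code{steps} (integer matrix over haplotypes).
#' @export
haplotypeSteps <- function(aln) {
  ht <- collapseHaplotypes(aln)
  mm <- mismatchMatrix(ht$representatives)
  list(haplotypes = ht, steps = mm$steps)
}

#' Write a partition as TSV
#'
#' @param p A \code{\linkS4class{Partition}}.
#' @param method Method label written into the second column.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writePartition <- function(p, method, path) {
  g <- groupOf(p)
  utils::write.table(
    data.frame(specimen_id = names(g), method = method, group_label = unname(g),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
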