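# canonical string key of a specimen block (order-free)
.blockKey <- function(ids) paste(sort(ids), collapse = "\r")

#' Compare a test partition against a reference partition
#'
#' Classifies every reference group (e.g. a morphospecies) against a test
#' partition (e.g. a MOTU set): a group is a \emph{perfect match} when it is
#' exactly equal to some test group, \emph{split} when its specimens occupy
#' two or more test groups, and \emph{lumped} when some test group holding
#' any of its specimens also holds specimens of another reference group.  A
#' group can be both split and lumped; a singleton reference group inside a
#' larger test group counts as lumped.  The bookkeeping identity
#' \code{perfect + split + lumped - both = nRefGroups} always holds.
#'
#' @param ref,test \code{\linkS4class{Partition}} objects over the same
#'   specimen set.
#' @return A \code{\linkS4class{CongruenceReport}} (asymmetric: swap the
#'   arguments to reverse the direction).
#' @examples
#' ref <- Partition(c(s1 = "A", s2 = "A", s3 = "B"))
#' test <- Partition(c(s1 = "X", s2 = "Y", s3 = "Z"))
#' comparePartitions(ref, test)
#' @export
comparePartitions <- function(ref, test) {
  stopifnot(is(ref, "Partition"), is(test, "Partition"))
  rs <- specimens(ref); ts <- specimens(test)
  if (!setequal(rs, ts)) {
    d <- c(setdiff(rs, ts), setdiff(ts, rs))
    stop("partitions cover different specimens; symmetric difference: ",
         paste(d, collapse = ", "))
  }
  refBlocks <- blocks(ref)
  testBlocks <- blocks(test)
  testOf <- groupOf(test)
  testSize <- vapply(testBlocks, length, 1L)
  testKeys <- vapply(testBlocks, .blockKey, "")

  perfect <- split <- lumped <- logical(length(refBlocks))
  nonsingleton <- logical(length(refBlocks))
  for (i in seq_along(refBlocks)) {
    b <- refBlocks[[i]]
    touched <- unique(testOf[b])
    split[i] <- length(touched) >= 2L
    lumped[i] <- any(testSize[touched] > vapply(touched, function(g)
      sum(testOf[b] == g), 1L))
    perfect[i] <- !split[i] && !lumped[i]
    nonsingleton[i] <- perfect[i] && length(b) >= 2L
  }
  nref <- length(refBlocks); ntest <- length(testBlocks)
  new("CongruenceReport",
      nRefGroups = nref, nTestGroups = ntest,
      nPerfectMatches = sum(perfect), nPerfectNonsingleton = sum(nonsingleton),
      nSplitRef = sum(split), nLumpedRef = sum(lumped),
      nBothSplitAndLumped = sum(split & lumped),
      accuracyPercent = roundHalfUp(100 * sum(perfect) / nref, 2),
      ratioTestVsRef = roundHalfUp(ntest / nref, 2),
      singletonCountTest = sum(testSize == 1L),
      doubletonCountTest = sum(testSize == 2L))
}

#' Pairwise perfect-match matrix over several partitions
#'
#' For every ordered pair of partitions counts the blocks that are
#' identically delimited by both; the diagonal carries each partition's own
#' group count.
#'
#' @param partitions Named list of \code{\linkS4class{Partition}} objects
#'   over the same specimens.
#' @return Symmetric integer matrix with partition names as dimnames.
#' @export
pairwiseMatchMatrix <- function(partitions) {
  stopifnot(is.list(partitions), length(partitions) >= 1L,
            !is.null(names(partitions)))
  base <- sort(specimens(partitions[[1L]]))
  keys <- lapply(partitions, function(p) {
    if (!setequal(specimens(p), base))
      stop("all partitions must cover the same specimen set")
    vapply(blocks(p), .blockKey, "")
  })
  k <- length(partitions)
  m <- matrix(0L, k, k, dimnames = list(names(partitions), names(partitions)))
  for (i in seq_len(k)) {
    m[i, i] <- length(keys[[i]])
    if (i < k) for (j in (i + 1L):k) {
      m[i, j] <- m[j, i] <- length(intersect(keys[[i]], keys[[j]]))
    }
  }
  m
}

#' Singleton/doubleton summary of a partition
#'
#' @param p A \code{\linkS4class{Partition}}.
#' @return A list with \code{nGroups}, \code{nSingletonGroups},
#'   \code{nDoubletonPairs} (groups of exactly 2 specimens),
#'   \code{nDoubletonSpecimens} (2 x pairs) and
#'   \code{singletonFractionPercent} (one decimal, half-up rounding).
#' @examples
#' motuSummary(Partition(c(a = "X", b = "X", c = "Y")))
#' @export
motuSummary <- function(p) {
  stopifnot(is(p, "Partition"))
  sz <- vapply(blocks(p), length, 1L)
  list(nGroups = length(sz),
       nSingletonGroups = sum(sz == 1L),
       nDoubletonPairs = sum(sz == 2L),
       nDoubletonSpecimens = 2L * sum(sz == 2L),
       singletonFractionPercent = roundHalfUp(100 * sum(sz == 1L) / length(sz), 1))
}

#' Write a congruence report as JSON and TSV
#'
#' @param report A \code{\linkS4class{CongruenceReport}}.
#' @param pathJson,pathTsv Output paths (either may be \code{NULL}).
#' @return List of the report fields, invisibly.
#' @export
writeCongruenceReport <- function(report, pathJson = NULL, pathTsv = NULL) {
  f <- list(
    n_ref_groups = report@nRefGroups,
    n_test_groups = report@nTestGroups,
    n_perfect_matches = report@nPerfectMatches,
    n_perfect_nonsingleton = report@nPerfectNonsingleton,
    n_split_ref = report@nSplitRef,
    n_lumped_ref = report@nLumpedRef,
    n_both_split_and_lumped = report@nBothSplitAndLumped,
    accuracy_percent = report@accuracyPercent,
    ratio_test_vs_ref = report@ratioTestVsRef,
    singleton_count_test = report@singletonCountTest,
    doubleton_count_test = report@doubletonCountTest)
  if (!is.null(pathJson))
    jsonlite::write_json(f, pathJson, auto_unbox = TRUE, digits = NA)
  if (!is.null(pathTsv))
    utils::write.table(data.frame(field = names(f),
                                  value = unlist(f, use.names = FALSE)),
                       pathTsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(f)
}
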