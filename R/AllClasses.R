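#' @import methods
NULL

#' Partition of specimens into species-like groups
#'
#' A \code{Partition} assigns every specimen to exactly one group
#' (a morphospecies, a MOTU, or a haplotype class).  Groups are identified
#' by character labels; block membership, not the label text, is what the
#' congruence machinery compares.
#'
#' @slot groups Named character vector mapping specimen id to group label.
#' @export
setClass("Partition", representation(groups = "character"))

setValidity("Partition", function(object) {
  g <- object@groups
  ids <- names(g)
  if (length(g) == 0L) return("partition is empty")
  if (is.null(ids) || any(ids == "") || anyNA(ids))
    return("all specimens must be named")
  if (anyDuplicated(ids)) return("duplicated specimen ids")
  if (anyNA(g) || any(g == "")) return("all specimens must carry a group label")
  TRUE
})

#' Construct a Partition
#'
#' @param groups Named character vector (or factor) mapping specimen id to
#'   group label, or an unnamed vector accompanied by \code{specimens}.
#' @param specimens Optional character vector of specimen ids, used when
#'   \code{groups} is unnamed.
#' @return A \code{\linkS4class{Partition}}.
#' @examples
#' p <- Partition(c(s1 = "A", s2 = "A", s3 = "B"))
#' nGroups(p)
#' @export
Partition <- function(groups, specimens = NULL) {
  nm <- if (is.null(specimens)) names(groups) else as.character(specimens)
  groups <- stats::setNames(as.character(groups), nm)
  new("Partition", groups = groups)
}

#' @describeIn Partition Specimen ids covered by the partition.
#' @param x,object A \code{Partition}.
#' @export
setGeneric("specimens", function(x) standardGeneric("specimens"))

#' @export
setMethod("specimens", "Partition", function(x) names(x@groups))

#' @describeIn Partition Group label of every specimen (named character).
#' @export
setGeneric("groupOf", function(x) standardGeneric("groupOf"))

#' @export
setMethod("groupOf", "Partition", function(x) x@groups)

#' @describeIn Partition Number of groups.
#' @export
setGeneric("nGroups", function(x) standardGeneric("nGroups"))

#' @export
setMethod("nGroups", "Partition", function(x) length(unique(x@groups)))

#' @describeIn Partition List of specimen-id blocks, one per group.
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))

#' @export
setMethod("blocks", "Partition", function(x) {
  split(names(x@groups), x@groups)
})

setMethod("show", "Partition", function(object) {
  sz <- table(object@groups)
  cat("Partition:", length(object@groups), "specimens in",
      length(sz), "groups\n")
  cat("  singleton groups:", sum(sz == 1L),
      " largest group:", max(sz), "\n")
})

#' Ground truth of a simulated community
#'
#' Holds the known species identity, abundance structure, elevational level
#' and sampling-unit assignment of every simulated specimen, so downstream
#' delimitation and richness estimates can be checked against truth.
#'
#' @slot speciesCount Number of true species.
#' @slot abundances Integer specimen count per species (named by species id).
#' @slot truePartition \code{\linkS4class{Partition}} specimen -> true species.
#' @slot levelOfSpecies Primary elevation level (m) per species.
#' @slot multiLevel Logical per species: occurs at two adjacent levels.
#' @slot unitOfSpecimen Sampling-unit id per specimen (named).
#' @slot methodOfSpecimen Collection method per specimen (named).
#' @slot levelOfSpecimen Elevation level (m) per specimen (named).
#' @slot seed Integer seed the community was generated from.
#' @export
setClass("CommunityTruth", representation(
  speciesCount = "integer",
  abundances = "integer",
  truePartition = "Partition",
  levelOfSpecies = "integer",
  multiLevel = "logical",
  unitOfSpecimen = "character",
  methodOfSpecimen = "character",
  levelOfSpecimen = "integer",
  seed = "integer"
))

setValidity("CommunityTruth", function(object) {
  if (sum(object@abundances) != length(specimens(object@truePartition)))
    return("abundances must sum to the number of specimens")
  if (any(object@abundances < 1L)) return("every abundance must be >= 1")
  bl <- vapply(blocks(object@truePartition), length, 1L)
  if (!identical(sort(as.integer(bl)), sort(as.integer(object@abundances))))
    return("true partition blocks must match the abundance vector")
  TRUE
})

setMethod("show", "CommunityTruth", function(object) {
  cat("CommunityTruth:", object@speciesCount, "species,",
      sum(object@abundances), "specimens\n")
  cat(sprintf("  singleton species: %d (%.1f%%)\n",
              sum(object@abundances == 1L),
              100 * mean(object@abundances == 1L)))
  cat("  levels:", paste(sort(unique(object@levelOfSpecies)), collapse = ", "),
      "m; seed:", object@seed, "\n")
})

#' Fitted single-threshold GMYC model
#'
#' @slot threshold Threshold age separating diversification from coalescence.
#' @slot lambda1,lambda2 Rates of the diversification and coalescent classes.
#' @slot p1,p2 Scaling exponents of the two classes.
#' @slot logLalt,logLnull Log-likelihoods of the mixed and one-class models.
#' @slot LR Likelihood-ratio statistic, \code{2 * (logLalt - logLnull)}.
#' @slot pValue Chi-squared p-value of the LR test.
#' @slot df Degrees of freedom used for the reference distribution.
#' @slot nEntities Number of delimited entities at the ML threshold.
#' @slot partition Induced specimen \code{\linkS4class{Partition}}.
#' @export
setClass("GmycFit", representation(
  threshold = "numeric", lambda1 = "numeric", lambda2 = "numeric",
  p1 = "numeric", p2 = "numeric",
  logLalt = "numeric", logLnull = "numeric",
  LR = "numeric", pValue = "numeric", df = "numeric",
  nEntities = "integer", partition = "Partition"
))

setValidity("GmycFit", function(object) {
  if (object@logLalt < object@logLnull - 1e-6)
    return("alternative log-likelihood below null")
  if (object@LR < -1e-6) return("negative LR statistic")
  if (object@nEntities < 1L) return("fewer than one entity")
  TRUE
})

setMethod("show", "GmycFit", function(object) {
  cat("Single-threshold GMYC fit\n")
  cat(sprintf("  entities: %d  threshold age: %.4g\n",
              object@nEntities, object@threshold))
  cat(sprintf("  logL alt: %.3f  null: %.3f  LR: %.3f  p = %.4g (df %g)\n",
              object@logLalt, object@logLnull, object@LR,
              object@pValue, object@df))
})

#' Fitted PTP (Poisson tree processes) model
#'
#' @slot rateSpeciation,rateCoalescent ML exponential rates of the
#'   between-species and within-species branch-length classes.
#' @slot logL Log-likelihood of the ML configuration.
#' @slot nEntities Number of delimited entities.
#' @slot degenerate TRUE when branch lengths carry no rate-shift signal.
#' @slot partition Induced specimen \code{\linkS4class{Partition}}.
#' @export
setClass("PtpFit", representation(
  rateSpeciation = "numeric", rateCoalescent = "numeric",
  logL = "numeric", nEntities = "integer", degenerate = "logical",
  partition = "Partition"
))

setMethod("show", "PtpFit", function(object) {
  cat("PTP fit\n")
  cat(sprintf("  entities: %d  logL: %.3f%s\n", object@nEntities,
              object@logL, if (object@degenerate) "  (degenerate)" else ""))
  cat(sprintf("  speciation rate: %.4g  coalescent rate: %.4g\n",
              object@rateSpeciation, object@rateCoalescent))
})

#' Congruence accounting between two partitions
#'
#' Asymmetric comparison of a test partition (typically a MOTU set) against a
#' reference partition (typically morphospecies): perfect matches, split and
#' lumped reference groups, and summary ratios.
#'
#' @slot nRefGroups,nTestGroups Group counts of the two partitions.
#' @slot nPerfectMatches Reference groups identical to some test group.
#' @slot nPerfectNonsingleton Perfect matches of size >= 2.
#' @slot nSplitRef Reference groups whose members occupy >= 2 test groups.
#' @slot nLumpedRef Reference groups sharing a test group with another
#'   reference group.
#' @slot nBothSplitAndLumped Reference groups that are both split and lumped.
#' @slot accuracyPercent 100 * perfect / reference groups.
#' @slot ratioTestVsRef Test group count over reference group count.
#' @slot singletonCountTest,doubletonCountTest Singleton and doubleton group
#'   counts of the test partition.
#' @export
setClass("CongruenceReport", representation(
  nRefGroups = "integer", nTestGroups = "integer",
  nPerfectMatches = "integer", nPerfectNonsingleton = "integer",
  nSplitRef = "integer", nLumpedRef = "integer",
  nBothSplitAndLumped = "integer",
  accuracyPercent = "numeric", ratioTestVsRef = "numeric",
  singletonCountTest = "integer", doubletonCountTest = "integer"
))

setValidity("CongruenceReport", function(object) {
  if (object@nPerfectMatches + object@nSplitRef + object@nLumpedRef -
      object@nBothSplitAndLumped != object@nRefGroups)
    return("perfect + split + lumped - both must equal the reference group count")
  TRUE
})

setMethod("show", "CongruenceReport", function(object) {
  cat("Congruence report (reference vs test)\n")
  cat(sprintf("  groups: %d ref, %d test (ratio %.2f)\n",
              object@nRefGroups, object@nTestGroups, object@ratioTestVsRef))
  cat(sprintf("  perfect matches: %d (%.2f%%; %d non-singleton)\n",
              object@nPerfectMatches, object@accuracyPercent,
              object@nPerfectNonsingleton))
  cat(sprintf("  split: %d  lumped: %d  both: %d\n",
              object@nSplitRef, object@nLumpedRef, object@nBothSplitAndLumped))
})

#' Statistical-parsimony connection limit
#'
#' The maximum number of mutational steps at which two haplotypes may be
#' joined into one network while the connection remains free of homoplasy
#' with the stated confidence.
#'
#' @slot maxSteps Maximum number of connecting steps.
#' @slot confidence Required probability of a non-homoplasious connection.
#' @slot seqLength Alignment length (sites) the limit was computed for.
#' @slot probability Parsimony probability attained at \code{maxSteps}.
#' @export
setClass("ConnectionLimit", representation(
  maxSteps = "integer", confidence = "numeric",
  seqLength = "integer", probability = "numeric"
))

setMethod("show", "ConnectionLimit", function(object) {
  cat(sprintf(
    "Connection limit: %d steps (%g%% confidence, %d sites, P = %.4f)\n",
    object@maxSteps, 100 * object@confidence, object@seqLength,
    object@probability))
})
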