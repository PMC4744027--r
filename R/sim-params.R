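#' Simulation parameters for the synthetic community generator
#'
#' Bundles every knob of the generator.  The defaults are calibrated to the
#' structure of a singleton-heavy tropical leaf-beetle barcode survey:
#' 266 species sampled as roughly 674 specimens of a 658-bp COI alignment,
#' about 52.6\% singleton species, three elevational levels (1000/2000/3000 m)
#' with near-complete turnover, and parataxonomic labelling error of the
#' split/lump kind.
#'
#' @param nSpecies Number of true species.
#' @param abundanceModel Either \code{list(type = "geometric", first, ratio)}
#'   giving a geometric rank-abundance series \code{round(first * ratio^(i-1))}
#'   (floored at 1), or \code{list(type = "explicit", abundances = <vector>)}.
#' @param targetSingletonFraction Desired fraction of species represented by
#'   a single specimen; realized within +/- 5 percentage points by forcing
#'   the smallest remaining abundances to 1 (or raising drawn singletons to 2
#'   on overshoot), up to an iteration cap of \code{nSpecies} moves.
#' @param speciationRate Yule birth rate of the species tree (per lineage,
#'   in units where the realized root age is later normalized to 1).
#' @param terminalGap Fraction of the (normalized) root age occupied by a
#'   speciation-free terminal window; emulates the deep interspecific
#'   divergence of a regionally restricted community sample.
#' @param coalescentScale Expected within-species coalescent tree depth as a
#'   fraction of the species-tree depth.
#' @param mutationRate Expected substitutions per site over one unit of tree
#'   time (the normalized root age).
#' @param alignmentLength Number of aligned sites (default 658).
#' @param nLevels Number of elevational levels (default 3: 1000/2000/3000 m).
#' @param turnoverProb Probability that a species is confined to exactly one
#'   elevational level.
#' @param splitRate Probability that a multi-specimen species is split into
#'   two morphospecies labels by the simulated parataxonomist.
#' @param lumpRate Probability that a pair of species adjacent in species-tree
#'   tip order is lumped under one morphospecies label.
#' @param seed Integer seed; every stochastic stage derives its stream from
#'   it deterministically.
#' @return A list of class \code{SimParams}.
#' @examples
#' p <- simParams(nSpecies = 20, seed = 1)
#' p$alignmentLength
#' @export
simParams <- function(nSpecies = 266L,
                      abundanceModel = list(type = "geometric",
                                            first = 7.5, ratio = 0.99),
                      targetSingletonFraction = 0.526,
                      speciationRate = 1,
                      terminalGap = 0.3,
                      coalescentScale = 0.02,
                      mutationRate = 0.1,
                      alignmentLength = 658L,
                      nLevels = 3L,
                      turnoverProb = 0.92,
                      splitRate = 0.15,
                      lumpRate = 0.15,
                      seed = 1L) {
  stopifnot(nSpecies >= 1L, alignmentLength >= 1L,
            speciationRate >= 0, coalescentScale >= 0, mutationRate >= 0,
            terminalGap >= 0, terminalGap < 1,
            targetSingletonFraction >= 0, targetSingletonFraction <= 1,
            turnoverProb >= 0, turnoverProb <= 1,
            splitRate >= 0, splitRate <= 1, lumpRate >= 0, lumpRate <= 1,
            nLevels >= 1L)
  if (!is.list(abundanceModel) || is.null(abundanceModel$type) ||
      !abundanceModel$type %in% c("geometric", "explicit"))
    stop("abundanceModel must be a geometric or explicit specification")
  structure(list(
    nSpecies = as.integer(nSpecies),
    abundanceModel = abundanceModel,
    targetSingletonFraction = targetSingletonFraction,
    speciationRate = speciationRate,
    terminalGap = terminalGap,
    coalescentScale = coalescentScale,
    mutationRate = mutationRate,
    alignmentLength = as.integer(alignmentLength),
    nLevels = as.integer(nLevels),
    turnoverProb = turnoverProb,
    splitRate = splitRate,
    lumpRate = lumpRate,
    seed = as.integer(seed)
  ), class = "SimParams")
}

#' @export
print.SimParams <- function(x, ...) {
  cat("SimParams:", x$nSpecies, "species,", x$alignmentLength,
      "bp, seed", x$seed, "\n")
  invisible(x)
}
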