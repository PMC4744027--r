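#' Simulate a community with known ground truth
#'
#' Draws a rank-abundance vector (geometric series or explicit), adjusts it
#' until the realized singleton fraction is within 5 percentage points of the
#' target, and assigns species to elevational levels and specimens to
#' sampling units.  A fraction \code{turnoverProb} of species is confined to
#' a single level; the remainder span two adjacent levels (possible only for
#' species with >= 2 specimens).  Sampling units are level-specific replicates
#' of five collection methods (sweep-netting, beating, hand collection,
#' light- and Malaise-trapping).
#'
#' @param params A \code{\link{simParams}} object.
#' @return A \code{\linkS4class{CommunityTruth}}.
#' @examples
#' truth <- simulateCommunity(simParams(nSpecies = 12, seed = 1))
#' truth
#' @export
simulateCommunity <- function(params) {
  stopifnot(inherits(params, "SimParams"))
  set.seed(.stageSeed(params$seed, 1L))
  n <- params$nSpecies

  am <- params$abundanceModel
  if (am$type == "explicit") {
    ab <- as.integer(am$abundances)
    if (length(ab) != n) stop("explicit abundance vector must have nSpecies entries")
    if (any(ab < 1L)) stop("abundances must be >= 1")
  } else {
    ab <- pmax(1L, as.integer(round(am$first * am$ratio^(seq_len(n) - 1))))
  }

  # nudge toward the target singleton fraction (+/- 5 points), capped
  target <- params$targetSingletonFraction
  cap <- n
  it <- 0L
  step <- 1 / n                     # each move changes the fraction by 1/n
  repeat {
    frac <- mean(ab == 1L)
    if (abs(frac - target) <= step / 2 || it >= cap) break
    if (frac < target) {
      cand <- which(ab > 1L)
      if (!length(cand)) break
      ab[cand[which.min(ab[cand])]] <- 1L
    } else {
      cand <- which(ab == 1L)
      if (!length(cand)) break
      ab[cand[1L]] <- 2L
    }
    it <- it + 1L
  }
  frac <- mean(ab == 1L)
  if (abs(frac - target) > 0.05)
    stop(sprintf(
      "singleton target %.3f unreachable within %d adjustments (achieved %.3f)",
      target, cap, frac))

  spId <- sprintf("sp%03d", seq_len(n))
  names(ab) <- spId
  specimen <- unlist(lapply(seq_len(n), function(i)
    sprintf("%s_%02d", spId[i], seq_len(ab[i]))), use.names = FALSE)
  speciesOf <- rep(spId, ab)

  levels <- c(1000L, 2000L, 3000L)[seq_len(min(params$nLevels, 3L))]
  if (params$nLevels > 3L) levels <- seq(1000L, by = 1000L,
                                         length.out = params$nLevels)
  primary <- if (length(levels) == 1L) rep(levels, n) else
    sample(levels, n, replace = TRUE)
  single <- stats::runif(n) < params$turnoverProb
  multi <- !single & ab >= 2L & length(levels) > 1L

  # second (adjacent) level for spanning species
  secondLevel <- rep(NA_integer_, n)
  if (any(multi)) {
    for (i in which(multi)) {
      pos <- match(primary[i], levels)
      nb <- c(pos - 1L, pos + 1L)
      nb <- nb[nb >= 1L & nb <= length(levels)]
      secondLevel[i] <- levels[if (length(nb) == 1L) nb else sample(nb, 1L)]
    }
  }

  # sampling units: per level, replicates of standard methods plus traps
  methods <- c("sweep", "beating", "hand", "light", "malaise")
  unitTab <- do.call(rbind, lapply(levels, function(lv) {
    data.frame(
      unit = c(sprintf("L%d_%s_%d", lv, rep(c("sweep", "beating", "hand"),
                                            each = 4L), 1:4),
               sprintf("L%d_%s_1", lv, c("light", "malaise"))),
      level = lv,
      method = c(rep(c("sweep", "beating", "hand"), each = 4L),
                 "light", "malaise"),
      stringsAsFactors = FALSE)
  }))
  mw <- c(sweep = 0.28, beating = 0.28, hand = 0.28,
          light = 0.08, malaise = 0.08)

  lvOfSpec <- integer(length(specimen))
  unitOfSpec <- character(length(specimen))
  k0 <- 0L
  for (i in seq_len(n)) {
    k <- ab[i]
    lv <- rep(primary[i], k)
    if (multi[i]) {
      # at least one specimen at each of the two levels
      nSecond <- 1L + stats::rbinom(1L, k - 2L, 0.5)
      lv[sample(k, nSecond)] <- secondLevel[i]
    }
    for (j in seq_len(k)) {
      cand <- unitTab[unitTab$level == lv[j], ]
      w <- mw[cand$method]
      unitOfSpec[k0 + j] <- cand$unit[sample(nrow(cand), 1L, prob = w)]
    }
    lvOfSpec[k0 + seq_len(k)] <- lv
    k0 <- k0 + k
  }
  methodOfSpec <- unitTab$method[match(unitOfSpec, unitTab$unit)]

  new("CommunityTruth",
      speciesCount = n,
      abundances = ab,
      truePartition = Partition(stats::setNames(speciesOf, specimen)),
      levelOfSpecies = stats::setNames(primary, spId),
      multiLevel = stats::setNames(multi, spId),
      unitOfSpecimen = stats::setNames(unitOfSpec, specimen),
      methodOfSpecimen = stats::setNames(methodOfSpec, specimen),
      levelOfSpecimen = stats::setNames(lvOfSpec, specimen),
      seed = params$seed)
}

# coalescent subtree for one species, scaled to a stochastic depth with
# expectation ~ scale, clamped below the attachment age
.coalSubtreeNewick <- function(tipIds, scale, attachAge) {
  k <- length(tipIds)
  ct <- ape::rcoal(k, tip.label = tipIds)
  depth <- max(ape::node.depth.edgelength(ct))
  target <- depth * scale / 2          # E[raw depth] = 2(1 - 1/k)
  if (target >= 0.9 * attachAge) target <- 0.9 * attachAge
  ct$edge.length <- ct$edge.length * (target / depth)
  nwk <- ape::write.tree(ct, digits = 14)
  list(newick = sub(";$", "", nwk), depth = target)
}

#' Simulate the genealogy of a community
#'
#' Builds an ultrametric specimen genealogy from two nested processes: a
#' Yule species tree (followed by a speciation-free terminal window of
#' relative length \code{terminalGap}) and an independent Kingman coalescent
#' within each species, scaled by \code{coalescentScale} and grafted so that
#' every within-species subtree is strictly younger than the origin of its
#' species' terminal branch.  The root age is normalized to 1 and tips are
#' labelled by specimen id.  Species with a single specimen contribute a
#' single tip.
#'
#' @param truth A \code{\linkS4class{CommunityTruth}}.
#' @param params The \code{\link{simParams}} used to generate it.
#' @return An ultrametric rooted \code{phylo}; the attribute
#'   \code{"speciesTipOrder"} records the species order along the tree tips.
#' @export
simulateGenealogy <- function(truth, params) {
  stopifnot(is(truth, "CommunityTruth"), inherits(params, "SimParams"))
  specimen <- specimens(truth@truePartition)
  if (length(specimen) < 2L) stop("need at least 2 specimens")
  set.seed(.stageSeed(params$seed, 2L))
  n <- truth@speciesCount
  ab <- truth@abundances
  spId <- names(ab)

  if (n == 1L) {
    ct <- ape::rcoal(ab[1L], tip.label = specimen)
    ct$edge.length <- ct$edge.length / max(ape::node.depth.edgelength(ct))
    tree <- ct
    attr(tree, "speciesTipOrder") <- spId
    return(tree)
  }

  st <- ape::rphylo(n, birth = max(params$speciationRate, 1e-8), death = 0)
  st$tip.label <- spId[sample(n)]       # random tip placement
  st$edge.length <- st$edge.length / max(ape::node.depth.edgelength(st))
  if (params$terminalGap > 0) {
    g <- params$terminalGap / (1 - params$terminalGap)
    pend <- st$edge[, 2L] <= n
    st$edge.length[pend] <- st$edge.length[pend] + g
    st$edge.length <- st$edge.length / (1 + g)
  }

  ages <- .nodeAges(st)
  nwk <- sub(";$", "", ape::write.tree(st, digits = 14))
  for (sp in spId) {
    tip <- match(sp, st$tip.label)
    k <- ab[sp]
    ids <- names(truth@truePartition@groups)[truth@truePartition@groups == sp]
    if (k == 1L) {
      nwk <- sub(paste0("([(,])", sp, ":"),
                 paste0("\\1", ids, ":"), nwk)
    } else {
      parent <- st$edge[st$edge[, 2L] == tip, 1L]
      attachAge <- ages[parent]
      sub <- .coalSubtreeNewick(ids, params$coalescentScale, attachAge)
      m <- regmatches(nwk, regexec(paste0("([(,])", sp, ":([0-9.eE+-]+)"), nwk))[[1]]
      blen <- as.numeric(m[3L])
      nwk <- sub(paste0("([(,])", sp, ":[0-9.eE+-]+"),
                 sprintf("\\1%s:%.14g", sub$newick,
                         max(blen - sub$depth, 1e-12)),
                 nwk)
    }
  }
  tree <- ape::read.tree(text = paste0(nwk, ";"))

  # snap tips exactly onto the present and the root onto age 1
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth[seq_len(ape::Ntip(tree))])
  pend <- match(seq_len(ape::Ntip(tree)), tree$edge[, 2L])
  tree$edge.length[pend] <- tree$edge.length[pend] +
    (h - depth[seq_len(ape::Ntip(tree))])
  tree$edge.length <- tree$edge.length / h
  sto <- unique(truth@truePartition@groups[tree$tip.label])
  attr(tree, "speciesTipOrder") <- sto
  tree
}

#' Evolve sequences along a genealogy under Jukes-Cantor
#'
#' The root sequence is uniform random over A/C/G/T; substitutions accrue
#' along branches under JC69 with \code{mutationRate} expected substitutions
#' per site per unit branch length.  Sequences are emitted already aligned
#' (no indels).
#'
#' @param tree A rooted \code{phylo} with branch lengths in time units.
#' @param params A \code{\link{simParams}} object.
#' @return A named \code{DNAStringSet}, one record per tree tip, all of
#'   length \code{alignmentLength}.
#' @export
simulateSequences <- function(tree, params) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "SimParams"))
  set.seed(.stageSeed(params$seed, 3L))
  len <- params$alignmentLength
  if (params$mutationRate == 0) {
    root <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
    s <- rep(root, ape::Ntip(tree))
    return(Biostrings::DNAStringSet(stats::setNames(s, tree$tip.label)))
  }
  sim <- phangorn::simSeq(tree, l = len, rate = params$mutationRate,
                          type = "DNA")
  m <- toupper(as.character(sim))
  s <- apply(m, 1L, paste, collapse = "")
  Biostrings::DNAStringSet(stats::setNames(s, rownames(m)))
}

#' Convert a time genealogy into a substitution tree
#'
#' Replaces every branch length (time units) by the realized number of
#' substitutions per site: a Poisson draw with mean
#' \code{mutationRate * time * alignmentLength}, divided by the alignment
#' length.  This mirrors what a tree inferred from finite sequences carries
#' -- in particular, branches short enough to have accumulated no
#' substitutions come out with length zero -- and is the branch-length
#' currency the PTP model operates on.
#'
#' @param tree A rooted \code{phylo} with branch lengths in time units.
#' @param params A \code{\link{simParams}} object.
#' @return A \code{phylo} with branch lengths in substitutions per site.
#' @export
substitutionTree <- function(tree, params) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "SimParams"))
  set.seed(.stageSeed(params$seed, 8L))
  lam <- params$mutationRate * tree$edge.length * params$alignmentLength
  out <- tree
  out$edge.length <- stats::rpois(length(lam), lam) / params$alignmentLength
  out
}

#' Perturb the true partition into parataxonomic morphospecies labels
#'
#' Emulates sorting error: each multi-specimen species is split into two
#' labels with probability \code{splitRate} (a uniform random bipartition of
#' its specimens), and each consecutive pair of species in species-tree tip
#' order is lumped under one label with probability \code{lumpRate} (pairs
#' containing a split species are left alone, so the result is a valid
#' partition).
#'
#' @param truth A \code{\linkS4class{CommunityTruth}}.
#' @param splitRate,lumpRate Probabilities in \code{[0, 1]}.
#' @param seed Integer seed.
#' @param speciesOrder Optional character vector giving the species-tree tip
#'   order (as recorded by \code{\link{simulateGenealogy}}); defaults to
#'   species id order.
#' @return A \code{\linkS4class{Partition}} of morphospecies labels.
#' @export
corruptMorphospecies <- function(truth, splitRate, lumpRate, seed,
                                 speciesOrder = NULL) {
  stopifnot(is(truth, "CommunityTruth"),
            splitRate >= 0, splitRate <= 1, lumpRate >= 0, lumpRate <= 1)
  set.seed(.stageSeed(seed, 4L))
  g <- truth@truePartition@groups
  spId <- names(truth@abundances)
  if (is.null(speciesOrder)) speciesOrder <- spId
  stopifnot(setequal(speciesOrder, spId))

  out <- paste0("m_", g)
  names(out) <- names(g)
  splitSp <- character(0)
  for (sp in spId) {
    members <- names(g)[g == sp]
    k <- length(members)
    if (k >= 2L && stats::runif(1L) < splitRate) {
      u <- sample(k - 1L, 1L)
      sideA <- sample(members, u)
      out[sideA] <- paste0("m_", sp, "_a")
      out[setdiff(members, sideA)] <- paste0("m_", sp, "_b")
      splitSp <- c(splitSp, sp)
    }
  }
  pairsStart <- if (length(speciesOrder) >= 2L)
    seq(1L, length(speciesOrder) - 1L, by = 2L) else integer(0)
  for (i in pairsStart) {
    a <- speciesOrder[i]; b <- speciesOrder[i + 1L]
    if (a %in% splitSp || b %in% splitSp) next
    if (stats::runif(1L) < lumpRate) {
      lab <- paste0("m_", a, "+", b)
      out[names(g)[g %in% c(a, b)]] <- lab
    }
  }
  Partition(out)
}
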