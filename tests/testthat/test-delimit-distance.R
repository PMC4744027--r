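mkDist <- function(v, ids) {
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  d[upper.tri(d)] <- v
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

test_that("threshold clustering is single-linkage transitive closure", {
  d <- mkDist(c(0.02, 0.10, 0.02), c("s1", "s2", "s3"))
  p <- clusterByThreshold(d, 0.03)
  expect_identical(nGroups(p), 1L)

  # no pair below the threshold: all singletons
  d2 <- mkDist(c(0.5, 0.6, 0.7), c("a", "b", "c"))
  expect_identical(nGroups(clusterByThreshold(d2, 0.03)), 3L)

  # strictly-below semantics: a tie at the threshold does not link
  d3 <- mkDist(0.03, c("a", "b"))
  expect_identical(nGroups(clusterByThreshold(d3, 0.03)), 2L)

  for (s in 1:20) {
    set.seed(s)
    n <- sample(5:30, 1)
    d <- mkDist(runif(n * (n - 1) / 2, 0, 0.12), sprintf("s%02d", 1:n))
    expect_lte(nGroups(clusterByThreshold(d, 0.075)),
               nGroups(clusterByThreshold(d, 0.03)))
  }
})

test_that("threshold clustering equals a DFS components oracle", {
  for (s in 1:200) {
    set.seed(s)
    n <- sample(4:30, 1)
    d <- mkDist(runif(n * (n - 1) / 2, 0, 0.1), sprintf("s%02d", 1:n))
    thr <- runif(1, 0.01, 0.09)
    mine <- groupOf(clusterByThreshold(d, thr))
    oracle <- componentsOracle(d, thr)
    # same grouping up to label names
    expect_identical(unname(vapply(split(names(mine), mine), paste,
                                   "", collapse = ",")),
                     unname(vapply(split(rownames(d), oracle), paste,
                                   "", collapse = ",")))
  }
})

test_that("the connection limit behaves like the parsimony probability", {
  lim <- connectionLimit(658, 0.95)
  expect_identical(lim@maxSteps, 8L)
  expect_gte(parsimonyProbability(lim@maxSteps, 658), 0.95)
  expect_lt(parsimonyProbability(lim@maxSteps + 1L, 658), 0.95)

  # non-increasing in confidence
  limits <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99),
                   function(cf) connectionLimit(658, cf)@maxSteps, 1L)
  expect_true(all(diff(limits) <= 0))

  # longer sequences allow more steps
  expect_gte(connectionLimit(1316, 0.95)@maxSteps,
             connectionLimit(658, 0.95)@maxSteps)

  # Monte-Carlo placement oracle of the same probability statement:
  # j mutations land on distinct sites of an m-site sequence
  set.seed(42)
  for (j in c(8L, 9L)) {
    hits <- mean(replicate(40000, {
      !anyDuplicated(sample.int(658, j, replace = TRUE))
    }))
    se <- sqrt(hits * (1 - hits) / 40000)
    expect_lt(abs(hits - parsimonyProbability(j, 658)), 3 * se)
  }

  expect_error(connectionLimit(0), ">= 1")
  expect_identical(connectionLimit(658, maxSteps = 12)@maxSteps, 12L)
})

test_that("parsimony networks are step-limited connected components", {
  ht <- collapseHaplotypes(Biostrings::DNAStringSet(
    c(s1 = "AAAA", s2 = "AAAT", s3 = "AAAT")))
  steps <- mismatchMatrix(ht$representatives)$steps
  p <- parsimonyNetworks(ht, steps,
                         connectionLimit(4, maxSteps = 10))
  expect_identical(nGroups(p), 1L)
  expect_identical(length(specimens(p)), 3L)

  # chain a-b-c with 8+8 steps joins via the chain despite a-c = 16
  ids <- c("a", "b", "c")
  stepM <- mkDist(c(8, 16, 8), ids)
  htc <- structure(list(
    haplotypeOfSpecimen = stats::setNames(1:3, ids),
    representatives = stats::setNames(Biostrings::DNAStringSet(
      c("A", "C", "G")), ids),
    nHaplotypes = 3L), class = "HaplotypeTable")
  names(htc$representatives) <- ids
  pc <- parsimonyNetworks(htc, stepM, connectionLimit(658, maxSteps = 10))
  expect_identical(nGroups(pc), 1L)

  # an isolated haplotype beyond the limit forms a singleton network
  stepM2 <- mkDist(c(2, 30, 30), ids)
  p2 <- parsimonyNetworks(htc, stepM2, connectionLimit(658, maxSteps = 10))
  expect_identical(nGroups(p2), 2L)

  # network count is non-increasing in the step limit
  counts <- vapply(c(1, 5, 10, 20, 40), function(ms)
    nGroups(parsimonyNetworks(htc, stepM2,
                              connectionLimit(658, maxSteps = ms))), 1L)
  expect_true(all(diff(counts) <= 0))

  expect_error(parsimonyNetworks(htc, stepM2 + 0.4,
                                 connectionLimit(658, maxSteps = 10)),
               "integer")
})

test_that("distance methods recover simulated species counts", {
  hits <- t(vapply(1:50, function(s) {
    fx <- simFixture(s)
    aln <- simulateSequences(fx$tree, fx$params)
    d <- pDistanceMatrix(aln)
    hs <- haplotypeSteps(aln)
    lim <- connectionLimit(fx$params$alignmentLength)
    c(dist = nGroups(clusterByThreshold(d, 0.03)),
      net = nGroups(parsimonyNetworks(hs$haplotypes, hs$steps, lim)))
  }, c(dist = 0, net = 0)))
  nTrue <- 20
  expect_gte(mean(abs(hits[, "dist"] - nTrue) <= 0.05 * nTrue), 0.9)
  expect_gte(mean(abs(hits[, "net"] - nTrue) <= 0.05 * nTrue), 0.9)
})
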