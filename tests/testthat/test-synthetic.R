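test_that("explicit unit abundances give an all-singleton community", {
  p <- simParams(nSpecies = 7,
                 abundanceModel = list(type = "explicit",
                                       abundances = rep(1L, 7)),
                 targetSingletonFraction = 1, seed = 3)
  truth <- simulateCommunity(p)
  expect_identical(sum(truth@abundances), 7L)
  expect_identical(length(specimens(truth@truePartition)), 7L)
  expect_true(all(truth@abundances == 1L))
})

test_that("study-scale defaults land near the published community shape", {
  truth <- simulateCommunity(simParams(seed = 11))
  frac <- mean(truth@abundances == 1L)
  expect_gte(frac, 0.476)
  expect_lte(frac, 0.576)
  expect_identical(truth@speciesCount, 266L)
})

test_that("the generator is deterministic under a fixed seed", {
  p <- simParams(nSpecies = 10, seed = 99)
  a <- simulateCommunity(p); b <- simulateCommunity(p)
  expect_identical(a@abundances, b@abundances)
  expect_identical(groupOf(a@truePartition), groupOf(b@truePartition))
  expect_identical(a@unitOfSpecimen, b@unitOfSpecimen)
  ta <- simulateGenealogy(a, p); tb <- simulateGenealogy(b, p)
  expect_identical(ape::write.tree(ta), ape::write.tree(tb))
  expect_identical(as.character(simulateSequences(ta, p)),
                   as.character(simulateSequences(tb, p)))
  ma <- corruptMorphospecies(a, 0.4, 0.4, 5)
  mb <- corruptMorphospecies(b, 0.4, 0.4, 5)
  expect_identical(groupOf(ma), groupOf(mb))
})

test_that("genealogies are ultrametric with monophyletic nested coalescents", {
  for (s in 1:25) {
    fx <- simFixture(s, nSpecies = 8)
    tr <- fx$tree
    expect_true(isUltrametricTree(tr, 1e-9))
    expect_equal(max(ape::node.depth.edgelength(tr)), 1, tolerance = 1e-9)
    ages <- max(ape::node.depth.edgelength(tr)) -
      ape::node.depth.edgelength(tr)
    parent <- integer(ape::Ntip(tr) + tr$Nnode)
    parent[tr$edge[, 2]] <- tr$edge[, 1]
    for (sp in names(which(fx$truth@abundances >= 2L))) {
      tips <- match(names(which(groupOf(fx$truth@truePartition) == sp)),
                    tr$tip.label)
      mrca <- ape::getMRCA(tr, tips)
      desc <- ape::extract.clade(tr, mrca)$tip.label
      expect_setequal(desc, tr$tip.label[tips])     # monophyletic
      expect_lt(ages[mrca], ages[parent[mrca]])     # younger than stem origin
    }
  }
})

test_that("degenerate communities produce the expected genealogy shapes", {
  # one species, several specimens: a pure coalescent tree
  p1 <- simParams(nSpecies = 1,
                  abundanceModel = list(type = "explicit", abundances = 6L),
                  targetSingletonFraction = 0, seed = 2)
  t1 <- simulateGenealogy(simulateCommunity(p1), p1)
  expect_identical(ape::Ntip(t1), 6L)
  expect_true(isUltrametricTree(t1, 1e-9))
  # n species of one specimen each: a pure species tree
  p2 <- simParams(nSpecies = 6,
                  abundanceModel = list(type = "explicit",
                                        abundances = rep(1L, 6)),
                  targetSingletonFraction = 1, seed = 2)
  t2 <- simulateGenealogy(simulateCommunity(p2), p2)
  expect_identical(ape::Ntip(t2), 6L)
})

test_that("sequence evolution follows the JC69 expectation", {
  # mutation rate zero: every sequence equals the root sequence
  p0 <- simParams(nSpecies = 2,
                  abundanceModel = list(type = "explicit", abundances = c(1L, 1L)),
                  targetSingletonFraction = 1, mutationRate = 0, seed = 4)
  tr <- ape::read.tree(text = "(sp001_01:0.5,sp002_01:0.5);")
  aln0 <- simulateSequences(tr, p0)
  expect_identical(length(unique(as.character(aln0))), 1L)
  expect_true(all(Biostrings::width(aln0) == 658L))

  # closed-form p-distance: p = 3/4 (1 - exp(-4 mu t / 3)) at path length t
  mu <- 0.2; t <- 1.0
  obs <- vapply(1:200, function(s) {
    p <- simParams(nSpecies = 2, mutationRate = mu, alignmentLength = 400,
                   abundanceModel = list(type = "explicit", abundances = c(1L, 1L)),
                   targetSingletonFraction = 1, seed = s)
    a <- simulateSequences(tr, p)
    pDistanceMatrix(a)[1, 2]
  }, 0)
  expected <- 3 / 4 * (1 - exp(-4 * mu * t / 3))
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - expected), 3 * se)
})

test_that("morphospecies corruption follows the split/lump rules", {
  p <- simParams(nSpecies = 6, seed = 8)
  truth <- simulateCommunity(p)
  expect_identical(groupOf(corruptMorphospecies(truth, 0, 0, 1)),
                   stats::setNames(paste0("m_", groupOf(truth@truePartition)),
                                   specimens(truth@truePartition)))
  # forced split of a single 4-specimen species yields exactly two labels
  p4 <- simParams(nSpecies = 1,
                  abundanceModel = list(type = "explicit", abundances = 4L),
                  targetSingletonFraction = 0, seed = 5)
  t4 <- simulateCommunity(p4)
  for (s in 1:10) {
    m <- corruptMorphospecies(t4, 1, 0, s)
    expect_identical(nGroups(m), 2L)
    expect_setequal(specimens(m), specimens(t4@truePartition))
  }
})
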