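test_that("mean path length smoothing follows the hand-computed rule", {
  # cherry with tip branches 1 and 3: parent age (1+3)/2, rescaled to 1
  ch <- ape::read.tree(text = "((a:1,b:3):1,c:4);")
  u <- ultrametricizeMPL(ch)
  expect_true(isUltrametricTree(u, 1e-9))
  ages <- max(ape::node.depth.edgelength(u)) - ape::node.depth.edgelength(u)
  expect_equal(max(ages), 1)
  # raw ages: root = mean(2, 4, 4) = 10/3; cherry = mean(1, 3) = 2
  expect_equal(ages[4], 1, tolerance = 1e-12)          # root node
  expect_equal(ages[5], 2 / (10 / 3), tolerance = 1e-12)
  expect_equal(unname(ages[1:3]), rep(0, 3), tolerance = 1e-12)

  # an already-ultrametric tree keeps its relative node ages
  set.seed(1)
  tr <- ape::rcoal(8)
  rel <- ape::node.depth.edgelength(tr) / max(ape::node.depth.edgelength(tr))
  u2 <- ultrametricizeMPL(tr)
  rel2 <- ape::node.depth.edgelength(u2)
  expect_equal(rel2, rel, tolerance = 1e-9)

  # clamping keeps the tree valid when raw means would invert parent/child
  inv <- ape::read.tree(text = "(((a:5,b:5):0.01,c:0.1):1,d:6);")
  ui <- ultrametricizeMPL(inv)
  expect_true(isUltrametricTree(ui, 1e-9))
  expect_true(all(ui$edge.length >= -1e-12))

  z <- ape::read.tree(text = "(a:0,b:0);")
  expect_error(ultrametricizeMPL(z), "degenerate")
})

test_that("GMYC fits validate input and honour its boundary behaviour", {
  set.seed(2)
  bad <- ape::rtree(6)
  expect_error(fitGmyc(bad), "ultrametricize")
  expect_error(fitGmyc(ape::rcoal(2)), "3 tips")

  fx <- simFixture(5, nSpecies = 6,
                   abundanceModel = list(type = "explicit",
                                         abundances = rep(4L, 6)),
                   targetSingletonFraction = 0)
  fit <- fitGmyc(fx$tree)
  expect_s4_class(fit, "GmycFit")
  expect_gte(fit@logLalt, fit@logLnull)
  expect_gte(fit@LR, 0)
  expect_identical(nGroups(gmycPartition(fit)), fit@nEntities)
  # clean simulated structure: recovers the six species exactly
  expect_identical(fit@nEntities, 6L)
  key <- function(p) sort(unname(vapply(blocks(p), function(b)
    paste(sort(b), collapse = "|"), "")))
  expect_identical(key(fit@partition), key(fx$truth@truePartition))
})

test_that("GMYC entities are clades and the scan dominates every threshold", {
  fx <- simFixture(9, nSpecies = 8)
  fit <- fitGmyc(fx$tree)
  tr <- fx$tree
  for (b in blocks(fit@partition)) {
    if (length(b) < 2) next
    mrca <- ape::getMRCA(tr, match(b, tr$tip.label))
    expect_setequal(ape::extract.clade(tr, mrca)$tip.label, b)
  }
  # selected threshold beats a sample of other candidate splits
  prep <- barcodeMOTU:::.gmycPrep(tr)
  lam0 <- c(1, 1)
  for (s in unique(c(1L, 3L, prep$nEv - 1L))) {
    M <- barcodeMOTU:::.gmycCoalCounts(prep, s)
    alt <- barcodeMOTU:::.gmycOptimize(
      barcodeMOTU:::.gmycNegLL(prep, s, M), 5L, 400L, lam0, !is.null(M))
    expect_gte(fit@logLalt + 1e-6, -alt$value)
  }
})

test_that("PTP matches the exhaustive oracle and degenerates gracefully", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  fs <- fitPtp(star)
  expect_true(fs@degenerate)
  expect_identical(fs@nEntities, 1L)

  # greedy search with restarts reproduces the exact optimum on small trees
  for (s in 1:8) {
    fx <- simFixture(200 + s, nSpecies = 4,
                     abundanceModel = list(type = "explicit",
                                           abundances = c(3L, 3L, 3L, 3L)),
                     targetSingletonFraction = 0)
    sub <- substitutionTree(fx$tree, fx$params)
    exact <- fitPtp(sub, nSites = 658, exhaustiveMax = 12L)
    greedy <- fitPtp(sub, nSites = 658, exhaustiveMax = 0L, seed = s)
    expect_equal(greedy@logL, exact@logL, tolerance = 1e-9)
    expect_identical(greedy@nEntities, exact@nEntities)
  }
})

test_that("PTP blocks are clades of the input tree", {
  fx <- simFixture(77, nSpecies = 10)
  sub <- substitutionTree(fx$tree, fx$params)
  fit <- fitPtp(sub, nSites = 658, seed = 1)
  for (b in blocks(fit@partition)) {
    if (length(b) < 2) next
    mrca <- ape::getMRCA(sub, match(b, sub$tip.label))
    expect_setequal(ape::extract.clade(sub, mrca)$tip.label, b)
  }
  expect_error(fitPtp(ape::rcoal(2)), "3 tips")
})
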