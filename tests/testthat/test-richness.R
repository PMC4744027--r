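# frozen 5-species x 4-unit fixture: q1 = 2, q2 = 1
fixtureInc <- function() {
  m <- matrix(c(1, 0, 0, 0,
                1, 1, 0, 0,
                0, 1, 0, 0,
                1, 1, 1, 0,
                1, 1, 1, 1) > 0, 5, 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:5), paste0("u", 1:4)))
  m
}

test_that("Chao2 and jackknife match the hand-evaluated closed forms", {
  inc <- fixtureInc()
  expect_equal(chao2(inc)$estimate, 6.5)          # 5 + (3/4) * 4/2
  expect_equal(jackknifeRichness(inc, 1)$estimate, 6.5)  # 5 + 2 * 3/4
  j2 <- jackknifeRichness(inc, 2)$estimate        # 5 + 2*5/4 - 1*4/12
  expect_equal(j2, 5 + 2 * 5 / 4 - 4 / 12)
  expect_true(is.na(jackknifeRichness(inc, 2)$se))

  # no uniques: the estimators return the observed richness
  sat <- matrix(TRUE, 3, 4, dimnames = list(paste0("s", 1:3), paste0("u", 1:4)))
  expect_equal(chao2(sat)$estimate, 3)
  expect_equal(chao2(sat)$se, 0)
  expect_equal(jackknifeRichness(sat, 1)$estimate, 3)
  expect_equal(jackknifeRichness(sat, 2)$estimate, 3)

  expect_error(chao2(fixtureInc()[, 1, drop = FALSE]), "2 sampling units")
  expect_error(jackknifeRichness(fixtureInc()[, 1:2], 2), "too few")
})

test_that("estimators agree with vegan's specpool and ignore column order", {
  skip_if_not_installed("vegan")
  for (s in 1:10) {
    inc <- randomIncidence(sample(8:25, 1), sample(4:10, 1), seed = 40 + s)
    sp <- vegan::specpool(t(inc))   # vegan wants sites x species
    expect_equal(chao2(inc)$estimate, sp$chao, tolerance = 1e-10)
    expect_equal(chao2(inc)$se, sp$chao.se, tolerance = 1e-10)
    expect_equal(jackknifeRichness(inc, 1)$estimate, sp$jack1, tolerance = 1e-10)
    expect_equal(jackknifeRichness(inc, 1)$se, sp$jack1.se, tolerance = 1e-10)
    expect_equal(jackknifeRichness(inc, 2)$estimate, sp$jack2, tolerance = 1e-10)

    perm <- sample(ncol(inc))
    expect_equal(chao2(inc[, perm])$estimate, chao2(inc)$estimate)
    expect_equal(jackknifeRichness(inc[, perm], 1)$se,
                 jackknifeRichness(inc, 1)$se)
  }
})

test_that("incidence matrices respect partition, units and filters", {
  meta <- data.frame(
    specimen_id = c("a", "b", "c", "d"),
    sampling_unit = c("u1", "u1", "u2", "u3"),
    level = c(1000, 1000, 2000, 2000),
    method = c("sweep", "sweep", "hand", "light"))
  p <- Partition(c(a = "X", b = "X", c = "Y", d = "Z"))
  inc <- buildIncidence(p, meta)
  expect_identical(dim(inc), c(3L, 3L))
  expect_identical(attr(inc, "specimensPerUnit"), c(2L, 1L, 1L))

  # excluding light-trapping drops its unit and the species found only there
  inc2 <- suppressMessages(buildIncidence(p, meta,
                                          methods = c("sweep", "hand")))
  expect_identical(rownames(inc2), c("X", "Y"))
  expect_error(buildIncidence(p, meta, methods = "malaise"), "no sampling")

  one <- buildIncidence(Partition(c(a = "X")), meta[1, ])
  expect_identical(dim(one), c(1L, 1L))
})

test_that("accumulation curves end at the observed richness and match
           the sample-based rarefaction expectation", {
  inc <- randomIncidence(15, 10, seed = 77)
  spu <- rep(3L, 10)
  coll <- accumulationCurve(inc, spu, method = "collector")
  expect_identical(nrow(coll), 10L)
  expect_equal(coll$richness[10], nrow(inc))
  expect_equal(coll$individuals[10], 30)

  rand <- accumulationCurve(inc, spu, method = "random", nPerm = 1000, seed = 4)
  expect_equal(rand$richness[10], nrow(inc))   # every permutation ends at Sobs
  for (k in c(2, 5, 8)) {
    expected <- rarefactionExpectation(inc, k)
    se <- sd(replicate(200, {
      o <- sample(10, k)
      sum(rowSums(inc[, o, drop = FALSE]) > 0)
    })) / sqrt(1000)
    expect_lt(abs(rand$richness[k] - expected), 3 * max(se, 1e-8))
  }

  one <- accumulationCurve(inc[, 1, drop = FALSE], 5L, method = "collector")
  expect_identical(nrow(one), 1L)
  expect_error(accumulationCurve(inc, spu, method = "nope"))
})

test_that("standardized richness matches the hypergeometric expectation", {
  set.seed(10)
  sizes <- c(5L, 3L, 1L, 1L, 2L, 4L)
  g <- rep(paste0("g", seq_along(sizes)), sizes)
  ids <- sprintf("s%02d", seq_along(g))
  p <- Partition(stats::setNames(g, ids))
  meta <- data.frame(specimen_id = ids, sampling_unit = "u1",
                     level = 2000, method = "sweep")

  full <- standardizedRichness(p, meta, 2000, nDraw = length(ids), reps = 50,
                               seed = 2)
  expect_equal(full$mean, length(sizes))
  expect_equal(full$lower, full$upper)

  st <- standardizedRichness(p, meta, 2000, nDraw = 7, reps = 4000, seed = 2)
  expected <- drawExpectation(sizes, 7)
  se <- sqrt(stats::var(replicate(400, {
    length(unique(g[sample(length(g), 7)]))
  })) / 4000)
  expect_lt(abs(st$mean - expected), 3 * max(se, 1e-8))
  expect_error(standardizedRichness(p, meta, 2000, nDraw = 100), "exceeds")
})

test_that("elevational occupancy histograms behave and sum to 100", {
  ids <- sprintf("s%02d", 1:12)
  g <- c(rep("A", 3), rep("B", 3), rep("C", 2), "D", "E", rep("F", 2))
  lv <- c(1000, 1000, 1000, 2000, 2000, 1000, 3000, 3000, 1000, 2000,
          3000, 3000)
  p <- Partition(stats::setNames(g, ids))
  meta <- data.frame(specimen_id = ids, level = lv,
                     sampling_unit = "u", method = "sweep")
  occ <- levelOccupancy(p, meta)
  expect_equal(sum(occ$percent), 100, tolerance = 0.2)
  expect_identical(sum(occ$nGroups), 6L)
  # B spans 1000 and 2000: one of six groups at two levels
  expect_identical(occ$nGroups[occ$nLevels == 2], 1L)

  confined <- Partition(stats::setNames(rep(c("A", "B"), each = 2),
                                        sprintf("t%d", 1:4)))
  metaC <- data.frame(specimen_id = sprintf("t%d", 1:4),
                      level = c(1000, 1000, 2000, 2000),
                      sampling_unit = "u", method = "sweep")
  occC <- levelOccupancy(confined, metaC)
  expect_identical(occC$percent[occC$nLevels == 1], 100)

  # rare-group exclusion removes groups of one or two specimens
  occR <- levelOccupancy(p, meta, excludeRare = TRUE)
  expect_identical(sum(occR$nGroups), 2L)    # only A and B survive
})
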