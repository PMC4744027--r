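# shared fixtures and independent brute-force oracles

# random alignment with gaps and ambiguity codes
randomAlignment <- function(n, len, seed, gapFrac = 0.08) {
  set.seed(seed)
  alphabet <- c("A", "C", "G", "T")
  dirty <- c("-", "N", "R", "Y")
  s <- vapply(seq_len(n), function(i) {
    x <- sample(alphabet, len, replace = TRUE)
    k <- rbinom(1, len, gapFrac)
    if (k > 0) x[sample(len, k)] <- sample(dirty, k, replace = TRUE)
    paste(x, collapse = "")
  }, "")
  Biostrings::DNAStringSet(stats::setNames(s, sprintf("t%02d", seq_len(n))))
}

# per-site loop oracle for uncorrected distances under pairwise deletion
pDistLoopOracle <- function(aln) {
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- 0; mis <- 0
    for (k in seq_len(ncol(m))) {
      a <- m[i, k]; b <- m[j, k]
      if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T")) {
        comp <- comp + 1
        if (a != b) mis <- mis + 1
      }
    }
    d[i, j] <- d[j, i] <- if (comp > 0) mis / comp else 0
  }
  d
}

# depth-first-search connected components of d < threshold
componentsOracle <- function(d, threshold) {
  n <- nrow(d)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      nb <- which(d[v, ] < threshold & is.na(comp))
      stack <- c(stack, setdiff(nb, v))
    }
  }
  comp
}

# brute-force split/lump/perfect classifier from the definitions
congruenceOracle <- function(ref, test) {
  rb <- blocks(ref); testOf <- groupOf(test); tb <- blocks(test)
  perfect <- split <- lumped <- both <- 0L
  for (b in rb) {
    touched <- unique(testOf[b])
    isSplit <- length(touched) >= 2L
    isLumped <- any(vapply(tb[touched], function(tbk)
      length(setdiff(tbk, b)) > 0L, TRUE))
    isPerfect <- length(touched) == 1L && setequal(tb[[touched]], b)
    perfect <- perfect + isPerfect
    split <- split + isSplit
    lumped <- lumped + isLumped
    both <- both + (isSplit && isLumped)
  }
  list(perfect = perfect, split = split, lumped = lumped, both = both,
       nRef = length(rb))
}

# random partition of ids into about k groups
randomPartition <- function(ids, k, seed) {
  set.seed(seed)
  Partition(stats::setNames(paste0("g", sample.int(k, length(ids),
                                                   replace = TRUE)), ids))
}

# random incidence matrix without empty rows
randomIncidence <- function(nSpecies, nUnits, seed, p = 0.3) {
  set.seed(seed)
  repeat {
    m <- matrix(runif(nSpecies * nUnits) < p, nSpecies, nUnits,
                dimnames = list(sprintf("s%02d", seq_len(nSpecies)),
                                sprintf("u%02d", seq_len(nUnits))))
    if (all(rowSums(m) > 0)) return(m)
  }
}

# expected sample-based rarefaction richness after k of m units
rarefactionExpectation <- function(inc, k) {
  m <- ncol(inc)
  ms <- rowSums(inc > 0)
  sum(1 - choose(m - ms, k) / choose(m, k))
}

# expected distinct groups when drawing n of N individuals without replacement
drawExpectation <- function(groupSizes, n) {
  N <- sum(groupSizes)
  sum(1 - choose(N - groupSizes, n) / choose(N, n))
}

# small simulated data set shared across tests
simFixture <- function(seed, nSpecies = 20, ...) {
  p <- simParams(nSpecies = nSpecies, seed = seed, ...)
  truth <- simulateCommunity(p)
  tree <- simulateGenealogy(truth, p)
  list(params = p, truth = truth, tree = tree)
}
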