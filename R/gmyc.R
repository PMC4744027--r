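# Single-threshold GMYC: a time threshold T splits an ultrametric genealogy
# into a diversification regime (events older than T; one Yule-like class)
# and independent within-entity coalescent regimes (events younger than T).
# During inter-event interval i the total branching rate is
#   b_i = lambda1 * n_div,i^p1 + lambda2 * sum_k [n_k,i (n_k,i - 1)]^p2
# and the likelihood is the product of b_i * exp(-b_i * x_i) over waiting
# intervals (the final interval to the present contributes survival only).
# Because the rate depends only on which events lie on either side of T,
# candidate thresholds reduce to the split index s = number of speciation
# events; T is reported as the midpoint between the flanking node ages.

# shared event/interval structure of an ultrametric tree
.gmycPrep <- function(tree, tol = 1e-6) {
  ntip <- ape::Ntip(tree)
  if (ntip < 3L) stop("GMYC needs at least 3 tips")
  if (!isUltrametricTree(tree, tol))
    stop("tree is not ultrametric; run ultrametricizeMPL() first")
  age <- .nodeAges(tree)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  ord <- nodes[order(age[nodes], decreasing = TRUE)]
  a <- age[ord]                              # a_1 >= a_2 >= ... (root first)
  nEv <- length(ord)
  rank <- integer(ntip + tree$Nnode)
  rank[ord] <- seq_len(nEv)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  # tips under each node
  nTips <- integer(ntip + tree$Nnode)
  nTips[seq_len(ntip)] <- 1L
  for (e in ape::postorder(tree)) {
    nTips[tree$edge[e, 1L]] <- nTips[tree$edge[e, 1L]] + nTips[tree$edge[e, 2L]]
  }
  x <- c(a, 0)[seq_len(nEv)] - c(a[-1L], 0)  # interval widths, last ends at 0
  list(tree = tree, ntip = ntip, ord = ord, ages = a, rank = rank,
       parent = parent, nTips = nTips, x = x, nEv = nEv)
}

# per-interval count matrix of within-entity lineage numbers for split s:
# M[j, c-1] = number of entities with c lineages during interval j (c >= 2)
.gmycCoalCounts <- function(prep, s) {
  nEv <- prep$nEv
  if (s >= nEv) return(NULL)                 # no coalescent events
  coalEv <- prep$ord[(s + 1L):nEv]           # events younger than T, by age
  eMap <- integer(prep$ntip + length(prep$rank))
  ent <- integer(length(coalEv))
  for (i in seq_along(coalEv)) {
    v <- coalEv[i]
    p <- prep$parent[v]
    ent[i] <- if (prep$rank[p] <= s) v else eMap[p]
    eMap[v] <- ent[i]
  }
  cmax <- max(prep$nTips[unique(ent)])
  M <- matrix(0, nrow = nEv, ncol = max(cmax - 1L, 1L))
  cnt <- rep(1L, length(prep$rank))          # lineages per entity root
  row <- numeric(ncol(M))
  for (i in seq_along(coalEv)) {
    e <- ent[i]
    c0 <- cnt[e]
    cnt[e] <- c0 + 1L
    if (c0 >= 2L) row[c0 - 1L] <- row[c0 - 1L] - 1
    row[c0] <- row[c0] + 1
    j <- s + i                               # config in force after the event
    if (j <= nEv) M[j, ] <- row
  }
  M
}

# negative log-likelihood factory; par = (log l1, log l2, t1, t2) with
# p = 0.1 + 1.9 * plogis(t)
.gmycNegLL <- function(prep, s, M) {
  nEv <- prep$nEv
  ndiv <- pmin(seq_len(nEv) + 1L, s + 1L)
  x <- prep$x
  evIdx <- seq_len(nEv - 1L)
  cvals <- if (is.null(M)) NULL else (seq_len(ncol(M)) + 1L)
  cc <- if (is.null(M)) NULL else cvals * (cvals - 1L)
  # par layout: (log l1, log l2, t1, t2) with coalescent class present,
  # (log l1, t1) without
  function(par) {
    if (is.null(M)) {
      l1 <- exp(par[1L]); p1 <- 0.1 + 1.9 * stats::plogis(par[2L])
      b <- l1 * ndiv^p1
    } else {
      l1 <- exp(par[1L]); p1 <- 0.1 + 1.9 * stats::plogis(par[3L])
      l2 <- exp(par[2L]); p2 <- 0.1 + 1.9 * stats::plogis(par[4L])
      b <- l1 * ndiv^p1 + l2 * as.vector(M %*% (cc^p2))
    }
    ll <- sum(log(b[evIdx])) - sum(b * x)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
}

.gmycOptimize <- function(negll, nStart, maxit, lam0, twoClass) {
  # starts cover both the rate scale and the exponent range (the latter
  # matters when the truth sits near an exponent bound, e.g. p ~ 2 for a
  # coalescent-dominated tree)
  lamOff <- c(0, 0, 0, -2, 2)[seq_len(nStart)]
  tOff <- c(0, 3, -3, 1, -1)[seq_len(nStart)]
  best <- NULL
  for (i in seq_along(lamOff)) {
    o <- lamOff[i]; t0 <- tOff[i]
    par0 <- if (twoClass)
      c(log(lam0[1L]) + o, log(lam0[2L]) + o, t0, t0)
    else c(log(lam0[1L]) + o, t0)
    fit <- stats::optim(par0, negll, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-9))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best
}

# wrap a 2-parameter one-class objective as used for the null model
.gmycNullNegLL <- function(prep) {
  nEv <- prep$nEv
  ndiv <- seq_len(nEv) + 1L
  x <- prep$x
  evIdx <- seq_len(nEv - 1L)
  function(par) {
    l1 <- exp(par[1L]); p1 <- 0.1 + 1.9 * stats::plogis(par[2L])
    b <- l1 * ndiv^p1
    ll <- sum(log(b[evIdx])) - sum(b * x)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
}

#' Fit the single-threshold GMYC model
#'
#' Scans every candidate threshold (placed between consecutive distinct node
#' ages), maximizes the mixed Yule/coalescent likelihood at each, and
#' compares the best fit against a null single-branching-process model
#' (one rate, one scaling exponent over the whole tree) by a likelihood-ratio
#' test with a chi-squared reference.
#'
#' The rate and exponent parameters are optimized by multi-start Nelder-Mead
#' with log-parameterized rates and exponents bounded in \code{[0.1, 2]}.
#' A cheap pass (\code{coarseStarts} starts) ranks the thresholds and the
#' best \code{refineTop} candidates are refitted with \code{starts} starts.
#' Ties in log-likelihood are broken toward fewer entities.
#'
#' @param tree Ultrametric rooted \code{phylo} with >= 3 tips.
#' @param df Degrees of freedom of the chi-squared LRT reference (default 3;
#'   the literature is unsettled, so this is configurable).
#' @param starts Number of optimizer starts for refined fits (default 5).
#' @param coarseStarts Starts used in the scanning pass (default 2).
#' @param refineTop Number of top-ranked thresholds refitted (default 5).
#' @param maxit Nelder-Mead iteration cap per start.
#' @return A \code{\linkS4class{GmycFit}}.
#' @examples
#' set.seed(7)
#' tr <- ape::rcoal(8)
#' fitGmyc(tr)
#' @export
fitGmyc <- function(tree, df = 3, starts = 5L, coarseStarts = 2L,
                    refineTop = 5L, maxit = 400L) {
  prep <- .gmycPrep(tree)
  nEv <- prep$nEv
  a <- prep$ages

  # crude rate scales for optimizer starts
  lamDiv <- max((nEv - 1L) / sum((seq_len(nEv) + 1L) * prep$x), 1e-6)
  lam0 <- c(lamDiv, lamDiv)

  nullFit <- .gmycOptimize(.gmycNullNegLL(prep), starts, maxit, lam0, FALSE)
  logLnull <- -nullFit$value

  # candidate splits: only between strictly distinct ages (plus all-singleton)
  bounds <- c(a[-1L], 0)
  cands <- which(a - bounds > 1e-12)

  scan <- function(s, nStart, it) {
    M <- .gmycCoalCounts(prep, s)
    .gmycOptimize(.gmycNegLL(prep, s, M), nStart, it, lam0, !is.null(M))
  }
  coarse <- vapply(cands, function(s)
    scan(s, coarseStarts, max(150L, maxit %/% 2L))$value, 0)
  top <- cands[order(coarse)][seq_len(min(refineTop, length(cands)))]

  bestS <- NA_integer_; bestFit <- NULL
  for (s in sort(top)) {                     # ascending: ties -> fewer entities
    fit <- scan(s, starts, maxit)
    if (is.null(bestFit) || fit$value < bestFit$value - 1e-9) {
      bestFit <- fit; bestS <- s
    }
  }
  logLalt <- max(-bestFit$value, logLnull)
  LR <- max(2 * (logLalt - logLnull), 0)

  threshold <- (a[bestS] + if (bestS < nEv) a[bestS + 1L] else 0) / 2
  part <- .gmycEntities(prep, bestS)
  par <- bestFit$par
  twoClass <- length(par) == 4L
  new("GmycFit",
      threshold = threshold,
      lambda1 = exp(par[1L]),
      lambda2 = if (twoClass) exp(par[2L]) else NA_real_,
      p1 = 0.1 + 1.9 * stats::plogis(par[if (twoClass) 3L else 2L]),
      p2 = if (twoClass) 0.1 + 1.9 * stats::plogis(par[4L]) else NA_real_,
      logLalt = logLalt, logLnull = logLnull,
      LR = LR, pValue = stats::pchisq(LR, df, lower.tail = FALSE), df = df,
      nEntities = nGroups(part), partition = part)
}

# specimen partition induced by split index s: entities are the lineages
# crossing the threshold
.gmycEntities <- function(prep, s) {
  tree <- prep$tree
  ntip <- prep$ntip
  eMap <- integer(ntip + tree$Nnode)
  if (s < prep$nEv) {
    for (v in prep$ord[(s + 1L):prep$nEv]) {
      p <- prep$parent[v]
      eMap[v] <- if (prep$rank[p] <= s) v else eMap[p]
    }
  }
  ent <- integer(ntip)
  for (t in seq_len(ntip)) {
    p <- prep$parent[t]
    ent[t] <- if (prep$rank[p] <= s) t else eMap[p]
  }
  lab <- vapply(split(seq_len(ntip), ent),
                function(m) min(tree$tip.label[m]), "")
  Partition(stats::setNames(lab[as.character(ent)], tree$tip.label))
}

#' Extract the specimen partition from a GMYC fit
#'
#' @param fit A \code{\linkS4class{GmycFit}}.
#' @return The \code{\linkS4class{Partition}} induced by the ML threshold.
#' @export
gmycPartition <- function(fit) {
  stopifnot(is(fit, "GmycFit"))
  fit@partition
}
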