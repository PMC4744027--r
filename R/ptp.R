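# Poisson tree processes (PTP): on a tree whose branch lengths carry
# substitutions, branches inside species subtrees and branches between
# species form two rate classes with separate ML rates.  Substitution
# numbers per branch are modelled by the discretized exponential (geometric)
# law when the number of sites is known -- the natural form for count data,
# and bounded for the zero-substitution branches that identical sequences
# produce -- and by the continuous exponential otherwise.
# A configuration is a set of "species root" nodes (tips allowed); an edge
# belongs to the within class when its parent endpoint lies inside a species
# subtree.  The search splits species roots greedily from the one-species
# configuration, tracking the best configuration along each (randomized)
# path; an exact exhaustive search over clade-consistent configurations is
# provided for small trees and used as the test oracle.

# class log-likelihood from (edge count n, length/count sum s):
# geometric on counts, or exponential at the ML rate on continuous lengths
.ptpClassLLFactory <- function(discrete) {
  if (discrete) {
    function(n, s) {
      if (n == 0L) return(0)
      if (s <= 0) return(0)                  # P(all zero) = 1 at q -> 0
      n * log(n / (n + s)) + s * log(s / (n + s))
    }
  } else {
    function(n, s) {
      if (n == 0L) return(0)
      m <- max(s / n, 1e-10)                 # floor guards zero-length classes
      n * log(1 / m) - n
    }
  }
}

# children list and per-node subtree edge sums/counts; branch weights are
# substitution counts (discrete mode) or raw lengths
.ptpPrep <- function(tree, nSites = NULL) {
  ntip <- ape::Ntip(tree)
  nTotal <- ntip + tree$Nnode
  elen <- numeric(nTotal)
  elen[tree$edge[, 2L]] <- if (is.null(nSites)) tree$edge.length else
    round(tree$edge.length * nSites)
  kids <- vector("list", nTotal)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1L]]] <- c(kids[[tree$edge[e, 1L]]], tree$edge[e, 2L])
  # per-node: number of edges and total length of the subtree below it
  subN <- integer(nTotal); subS <- numeric(nTotal)
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    subN[p] <- subN[p] + subN[ch] + 1L
    subS[p] <- subS[p] + subS[ch] + elen[ch]
  }
  list(tree = tree, ntip = ntip, root = ntip + 1L, elen = elen,
       kids = kids, subN = subN, subS = subS,
       totN = nrow(tree$edge), totS = sum(elen),
       classLL = .ptpClassLLFactory(!is.null(nSites)),
       nSites = nSites)
}

.ptpLL <- function(prep, nw, sw, nb, sb)
  prep$classLL(nw, sw) + prep$classLL(nb, sb)

# likelihood of a species-root set: within class = union of species subtrees
.ptpConfigLL <- function(prep, roots) {
  nw <- sum(prep$subN[roots]); sw <- sum(prep$subS[roots])
  .ptpLL(prep, nw, sw, prep$totN - nw, prep$totS - sw)
}

# one greedy path: repeatedly split a species root into its children,
# always applying the (randomized) best available split even when it lowers
# the likelihood, and remember the best configuration encountered
.ptpGreedyPath <- function(prep, jitter = 0) {
  roots <- prep$root
  nw <- prep$subN[prep$root]; sw <- prep$subS[prep$root]
  best <- list(ll = .ptpLL(prep, nw, sw, prep$totN - nw, prep$totS - sw),
               roots = roots)
  repeat {
    cand <- roots[roots > prep$ntip]
    if (!length(cand)) break
    # splitting r removes the edges r -> children from the within class
    delta <- vapply(cand, function(r) {
      ch <- prep$kids[[r]]
      .ptpLL(prep, nw - length(ch), sw - sum(prep$elen[ch]),
             prep$totN - nw + length(ch), prep$totS - sw + sum(prep$elen[ch]))
    }, 0)
    pick <- if (jitter > 0) {
      which.max(delta + stats::rnorm(length(delta), 0, jitter * stats::sd(c(delta, 0))))
    } else which.max(delta)
    r <- cand[pick]
    ch <- prep$kids[[r]]
    nw <- nw - length(ch); sw <- sw - sum(prep$elen[ch])
    roots <- c(setdiff(roots, r), ch)
    ll <- .ptpLL(prep, nw, sw, prep$totN - nw, prep$totS - sw)
    if (ll > best$ll + 1e-12) best <- list(ll = ll, roots = roots)
  }
  best
}

# exhaustive ML over all clade-consistent configurations (small trees only)
.ptpExhaustive <- function(prep) {
  configs <- function(v) {
    own <- list(v)
    if (v <= prep$ntip) return(own)
    ch <- prep$kids[[v]]
    sub <- lapply(ch, configs)
    combo <- sub[[1L]]
    for (i in seq_along(sub)[-1L]) {
      combo <- unlist(lapply(combo, function(a)
        lapply(sub[[i]], function(b) c(a, b))), recursive = FALSE)
    }
    c(own, combo)
  }
  all <- configs(prep$root)
  ll <- vapply(all, function(r) .ptpConfigLL(prep, r), 0)
  ord <- order(-ll, vapply(all, length, 1L))
  list(ll = ll[ord[1L]], roots = all[[ord[1L]]])
}

#' Fit the PTP species-delimitation model
#'
#' Maximum-likelihood Poisson tree processes on a rooted tree with
#' substitution branch lengths: within-species and between-species branches
#' form two rate classes with separate ML rates, and the ML set of species
#' subtrees is searched by greedy node splitting from the one-species
#' configuration with random restarts (default 10, fixed seed).  For trees
#' of at most \code{exhaustiveMax} tips the exact exhaustive optimum over
#' all clade-consistent configurations is used instead.
#'
#' When \code{nSites} is supplied, branch lengths are converted to
#' substitution counts (\code{round(length * nSites)}) and each class is
#' modelled by the discretized exponential (geometric) law, the natural
#' distribution for the substitution numbers PTP operates on and the only
#' well-posed choice when identical sequences produce zero-length branches.
#' Without \code{nSites}, lengths are modelled as continuous exponential.
#'
#' @param tree Rooted \code{phylo} with substitution branch lengths,
#'   >= 3 tips.
#' @param nSites Number of alignment sites behind the branch lengths
#'   (recommended); \code{NULL} selects the continuous-length model.
#' @param restarts Number of randomized greedy restarts.
#' @param seed Seed for the randomized restarts.
#' @param exhaustiveMax Tip count up to which the search is exact.
#' @return A \code{\linkS4class{PtpFit}}; reported rates are per-site
#'   reciprocal mean branch lengths of the two classes.
#' @examples
#' tr <- ape::read.tree(text = "((a:0.01,b:0.01):0.5,(c:0.02,d:0.01):0.4);")
#' fitPtp(tr, nSites = 658)
#' @export
fitPtp <- function(tree, nSites = NULL, restarts = 10L, seed = 1L,
                   exhaustiveMax = 12L) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 3L) stop("PTP needs at least 3 tips")
  if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
  prep <- .ptpPrep(tree, nSites)

  el <- tree$edge.length
  if (stats::sd(el) <= 1e-12 * max(mean(el), 1e-300)) {
    part <- Partition(stats::setNames(rep(min(tree$tip.label),
                                          prep$ntip), tree$tip.label))
    rate <- 1 / max(mean(el), 1e-10)
    return(new("PtpFit", rateSpeciation = rate, rateCoalescent = rate,
               logL = .ptpConfigLL(prep, prep$root), nEntities = 1L,
               degenerate = TRUE, partition = part))
  }

  if (prep$ntip <= exhaustiveMax) {
    best <- .ptpExhaustive(prep)
  } else {
    set.seed(.stageSeed(seed, 7L))
    best <- .ptpGreedyPath(prep, jitter = 0)
    for (i in seq_len(restarts - 1L)) {
      cand <- .ptpGreedyPath(prep, jitter = 0.25)
      better <- cand$ll > best$ll + 1e-9 ||
        (abs(cand$ll - best$ll) <= 1e-9 &&
           length(cand$roots) < length(best$roots))
      if (better) best <- cand
    }
  }

  roots <- best$roots
  nw <- sum(prep$subN[roots]); sw <- sum(prep$subS[roots])
  nb <- prep$totN - nw; sb <- prep$totS - sw
  part <- .ptpPartition(prep, roots)
  scale <- if (is.null(nSites)) 1 else 1 / nSites    # back to per-site units
  new("PtpFit",
      rateSpeciation = if (nb > 0L) nb / max(sb * scale, 1e-10) else NA_real_,
      rateCoalescent = if (nw > 0L) nw / max(sw * scale, 1e-10) else NA_real_,
      logL = best$ll, nEntities = nGroups(part),
      degenerate = FALSE, partition = part)
}

# specimen partition induced by a species-root set
.ptpPartition <- function(prep, roots) {
  tree <- prep$tree
  lab <- character(prep$ntip)
  assign <- function(v, r) {
    if (v <= prep$ntip) { lab[v] <<- r; return(invisible()) }
    for (ch in prep$kids[[v]]) assign(ch, r)
  }
  for (r in roots) assign(r, as.character(r))
  named <- vapply(split(seq_len(prep$ntip), lab),
                  function(m) min(tree$tip.label[m]), "")
  Partition(stats::setNames(named[lab], tree$tip.label))
}

#' Extract the specimen partition from a PTP fit
#'
#' @param fit A \code{\linkS4class{PtpFit}}.
#' @return The induced \code{\linkS4class{Partition}}.
#' @export
ptpPartition <- function(fit) {
  stopifnot(is(fit, "PtpFit"))
  fit@partition
}
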