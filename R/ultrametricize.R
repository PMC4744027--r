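#' Read a rooted newick tree, discarding support values
#'
#' @param path Newick file; internal node labels (e.g. bootstrap supports)
#'   are tolerated and dropped.
#' @return A rooted \code{phylo}.
#' @export
readTimeTree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  tree$node.label <- NULL
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
  tree
}

#' Make a tree ultrametric by mean path length smoothing
#'
#' Assigns every internal node the mean of its node-to-tip path lengths
#' (over all descendant tips), clamps child ages to their parent's age where
#' the raw means would invert, and rescales all ages so the root sits at an
#' arbitrary age of 1.  This is the mean-path-length flavour of relative
#' rate smoothing, used to convert a substitution tree into relative time.
#'
#' @param tree A rooted \code{phylo} with non-negative branch lengths.
#' @return An ultrametric \code{phylo} with root age 1.
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:3):1,c:4);")
#' mpl <- ultrametricizeMPL(tr)
#' max(ape::node.depth.edgelength(mpl))
#' @export
ultrametricizeMPL <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  nTotal <- ntip + nnode
  root <- ntip + 1L
  elen <- stats::setNames(numeric(nTotal), NULL)
  elen[tree$edge[, 2L]] <- tree$edge.length

  # postorder accumulation of (sum of path lengths to tips, tip count)
  sumPath <- numeric(nTotal)
  nTips <- integer(nTotal)
  nTips[seq_len(ntip)] <- 1L
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    sumPath[p] <- sumPath[p] + sumPath[ch] + nTips[ch] * elen[ch]
    nTips[p] <- nTips[p] + nTips[ch]
  }
  age <- numeric(nTotal)
  age[root:(nTotal)] <- sumPath[root:nTotal] / nTips[root:nTotal]
  if (age[root] <= 0) stop("degenerate tree: all root-to-tip paths have length 0")

  # clamp children to parents, walking root-to-tip (preorder)
  for (e in rev(ape::postorder(tree))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    if (ch > ntip && age[ch] > age[p]) age[ch] <- age[p]
  }
  age <- age / age[root]
  out <- tree
  out$edge.length <- age[tree$edge[, 1L]] - age[tree$edge[, 2L]]
  out
}
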