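# internal helpers shared across modules

# round half away from zero, the convention used for reported percentages
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# ages (root-to-tip distance subtracted from root height) for every node;
# returns vector indexed by ape node number (tips first)
.nodeAges <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Test whether a rooted tree is ultrametric
#'
#' All root-to-tip path lengths must agree within \code{tol} times the root
#' age.
#'
#' @param tree A rooted \code{phylo} tree with branch lengths.
#' @param tol Relative tolerance (default 1e-6).
#' @return Logical.
#' @export
isUltrametricTree <- function(tree, tol = 1e-6) {
  depth <- ape::node.depth.edgelength(tree)
  tips <- depth[seq_len(ape::Ntip(tree))]
  h <- max(tips)
  if (h <= 0) return(FALSE)
  (max(tips) - min(tips)) <= tol * h
}

# deterministic component labels: each component labelled by the smallest
# contained element id (lexicographic); returns Partition
.componentsPartition <- function(ids, edges) {
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- find(edges[r, 1L]); b <- find(edges[r, 2L])
      if (a != b) parent[b] <- a
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  lab <- vapply(split(seq_len(n), comp), function(m) min(ids[m]), "")
  Partition(stats::setNames(lab[as.character(comp)], ids))
}

# small non-cryptographic content hash (FNV-1a over serialized object),
# used for run provenance
.contentHash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  n <- length(raw)
  # cap work on very large objects; fold the full length in instead
  raw <- c(raw[seq_len(min(n, 65536L))], writeBin(n, raw()))
  h <- 0
  # simple 31-bit polynomial rolling hash, exact in doubles
  for (b in as.integer(raw)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# derive a valid 32-bit stage seed from a base seed and an offset
.stageSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 131 + offset) %% 2147483647)
}
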