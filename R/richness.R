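#' Build a species-by-sampling-unit incidence matrix
#'
#' Presence/absence of every group of a partition across sampling units,
#' optionally restricted to a subset of collection methods (the standardized
#' methods of a survey) and elevational levels.  Species absent from every
#' retained unit are dropped with a message.
#'
#' @param p A \code{\linkS4class{Partition}} (morphospecies, a MOTU set, or
#'   haplotypes).
#' @param meta Specimen metadata \code{data.frame} with columns
#'   \code{specimen_id}, \code{sampling_unit}, \code{level}, \code{method}
#'   (see \code{\link{specimenTable}}).
#' @param methods Optional character vector of methods to retain
#'   (e.g. \code{c("sweep", "beating", "hand")}).
#' @param levels Optional vector of elevational levels to retain.
#' @return Logical incidence matrix (groups x units) with attribute
#'   \code{"specimensPerUnit"} (integer, specimens per retained unit).
#' @export
buildIncidence <- function(p, meta, methods = NULL, levels = NULL) {
  stopifnot(is(p, "Partition"), is.data.frame(meta))
  if (!all(specimens(p) %in% meta$specimen_id))
    stop("metadata lacks specimens present in the partition")
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(methods)) keep <- keep & meta$method %in% methods
  if (!is.null(levels)) keep <- keep & meta$level %in% levels
  meta <- meta[keep & meta$specimen_id %in% specimens(p), , drop = FALSE]
  if (nrow(meta) == 0L) stop("no sampling units retained by the filter")
  g <- groupOf(p)[meta$specimen_id]
  units <- sort(unique(meta$sampling_unit))
  groups <- sort(unique(g))
  inc <- table(factor(g, groups), factor(meta$sampling_unit, units)) > 0
  inc <- matrix(inc, nrow = length(groups),
                dimnames = list(groups, units))
  dropped <- sum(rowSums(inc) == 0L)
  if (dropped > 0L) {
    message(dropped, " group(s) absent from all retained units dropped")
    inc <- inc[rowSums(inc) > 0L, , drop = FALSE]
  }
  nTotal <- nGroups(p)
  if (nrow(inc) < nTotal)
    message(nTotal - nrow(inc), " group(s) outside the retained units")
  attr(inc, "specimensPerUnit") <-
    as.integer(table(factor(meta$sampling_unit, units)))
  inc
}

# incidence frequencies: q1 = uniques, q2 = duplicates, m = units
.incFreq <- function(inc) {
  freq <- rowSums(inc > 0)
  list(Sobs = nrow(inc), q1 = sum(freq == 1L), q2 = sum(freq == 2L),
       m = ncol(inc), freq = freq)
}

#' Chao2 incidence-based richness estimate
#'
#' Classic small-sample-corrected Chao2,
#' \deqn{\hat S = S_{obs} + \frac{m-1}{m}\,\frac{q_1^2}{2 q_2},}
#' with the bias-corrected fallback
#' \eqn{S_{obs} + \frac{m-1}{m}\, q_1 (q_1 - 1)/2} when no duplicates exist,
#' and the matching standard-error convention of incidence-based barcoding
#' practice.
#'
#' @param inc Incidence matrix from \code{\link{buildIncidence}} (>= 2 units).
#' @return One-row \code{data.frame}: \code{estimator}, \code{Sobs},
#'   \code{estimate}, \code{se}.
#' @examples
#' inc <- matrix(c(1,0,0,0, 1,1,0,0, 0,1,0,0, 1,1,1,0, 1,1,1,1) > 0, 5, 4,
#'               byrow = TRUE)
#' chao2(inc)  # Sobs 5, q1 = 2, q2 = 1, m = 4 -> 6.5
#' @export
chao2 <- function(inc) {
  f <- .incFreq(inc)
  if (f$m < 2L) stop("Chao2 needs at least 2 sampling units")
  ssc <- (f$m - 1) / f$m
  if (f$q2 > 0) {
    est <- f$Sobs + ssc * f$q1^2 / (2 * f$q2)
    aa <- f$q1 / f$q2
    v <- f$q1 * ssc * (0.5 + ssc * (1 + aa / 4) * aa) * aa
  } else {
    est <- f$Sobs + ssc * f$q1 * (f$q1 - 1) / 2
    v <- ssc * (ssc * (f$q1 * (2 * f$q1 - 1)^2 / 4 - f$q1^4 / est / 4) +
                  f$q1 * (f$q1 - 1) / 2)
  }
  data.frame(estimator = "chao2", Sobs = f$Sobs, estimate = est,
             se = sqrt(max(v, 0)), stringsAsFactors = FALSE)
}

#' First- and second-order jackknife richness estimates
#'
#' \code{jack1 = Sobs + q1 (m-1)/m} with its standard incidence-based SE;
#' \code{jack2 = Sobs + q1 (2m-3)/m - q2 (m-2)^2 / (m (m-1))}, for which no
#' SE is reported (matching the conventional printed output shape).
#'
#' @param inc Incidence matrix (needs \code{m >= order + 1} units).
#' @param order 1 or 2.
#' @return One-row \code{data.frame} as in \code{\link{chao2}}; \code{se}
#'   is \code{NA} for order 2.
#' @export
jackknifeRichness <- function(inc, order = 1L) {
  stopifnot(order %in% c(1L, 2L))
  f <- .incFreq(inc)
  if (f$m < order + 1L) stop("too few sampling units for jackknife order ", order)
  if (order == 1L) {
    est <- f$Sobs + f$q1 * (f$m - 1) / f$m
    uniques <- rownames(inc)[f$freq == 1L]
    cnt <- colSums(inc[uniques, , drop = FALSE] > 0)
    v <- (sum(cnt^2) - f$q1 / f$m) * (f$m - 1) / f$m
    data.frame(estimator = "jack1", Sobs = f$Sobs, estimate = est,
               se = sqrt(max(v, 0)), stringsAsFactors = FALSE)
  } else {
    est <- f$Sobs + f$q1 * (2 * f$m - 3) / f$m -
      f$q2 * (f$m - 2)^2 / (f$m * (f$m - 1))
    data.frame(estimator = "jack2", Sobs = f$Sobs, estimate = est,
               se = NA_real_, stringsAsFactors = FALSE)
  }
}

#' Sample-based species accumulation curve
#'
#' Accumulates sampling units and records the growth of group richness
#' against the cumulative number of analysed individuals.  Method
#' \code{"random"} adds the units in random order over \code{nPerm}
#' permutations and reports the mean with a 2.5/97.5 percentile envelope;
#' method \code{"collector"} adds them in the order they appear.
#'
#' @param inc Incidence matrix from \code{\link{buildIncidence}}.
#' @param specimensPerUnit Integer specimens per unit (defaults to the
#'   attribute stored on \code{inc}).
#' @param method \code{"random"} or \code{"collector"}.
#' @param nPerm Number of permutations for \code{"random"} (default 1000).
#' @param seed Seed for the permutations.
#' @return \code{data.frame} with columns \code{units},
#'   \code{individuals} (cumulative, averaged over permutations for
#'   \code{"random"}), \code{richness}, \code{lower}, \code{upper}.
#' @export
accumulationCurve <- function(inc, specimensPerUnit = NULL,
                              method = c("random", "collector"),
                              nPerm = 1000L, seed = 1L) {
  method <- match.arg(method)
  m <- ncol(inc)
  if (is.null(specimensPerUnit))
    specimensPerUnit <- attr(inc, "specimensPerUnit")
  if (is.null(specimensPerUnit) || length(specimensPerUnit) != m)
    stop("specimensPerUnit must give one count per unit")
  oneOrder <- function(o) {
    first <- apply(inc[, o, drop = FALSE] > 0, 1L, which.max)
    cumsum(tabulate(first, m))
  }
  if (method == "collector") {
    rich <- oneOrder(seq_len(m))
    return(data.frame(units = seq_len(m),
                      individuals = cumsum(specimensPerUnit),
                      richness = rich, lower = rich, upper = rich))
  }
  stopifnot(nPerm >= 1L)
  set.seed(.stageSeed(seed, 5L))
  rich <- matrix(0L, nPerm, m)
  ind <- matrix(0, nPerm, m)
  for (r in seq_len(nPerm)) {
    o <- sample.int(m)
    rich[r, ] <- oneOrder(o)
    ind[r, ] <- cumsum(specimensPerUnit[o])
  }
  data.frame(units = seq_len(m),
             individuals = colMeans(ind),
             richness = colMeans(rich),
             lower = apply(rich, 2L, stats::quantile, 0.025),
             upper = apply(rich, 2L, stats::quantile, 0.975))
}

#' Richness standardized to equal sampling intensity
#'
#' Randomly draws \code{nDraw} individuals without replacement from the
#' specimens of one pool (e.g. one elevational level), counts the distinct
#' groups per draw, and reports the mean with a 2.5/97.5 percentile
#' interval.  This is the resampling standardization used to compare levels
#' sampled with different intensity.
#'
#' @param p A \code{\linkS4class{Partition}}.
#' @param meta Specimen metadata (see \code{\link{buildIncidence}}).
#' @param level Elevational level defining the pool.
#' @param nDraw Individuals per draw (must not exceed the pool size).
#' @param reps Number of draws (default 10000).
#' @param seed Seed.
#' @param methods Optional method filter applied before pooling.
#' @return List with \code{mean}, \code{lower}, \code{upper},
#'   \code{poolSize}, \code{nDraw}, \code{reps}.
#' @export
standardizedRichness <- function(p, meta, level, nDraw, reps = 10000L,
                                 seed = 1L, methods = NULL) {
  stopifnot(is(p, "Partition"))
  keep <- meta$level == level & meta$specimen_id %in% specimens(p)
  if (!is.null(methods)) keep <- keep & meta$method %in% methods
  pool <- groupOf(p)[meta$specimen_id[keep]]
  n <- length(pool)
  if (nDraw > n) stop("nDraw (", nDraw, ") exceeds pool size (", n, ")")
  set.seed(.stageSeed(seed, 6L))
  draws <- vapply(seq_len(reps), function(i)
    length(unique(pool[sample.int(n, nDraw)])), 1L)
  list(mean = mean(draws),
       lower = unname(stats::quantile(draws, 0.025)),
       upper = unname(stats::quantile(draws, 0.975)),
       poolSize = n, nDraw = as.integer(nDraw), reps = as.integer(reps))
}

#' Elevational occupancy of groups
#'
#' Histogram of the number of elevational levels at which each group occurs,
#' as percentages over occupancy classes.  With \code{excludeRare = TRUE},
#' groups represented by at most two specimens are removed first, since
#' singletons and doubletons can never span more than their specimen count
#' of levels.
#'
#' @param p A \code{\linkS4class{Partition}}.
#' @param meta Specimen metadata with \code{specimen_id} and \code{level}.
#' @param excludeRare Drop groups of <= 2 specimens first.
#' @return \code{data.frame} with \code{nLevels}, \code{nGroups},
#'   \code{percent} (one decimal, summing to 100 up to rounding).
#' @export
levelOccupancy <- function(p, meta, excludeRare = FALSE) {
  stopifnot(is(p, "Partition"))
  lv <- stats::setNames(meta$level, meta$specimen_id)
  if (anyNA(lv[specimens(p)])) stop("every specimen needs a level")
  bl <- blocks(p)
  if (excludeRare) bl <- bl[vapply(bl, length, 1L) > 2L]
  if (!length(bl)) stop("no groups left after rare-group exclusion")
  occ <- vapply(bl, function(b) length(unique(lv[b])), 1L)
  maxLv <- length(unique(meta$level))
  counts <- tabulate(occ, maxLv)
  data.frame(nLevels = seq_len(maxLv), nGroups = counts,
             percent = roundHalfUp(100 * counts / length(bl), 1))
}
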