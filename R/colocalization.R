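## Wilcoxon rank-sum wrapper: exact enumeration for small tie-free samples,
## normal approximation with tie correction otherwise.
.rank_sum <- function(x, y, alternative) {
  if (length(unique(c(x, y))) == 1L)   # fully tied: no evidence either way
    return(list(statistic = length(x) * length(y) / 2, p.value = 1,
                exact = FALSE))
  exact <- length(x) < 10L && length(y) < 10L &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value, exact = exact)
}

#' Enumerate bin-pair categories and their comparisons
#'
#' The three bin categories NI/I/RI give 6 unordered bin-pair categories
#' (pairs with repetition) and 15 unordered comparisons between those
#' category pairs.
#'
#' @return list with \code{categories} (6 x 2 character matrix) and
#'   \code{comparisons} (15 x 2 integer matrix of row indices into
#'   \code{categories}).
#' @examples
#' nrow(enumerateCategoryPairs()$categories)    # 6
#' nrow(enumerateCategoryPairs()$comparisons)   # 15
#' @export
enumerateCategoryPairs <- function() {
  cats <- c("NI", "I", "RI")
  idx <- which(upper.tri(matrix(0, 3, 3), diag = TRUE), arr.ind = TRUE)
  categories <- cbind(cats[idx[, 1L]], cats[idx[, 2L]])
  colnames(categories) <- c("cat1", "cat2")
  comparisons <- t(utils::combn(nrow(categories), 2L))
  colnames(comparisons) <- c("pairA", "pairB")
  list(categories = categories, comparisons = comparisons)
}

#' Normalized contact scores for one bin-pair category
#'
#' Collects every normalized score \eqn{\hat h_{ij}} (i < j, diagonal
#' excluded) whose two bins carry exactly the requested unordered category
#' pair, optionally restricted to a bin subset (e.g. bins containing a TSS,
#' or bins of one chromatin compartment).
#'
#' @param norm a [NormalizedContactMap-class].
#' @param profile a categorized [BinnedInsertionProfile-class] on the same
#'   binning.
#' @param pair character vector of length 2, e.g. \code{c("RI", "RI")}.
#' @param binSubset optional integer vector of bin indices; both bins of a
#'   pair must belong to it.
#' @return numeric vector of normalized scores.
#' @export
categoryPairScores <- function(norm, profile, pair, binSubset = NULL) {
  stopifnot(is(norm, "NormalizedContactMap"),
            is(profile, "BinnedInsertionProfile"))
  if (!length(profile@categories))
    stop("profile is not categorized; run categorizeBins() first")
  n <- nrow(norm@ranks)
  if (n != length(profile@counts))
    stop("norm and profile must share the binning")
  cats <- profile@categories
  keep <- seq_len(n)
  if (!is.null(binSubset)) keep <- intersect(keep, binSubset)
  i1 <- intersect(which(cats == pair[1L]), keep)
  i2 <- intersect(which(cats == pair[2L]), keep)
  if (identical(pair[1L], pair[2L])) {
    if (length(i1) < 2L) stop("no bin pairs for category pair ",
                              paste(pair, collapse = "-"))
    cmb <- utils::combn(i1, 2L)
    ii <- cmb[1L, ]; jj <- cmb[2L, ]
  } else {
    g <- expand.grid(i = i1, j = i2)
    ii <- pmin(g$i, g$j); jj <- pmax(g$i, g$j)
    ok <- ii != jj
    ii <- ii[ok]; jj <- jj[ok]
  }
  if (!length(ii)) stop("no bin pairs for category pair ",
                        paste(pair, collapse = "-"))
  norm@ranks[cbind(ii, jj)]
}

#' Compare the contact scores of two bin-pair categories
#'
#' Two-sided Wilcoxon rank-sum test between two score vectors, with the
#' difference of medians as effect size.
#'
#' @param scoresA,scoresB numeric vectors from [categoryPairScores()].
#' @return list with \code{statistic}, \code{p.value}, \code{effectSize}
#'   (median(A) - median(B)) and \code{exact}.
#' @export
compareCategoryPairs <- function(scoresA, scoresB) {
  if (!length(scoresA) || !length(scoresB))
    stop("both score vectors must be non-empty")
  rs <- .rank_sum(scoresA, scoresB, "two.sided")
  rs$effectSize <- stats::median(scoresA) - stats::median(scoresB)
  rs
}

#' Insertion count of each inserted bin's nearest spatial neighbour
#'
#' For every inserted bin, finds the bin with maximal normalized Hi-C
#' contact to it (the nearest spatial neighbour), excluding the bin itself
#' and its linear neighbours within \code{excludeAdjacent} bins, and reports
#' that neighbour's insertion count. Ties are broken toward the smaller bin
#' index and flagged.
#'
#' @param norm a [NormalizedContactMap-class].
#' @param profile a [BinnedInsertionProfile-class] on the same binning.
#' @param excludeAdjacent linear bins on each side to exclude (default 1).
#' @return data.frame with columns \code{bin}, \code{neighborBin},
#'   \code{neighborCount}, \code{tie}.
#' @export
nearestSpatialNeighborScores <- function(norm, profile,
                                         excludeAdjacent = 1L) {
  stopifnot(is(norm, "NormalizedContactMap"),
            is(profile, "BinnedInsertionProfile"))
  n <- nrow(norm@ranks)
  if (n != length(profile@counts))
    stop("norm and profile must share the binning")
  bins <- which(profile@counts > 0L)
  rows <- lapply(bins, function(i) {
    excl <- max(1L, i - excludeAdjacent):min(n, i + excludeAdjacent)
    cand <- setdiff(seq_len(n), excl)
    if (!length(cand)) return(NULL)
    sc <- norm@ranks[i, cand]
    j <- cand[which.max(sc)]
    data.frame(bin = i, neighborBin = j,
               neighborCount = profile@counts[j],
               tie = sum(sc == max(sc)) > 1L)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows))
    return(data.frame(bin = integer(), neighborBin = integer(),
                      neighborCount = integer(), tie = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.cluster_bins <- function(cl) seq.int(cl$startBin, cl$endBin)

#' Test co-localization of one insertion-cluster pair
#'
#' The positive distribution is the n x m block of normalized Hi-C scores
#' between the bins of the two clusters (clusters are pre-expanded to at
#' least 3 bins, so n x m >= 9). The negative (null) distribution collects
#' all normalized scores at genomic bin distances within the cluster pair's
#' distance range \eqn{[d_{min}, d_{max}]}, excluding the positive entries
#' themselves, widened one distance at a time (alternating below d_min and
#' above d_max) until it holds at least L scores. A one-tailed Wilcoxon
#' rank-sum test asks whether the positive scores exceed the null.
#'
#' @param norm a [NormalizedContactMap-class].
#' @param icA,icB one-row data.frames (rows of a [detectClusters()] table)
#'   on the same chromosome with disjoint extents.
#' @param L minimum size of the negative distribution; "auto" = 2 x n bins.
#' @return one-row data.frame: \code{chrom}, \code{startBpA}, \code{endBpA},
#'   \code{startBpB}, \code{endBpB}, \code{nPos}, \code{dMin}, \code{dMax},
#'   \code{nNeg}, \code{pRaw}, \code{exact}.
#' @export
clicTest <- function(norm, icA, icB, L = "auto") {
  stopifnot(is(norm, "NormalizedContactMap"))
  n <- nrow(norm@ranks)
  if (identical(L, "auto")) L <- 2L * n
  a <- .cluster_bins(icA); b <- .cluster_bins(icB)
  if (icA$chrom != icB$chrom || norm@chrom != icA$chrom)
    stop("clicTest needs two clusters on the normalized map's chromosome")
  if (length(intersect(a, b)))
    stop("cluster extents overlap; co-localization is defined for disjoint loci")
  if (max(a) > n || max(b) > n) stop("cluster extent outside the contact map")
  pos <- as.vector(norm@ranks[a, b])
  dists <- abs(outer(a, b, "-"))
  dMin <- min(dists); dMax <- max(dists)
  # null scores at bin distance k, skipping the positive (A x B) entries
  diag_vals <- function(k) {
    ii <- seq_len(n - k)
    excl <- (ii %in% a & (ii + k) %in% b) | (ii %in% b & (ii + k) %in% a)
    idx <- cbind(ii[!excl], ii[!excl] + k)
    norm@ranks[idx]
  }
  neg <- unlist(lapply(dMin:dMax, diag_vals), use.names = FALSE)
  lo <- dMin; hi <- dMax
  while (length(neg) < L) {
    if (lo <= 1L && hi >= n - 1L)
      stop("chromosome too short to build an L-sized null distribution")
    if (lo > 1L) {
      lo <- lo - 1L
      neg <- c(neg, diag_vals(lo))
      if (length(neg) >= L) break
    }
    if (hi < n - 1L) {
      hi <- hi + 1L
      neg <- c(neg, diag_vals(hi))
    }
  }
  rs <- .rank_sum(pos, neg, "greater")
  data.frame(chrom = norm@chrom,
             startBpA = icA$startBp, endBpA = icA$endBp,
             startBpB = icB$startBp, endBpB = icB$endBp,
             nPos = length(pos), dMin = dMin, dMax = dMax,
             nNeg = length(neg), pRaw = rs$p.value, exact = rs$exact)
}

#' Detect co-localized insertion clusters (CLICs)
#'
#' Runs [clicTest()] on every unordered intra-chromosomal pair of
#' high-scoring insertion clusters with disjoint extents, then controls the
#' family-wise error rate over the whole family of tests with Holm's
#' step-down procedure. A pair is a CLIC when its Holm-adjusted p-value is
#' at or below \code{alpha}.
#'
#' @param norms a [NormalizedContactMap-class] or a named list of them (one
#'   per chromosome).
#' @param highClusters data.frame of high-scoring clusters
#'   (from [splitByPeakHeight()]).
#' @param alpha family-wise significance level (default 1e-5).
#' @param L minimum null size passed to [clicTest()]; "auto" = twice the bin
#'   count of each map.
#' @return data.frame with one row per tested pair: the [clicTest()] columns
#'   plus \code{icA}, \code{icB} (row indices into \code{highClusters}),
#'   \code{pHolm} and \code{significant}. Pairs skipped because their
#'   extents overlap are counted in attribute \code{"nSkippedOverlap"}.
#' @examples
#' cfg <- simulationConfig(nBins = 200, seed = 11,
#'   clusterSpecs = data.frame(centerBin = c(40, 150), widthBp = 120000,
#'     expectedHits = 30, selected = TRUE),
#'   plantedClicPairs = data.frame(a = 1, b = 2, boost = 6,
#'     exclusivity = 0.5))
#' ins <- simulateInsertions(cfg)
#' cl <- detectClusters(smoothInsertionDensity(ins), ins)
#' nm <- rankNormalize(plantClicContacts(simulateContactMap(cfg),
#'   list(list(a = c(38, 42), b = c(148, 152), boost = 6))))
#' clics <- detectClics(nm, splitByPeakHeight(cl)$high, alpha = 0.01)
#' @export
detectClics <- function(norms, highClusters, alpha = 1e-5, L = "auto") {
  if (is(norms, "NormalizedContactMap"))
    norms <- stats::setNames(list(norms), norms@chrom)
  if (is.null(highClusters) || nrow(highClusters) < 2L)
    stop("need at least 2 high-scoring clusters")
  tests <- list()
  skipped <- 0L
  for (ch in names(norms)) {
    idx <- which(highClusters$chrom == ch)
    if (length(idx) < 2L) next
    for (u in seq_along(idx)[-length(idx)]) for (w in (u + 1L):length(idx)) {
      i <- idx[u]; j <- idx[w]
      a <- highClusters[i, ]; b <- highClusters[j, ]
      if (max(a$startBin, b$startBin) <= min(a$endBin, b$endBin)) {
        skipped <- skipped + 1L
        next
      }
      rec <- clicTest(norms[[ch]], a, b, L = L)
      rec$icA <- i; rec$icB <- j
      tests[[length(tests) + 1L]] <- rec
    }
  }
  if (!length(tests)) stop("no testable (disjoint) cluster pairs")
  out <- do.call(rbind, tests)
  out$pHolm <- stats::p.adjust(out$pRaw, method = "holm")
  out$significant <- out$pHolm <= alpha
  rownames(out) <- NULL
  attr(out, "nSkippedOverlap") <- skipped
  out
}
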