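#' Binary sample-by-locus occupancy matrix
#'
#' Entry (s, l) is 1 iff sample s carries at least one insertion inside
#' locus l's extent (base pairs, half-open: an insertion exactly at the
#' locus start counts, one exactly at the end does not).
#'
#' @param data an [InsertionDataset-class].
#' @param loci data.frame of cluster extents with columns \code{chrom},
#'   \code{startBp}, \code{endBp} (e.g. from [detectClusters()]).
#' @return integer matrix, samples x loci (0/1), rownames the cohort
#'   roster, colnames \code{locus_<row>}.
#' @export
sampleLocusMatrix <- function(data, loci) {
  stopifnot(is(data, "InsertionDataset"))
  loci <- as.data.frame(loci)
  rec <- data@records
  m <- matrix(0L, nrow = length(data@samples), ncol = nrow(loci),
              dimnames = list(data@samples,
                              if (nrow(loci)) sprintf("locus_%d",
                                                      seq_len(nrow(loci)))))
  for (l in seq_len(nrow(loci))) {
    inside <- rec$chrom == loci$chrom[l] &
      rec$pos >= loci$startBp[l] & rec$pos < loci$endBp[l]
    m[unique(rec$sample[inside]), l] <- 1L
  }
  m
}

#' Mean-Manhattan distance between two locus occupancy columns
#'
#' The fraction of samples in which exactly one of the two loci carries an
#' insertion. 0 for identical occupancy, 1 for perfectly mutually exclusive
#' occupancy covering every sample; high values indicate mutual exclusion.
#'
#' @param m a [sampleLocusMatrix()] matrix.
#' @param locusA,locusB column names or indices.
#' @return numeric in [0, 1].
#' @examples
#' m <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
#' meanManhattan(m, "a", "b")  # 0.5
#' @export
meanManhattan <- function(m, locusA, locusB) {
  if (nrow(m) == 0L) stop("occupancy matrix has zero samples")
  mean(m[, locusA] != m[, locusB])
}

#' Compare mutual exclusion of CLIC pairs against control pairs
#'
#' Two-sided Wilcoxon rank-sum test between the Mean-Manhattan distances of
#' CLIC locus pairs and those of control (non-significant) pairs.
#'
#' @param m a [sampleLocusMatrix()] matrix.
#' @param clicPairs,controlPairs two-column matrices/data.frames of locus
#'   identifiers (columns of \code{m}).
#' @return list with \code{statistic}, \code{p.value}, \code{medianClic},
#'   \code{medianControl}.
#' @export
mutualExclusionComparison <- function(m, clicPairs, controlPairs) {
  clicPairs <- as.matrix(clicPairs); controlPairs <- as.matrix(controlPairs)
  if (!nrow(clicPairs) || !nrow(controlPairs))
    stop("both pair lists must be non-empty")
  dist_of <- function(p) vapply(seq_len(nrow(p)), function(i)
    meanManhattan(m, p[i, 1L], p[i, 2L]), numeric(1L))
  dC <- dist_of(clicPairs); dK <- dist_of(controlPairs)
  rs <- .rank_sum(dC, dK, "two.sided")
  list(statistic = rs$statistic, p.value = rs$p.value,
       medianClic = stats::median(dC), medianControl = stats::median(dK))
}

#' Fisher's exact enrichment test for two set memberships
#'
#' Cross-classifies a universe by membership in two sets and tests
#' association with Fisher's exact test (two-sided). Used uniformly for
#' CIS-gene overlap, cancer-gene overlap, TFBS-carrier overlap and high- vs
#' low-scoring cluster interaction counts.
#'
#' @param membersA,membersB vectors, subsets of \code{universe}.
#' @param universe vector of all items.
#' @return list with \code{table} (2 x 2), \code{oddsRatio} (conditional
#'   MLE), \code{p.value} and \code{degenerate} (TRUE when a margin is 0 or
#'   the whole universe).
#' @export
enrichmentTest <- function(membersA, membersB, universe) {
  if (!length(universe)) stop("empty universe")
  if (!all(membersA %in% universe) || !all(membersB %in% universe))
    stop("memberships must be subsets of the universe")
  inA <- factor(universe %in% membersA, levels = c(TRUE, FALSE))
  inB <- factor(universe %in% membersB, levels = c(TRUE, FALSE))
  tab <- table(A = inA, B = inB)
  ft <- stats::fisher.test(tab)
  list(table = tab, oddsRatio = unname(ft$estimate), p.value = ft$p.value,
       degenerate = any(rowSums(tab) %in% c(0L, length(universe))) ||
         any(colSums(tab) %in% c(0L, length(universe))))
}

#' Call TFBS-carrier clusters
#'
#' A cluster carries transcription-factor binding sites when its
#' length-normalized peak count (number of peaks whose midpoint falls
#' inside the cluster extent, divided by the extent length in bp) strictly
#' exceeds the median density over all supplied clusters.
#'
#' @param ics data.frame of cluster extents (\code{chrom}, \code{startBp},
#'   \code{endBp}).
#' @param peaks data.frame of peak intervals (\code{chrom}, \code{start},
#'   \code{end}, bp).
#' @return data.frame with \code{density} and logical \code{carrier}, one
#'   row per cluster.
#' @export
tfbsCarrier <- function(ics, peaks) {
  ics <- as.data.frame(ics)
  if (!nrow(ics)) stop("empty cluster list")
  peaks <- as.data.frame(peaks)
  mid <- if (nrow(peaks)) (peaks$start + peaks$end) / 2 else numeric(0)
  dens <- vapply(seq_len(nrow(ics)), function(i) {
    k <- sum(nrow(peaks) > 0 & peaks$chrom == ics$chrom[i] &
             mid >= ics$startBp[i] & mid < ics$endBp[i])
    k / (ics$endBp[i] - ics$startBp[i])
  }, numeric(1L))
  data.frame(density = dens, carrier = dens > stats::median(dens))
}

## Welch two-sample t statistic, sign = inserted group minus background
.welch_t <- function(x, grp) {
  x1 <- x[grp]; x0 <- x[!grp]
  if (length(x1) < 2L || length(x0) < 2L)
    stop("undefined score: a group has fewer than 2 samples")
  v1 <- stats::var(x1); v0 <- stats::var(x0)
  se <- sqrt(v1 / length(x1) + v0 / length(x0))
  if (se == 0) stop("undefined score: zero variance in both groups")
  (mean(x1) - mean(x0)) / se
}

#' Insertion-expression association scores T_A and T_AB
#'
#' For a gene residing in CLIC locus A, T_A is the Welch two-sample
#' t-statistic of the gene's expression between samples with and without an
#' insertion in locus A (positive = inserted group higher). T_AB uses the
#' same contrast with group membership defined by an insertion in locus A
#' or in the CLIC partner locus B, capturing the additional effect of
#' spatially co-located distal insertions. When locus B is never inserted
#' the two groupings coincide and T_AB equals T_A exactly.
#'
#' @param expr expression matrix, genes x samples.
#' @param gene gene identifier (rowname of \code{expr}).
#' @param m a [sampleLocusMatrix()] matrix over the same samples.
#' @param locusA,locusB columns of \code{m}.
#' @return named numeric vector \code{c(tA = ..., tAB = ...)}.
#' @export
expressionTScores <- function(expr, gene, m, locusA, locusB) {
  samples <- colnames(expr)
  if (is.null(samples) || !all(samples %in% rownames(m)))
    stop("expression samples must appear in the occupancy matrix")
  x <- expr[gene, ]
  a <- m[samples, locusA] == 1L
  ab <- a | (m[samples, locusB] == 1L)
  c(tA = .welch_t(x, a), tAB = .welch_t(x, ab))
}

#' Spatial association delta
#'
#' \eqn{sign(T_A) (T_{AB} - T_A)}: positive when adding the spatially
#' co-located distal insertions amplifies the local (activating or
#' repressing) expression effect. When T_A is exactly 0 the delta falls
#' back to |T_AB| with attribute \code{zeroSign = TRUE}.
#'
#' @param tA,tAB association scores from [expressionTScores()].
#' @return signed numeric delta (attribute \code{zeroSign} flags tA == 0).
#' @examples
#' spatialAssociationDelta(2, 3)    # +1
#' spatialAssociationDelta(-2, -3)  # +1
#' @export
spatialAssociationDelta <- function(tA, tAB) {
  if (tA == 0) {
    out <- abs(tAB)
    attr(out, "zeroSign") <- TRUE
    return(out)
  }
  out <- sign(tA) * (tAB - tA)
  attr(out, "zeroSign") <- FALSE
  out
}
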