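#' Coarsen a contact map by summing blocks of bins
#'
#' Sums \code{factor x factor} blocks of consecutive bins, e.g. turning 40 kb
#' maps into 200 kb maps with \code{factor = 5}. A trailing partial block is
#' summed as-is. The total contact sum and symmetry are conserved exactly.
#'
#' @param map a [ContactMap-class].
#' @param factor integer >= 1, number of consecutive bins per coarse bin.
#' @return A [ContactMap-class] at bin size \code{binSize * factor}.
#' @examples
#' m <- contactMap(matrix(1, 10, 10))
#' contactScores(coarsenContactMap(m, 5))  # 2 x 2 matrix of 25s
#' @export
coarsenContactMap <- function(map, factor) {
  stopifnot(is(map, "ContactMap"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be an integer >= 1")
  if (factor == 1L) return(map)
  n <- nrow(map@scores)
  grp <- (seq_len(n) - 1L) %/% factor + 1L
  agg <- rowsum(map@scores, grp)            # sum rows within blocks
  agg <- t(rowsum(t(agg), grp))             # then columns
  contactMap(agg, chrom = map@chrom, binSize = map@binSize * factor)
}

.superdiag <- function(m, k) {
  n <- nrow(m)
  m[cbind(seq_len(n - k), seq_len(n - k) + k)]
}

#' Build the distance-matched score pool for one superdiagonal
#'
#' The pool starts with the k-th superdiagonal of the contact matrix (all
#' scores at bin distance k). If it is shorter than the target length L,
#' whole neighbouring superdiagonals are appended in the order k-1, k+1,
#' k-2, k+2, ... (skipping distances outside 1..n-1) until the pooled length
#' reaches at least L. The k-th superdiagonal's own entries always occupy
#' the head of the pool, so their positions are known to callers.
#'
#' @param map a [ContactMap-class].
#' @param k bin distance (1 <= k <= n-1).
#' @param L target pool length.
#' @return numeric vector of pooled scores, length >= min(L, all scores).
#' @export
buildSuperdiagonalPool <- function(map, k, L) {
  stopifnot(is(map, "ContactMap"))
  n <- nrow(map@scores)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n - 1L)
    stop(sprintf("k must lie in 1..%d", n - 1L))
  if (L < 1) stop("L must be >= 1")
  pool <- .superdiag(map@scores, k)
  delta <- 0L
  while (length(pool) < L) {
    delta <- delta + 1L
    lo <- k - delta; hi <- k + delta
    if (lo < 1L && hi > n - 1L) break     # chromosome exhausted
    if (lo >= 1L) pool <- c(pool, .superdiag(map@scores, lo))
    if (length(pool) >= L) break
    if (hi <= n - 1L) pool <- c(pool, .superdiag(map@scores, hi))
  }
  pool
}

#' Rank-based distance normalization of a contact map
#'
#' Removes the genomic-distance bias of Hi-C contacts without assuming any
#' parametric score distribution: each score is replaced by its average-tie
#' rank among scores at the same (or, where superdiagonals are short,
#' similar) genomic distance, scaled by the pool size to (0, 1]. Pools are
#' built by [buildSuperdiagonalPool()]; the target pool length L defaults to
#' twice the number of bins ("auto"), matching the convention of sizing L by
#' the longest chromosome in a run. The diagonal is set to the NA sentinel
#' and excluded from every downstream test.
#'
#' @param map a [ContactMap-class] with at least 3 bins.
#' @param L target pool length, or "auto" for 2 x n bins. When normalizing
#'   several chromosomes of one run, pass the same explicit L (twice the bin
#'   count of the longest chromosome) to all of them.
#' @return A [NormalizedContactMap-class].
#' @examples
#' m <- simulateContactMap(simulationConfig(nBins = 60, seed = 2))
#' nm <- rankNormalize(m)
#' range(normalizedScores(nm), na.rm = TRUE)
#' @export
rankNormalize <- function(map, L = "auto") {
  stopifnot(is(map, "ContactMap"))
  n <- nrow(map@scores)
  if (n < 3L) stop("need at least 3 bins for meaningful superdiagonals")
  if (identical(L, "auto")) L <- 2L * n
  L <- as.integer(L)
  out <- matrix(NA_real_, n, n)
  for (k in seq_len(n - 1L)) {
    pool <- buildSuperdiagonalPool(map, k, L)
    m <- n - k
    r <- rank(pool, ties.method = "average")[seq_len(m)] / length(pool)
    idx <- cbind(seq_len(m), seq_len(m) + k)
    out[idx] <- r
    out[idx[, c(2L, 1L), drop = FALSE]] <- r
  }
  new("NormalizedContactMap", chrom = map@chrom, binSize = map@binSize,
      ranks = out, poolLength = L)
}

#' Chromatin compartment track from the contact correlation matrix
#'
#' Computes the bin-by-bin Pearson correlation matrix of the normalized
#' contacts (diagonal sentinel excluded pairwise) and extracts its first
#' principal component. The sign of PC1 partitions bins into the two
#' chromatin compartments. Orientation: PC1 is flipped, if needed, so that
#' it correlates positively with per-bin total normalized contact, a proxy
#' for the open compartment; bins whose contact profile has zero variance
#' are masked (NA).
#'
#' @param norm a [NormalizedContactMap-class] with >= 3 bins.
#' @return A [CompartmentTrack-class].
#' @export
compartmentPC1 <- function(norm) {
  stopifnot(is(norm, "NormalizedContactMap"))
  r <- norm@ranks
  n <- nrow(r)
  if (n < 3L) stop("need at least 3 bins")
  sds <- apply(r, 2L, stats::sd, na.rm = TRUE)
  keep <- which(sds > 0)
  if (length(keep) < 3L)
    stop("degenerate input: contact matrix has (near-)constant bin profiles")
  C <- suppressWarnings(stats::cor(r[, keep, drop = FALSE],
                                   use = "pairwise.complete.obs"))
  C[!is.finite(C)] <- 0
  pc <- stats::prcomp(C, center = TRUE, scale. = FALSE)
  v <- pc$x[, 1L]
  tot <- colSums(r[, keep, drop = FALSE], na.rm = TRUE)
  orient <- stats::cor(v, tot)
  oriented <- is.finite(orient) && orient != 0
  if (oriented && orient < 0) v <- -v
  v <- v / sqrt(sum(v^2))
  full <- rep(NA_real_, n)
  full[keep] <- v
  new("CompartmentTrack", chrom = norm@chrom, binSize = norm@binSize,
      pc1 = full, openIsPositive = oriented)
}

#' Correlate per-bin insertion counts with the compartment eigenvector
#'
#' Pearson correlation (with two-sided p-value) between the per-bin
#' insertion counts and PC1, quantifying the preference of insertions for
#' open chromatin. Masked PC1 bins are dropped.
#'
#' @param track a [CompartmentTrack-class].
#' @param profile a [BinnedInsertionProfile-class] on the same binning.
#' @return list with elements \code{correlation} and \code{p.value}.
#' @export
correlateInsertionsCompartment <- function(track, profile) {
  stopifnot(is(track, "CompartmentTrack"),
            is(profile, "BinnedInsertionProfile"))
  if (length(track@pc1) != length(profile@counts))
    stop("track and profile must share the binning")
  ok <- !is.na(track@pc1)
  x <- profile@counts[ok]; y <- track@pc1[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in counts or PC1")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(correlation = unname(ct$estimate), p.value = ct$p.value)
}
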