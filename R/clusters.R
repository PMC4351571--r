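#' Bin insertions into fixed-width genomic bins
#'
#' Counts insertions per half-open bin \code{[(i-1)*binSize, i*binSize)} for
#' every chromosome of the dataset (an insertion at exactly one bin width
#' falls in the second bin).
#'
#' @param data an [InsertionDataset-class].
#' @param binSize bin width in bp (the category analysis uses 200 kb).
#' @return named list of [BinnedInsertionProfile-class], one per chromosome.
#' @examples
#' ins <- simulateInsertions(simulationConfig(nBins = 100, seed = 5))
#' prof <- binInsertions(ins, 200000)[[1]]
#' prof
#' @export
binInsertions <- function(data, binSize) {
  stopifnot(is(data, "InsertionDataset"))
  if (binSize <= 0) stop("binSize must be positive")
  out <- lapply(names(data@genome), function(ch) {
    len <- data@genome[[ch]]
    nb <- as.integer(ceiling(len / binSize))
    pos <- data@records$pos[data@records$chrom == ch]
    if (any(pos < 0 | pos >= len))
      stop(sprintf("insertion outside chromosome %s bounds", ch))
    idx <- floor(pos / binSize) + 1L
    counts <- tabulate(idx, nbins = nb)
    new("BinnedInsertionProfile", chrom = ch, binSize = as.numeric(binSize),
        counts = as.integer(counts), categories = character(0))
  })
  stats::setNames(out, names(data@genome))
}

#' Categorize bins by insertion recurrence
#'
#' Labels each bin non-inserted (NI, S = 0), inserted (I, 0 < S <= Nm) or
#' recurrently inserted (RI, S > Nr). Bins with Nm < S <= Nr fall between
#' the categories, are labelled UNASSIGNED and are excluded from category
#' tests. Defaults Nm = 2, Nr = 5.
#'
#' @param profile a [BinnedInsertionProfile-class].
#' @param Nm maximum count for the I category.
#' @param Nr minimum exceeded count for the RI category (Nm <= Nr).
#' @return The profile with its \code{categories} slot filled.
#' @export
categorizeBins <- function(profile, Nm = 2L, Nr = 5L) {
  stopifnot(is(profile, "BinnedInsertionProfile"))
  if (Nm <= 0 || Nm > Nr) stop("need 0 < Nm <= Nr")
  s <- profile@counts
  cats <- ifelse(s == 0L, "NI",
          ifelse(s <= Nm, "I",
          ifelse(s > Nr, "RI", "UNASSIGNED")))
  initialize(profile, categories = cats)
}

#' Gaussian-kernel-smoothed insertion density
#'
#' Evaluates \eqn{f(x) = \sum_m \exp(-(x - p_m)^2 / (2\sigma^2))} over all
#' insertion positions \eqn{p_m} of a chromosome, on a regular grid. No
#' kernel-area normalization is applied: one isolated insertion has peak
#' height exactly 1, so heights count effective overlapping insertions.
#'
#' @param data an [InsertionDataset-class].
#' @param sigma kernel standard deviation in bp (default 40 kb, i.e. a
#'   2-sigma window of 80 kb).
#' @param gridStep grid spacing in bp (default sigma/4).
#' @param chromName chromosome to smooth; default the first in the genome.
#' @return A [DensityTrack-class].
#' @export
smoothInsertionDensity <- function(data, sigma = 40000,
                                   gridStep = sigma / 4,
                                   chromName = names(data@genome)[1L]) {
  stopifnot(is(data, "InsertionDataset"))
  if (sigma <= 0 || gridStep <= 0) stop("sigma and gridStep must be positive")
  len <- data@genome[[chromName]]
  grid <- seq(0, len, by = gridStep)
  pos <- data@records$pos[data@records$chrom == chromName]
  vals <- numeric(length(grid))
  if (length(pos)) {
    # chunk over insertions to bound the outer() allocation
    step <- max(1L, floor(2e6 / length(grid)))
    for (i in seq(1L, length(pos), by = step)) {
      p <- pos[i:min(i + step - 1L, length(pos))]
      vals <- vals + colSums(exp(-outer(p, grid, "-")^2 / (2 * sigma^2)))
    }
  }
  new("DensityTrack", chrom = chromName, grid = grid, values = vals)
}

## walk downhill from a peak until the value stops decreasing
.flank_min <- function(v, p, dir) {
  j <- p
  while (j + dir >= 1L && j + dir <= length(v) && v[j + dir] < v[j])
    j <- j + dir
  j
}

#' Detect insertion clusters as peaks of the smoothed density
#'
#' Insertion clusters (ICs) are the strict local maxima of the smoothed
#' insertion density f(x). Each cluster's extent runs between the two
#' flanking local minima of f, aligned outward to the nearest bin boundary;
#' clusters spanning fewer than 3 bins are expanded by one bin on both sides
#' so that every cluster pair later yields at least a 3 x 3 block of contact
#' scores. Overlapping clusters are kept separate, and the overlap with the
#' previous cluster is reported.
#'
#' @param density a [DensityTrack-class].
#' @param data the [InsertionDataset-class] the density was computed from
#'   (used to record which samples hit each cluster).
#' @param binSize bin width in bp used for boundary alignment (default 40 kb).
#' @return data.frame with one row per cluster: \code{chrom},
#'   \code{peakPos} (bp), \code{peakHeight}, \code{startBin}, \code{endBin}
#'   (1-based inclusive), \code{nBins}, \code{startBp}, \code{endBp}
#'   (half-open), \code{overlapsPrevious}, and a list column
#'   \code{sampleHits}. The bin size is attached as attribute
#'   \code{"binSize"}.
#' @export
detectClusters <- function(density, data, binSize = 40000) {
  stopifnot(is(density, "DensityTrack"), is(data, "InsertionDataset"))
  v <- density@values
  g <- density@grid
  nGrid <- length(v)
  len <- data@genome[[density@chrom]]
  nBinsChrom <- as.integer(ceiling(len / binSize))
  empty <- data.frame(chrom = character(), peakPos = numeric(),
                      peakHeight = numeric(), startBin = integer(),
                      endBin = integer(), nBins = integer(),
                      startBp = numeric(), endBp = numeric(),
                      overlapsPrevious = logical())
  empty$sampleHits <- list()
  attr(empty, "binSize") <- binSize
  if (nGrid < 3L) return(empty)
  interior <- 2:(nGrid - 1L)
  peaks <- interior[v[interior] > v[interior - 1L] &
                    v[interior] > v[interior + 1L]]
  if (!length(peaks)) return(empty)
  rows <- lapply(peaks, function(p) {
    l <- .flank_min(v, p, -1L)
    r <- .flank_min(v, p, +1L)
    startBin <- as.integer(floor(g[l] / binSize)) + 1L
    endBin <- max(as.integer(ceiling(g[r] / binSize)), startBin)
    if (endBin - startBin + 1L < 3L) {
      startBin <- startBin - 1L
      endBin <- endBin + 1L
    }
    startBin <- max(1L, startBin)
    endBin <- min(nBinsChrom, endBin)
    data.frame(chrom = density@chrom, peakPos = g[p], peakHeight = v[p],
               startBin = startBin, endBin = endBin,
               nBins = endBin - startBin + 1L,
               startBp = (startBin - 1) * binSize,
               endBp = endBin * binSize)
  })
  out <- do.call(rbind, rows)
  out$overlapsPrevious <- c(FALSE, out$startBin[-1L] <=
                              out$endBin[-nrow(out)])
  rec <- data@records[data@records$chrom == density@chrom, ]
  out$sampleHits <- lapply(seq_len(nrow(out)), function(i) {
    sort(unique(rec$sample[rec$pos >= out$startBp[i] &
                           rec$pos < out$endBp[i]]))
  })
  rownames(out) <- NULL
  attr(out, "binSize") <- binSize
  out
}

#' Split insertion clusters at the median peak height
#'
#' The genome-wide median peak height over all supplied clusters separates
#' high-scoring clusters (strictly above the median; some evidence of
#' selection) from low-scoring background clusters.
#'
#' @param clusters data.frame from [detectClusters()], typically the
#'   concatenation over all chromosomes.
#' @return list with elements \code{high}, \code{low} (both data.frames) and
#'   \code{threshold} (the median peak height).
#' @export
splitByPeakHeight <- function(clusters) {
  if (is.null(clusters) || nrow(clusters) == 0L)
    stop("no clusters supplied")
  thr <- stats::median(clusters$peakHeight)
  list(high = clusters[clusters$peakHeight > thr, , drop = FALSE],
       low = clusters[clusters$peakHeight <= thr, , drop = FALSE],
       threshold = thr)
}

#' Randomize insertion locations as a destructive control
#'
#' Redraws every insertion position uniformly, either across the whole
#' genome ("uniform") or uniformly within a supplied set of bins
#' ("tss_bins", emulating restriction to bins containing a transcription
#' start site). The number of insertions per sample is conserved.
#'
#' @param data an [InsertionDataset-class].
#' @param mode "uniform" or "tss_bins".
#' @param tssBins for mode "tss_bins": data.frame with columns \code{chrom}
#'   and \code{bin} (1-based) identifying the allowed bins.
#' @param binSize bin width for interpreting \code{tssBins}.
#' @param seed integer seed.
#' @return A randomized [InsertionDataset-class].
#' @export
randomizeInsertions <- function(data, mode = c("uniform", "tss_bins"),
                                tssBins = NULL, binSize = 200000,
                                seed = 1L) {
  stopifnot(is(data, "InsertionDataset"))
  mode <- match.arg(mode)
  set.seed(as.integer(seed))
  rec <- data@records
  nIns <- nrow(rec)
  if (mode == "uniform") {
    lens <- data@genome
    ch <- names(lens)[sample.int(length(lens), nIns, replace = TRUE,
                                 prob = lens / sum(lens))]
    pos <- stats::runif(nIns, 0, lens[ch])
  } else {
    if (is.null(tssBins) || nrow(tssBins) == 0L)
      stop("tss_bins mode needs a non-empty bin set")
    pick <- sample.int(nrow(tssBins), nIns, replace = TRUE)
    ch <- as.character(tssBins$chrom[pick])
    lo <- (tssBins$bin[pick] - 1) * binSize
    hi <- pmin(tssBins$bin[pick] * binSize, data@genome[ch])
    pos <- stats::runif(nIns, lo, hi)
  }
  insertionDataset(
    data.frame(chrom = ch, pos = pos, sample = rec$sample,
               stringsAsFactors = FALSE),
    genome = data@genome, samples = data@samples)
}
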