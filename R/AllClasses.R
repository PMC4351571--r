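#' @import methods
NULL

.check_symmetric <- function(m, tol = 1e-8) {
  isTRUE(all(abs(m - t(m)) <= tol * (1 + max(abs(m), na.rm = TRUE)), na.rm = TRUE))
}

#' ContactMap: binned intra-chromosomal Hi-C contact scores
#'
#' A symmetric, non-negative \code{n x n} matrix of Hi-C contact scores
#' \eqn{h_{ij}} between fixed-width genomic bins of one chromosome, assumed
#' already corrected for experimental biases. Bin \code{i} covers the
#' half-open interval \code{[(i-1)*binSize, i*binSize)} in base pairs.
#'
#' @slot chrom chromosome label.
#' @slot binSize bin width in base pairs.
#' @slot scores symmetric non-negative numeric matrix of contact scores.
#'
#' @seealso [contactMap()], [rankNormalize()], [coarsenContactMap()]
#' @export
setClass("ContactMap",
  representation(chrom = "character", binSize = "numeric", scores = "matrix"))

setValidity("ContactMap", function(object) {
  m <- object@scores
  if (length(object@chrom) != 1L) return("chrom must be a single label")
  if (length(object@binSize) != 1L || object@binSize <= 0)
    return("binSize must be a single positive number")
  if (nrow(m) != ncol(m)) return("scores must be a square matrix")
  if (nrow(m) < 2L) return("contact map needs at least 2 bins")
  if (anyNA(m)) return("scores must not contain NA")
  if (any(m < 0)) return("scores must be non-negative")
  if (!.check_symmetric(m)) return("scores must be symmetric")
  TRUE
})

#' Construct a ContactMap
#'
#' @param scores symmetric non-negative numeric matrix.
#' @param chrom chromosome label.
#' @param binSize bin width in base pairs (default 40 kb).
#' @return A [ContactMap-class] object.
#' @examples
#' m <- matrix(c(4, 2, 1, 2, 4, 2, 1, 2, 4), 3)
#' contactMap(m, chrom = "chr1", binSize = 40000)
#' @export
contactMap <- function(scores, chrom = "chrS", binSize = 40000) {
  new("ContactMap", chrom = chrom, binSize = as.numeric(binSize),
      scores = unname(as.matrix(scores)))
}

#' NormalizedContactMap: rank-normalized contact scores
#'
#' Holds \eqn{\hat h_{ij}}, the per-distance rank-normalized contact scores in
#' \code{(0, 1]}. Each raw score is replaced by its average-tie rank within a
#' pool of scores at the same (or, for long distances, similar) genomic
#' distance, divided by the pool size. The main diagonal carries the sentinel
#' \code{NA} and is excluded from all downstream tests.
#'
#' @slot chrom chromosome label.
#' @slot binSize bin width in base pairs.
#' @slot ranks symmetric matrix of normalized scores in (0, 1]; diagonal NA.
#' @slot poolLength the target pool length L used for normalization.
#' @seealso [rankNormalize()]
#' @export
setClass("NormalizedContactMap",
  representation(chrom = "character", binSize = "numeric",
                 ranks = "matrix", poolLength = "integer"))

setValidity("NormalizedContactMap", function(object) {
  r <- object@ranks
  if (nrow(r) != ncol(r)) return("ranks must be square")
  off <- r[upper.tri(r)]
  if (anyNA(off)) return("off-diagonal normalized scores must not be NA")
  if (any(off <= 0 | off > 1)) return("normalized scores must lie in (0, 1]")
  if (!all(is.na(diag(r)))) return("diagonal must be the NA sentinel")
  if (!.check_symmetric(r)) return("ranks must be symmetric")
  if (object@poolLength < 1L) return("poolLength must be >= 1")
  TRUE
})

#' CompartmentTrack: per-bin chromatin compartment eigenvector
#'
#' The first principal component (PC1) of the correlation matrix of the
#' normalized Hi-C contacts. The sign of PC1 partitions bins into the two
#' chromatin compartments; the track is oriented so that positive values
#' correspond to bins with higher total contact (a proxy for the open, A-type
#' compartment), recorded in \code{openIsPositive}.
#'
#' @slot chrom chromosome label.
#' @slot binSize bin width in base pairs.
#' @slot pc1 numeric vector, one value per bin (NA for masked bins); unit
#'   Euclidean norm over unmasked bins.
#' @slot openIsPositive logical; TRUE when the orientation rule could be
#'   applied so that positive PC1 marks high-contact (open) bins.
#' @seealso [compartmentPC1()]
#' @export
setClass("CompartmentTrack",
  representation(chrom = "character", binSize = "numeric",
                 pc1 = "numeric", openIsPositive = "logical"))

setValidity("CompartmentTrack", function(object) {
  v <- object@pc1[!is.na(object@pc1)]
  if (length(v) == 0L) return("pc1 must contain at least one unmasked bin")
  if (abs(sqrt(sum(v^2)) - 1) > 1e-6) return("pc1 must have unit norm")
  TRUE
})

#' InsertionDataset: retroviral insertion sites across a tumour cohort
#'
#' One record per insertion: chromosome, base-pair position (0-based) and the
#' sample (tumour) carrying it. The sample roster is kept explicitly so that
#' samples without insertions still count in cohort-level statistics.
#'
#' @slot records data.frame with columns \code{chrom} (character),
#'   \code{pos} (numeric, 0-based bp) and \code{sample} (character).
#' @slot samples character vector: the full cohort roster.
#' @slot genome named numeric vector of chromosome lengths in bp.
#' @seealso [insertionDataset()], [simulateInsertions()], [binInsertions()]
#' @export
setClass("InsertionDataset",
  representation(records = "data.frame", samples = "character",
                 genome = "numeric"))

setValidity("InsertionDataset", function(object) {
  r <- object@records
  if (!all(c("chrom", "pos", "sample") %in% names(r)))
    return("records needs columns chrom, pos, sample")
  if (is.null(names(object@genome)) || any(object@genome <= 0))
    return("genome must be a named vector of positive lengths")
  if (nrow(r)) {
    bad <- !(r$chrom %in% names(object@genome))
    if (any(bad))
      return(sprintf("record %d on unknown chromosome '%s'",
                     which(bad)[1L], r$chrom[which(bad)[1L]]))
    out <- r$pos < 0 | r$pos >= object@genome[r$chrom]
    if (any(out))
      return(sprintf("record %d outside chromosome bounds", which(out)[1L]))
    if (!all(r$sample %in% object@samples))
      return("records contain samples absent from the cohort roster")
  }
  TRUE
})

#' Construct an InsertionDataset
#'
#' @param records data.frame with columns chrom, pos (0-based bp), sample.
#' @param samples cohort roster; defaults to the samples seen in records.
#' @param genome named numeric vector of chromosome lengths (bp).
#' @return An [InsertionDataset-class] object.
#' @export
insertionDataset <- function(records, genome,
                             samples = sort(unique(records$sample))) {
  records <- as.data.frame(records)[, c("chrom", "pos", "sample")]
  records$chrom <- as.character(records$chrom)
  records$pos <- as.numeric(records$pos)
  records$sample <- as.character(records$sample)
  rownames(records) <- NULL
  new("InsertionDataset", records = records, samples = as.character(samples),
      genome = genome)
}

#' BinnedInsertionProfile: per-bin insertion counts and categories
#'
#' Per-bin insertion counts \eqn{S_i} for one chromosome, with the optional
#' three-way categorization into non-inserted (NI, \eqn{S_i = 0}), inserted
#' (I, \eqn{0 < S_i \le N_m}) and recurrently inserted (RI, \eqn{S_i > N_r})
#' bins. Bins with \eqn{N_m < S_i \le N_r} fall between the categories and
#' are labelled UNASSIGNED, which excludes them from category tests.
#'
#' @slot chrom chromosome label.
#' @slot binSize bin width in bp.
#' @slot counts integer vector of per-bin insertion counts.
#' @slot categories character vector of labels in NI/I/RI/UNASSIGNED, or
#'   length zero before [categorizeBins()] is applied.
#' @seealso [binInsertions()], [categorizeBins()]
#' @export
setClass("BinnedInsertionProfile",
  representation(chrom = "character", binSize = "numeric",
                 counts = "integer", categories = "character"))

setValidity("BinnedInsertionProfile", function(object) {
  if (any(object@counts < 0)) return("counts must be non-negative")
  nc <- length(object@categories)
  if (nc != 0L && nc != length(object@counts))
    return("categories must be empty or match counts in length")
  if (nc && !all(object@categories %in% c("NI", "I", "RI", "UNASSIGNED")))
    return("categories must be NI, I, RI or UNASSIGNED")
  TRUE
})

#' DensityTrack: kernel-smoothed insertion density
#'
#' The Gaussian-kernel-smoothed insertion count \eqn{f(x)} evaluated on a
#' regular base-pair grid. No kernel-area normalization is applied, so a
#' single isolated insertion contributes a peak of height exactly 1 and peak
#' heights read as effective numbers of overlapping insertions.
#'
#' @slot chrom chromosome label.
#' @slot grid strictly increasing numeric vector of bp positions.
#' @slot values non-negative numeric vector, \eqn{f} at each grid point.
#' @seealso [smoothInsertionDensity()], [detectClusters()]
#' @export
setClass("DensityTrack",
  representation(chrom = "character", grid = "numeric", values = "numeric"))

setValidity("DensityTrack", function(object) {
  if (length(object@grid) != length(object@values))
    return("grid and values must match in length")
  if (length(object@grid) > 1L && any(diff(object@grid) <= 0))
    return("grid must be strictly increasing")
  if (any(object@values < 0)) return("density values must be non-negative")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap: %s, %d bins of %g bp (total %.3g contacts)\n",
              object@chrom, nrow(object@scores), object@binSize,
              sum(object@scores)))
})

setMethod("show", "NormalizedContactMap", function(object) {
  cat(sprintf("NormalizedContactMap: %s, %d bins of %g bp, pool length L=%d\n",
              object@chrom, nrow(object@ranks), object@binSize,
              object@poolLength))
})

setMethod("show", "CompartmentTrack", function(object) {
  s <- sign(object@pc1)
  cat(sprintf(
    "CompartmentTrack: %s, %d bins (%d positive / %d negative / %d masked)\n",
    object@chrom, length(object@pc1), sum(s > 0, na.rm = TRUE),
    sum(s < 0, na.rm = TRUE), sum(is.na(s))))
})

setMethod("show", "InsertionDataset", function(object) {
  cat(sprintf(
    "InsertionDataset: %d insertions, %d samples, %d chromosome(s)\n",
    nrow(object@records), length(object@samples), length(object@genome)))
})

setMethod("show", "BinnedInsertionProfile", function(object) {
  cat(sprintf("BinnedInsertionProfile: %s, %d bins of %g bp, %d insertions%s\n",
              object@chrom, length(object@counts), object@binSize,
              sum(object@counts),
              if (length(object@categories)) " (categorized)" else ""))
})

setMethod("show", "DensityTrack", function(object) {
  cat(sprintf("DensityTrack: %s, %d grid points, max f(x)=%.3g\n",
              object@chrom, length(object@grid),
              if (length(object@values)) max(object@values) else NA_real_))
})

## ---- accessors ----------------------------------------------------------

#' Accessors for clichunter objects
#'
#' Small read-only accessors for the S4 containers: \code{chrom()} and
#' \code{binSize()} work on any binned object; \code{contactScores()} returns
#' the raw score matrix of a [ContactMap-class]; \code{normalizedScores()} the
#' rank matrix of a [NormalizedContactMap-class]; \code{pc1()} the eigenvector
#' of a [CompartmentTrack-class]; \code{insertionRecords()},
#' \code{sampleRoster()} and \code{genomeLengths()} the parts of an
#' [InsertionDataset-class]; \code{binCounts()} and \code{binCategories()} the
#' parts of a [BinnedInsertionProfile-class].
#'
#' @param x object to access.
#' @return The slot value (matrix, vector or data.frame as documented above).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chrom", function(x) standardGeneric("chrom"))
#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname accessors
#' @export
setGeneric("contactScores", function(x) standardGeneric("contactScores"))
#' @rdname accessors
#' @export
setGeneric("normalizedScores", function(x) standardGeneric("normalizedScores"))
#' @rdname accessors
#' @export
setGeneric("pc1", function(x) standardGeneric("pc1"))
#' @rdname accessors
#' @export
setGeneric("insertionRecords", function(x) standardGeneric("insertionRecords"))
#' @rdname accessors
#' @export
setGeneric("sampleRoster", function(x) standardGeneric("sampleRoster"))
#' @rdname accessors
#' @export
setGeneric("genomeLengths", function(x) standardGeneric("genomeLengths"))
#' @rdname accessors
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))
#' @rdname accessors
#' @export
setGeneric("binCategories", function(x) standardGeneric("binCategories"))

#' @rdname accessors
setMethod("chrom", "ContactMap", function(x) x@chrom)
#' @rdname accessors
setMethod("chrom", "NormalizedContactMap", function(x) x@chrom)
#' @rdname accessors
setMethod("chrom", "CompartmentTrack", function(x) x@chrom)
#' @rdname accessors
setMethod("chrom", "BinnedInsertionProfile", function(x) x@chrom)
#' @rdname accessors
setMethod("chrom", "DensityTrack", function(x) x@chrom)
#' @rdname accessors
setMethod("binSize", "ContactMap", function(x) x@binSize)
#' @rdname accessors
setMethod("binSize", "NormalizedContactMap", function(x) x@binSize)
#' @rdname accessors
setMethod("binSize", "CompartmentTrack", function(x) x@binSize)
#' @rdname accessors
setMethod("binSize", "BinnedInsertionProfile", function(x) x@binSize)
#' @rdname accessors
setMethod("contactScores", "ContactMap", function(x) x@scores)
#' @rdname accessors
setMethod("normalizedScores", "NormalizedContactMap", function(x) x@ranks)
#' @rdname accessors
setMethod("pc1", "CompartmentTrack", function(x) x@pc1)
#' @rdname accessors
setMethod("insertionRecords", "InsertionDataset", function(x) x@records)
#' @rdname accessors
setMethod("sampleRoster", "InsertionDataset", function(x) x@samples)
#' @rdname accessors
setMethod("genomeLengths", "InsertionDataset", function(x) x@genome)
#' @rdname accessors
setMethod("binCounts", "BinnedInsertionProfile", function(x) x@counts)
#' @rdname accessors
setMethod("binCategories", "BinnedInsertionProfile", function(x) x@categories)
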