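#' Bin intervals of the planted clusters of a simulation
#'
#' Converts each cluster spec (centre bin, width in bp) into the 1-based
#' inclusive bin interval covering centre +/- (width/2 + pad), used both to
#' plant elevated contacts and to evaluate recovery. The pad defaults to
#' 160 kb, the 4-sigma skirt of the 40 kb cluster-calling kernel, so the
#' planted contact locus matches the spatial footprint that the cluster
#' caller assigns to the insertion cluster.
#'
#' @param config a [SimulationConfig-class].
#' @param pad half-width extension in bp beyond the insertion spread.
#' @return list of integer length-2 vectors (start bin, end bin).
#' @export
plantedIntervals <- function(config, pad = 160000) {
  cs <- config@clusterSpecs
  lapply(seq_len(nrow(cs)), function(i) {
    ctr <- (cs$centerBin[i] - 0.5) * config@binSize
    lo <- max(0, ctr - cs$widthBp[i] / 2 - pad)
    hi <- min(config@nBins * config@binSize, ctr + cs$widthBp[i] / 2 + pad)
    c(floor(lo / config@binSize) + 1L,
      min(as.integer(ceiling(hi / config@binSize)), config@nBins))
  })
}

#' Simulate a complete synthetic study
#'
#' Builds the contact map (with planted pair contacts boosted), the
#' insertion cohort and, optionally, the expression matrix from one
#' [SimulationConfig-class].
#'
#' @param config a [SimulationConfig-class].
#' @param withExpression also simulate the expression matrix.
#' @return list with \code{map} (boosted [ContactMap-class]),
#'   \code{insertions}, \code{intervals} (from [plantedIntervals()]) and
#'   optionally \code{expression}.
#' @export
simulateStudy <- function(config, withExpression = FALSE) {
  map <- simulateContactMap(config)
  iv <- plantedIntervals(config)
  pp <- config@plantedClicPairs
  if (nrow(pp)) {
    pairs <- lapply(seq_len(nrow(pp)), function(r)
      list(a = iv[[pp$a[r]]], b = iv[[pp$b[r]]], boost = pp$boost[r]))
    map <- plantClicContacts(map, pairs)
  }
  ins <- simulateInsertions(config)
  out <- list(map = map, insertions = ins, intervals = iv)
  if (withExpression) {
    loci <- data.frame(
      chrom = names(ins@genome)[1L],
      start = vapply(iv, function(v) (v[1L] - 1) * config@binSize, 0),
      end = vapply(iv, function(v) v[2L] * config@binSize, 0))
    out$expression <- simulateExpression(
      ins, loci, config,
      partners = if (nrow(pp)) pp[, c("a", "b")] else NULL)
  }
  out
}

#' Run the full co-localization pipeline
#'
#' Executes the analysis end to end on one or more chromosomes:
#' rank normalization of each contact map, compartment track and
#' insertion-compartment correlation at the coarse bin size, insertion
#' binning and categorization, kernel-density cluster calling, the median
#' peak-height split, CLIC detection with Holm control, the sample-locus
#' occupancy matrix and the mutual-exclusion comparison of significant
#' versus non-significant pairs. When \code{outDir} is given, all tables
#' are written (TSV/BED/bedGraph) together with a machine-readable JSON run
#' manifest (parameters, seed, counts at each stage).
#'
#' @param insertions an [InsertionDataset-class].
#' @param maps a [ContactMap-class] or named list of them (one per
#'   chromosome, at the fine bin size).
#' @param coarsenFactor fine bins per coarse bin (default 5: 40 kb to
#'   200 kb).
#' @param sigma Gaussian kernel sd in bp (default 40 kb).
#' @param Nm,Nr category thresholds (defaults 2 and 5).
#' @param alpha family-wise CLIC significance level (default 1e-5).
#' @param L pool/null length policy: "auto" uses twice the bin count of the
#'   longest chromosome for every map.
#' @param outDir optional output directory.
#' @param seed integer recorded in the manifest.
#' @return list bundle: \code{norm} (fine), \code{normCoarse},
#'   \code{compartments}, \code{compartmentCorrelation}, \code{profiles}
#'   (categorized, coarse), \code{clusters}, \code{split}, \code{clics},
#'   \code{occupancy}, \code{mutualExclusion} (NULL when either pair set is
#'   empty), \code{manifest}.
#' @export
runPipeline <- function(insertions, maps, coarsenFactor = 5L,
                        sigma = 40000, Nm = 2L, Nr = 5L, alpha = 1e-5,
                        L = "auto", outDir = NULL, seed = NA_integer_) {
  stopifnot(is(insertions, "InsertionDataset"))
  if (is(maps, "ContactMap")) maps <- stats::setNames(list(maps), maps@chrom)
  if (!all(names(maps) %in% names(insertions@genome)))
    stop("contact maps reference chromosomes absent from the genome")
  binFine <- maps[[1L]]@binSize
  binCoarse <- binFine * coarsenFactor
  nBinsMax <- max(vapply(maps, function(m) nrow(m@scores), 0L))
  Lfine <- if (identical(L, "auto")) 2L * nBinsMax else as.integer(L)

  norm <- lapply(maps, rankNormalize, L = Lfine)
  coarse <- lapply(maps, coarsenContactMap, factor = coarsenFactor)
  nCoarseMax <- max(vapply(coarse, function(m) nrow(m@scores), 0L))
  normCoarse <- lapply(coarse, rankNormalize,
                       L = if (identical(L, "auto")) 2L * nCoarseMax
                           else as.integer(L))
  compartments <- lapply(normCoarse, compartmentPC1)

  profiles <- binInsertions(insertions, binCoarse)
  profiles <- lapply(profiles, categorizeBins, Nm = Nm, Nr = Nr)
  compCor <- lapply(names(maps), function(ch)
    tryCatch(correlateInsertionsCompartment(compartments[[ch]],
                                            profiles[[ch]]),
             error = function(e) NULL))
  names(compCor) <- names(maps)

  clusters <- do.call(rbind, lapply(names(maps), function(ch) {
    d <- smoothInsertionDensity(insertions, sigma = sigma, chromName = ch)
    detectClusters(d, insertions, binSize = binFine)
  }))
  if (is.null(clusters) || nrow(clusters) == 0L)
    stop("stage detect_clusters: no insertion clusters found")
  split <- splitByPeakHeight(clusters)

  clics <- tryCatch(detectClics(norm, split$high, alpha = alpha, L = Lfine),
                    error = function(e)
                      stop("stage detect_clics: ", conditionMessage(e)))

  occupancy <- sampleLocusMatrix(insertions, split$high)
  sig <- clics[clics$significant, c("icA", "icB"), drop = FALSE]
  ctl <- clics[!clics$significant, c("icA", "icB"), drop = FALSE]
  # icA/icB are positional indices into split$high, i.e. occupancy columns
  me <- if (nrow(sig) && nrow(ctl)) {
    mutualExclusionComparison(occupancy, cbind(sig$icA, sig$icB),
                              cbind(ctl$icA, ctl$icB))
  } else NULL

  manifest <- list(
    parameters = list(binFine = binFine, binCoarse = binCoarse,
                      coarsenFactor = coarsenFactor, sigma = sigma,
                      Nm = Nm, Nr = Nr, alpha = alpha, L = Lfine,
                      seed = seed),
    counts = list(nInsertions = nrow(insertions@records),
                  nSamples = length(insertions@samples),
                  nChromosomes = length(maps),
                  nClusters = nrow(clusters),
                  nHighClusters = nrow(split$high),
                  peakHeightThreshold = split$threshold,
                  nPairsTested = nrow(clics),
                  nClics = sum(clics$significant)),
    version = as.character(utils::packageVersion("clichunter")))

  bundle <- list(norm = norm, normCoarse = normCoarse,
                 compartments = compartments,
                 compartmentCorrelation = compCor,
                 profiles = profiles, clusters = clusters, split = split,
                 clics = clics, occupancy = occupancy,
                 mutualExclusion = me, manifest = manifest)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeInsertions(insertions, file.path(outDir, "insertions.tsv"))
    writeClustersBed(clusters, file.path(outDir, "clusters.bed"))
    writeClics(clics, file.path(outDir, "clics.tsv"))
    writeClics(clics, file.path(outDir, "clics.bedpe"), format = "bedpe")
    for (ch in names(maps)) {
      writeContactMap(norm[[ch]], file.path(outDir,
        sprintf("normalized_%s.tsv", ch)))
      writeBedGraph(compartments[[ch]], file.path(outDir,
        sprintf("compartments_%s.bedgraph", ch)))
    }
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}
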