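#' SimulationConfig: study conditions for the synthetic genome
#'
#' Bundles every parameter of the synthetic-data generator: one synthetic
#' chromosome of \code{nBins} bins with power-law contact decay and a plaid
#' two-compartment structure, an insertion cohort of uniform background plus
#' selected clusters, optional planted co-localized cluster pairs with
#' elevated contact and mutually exclusive occupancy, and an expression
#' matrix with planted cis/trans effects.
#'
#' @slot nBins bins per synthetic chromosome (>= 10).
#' @slot binSize base pairs per bin (default 40 kb).
#' @slot decayExponent power-law exponent of contact decay with bin distance.
#' @slot compartmentBlockLen bins per alternating compartment block.
#' @slot compartmentContrast multiplicative same-compartment boost (>= 1).
#' @slot noiseDispersion sdlog of the multiplicative log-normal contact noise.
#' @slot nSamples cohort size.
#' @slot backgroundRate expected background insertions per sample per
#'   chromosome.
#' @slot clusterSpecs data.frame with columns \code{centerBin},
#'   \code{widthBp}, \code{expectedHits}, \code{selected}.
#' @slot plantedClicPairs data.frame with columns \code{a}, \code{b} (row
#'   indices into clusterSpecs), \code{boost} (contact boost factor) and
#'   \code{exclusivity} (degree of mutual exclusion in [0, 1]).
#' @slot effectSize expression shift per inserted sample.
#' @slot noiseSd expression noise scale.
#' @slot seed integer seed; all generator functions are deterministic in it.
#' @seealso [simulationConfig()], [simulateContactMap()],
#'   [simulateInsertions()], [simulateExpression()]
#' @export
setClass("SimulationConfig",
  representation(nBins = "integer", binSize = "numeric",
                 decayExponent = "numeric", compartmentBlockLen = "integer",
                 compartmentContrast = "numeric", noiseDispersion = "numeric",
                 nSamples = "integer", backgroundRate = "numeric",
                 clusterSpecs = "data.frame", plantedClicPairs = "data.frame",
                 effectSize = "numeric", noiseSd = "numeric",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nBins < 10L) return("nBins: must be >= 10")
  if (object@binSize <= 0) return("binSize: must be positive")
  if (object@decayExponent < 0) return("decayExponent: must be >= 0")
  if (object@compartmentBlockLen < 1L)
    return("compartmentBlockLen: must be >= 1")
  if (object@compartmentContrast < 1)
    return("compartmentContrast: must be >= 1")
  if (object@noiseDispersion < 0) return("noiseDispersion: must be >= 0")
  if (object@nSamples < 1L) return("nSamples: must be >= 1")
  if (object@backgroundRate < 0) return("backgroundRate: must be >= 0")
  cs <- object@clusterSpecs
  if (nrow(cs)) {
    if (!all(c("centerBin", "widthBp", "expectedHits", "selected") %in%
             names(cs)))
      return("clusterSpecs: needs centerBin, widthBp, expectedHits, selected")
    if (any(cs$widthBp <= 0)) return("clusterSpecs: all widths must be > 0")
    if (any(cs$centerBin < 1 | cs$centerBin > object@nBins))
      return("clusterSpecs: centerBin out of chromosome bounds")
  }
  pp <- object@plantedClicPairs
  if (nrow(pp)) {
    if (!all(c("a", "b", "boost", "exclusivity") %in% names(pp)))
      return("plantedClicPairs: needs a, b, boost, exclusivity")
    if (any(pp$exclusivity < 0 | pp$exclusivity > 1))
      return("plantedClicPairs: exclusivity must lie in [0, 1]")
    if (any(pp$a < 1 | pp$a > nrow(cs) | pp$b < 1 | pp$b > nrow(cs)))
      return("plantedClicPairs: cluster index out of range")
    if (any(pp$a == pp$b))
      return("plantedClicPairs: a and b must differ")
  }
  if (object@noiseSd < 0) return("noiseSd: must be >= 0")
  TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: %d bins x %g bp, decay %.2g, contrast %.2g ",
    "(blocks of %d)\n  cohort of %d samples, background rate %.2g, ",
    "%d planted cluster(s), %d planted pair(s), seed %d\n"),
    object@nBins, object@binSize, object@decayExponent,
    object@compartmentContrast, object@compartmentBlockLen, object@nSamples,
    object@backgroundRate, nrow(object@clusterSpecs),
    nrow(object@plantedClicPairs), object@seed))
})

#' Default planted clusters for the synthetic chromosome
#'
#' Four selected clusters, 120 kb wide with 40 expected hits each, centred in
#' open-compartment blocks of the default 500-bin plaid layout.
#'
#' @return data.frame usable as \code{clusterSpecs}.
#' @export
defaultClusterSpecs <- function() {
  data.frame(centerBin = c(60L, 160L, 310L, 460L),
             widthBp = 120000, expectedHits = 40L, selected = TRUE)
}

#' Default planted CLIC pairs
#'
#' Two cluster pairs with contact boost 5 and exclusivity 0.8.
#'
#' @return data.frame usable as \code{plantedClicPairs}.
#' @export
defaultClicPairs <- function() {
  data.frame(a = c(1L, 2L), b = c(3L, 4L), boost = 5, exclusivity = 0.8)
}

#' Construct a SimulationConfig
#'
#' All arguments have defaults describing the reference synthetic study: a
#' 20 Mb chromosome at 40 kb bins with contact decay exponent 1, plaid
#' compartments of 1 Mb blocks at contrast 3, log-normal contact noise
#' (sdlog 0.3), a 100-sample cohort with one background insertion per sample
#' per chromosome, four planted 40-hit clusters and two planted CLIC pairs
#' with contact boost 5 and exclusivity 0.8.
#'
#' @param nBins,binSize,decayExponent,compartmentBlockLen,compartmentContrast
#'   see [SimulationConfig-class].
#' @param noiseDispersion,nSamples,backgroundRate,clusterSpecs
#'   see [SimulationConfig-class].
#' @param plantedClicPairs,effectSize,noiseSd,seed see
#'   [SimulationConfig-class].
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nBins = 100, clusterSpecs = data.frame(
#'   centerBin = 50, widthBp = 120000, expectedHits = 20, selected = TRUE),
#'   plantedClicPairs = data.frame()[0, ])
#' cfg
#' @export
simulationConfig <- function(nBins = 500L, binSize = 40000,
                             decayExponent = 1,
                             compartmentBlockLen = 25L,
                             compartmentContrast = 3,
                             noiseDispersion = 0.3,
                             nSamples = 100L, backgroundRate = 1,
                             clusterSpecs = defaultClusterSpecs(),
                             plantedClicPairs = defaultClicPairs(),
                             effectSize = 2, noiseSd = 1, seed = 1L) {
  if (nrow(as.data.frame(clusterSpecs)) == 0L)
    clusterSpecs <- data.frame(centerBin = integer(), widthBp = numeric(),
                               expectedHits = integer(), selected = logical())
  if (nrow(as.data.frame(plantedClicPairs)) == 0L)
    plantedClicPairs <- data.frame(a = integer(), b = integer(),
                                   boost = numeric(), exclusivity = numeric())
  new("SimulationConfig", nBins = as.integer(nBins),
      binSize = as.numeric(binSize), decayExponent = as.numeric(decayExponent),
      compartmentBlockLen = as.integer(compartmentBlockLen),
      compartmentContrast = as.numeric(compartmentContrast),
      noiseDispersion = as.numeric(noiseDispersion),
      nSamples = as.integer(nSamples),
      backgroundRate = as.numeric(backgroundRate),
      clusterSpecs = as.data.frame(clusterSpecs),
      plantedClicPairs = as.data.frame(plantedClicPairs),
      effectSize = as.numeric(effectSize), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

#' Compartment labels of the synthetic plaid layout
#'
#' Deterministic alternating blocks: bins 1..blockLen are compartment "A"
#' (open), the next blockLen bins "B", and so on.
#'
#' @param config a [SimulationConfig-class].
#' @return character vector of length nBins with values "A"/"B".
#' @export
compartmentLabels <- function(config) {
  blk <- ((seq_len(config@nBins) - 1L) %/% config@compartmentBlockLen) %% 2L
  c("A", "B")[blk + 1L]
}

#' Simulate a Hi-C contact map with distance decay and plaid compartments
#'
#' Expected contact between bins i and j is \eqn{(|i-j|+1)^{-\gamma}},
#' multiplied by \code{compartmentContrast} when both bins lie in the same
#' compartment block, times multiplicative log-normal noise with unit mean.
#' The matrix is exactly symmetric and non-negative, and the diagonal is
#' maximal in expectation.
#'
#' @param config a [SimulationConfig-class].
#' @return A [ContactMap-class].
#' @examples
#' m <- simulateContactMap(simulationConfig(nBins = 50, seed = 7))
#' m
#' @export
simulateContactMap <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  n <- config@nBins
  set.seed(config@seed)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  mu <- (d + 1)^(-config@decayExponent)
  comp <- compartmentLabels(config)
  same <- outer(comp, comp, "==")
  mu[same] <- mu[same] * config@compartmentContrast
  s <- config@noiseDispersion
  if (s > 0) {
    # unit-mean log-normal noise, symmetrized from the upper triangle
    z <- matrix(0, n, n)
    up <- upper.tri(z, diag = TRUE)
    z[up] <- exp(stats::rnorm(sum(up), sd = s) - s^2 / 2)
    z <- z + t(z) - diag(diag(z))
    mu <- mu * z
  }
  contactMap(mu, chrom = "chrS", binSize = config@binSize)
}

.interval_bins <- function(iv) seq.int(iv[1L], iv[2L])

#' Plant elevated contact between locus pairs
#'
#' Multiplies the contact submatrix between two disjoint bin intervals (and
#' its transpose) by a boost factor, leaving all other entries, and the
#' symmetry of the map, untouched. This creates the positive co-localization
#' signal that [detectClics()] is designed to recover.
#'
#' @param map a [ContactMap-class].
#' @param pairs list of lists, each with elements \code{a} and \code{b}
#'   (integer length-2 vectors: first and last bin, 1-based inclusive) and
#'   \code{boost} (numeric >= 1).
#' @return The boosted [ContactMap-class].
#' @examples
#' m <- simulateContactMap(simulationConfig(nBins = 50, seed = 1))
#' b <- plantClicContacts(m, list(list(a = c(5, 8), b = c(30, 33), boost = 5)))
#' @export
plantClicContacts <- function(map, pairs) {
  stopifnot(is(map, "ContactMap"))
  n <- nrow(map@scores)
  sc <- map@scores
  for (p in pairs) {
    a <- as.integer(p$a); b <- as.integer(p$b); boost <- p$boost
    if (length(a) != 2L || length(b) != 2L || a[1L] > a[2L] || b[1L] > b[2L])
      stop("each pair needs bin intervals a = c(start, end), b = c(start, end)")
    if (a[1L] < 1L || b[1L] < 1L || a[2L] > n || b[2L] > n)
      stop("locus interval outside contact map bounds")
    if (max(a[1L], b[1L]) <= min(a[2L], b[2L]))
      stop("locus pair intervals overlap; a CLIC pair must be disjoint")
    if (boost < 1) stop("boost must be >= 1")
    ia <- .interval_bins(a); ib <- .interval_bins(b)
    sc[ia, ib] <- sc[ia, ib] * boost
    sc[ib, ia] <- sc[ib, ia] * boost
  }
  contactMap(sc, chrom = map@chrom, binSize = map@binSize)
}

## joint hit-sample assignment honouring planted exclusivity
.assign_hit_samples <- function(config) {
  cs <- config@clusterSpecs
  pp <- config@plantedClicPairs
  n <- config@nSamples
  k <- as.integer(round(cs$expectedHits))
  if (any(k > n))
    stop("cluster expected hits exceed the number of samples")
  hits <- vector("list", nrow(cs))
  done <- rep(FALSE, nrow(cs))
  if (nrow(pp)) for (r in seq_len(nrow(pp))) {
    ia <- pp$a[r]; ib <- pp$b[r]
    if (done[ia] || done[ib]) next  # a cluster joins at most one pair
    e <- pp$exclusivity[r]
    kA <- k[ia]; kB <- k[ib]
    sa <- sample.int(n, kA)
    # overlap: hypergeometric (independence) thinned by the exclusivity degree
    ov <- stats::rhyper(1L, kA, n - kA, kB)
    ov <- stats::rbinom(1L, ov, 1 - e)
    shared <- if (ov > 0L) sample(sa, ov) else integer()
    rest <- setdiff(seq_len(n), sa)
    sb <- c(shared, sample(rest, kB - ov))
    hits[[ia]] <- sa; hits[[ib]] <- sb
    done[c(ia, ib)] <- TRUE
  }
  for (i in seq_len(nrow(cs))) if (!done[i]) {
    hits[[i]] <- sample.int(n, k[i]); done[i] <- TRUE
  }
  hits
}

#' Simulate an insertion cohort with uniform background and planted clusters
#'
#' Each sample receives a Poisson number of background insertions placed
#' uniformly along the chromosome. Each planted cluster draws its hit samples
#' without replacement and places one insertion per hit sample at a position
#' drawn from a Gaussian kernel of sd = width/4 around the cluster centre.
#' For each planted pair with exclusivity e, the overlap between the two hit
#' sample sets is the independence (hypergeometric) overlap thinned by a
#' factor (1 - e): e = 1 gives perfectly exclusive occupancy, e = 0 matches
#' independent assignment in expectation.
#'
#' @param config a [SimulationConfig-class].
#' @param chromName chromosome label for the synthetic chromosome.
#' @return An [InsertionDataset-class].
#' @examples
#' ins <- simulateInsertions(simulationConfig(nBins = 100, seed = 3,
#'   clusterSpecs = data.frame(centerBin = 50, widthBp = 120000,
#'     expectedHits = 20, selected = TRUE), plantedClicPairs = data.frame()))
#' ins
#' @export
simulateInsertions <- function(config, chromName = "chrS") {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed + 1L)
  n <- config@nSamples
  len <- config@nBins * config@binSize
  samples <- sprintf("S%03d", seq_len(n))
  pos <- numeric(0); who <- character(0)
  nbk <- stats::rpois(n, config@backgroundRate)
  if (sum(nbk) > 0) {
    pos <- stats::runif(sum(nbk), 0, len)
    who <- rep(samples, nbk)
  }
  cs <- config@clusterSpecs
  if (nrow(cs)) {
    hits <- .assign_hit_samples(config)
    for (i in seq_len(nrow(cs))) {
      ctr <- (cs$centerBin[i] - 0.5) * config@binSize
      p <- stats::rnorm(length(hits[[i]]), ctr, cs$widthBp[i] / 4)
      p <- pmin(pmax(p, 0), len - 1)
      pos <- c(pos, p)
      who <- c(who, samples[hits[[i]]])
    }
  }
  genome <- stats::setNames(len, chromName)
  insertionDataset(
    data.frame(chrom = chromName, pos = pos, sample = who,
               stringsAsFactors = FALSE),
    genome = genome, samples = samples)
}

#' Simulate an expression matrix with planted cis and trans effects
#'
#' One gene per supplied locus plus unaffected filler genes. Expression is
#' baseline + effectSize x indicator(sample carries an insertion in the
#' gene's locus or in a locus planted as its CLIC partner) + Gaussian noise.
#'
#' @param insertions an [InsertionDataset-class].
#' @param loci data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (bp, 0-based half-open), one gene per row.
#' @param config a [SimulationConfig-class] (effectSize, noiseSd, seed).
#' @param partners optional data.frame with columns \code{a}, \code{b}: row
#'   indices into \code{loci} forming CLIC partners (insertions in either
#'   locus shift both partner genes).
#' @param nFiller number of unaffected filler genes.
#' @param baseline baseline expression level.
#' @return numeric matrix, genes x samples; rownames \code{locus_<i>} for
#'   planted genes and \code{filler_<j>} for fillers, colnames the cohort
#'   roster. The locus table is attached as attribute \code{"loci"}.
#' @export
simulateExpression <- function(insertions, loci, config, partners = NULL,
                               nFiller = 200L, baseline = 8) {
  stopifnot(is(insertions, "InsertionDataset"),
            is(config, "SimulationConfig"))
  loci <- as.data.frame(loci)
  glen <- insertions@genome
  if (nrow(loci)) {
    if (any(!(loci$chrom %in% names(glen))) ||
        any(loci$start < 0 | loci$end > glen[loci$chrom]))
      stop("locus outside genome bounds")
  }
  set.seed(config@seed + 2L)
  samples <- insertions@samples
  rec <- insertions@records
  hit <- function(iv) {
    inside <- rec$chrom == iv$chrom & rec$pos >= iv$start & rec$pos < iv$end
    samples %in% rec$sample[inside]
  }
  ind <- vapply(seq_len(nrow(loci)),
                function(i) hit(loci[i, ]), logical(length(samples)))
  ind <- matrix(ind, ncol = max(nrow(loci), 0L))
  eff <- ind
  if (!is.null(partners) && nrow(partners)) {
    for (r in seq_len(nrow(partners))) {
      a <- partners$a[r]; b <- partners$b[r]
      joint <- ind[, a] | ind[, b]
      eff[, a] <- joint; eff[, b] <- joint
    }
  }
  ng <- nrow(loci) + nFiller
  expr <- matrix(baseline + stats::rnorm(ng * length(samples),
                                         sd = config@noiseSd),
                 nrow = ng, ncol = length(samples),
                 dimnames = list(
                   c(if (nrow(loci)) sprintf("locus_%d", seq_len(nrow(loci))),
                     if (nFiller) sprintf("filler_%d", seq_len(nFiller))),
                   samples))
  if (nrow(loci))
    expr[seq_len(nrow(loci)), ] <- expr[seq_len(nrow(loci)), ] +
      config@effectSize * t(eff)
  attr(expr, "loci") <- loci
  expr
}
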