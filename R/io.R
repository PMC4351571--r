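#' Read an insertion table
#'
#' Parses a BED-like tab-separated file with columns chrom, start, end,
#' sample (0-based half-open; the insertion position is the start). Lines
#' starting with '#' are skipped; malformed lines are rejected with their
#' line number.
#'
#' @param path file path.
#' @param genome named numeric vector of chromosome lengths; when NULL,
#'   lengths are inferred as the largest end coordinate per chromosome.
#' @param samples cohort roster; defaults to the samples seen in the file.
#' @return An [InsertionDataset-class].
#' @export
readInsertions <- function(path, genome = NULL, samples = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    warning("empty insertion file: ", path)
    if (is.null(genome)) genome <- c(chrUnknown = 1)
    return(insertionDataset(
      data.frame(chrom = character(), pos = numeric(), sample = character()),
      genome = genome, samples = if (is.null(samples)) character() else samples))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4L))
    stop(sprintf("line %d: expected 4 tab-separated fields, got %d",
                 lineNo[which(nf < 4L)[1L]], nf[which(nf < 4L)[1L]]))
  chromv <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  samp <- vapply(parts, `[[`, "", 4L)
  bad <- is.na(start) | is.na(end) | start < 0 | end <= start
  if (any(bad))
    stop(sprintf("line %d: invalid coordinates", lineNo[which(bad)[1L]]))
  if (is.null(genome))
    genome <- tapply(end, chromv, max)[unique(chromv)]
  unknown <- !(chromv %in% names(genome))
  if (any(unknown))
    stop(sprintf("line %d: unknown chromosome '%s'",
                 lineNo[which(unknown)[1L]], chromv[which(unknown)[1L]]))
  rec <- data.frame(chrom = chromv, pos = start, sample = samp,
                    stringsAsFactors = FALSE)
  insertionDataset(rec, genome = genome,
                   samples = if (is.null(samples)) sort(unique(samp))
                             else samples)
}

#' Write an insertion table
#'
#' Four-column BED-like TSV (chrom, start, end = start + 1, sample),
#' 0-based half-open.
#'
#' @param data an [InsertionDataset-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeInsertions <- function(data, path) {
  stopifnot(is(data, "InsertionDataset"))
  rec <- data@records
  utils::write.table(
    data.frame(rec$chrom, format(rec$pos, scientific = FALSE, trim = TRUE),
               format(rec$pos + 1, scientific = FALSE, trim = TRUE),
               rec$sample),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a contact map from text
#'
#' Dense dialect: a whitespace-separated square matrix; asymmetry beyond a
#' relative 1e-8 is an error. COO dialect: three columns (bin_i, bin_j,
#' score) with 0-based bin indices; missing mirror entries are filled by
#' symmetry, conflicting mirror entries are an error.
#'
#' @param path file path.
#' @param dialect "dense" or "coo".
#' @param chrom chromosome label to attach.
#' @param binSize bin width in bp.
#' @param nBins for COO input: total bin count (default: largest index + 1).
#' @return A [ContactMap-class].
#' @export
readContactMap <- function(path, dialect = c("dense", "coo"),
                           chrom = "chrS", binSize = 40000, nBins = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "dense") {
    m <- as.matrix(utils::read.table(path))
    if (nrow(m) != ncol(m)) stop("dense contact map must be square")
    if (!.check_symmetric(m)) stop("dense contact map is asymmetric")
    m <- (m + t(m)) / 2   # remove rounding asymmetry
    return(contactMap(m, chrom = chrom, binSize = binSize))
  }
  coo <- utils::read.table(path)
  if (ncol(coo) < 3L) stop("COO contact map needs 3 columns: i, j, score")
  i <- as.integer(coo[[1L]]) + 1L
  j <- as.integer(coo[[2L]]) + 1L
  v <- as.numeric(coo[[3L]])
  n <- if (is.null(nBins)) max(i, j) else as.integer(nBins)
  m <- matrix(0, n, n)
  m[cbind(i, j)] <- v
  mt <- t(m)
  conflict <- m != 0 & mt != 0 & abs(m - mt) > 1e-8 * (1 + abs(m))
  if (any(conflict)) stop("COO contact map has conflicting mirror entries")
  m <- pmax(m, mt)
  contactMap(m, chrom = chrom, binSize = binSize)
}

#' Write a contact map to text
#'
#' @param map a [ContactMap-class] or [NormalizedContactMap-class] (the
#'   normalized diagonal sentinel is written as NA).
#' @param path output file path.
#' @param dialect "dense" (whitespace matrix) or "coo" (0-based upper
#'   triangle including the diagonal, non-zero entries only).
#' @return \code{path}, invisibly.
#' @export
writeContactMap <- function(map, path, dialect = c("dense", "coo")) {
  dialect <- match.arg(dialect)
  m <- if (is(map, "NormalizedContactMap")) map@ranks else map@scores
  if (dialect == "dense") {
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    idx <- which(upper.tri(m, diag = TRUE) & m != 0 & !is.na(m),
                 arr.ind = TRUE)
    utils::write.table(
      data.frame(idx[, 1L] - 1L, idx[, 2L] - 1L, m[idx]),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a per-bin or per-grid-point track as bedGraph
#'
#' @param x a [CompartmentTrack-class] (one interval per bin) or a
#'   [DensityTrack-class] (one interval per grid step).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeBedGraph <- function(x, path) {
  if (is(x, "CompartmentTrack")) {
    n <- length(x@pc1)
    df <- data.frame(x@chrom, (seq_len(n) - 1) * x@binSize,
                     seq_len(n) * x@binSize, x@pc1)
  } else if (is(x, "DensityTrack")) {
    g <- x@grid
    step <- if (length(g) > 1L) g[2L] - g[1L] else 1
    df <- data.frame(x@chrom, g, g + step, x@values)
  } else stop("unsupported track type")
  df[, 2L] <- format(df[, 2L], scientific = FALSE, trim = TRUE)
  df[, 3L] <- format(df[, 3L], scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write insertion clusters as BED6
#'
#' Score column carries the peak height; the thick/strand fields follow the
#' BED convention (strand '.').
#'
#' @param clusters data.frame from [detectClusters()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeClustersBed <- function(clusters, path) {
  df <- data.frame(clusters$chrom,
                   format(clusters$startBp, scientific = FALSE, trim = TRUE),
                   format(clusters$endBp, scientific = FALSE, trim = TRUE),
                   sprintf("IC_%d", seq_len(nrow(clusters))),
                   clusters$peakHeight, ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write CLIC results
#'
#' "tsv": one row per tested pair with both intervals, the positive-set
#' size, the distance range, raw and Holm-adjusted p-values and the
#' significance flag. "bedpe": the standard 10-column BEDPE dialect with
#' -log10(pHolm) in the score column, for genome-browser loading.
#'
#' @param clics data.frame from [detectClics()].
#' @param path output file path.
#' @param format "tsv" or "bedpe".
#' @return \code{path}, invisibly.
#' @export
writeClics <- function(clics, path, format = c("tsv", "bedpe")) {
  format <- match.arg(format)
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  if (format == "tsv") {
    df <- data.frame(chrom = clics$chrom,
                     startA = fmt(clics$startBpA), endA = fmt(clics$endBpA),
                     startB = fmt(clics$startBpB), endB = fmt(clics$endBpB),
                     nPos = clics$nPos, dMin = clics$dMin, dMax = clics$dMax,
                     pRaw = clics$pRaw, pHolm = clics$pHolm,
                     significant = clics$significant)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    df <- data.frame(clics$chrom, fmt(clics$startBpA), fmt(clics$endBpA),
                     clics$chrom, fmt(clics$startBpB), fmt(clics$endBpB),
                     sprintf("CLIC_%d", seq_len(nrow(clics))),
                     round(-log10(pmax(clics$pHolm, 1e-300)), 3), ".", ".")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a flat key = value run configuration file
#'
#' One \code{key = value} pair per line, '#' comments allowed. Values are
#' parsed as numbers where possible, otherwise kept as strings.
#'
#' @param path file path.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1L]])
  keys <- trimws(vapply(kv, `[[`, "", 2L))
  vals <- trimws(vapply(kv, `[[`, "", 3L))
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(out, keys)
}
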