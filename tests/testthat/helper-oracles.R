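# Independent brute-force oracles, deliberately naive.

# One-tailed (greater) exact Wilcoxon rank-sum p by full enumeration over all
# C(n+m, n) assignments of the pooled ranks to group x. Tie-free values only.
enumWilcoxGreater <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  wObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(nx + ny, nx)
  ws <- apply(sets, 2L, function(s) sum(r[s])) - nx * (nx + 1) / 2
  mean(ws >= wObs)
}

# Textbook Holm step-down adjusted p-values.
bruteHolm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, run)
  }
  adj
}

# Two-sided Fisher exact p for a 2x2 table by summing hypergeometric point
# probabilities no larger than the observed one.
bruteFisher <- function(tab) {
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0L, c1 - m2); hi <- min(m1, c1)
  probs <- stats::dhyper(lo:hi, m1, m2, c1)
  pObs <- stats::dhyper(a, m1, m2, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Deterministic plaid contact map: power-law decay times contrast for
# same-block bins, no noise.
plaidMap <- function(n = 20, blockLen = 10, contrast = 3, decay = 1,
                     binSize = 40000) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  mu <- (d + 1)^(-decay)
  blk <- ((seq_len(n) - 1) %/% blockLen) %% 2
  same <- outer(blk, blk, "==")
  mu[same] <- mu[same] * contrast
  contactMap(mu, chrom = "chrT", binSize = binSize)
}

# Tiny insertion dataset on one chromosome from a vector of positions.
makeInsertions <- function(pos, sample = sprintf("S%02d", seq_along(pos)),
                           chromLen = 4e6, chromName = "chrT") {
  insertionDataset(
    data.frame(chrom = chromName, pos = pos, sample = sample),
    genome = stats::setNames(chromLen, chromName),
    samples = sort(unique(sample)))
}

# Config helpers: map-only (no cohort structure) and a small planted study.
mapOnlyConfig <- function(...) {
  simulationConfig(..., clusterSpecs = data.frame(),
                   plantedClicPairs = data.frame())
}
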