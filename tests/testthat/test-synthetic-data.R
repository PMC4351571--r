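test_that("contact maps are symmetric, non-negative and seed-deterministic", {
  for (s in 1:5) {
    cfg <- mapOnlyConfig(nBins = 40, seed = s, noiseDispersion = 0.5)
    m <- contactScores(simulateContactMap(cfg))
    expect_identical(m, t(m))
    expect_true(all(m >= 0))
  }
  cfg <- mapOnlyConfig(nBins = 60, seed = 99)
  expect_identical(contactScores(simulateContactMap(cfg)),
                   contactScores(simulateContactMap(cfg)))
  ins1 <- simulateInsertions(simulationConfig(seed = 12))
  ins2 <- simulateInsertions(simulationConfig(seed = 12))
  expect_identical(insertionRecords(ins1), insertionRecords(ins2))
})

test_that("noise-free map without plaid follows the pure power law", {
  cfg <- mapOnlyConfig(nBins = 50, seed = 1, compartmentContrast = 1,
                       noiseDispersion = 0, decayExponent = 1.2)
  m <- contactScores(simulateContactMap(cfg))
  for (k in c(1, 5, 20)) {
    ii <- seq_len(50 - k)
    expect_equal(mean(m[cbind(ii, ii + k)]), (k + 1)^(-1.2), tolerance = 1e-9)
  }
  # diagonal maximal
  expect_true(all(m[upper.tri(m)] <= min(diag(m))))
})

test_that("same-compartment contacts exceed cross-compartment by the contrast factor", {
  # tolerance frozen from a 20-replicate calibration of this configuration
  # (mean distance-matched ratio 3.01, sd 0.046)
  ratios <- vapply(1:20, function(s) {
    cfg <- mapOnlyConfig(nBins = 100, seed = s, compartmentBlockLen = 10,
                         compartmentContrast = 3, noiseDispersion = 0.3)
    m <- contactScores(simulateContactMap(cfg))
    comp <- compartmentLabels(cfg)
    same <- outer(comp, comp, "==")
    d <- abs(outer(1:100, 1:100, "-"))
    rk <- vapply(1:40, function(k) {
      sel <- d == k
      mean(m[sel & same]) / mean(m[sel & !same])
    }, numeric(1))
    mean(rk[is.finite(rk)])
  }, numeric(1))
  expect_equal(mean(ratios), 3, tolerance = 0.05)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(simulationConfig(nBins = 5), "nBins")
  expect_error(simulationConfig(compartmentContrast = 0.5),
               "compartmentContrast")
  expect_error(simulationConfig(
    clusterSpecs = data.frame(centerBin = 10, widthBp = 0,
                              expectedHits = 5, selected = TRUE)),
    "widths")
  expect_error(simulationConfig(
    plantedClicPairs = data.frame(a = 1, b = 3, boost = 5,
                                  exclusivity = 1.5)),
    "exclusivity")
})

test_that("planting contacts is a local multiplicative boost preserving symmetry", {
  cfg <- mapOnlyConfig(nBins = 50, seed = 4)
  m0 <- simulateContactMap(cfg)
  # boost 1 is the identity
  p1 <- plantClicContacts(m0, list(list(a = c(5, 8), b = c(30, 33),
                                        boost = 1)))
  expect_identical(contactScores(p1), contactScores(m0))
  # boost 5 scales the A x B submatrix sum, leaves the rest unchanged
  p5 <- plantClicContacts(m0, list(list(a = c(5, 8), b = c(30, 33),
                                        boost = 5)))
  s0 <- contactScores(m0); s5 <- contactScores(p5)
  expect_equal(sum(s5[5:8, 30:33]), 5 * sum(s0[5:8, 30:33]))
  expect_identical(s5, t(s5))
  untouched <- s5
  untouched[5:8, 30:33] <- s0[5:8, 30:33]
  untouched[30:33, 5:8] <- s0[30:33, 5:8]
  expect_identical(untouched, s0)
  expect_error(
    plantClicContacts(m0, list(list(a = c(5, 10), b = c(8, 12), boost = 2))),
    "overlap")
})

test_that("planted pairs stay elevated after rank normalization", {
  hits <- 0L
  for (s in 1:20) {
    cfg <- mapOnlyConfig(nBins = 100, seed = s, compartmentContrast = 1)
    m <- plantClicContacts(simulateContactMap(cfg),
                           list(list(a = c(20, 24), b = c(60, 64),
                                     boost = 5)))
    r <- normalizedScores(rankNormalize(m))
    pos <- mean(r[20:24, 60:64])
    d <- abs(outer(1:100, 1:100, "-"))
    dr <- range(abs(outer(20:24, 60:64, "-")))
    sel <- d >= dr[1] & d <= dr[2] & upper.tri(d)
    if (pos > mean(r[sel], na.rm = TRUE)) hits <- hits + 1L
  }
  expect_identical(hits, 20L)
})

test_that("a background-free cluster places exactly its expected hits in distinct samples", {
  cfg <- simulationConfig(
    nBins = 100, seed = 3, backgroundRate = 0,
    clusterSpecs = data.frame(centerBin = 50, widthBp = 120000,
                              expectedHits = 50, selected = TRUE),
    plantedClicPairs = data.frame())
  ins <- simulateInsertions(cfg)
  rec <- insertionRecords(ins)
  expect_identical(nrow(rec), 50L)
  expect_identical(length(unique(rec$sample)), 50L)
  expect_error(simulateInsertions(simulationConfig(
    nBins = 100, nSamples = 10,
    clusterSpecs = data.frame(centerBin = 50, widthBp = 120000,
                              expectedHits = 20, selected = TRUE),
    plantedClicPairs = data.frame())),
    "exceed")
})

test_that("planted exclusivity controls co-occupancy of cluster pairs", {
  pairCfg <- function(seed, e) simulationConfig(
    nBins = 200, seed = seed, backgroundRate = 0, nSamples = 100,
    clusterSpecs = data.frame(centerBin = c(50, 150), widthBp = 120000,
                              expectedHits = 40, selected = TRUE),
    plantedClicPairs = data.frame(a = 1, b = 2, boost = 5,
                                  exclusivity = e))
  cooc <- function(ins) {
    rec <- insertionRecords(ins)
    inA <- unique(rec$sample[rec$pos < 4e6])
    inB <- unique(rec$sample[rec$pos >= 4e6])
    length(intersect(inA, inB))
  }
  # e = 1: perfectly exclusive
  for (s in 1:10) expect_identical(cooc(simulateInsertions(pairCfg(s, 1))), 0L)
  # e = 0: matches the independent-assignment expectation 40*40/100 = 16
  co <- vapply(1:100, function(s) cooc(simulateInsertions(pairCfg(s, 0))),
               numeric(1))
  # binomial-scale error of the mean over 100 replicates (sd < 3.5)
  expect_lt(abs(mean(co) - 16), 3 * 3.5 / sqrt(100))
})

test_that("background-only cohorts bin uniformly", {
  ok <- 0L
  for (s in 1:50) {
    cfg <- simulationConfig(nBins = 100, seed = s, backgroundRate = 10,
                            compartmentContrast = 1,
                            clusterSpecs = data.frame(),
                            plantedClicPairs = data.frame())
    prof <- binInsertions(simulateInsertions(cfg), 200000)[[1]]
    p <- suppressWarnings(stats::chisq.test(binCounts(prof))$p.value)
    if (p > 0.01) ok <- ok + 1L
  }
  expect_gte(ok, 48L)  # >= 95% of replicates
})

test_that("expression generator plants cis and trans effects as specified", {
  cfg <- simulationConfig(
    nBins = 200, seed = 8, backgroundRate = 0, nSamples = 60,
    clusterSpecs = data.frame(centerBin = c(50, 150), widthBp = 120000,
                              expectedHits = 20, selected = TRUE),
    plantedClicPairs = data.frame(a = 1, b = 2, boost = 5,
                                  exclusivity = 0.8),
    effectSize = 3, noiseSd = 1)
  st <- simulateStudy(cfg, withExpression = TRUE)
  expr <- st$expression
  expect_identical(dim(expr), c(202L, 60L))
  # null generator: zero effect leaves scores centred at zero
  ts <- vapply(1:30, function(s) {
    cfgS <- simulationConfig(
      nBins = 200, seed = s, backgroundRate = 0, nSamples = 60,
      clusterSpecs = data.frame(centerBin = 50, widthBp = 120000,
                                expectedHits = 20, selected = TRUE),
      plantedClicPairs = data.frame(), effectSize = 0, noiseSd = 1)
    stS <- simulateStudy(cfgS, withExpression = TRUE)
    occ <- sampleLocusMatrix(stS$insertions, data.frame(
      chrom = "chrS",
      startBp = (stS$intervals[[1]][1] - 1) * 40000,
      endBp = stS$intervals[[1]][2] * 40000))
    colnames(occ) <- "A"
    occ <- cbind(occ, B = 0L)
    expressionTScores(stS$expression, "locus_1", occ, "A", "B")[["tA"]]
  }, numeric(1))
  expect_lt(abs(mean(ts)), 2 / sqrt(30))
})
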