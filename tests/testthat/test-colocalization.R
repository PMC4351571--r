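test_that("category-pair enumeration yields 6 categories and 15 distinct comparisons", {
  e <- enumerateCategoryPairs()
  expect_identical(nrow(e$categories), 6L)
  expect_identical(nrow(e$comparisons), 15L)
  expect_true(all(e$comparisons[, 1] != e$comparisons[, 2]))
  keys <- apply(e$categories, 1, paste, collapse = "-")
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("category-pair scores equal a brute-force double loop", {
  set.seed(23)
  n <- 30
  cfg <- mapOnlyConfig(nBins = n, seed = 23)
  nm <- rankNormalize(simulateContactMap(cfg))
  cats <- sample(c("NI", "I", "RI", "UNASSIGNED"), n, TRUE,
                 prob = c(0.4, 0.3, 0.2, 0.1))
  prof <- new("BinnedInsertionProfile", chrom = "chrS", binSize = 40000,
              counts = rep(1L, n), categories = cats)
  r <- normalizedScores(nm)
  for (pair in list(c("NI", "NI"), c("NI", "RI"), c("I", "RI"))) {
    got <- sort(categoryPairScores(nm, prof, pair))
    brute <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (setequal(c(cats[i], cats[j]), unique(pair)))
        brute <- c(brute, r[i, j])
    }
    expect_equal(got, sort(brute))
  }
  # an all-NI profile yields every off-diagonal score
  allNI <- new("BinnedInsertionProfile", chrom = "chrS", binSize = 40000,
               counts = rep(0L, n), categories = rep("NI", n))
  expect_identical(length(categoryPairScores(nm, allNI, c("NI", "NI"))),
                   as.integer(n * (n - 1) / 2))
  # exactly C(3,2) scores for three RI bins
  cats3 <- rep("NI", n); cats3[c(3, 10, 20)] <- "RI"
  prof3 <- new("BinnedInsertionProfile", chrom = "chrS", binSize = 40000,
               counts = rep(0L, n), categories = cats3)
  expect_identical(length(categoryPairScores(nm, prof3, c("RI", "RI"))), 3L)
  expect_error(categoryPairScores(nm, prof3, c("I", "I")), "no bin pairs")
})

test_that("category-pair comparison is a two-sided rank-sum with median effect", {
  x <- c(0.2, 0.5, 0.8, 0.4)
  same <- compareCategoryPairs(x, x)
  expect_equal(same$p.value, 1)
  expect_equal(same$effectSize, 0)
  set.seed(3)
  a <- stats::runif(200) + 0.3
  b <- stats::runif(200)
  shift <- compareCategoryPairs(a, b)
  expect_lt(shift$p.value, 0.01)
  expect_gt(shift$effectSize, 0.2)
  expect_error(compareCategoryPairs(numeric(0), b), "non-empty")
})

test_that("exact rank-sum p-values match full enumeration for tiny samples", {
  set.seed(77)
  for (rep in 1:10) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- stats::rnorm(nx); y <- stats::rnorm(ny)
    got <- clichunter:::.rank_sum(x, y, "greater")
    expect_true(got$exact)
    expect_equal(got$p.value, enumWilcoxGreater(x, y), tolerance = 1e-12)
  }
})

test_that("nearest spatial neighbours follow maximal contact with smaller-index ties", {
  r <- matrix(0.1, 6, 6); diag(r) <- NA
  r[1, 4] <- r[4, 1] <- 0.9
  r[1, 5] <- r[5, 1] <- 0.9            # tie with bin 4
  r[2, 6] <- r[6, 2] <- 0.7
  r[upper.tri(r)] <- t(r)[upper.tri(r)]
  nm <- new("NormalizedContactMap", chrom = "chrT", binSize = 40000,
            ranks = r, poolLength = 10L)
  prof <- new("BinnedInsertionProfile", chrom = "chrT", binSize = 40000,
              counts = c(2L, 1L, 0L, 5L, 3L, 0L), categories = character(0))
  nn <- nearestSpatialNeighborScores(nm, prof)
  expect_identical(nn$neighborBin[nn$bin == 1], 4L)   # smaller index wins
  expect_true(nn$tie[nn$bin == 1])
  expect_identical(nn$neighborCount[nn$bin == 1], 5L)
  expect_identical(nn$neighborBin[nn$bin == 2], 6L)
  # adjacent bins are excluded from the search
  r2 <- matrix(0.1, 6, 6); diag(r2) <- NA
  r2[3, 4] <- r2[4, 3] <- 0.99
  r2[3, 6] <- r2[6, 3] <- 0.5
  nm2 <- new("NormalizedContactMap", chrom = "chrT", binSize = 40000,
             ranks = r2, poolLength = 10L)
  prof2 <- new("BinnedInsertionProfile", chrom = "chrT", binSize = 40000,
               counts = c(0L, 0L, 1L, 0L, 0L, 4L), categories = character(0))
  nn2 <- nearestSpatialNeighborScores(nm2, prof2)
  expect_identical(nn2$neighborBin[nn2$bin == 3], 6L)
})

test_that("planted pair bins pick their partner locus as nearest neighbour", {
  m <- plantClicContacts(plaidMap(n = 50, blockLen = 50, contrast = 1),
                         list(list(a = c(10, 12), b = c(40, 42), boost = 5)))
  nm <- rankNormalize(m)
  counts <- rep(0L, 50); counts[c(10:12, 40:42)] <- 5L
  prof <- new("BinnedInsertionProfile", chrom = "chrT", binSize = 40000,
              counts = counts, categories = character(0))
  nn <- nearestSpatialNeighborScores(nm, prof)
  for (b in 10:12)
    expect_true(nn$neighborBin[nn$bin == b] %in% 40:42)
  for (b in 40:42)
    expect_true(nn$neighborBin[nn$bin == b] %in% 10:12)
})

test_that("clicTest builds the positive and negative sets per contract", {
  cfg <- mapOnlyConfig(nBins = 80, seed = 41, compartmentContrast = 1)
  nm <- rankNormalize(simulateContactMap(cfg))
  ic <- function(s, e) data.frame(chrom = "chrS", startBin = s, endBin = e,
                                  startBp = (s - 1) * 40000, endBp = e * 40000)
  res <- clicTest(nm, ic(10, 12), ic(30, 32), L = 100)
  expect_identical(res$nPos, 9L)             # minimum-size clusters: 3 x 3
  expect_identical(res$dMin, 18L)
  expect_identical(res$dMax, 22L)
  # negative set: all entries at distances 18..22 minus the 9 positives
  expect_identical(res$nNeg, as.integer(sum(80 - 18:22) - 9))
  # symmetric in cluster order
  res2 <- clicTest(nm, ic(30, 32), ic(10, 12), L = 100)
  expect_equal(res2$pRaw, res$pRaw)
  expect_identical(res2$nPos, res$nPos)
  expect_error(clicTest(nm, ic(10, 14), ic(13, 16), L = 50), "overlap")
  expect_error(clicTest(nm, ic(10, 12), ic(30, 32), L = 1e6), "too short")
})

test_that("clicTest p-values are uniform under the null", {
  ps <- vapply(1:200, function(s) {
    cfg <- mapOnlyConfig(nBins = 60, seed = s, compartmentContrast = 1)
    nm <- rankNormalize(simulateContactMap(cfg))
    a0 <- sample(5:20, 1); b0 <- sample(35:50, 1)
    ic <- function(s0) data.frame(chrom = "chrS", startBin = s0,
                                  endBin = s0 + 2,
                                  startBp = (s0 - 1) * 40000,
                                  endBp = (s0 + 2) * 40000)
    clicTest(nm, ic(a0), ic(b0), L = 120)$pRaw
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("a planted boost yields a strongly significant pair", {
  cfg <- mapOnlyConfig(nBins = 200, seed = 19, compartmentContrast = 1)
  m <- plantClicContacts(simulateContactMap(cfg),
                         list(list(a = c(50, 55), b = c(120, 125),
                                   boost = 5)))
  nm <- rankNormalize(m)
  ic <- function(s, e) data.frame(chrom = "chrS", startBin = s, endBin = e,
                                  startBp = (s - 1) * 40000, endBp = e * 40000)
  res <- clicTest(nm, ic(50, 55), ic(120, 125))
  expect_lt(res$pRaw, 1e-10)
})

test_that("Holm adjustment in detectClics matches a brute-force step-down", {
  set.seed(55)
  for (rep in 1:100) {
    p <- stats::runif(sample(3:20, 1))^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, "holm"), bruteHolm(p), tolerance = 1e-12)
  }
  # k clusters on one chromosome give k(k-1)/2 tests
  cfg <- mapOnlyConfig(nBins = 120, seed = 28, compartmentContrast = 1)
  nm <- rankNormalize(simulateContactMap(cfg))
  starts <- c(10, 30, 55, 80, 100)
  hc <- do.call(rbind, lapply(starts, function(s)
    data.frame(chrom = "chrS", peakHeight = 10, startBin = s, endBin = s + 2,
               nBins = 3, startBp = (s - 1) * 40000, endBp = (s + 2) * 40000)))
  cc <- detectClics(nm, hc, alpha = 0.05)
  expect_identical(nrow(cc), 10L)
  expect_equal(cc$pHolm, bruteHolm(cc$pRaw), tolerance = 1e-12)
})

test_that("CLIC detection is invariant under monotone transforms of raw scores", {
  cfg <- mapOnlyConfig(nBins = 100, seed = 61, compartmentContrast = 1)
  raw <- simulateContactMap(cfg)
  ic <- function(s, e) data.frame(chrom = "chrS", startBin = s, endBin = e,
                                  startBp = (s - 1) * 40000, endBp = e * 40000)
  p0 <- clicTest(rankNormalize(raw), ic(20, 24), ic(60, 64))$pRaw
  expMap <- contactMap(exp(contactScores(raw)), binSize = 40000)
  expect_equal(clicTest(rankNormalize(expMap), ic(20, 24), ic(60, 64))$pRaw,
               p0)
})
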