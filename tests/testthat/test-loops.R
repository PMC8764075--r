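# A deterministic decay background with optional multiplied pixels.
decayMatrix <- function(n, scale = 20, alpha = 1, pixels = list()) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  m <- scale * ifelse(d == 0, 1, d^(-alpha))
  for (p in pixels) {
    m[p[1], p[2]] <- m[p[1], p[2]] * p[3]
    m[p[2], p[1]] <- m[p[1], p[2]]
  }
  round(m)
}

test_that("loop detection recovers a planted pixel and merges neighbors", {
  n <- 300
  m <- decayMatrix(n, scale = 60, pixels = list(c(100, 150, 5)))
  cm <- ContactMatrix(m, binSize = 1e4)
  det <- detectLoops(cm)
  expect_equal(nrow(det), 1)
  expect_equal(c(det$bin1, det$bin2), c(99, 149))
  expect_lt(det$fdr, 0.05)
  # adjacent enriched pixels merge into one loop
  m2 <- decayMatrix(n, scale = 60,
                    pixels = list(c(100, 150, 5), c(100, 151, 5)))
  det2 <- detectLoops(ContactMatrix(m2, binSize = 1e4))
  expect_equal(nrow(det2), 1)
  expect_equal(det2$nPixels, 2)
  expect_error(detectLoops(cm, minDist = 1e6, maxDist = 1e5), "exceed")
})

test_that("loop detection is calibrated on pure-decay matrices", {
  gm <- simulateGenome(1, 8e6, 1e4, 10, seed = 1)
  falsePix <- 0
  for (s in 1:5) {
    cm <- simulateContactMatrix(gm, NULL, binSize = 1e4, depthPairs = 2e6,
                                seed = 700 + s)
    falsePix <- falsePix + nrow(detectLoops(cm))
  }
  expect_lte(falsePix / 5, 1)
})

test_that("CPM is count x 1e6 over library total", {
  m <- matrix(0, 10, 10)
  m[2, 8] <- m[8, 2] <- 5
  m[1, 2] <- m[2, 1] <- 1e6 - 5
  cm <- ContactMatrix(m, binSize = 1e4)
  loopDf <- data.frame(bin1 = 1, bin2 = 7)
  expect_equal(loopStrengthCpm(cm, loopDf), 5)
  cm2 <- ContactMatrix(m * 2, binSize = 1e4)
  expect_equal(loopStrengthCpm(cm2, loopDf), 5)  # counts and total both x2
  # doubling only the total halves CPM
  m3 <- m; m3[1, 2] <- m3[2, 1] <- 2e6 - 5
  expect_equal(loopStrengthCpm(ContactMatrix(m3, binSize = 1e4), loopDf),
               2.5, tolerance = 1e-5)
  expect_error(loopStrengthCpm(ContactMatrix(matrix(0, 5, 5), binSize = 1e4),
                               loopDf), "zero")
})

test_that("CPM equalizes across stages after scaling to the smallest", {
  base <- decayMatrix(100, scale = 10)
  cmA <- ContactMatrix(base, binSize = 1e4)
  cmB <- ContactMatrix(base * 3, binSize = 1e4)  # same shape, 3x depth
  sc <- normalizeToSmallest(list(cmA, cmB))
  loopDf <- data.frame(bin1 = 10, bin2 = 40)
  expect_equal(loopStrengthCpm(sc[[1]], loopDf),
               loopStrengthCpm(sc[[2]], loopDf))
})

test_that("APA is exact on flat obs/exp and detects planted enrichment", {
  cm <- ContactMatrix(matrix(1, 60, 60), binSize = 1e4)
  cm@oe <- matrix(1, 60, 60)
  pairs <- data.frame(bin1 = c(10, 20), bin2 = c(40, 50))
  apa <- aggregateContacts(cm, pairs, flankBins = 3)
  expect_true(all(apa$apa == 1))
  expect_equal(apa$centerEnrichment, 1)
  # one pair vs the same pair repeated: identical APA
  apa1 <- aggregateContacts(cm, pairs[1, ], flankBins = 3)
  apa2 <- aggregateContacts(cm, pairs[c(1, 1, 1), ], flankBins = 3)
  expect_equal(apa1$apa, apa2$apa)
  # pairs without a full window are skipped and counted
  apaEdge <- aggregateContacts(cm, data.frame(bin1 = c(0, 10),
                                              bin2 = c(2, 40)),
                               flankBins = 3)
  expect_equal(apaEdge$nSkipped, 1)
  expect_error(aggregateContacts(cm, pairs[0, ]), "empty")
})

test_that("planted loops beat distance-matched random pairs in APA", {
  gm <- simulateGenome(1, 10e6, 1e4, 50, seed = 1)
  tr <- simulateArchitecture(gm, tadCount = 5, loopCount = 40,
                             nEnhancers = 80,
                             trajectoryMix = c(stable = 1), seed = 3)
  cm <- simulateContactMatrix(gm, tr, stage = 1, binSize = 1e4,
                              depthPairs = 5e6, seed = 8)
  cm <- observedOverExpected(krBalance(cm))
  lt <- loops(tr)
  planted <- data.frame(bin1 = lt$anchor1 / 1e4, bin2 = lt$anchor2 / 1e4)
  ce <- aggregateContacts(cm, planted)$centerEnrichment
  expect_gt(ce, 1.5)
  rnd <- randomMatchedPairs(cm, planted, seed = 4)
  ceR <- aggregateContacts(cm, rnd)$centerEnrichment
  expect_lt(abs(ceR - 1), 0.2)
  expect_gt(ce, ceR)
})

test_that("region-pair quantification averages obs/exp between regions", {
  cm <- ContactMatrix(matrix(1, 20, 20), binSize = 5e3)
  oe <- matrix(1, 20, 20)
  # 2x2-bin regions with values {1,2,3,4} between them -> mean 2.5
  oe[3:4, 11:12] <- c(1, 3, 2, 4)
  cm@oe <- oe
  v <- quantifyRegionPair(cm, c(2 * 5e3, 4 * 5e3), c(10 * 5e3, 12 * 5e3))
  expect_equal(as.numeric(v), 2.5)
  expect_false(attr(v, "overlapFlag"))
  # flat obs/exp -> 1 for any pair of regions
  cm@oe <- matrix(1, 20, 20)
  expect_equal(as.numeric(quantifyRegionPair(cm, c(0, 2e4), c(5e4, 7e4))), 1)
  # overlapping regions are computed but flagged
  expect_warning(vo <- quantifyRegionPair(cm, c(0, 2e4), c(1e4, 3e4)),
                 "overlap")
  expect_true(attr(vo, "overlapFlag"))
})

test_that("a sliding region scan tiles the requested span", {
  cm <- ContactMatrix(matrix(1, 200, 200), binSize = 5e3)
  cm@oe <- matrix(1, 200, 200)
  # scan mirroring a promoter-relative window series: the span from
  # -212 kb to +574 kb covers 786 kb
  p1 <- 300e3
  scan <- quantifyRegionSeries(cm, c(p1 - 2.5e3, p1 + 2.5e3),
                               from = p1 - 212e3, to = p1 + 574e3,
                               windowBp = 5e3)
  expect_equal(max(scan$end) - min(scan$start), 786e3 - 1e3)
  expect_true(all(abs(scan$meanOE - 1) < 1e-12))
})
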