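test_that("insulation matches the brute-force mean-z oracle", {
  # constant matrix: all z-scores 0
  cm <- ContactMatrix(matrix(6, 12, 12), binSize = 4e4)
  prof <- insulationProfile(cm, windowBins = 3)
  expect_true(all(prof$score[4:9] == 0))
  expect_true(all(is.na(prof$score[c(1:3, 10:12)])))
  expect_equal(prof$strength, -prof$score)
  # two-block matrix: minimum at the junction, oracle agreement to 1e-10
  m <- twoBlockMatrix(5, 5, hi = 10, lo = 1)
  cm2 <- ContactMatrix(m, binSize = 4e4)
  p2 <- insulationProfile(cm2, windowBins = 3)
  oracle <- insulationOracle(m, 3)
  expect_equal(p2$score, oracle, tolerance = 1e-10)
  # the junction's crossing window is tied between the last upstream and
  # first downstream bin; position is resolved to within one bin
  valid <- which(!is.na(p2$score))
  expect_true(p2$bin[valid][which.min(p2$score[valid])] %in% c(4, 5))
  # scale invariance
  p2k <- insulationProfile(ContactMatrix(m * 17, binSize = 4e4),
                           windowBins = 3)
  expect_equal(p2k$score, p2$score)
  # chromosome shorter than the window: all NA
  pShort <- insulationProfile(ContactMatrix(matrix(1, 4, 4), binSize = 4e4),
                              windowBins = 3)
  expect_true(all(is.na(pShort$score)))
})

test_that("boundary calling finds planted junctions and nothing else", {
  # monotone profile -> no boundaries
  prof <- data.frame(bin = 0:9, start = (0:9) * 4e4,
                     score = seq(-1, 1, length.out = 10))
  prof$strength <- -prof$score
  expect_equal(nrow(callBoundaries(prof)), 0)
  # two-block toy: exactly one boundary at the junction
  m <- twoBlockMatrix(5, 5, hi = 10, lo = 1)
  p <- insulationProfile(ContactMatrix(m, binSize = 4e4), windowBins = 3)
  b <- callBoundaries(p, minProminence = 0.1)
  expect_equal(nrow(b), 1)
  expect_true(b$bin %in% c(4, 5))
  # three blocks, boundaries 5 bins apart: both called
  n <- 15
  m3 <- matrix(1, n, n)
  for (blk in list(1:5, 6:10, 11:15)) m3[blk, blk] <- 10
  p3 <- insulationProfile(ContactMatrix(m3, binSize = 4e4), windowBins = 2)
  b3 <- callBoundaries(p3, minProminence = 0.1)
  expect_equal(nrow(b3), 2)
  expect_true(b3$bin[1] %in% c(4, 5) && b3$bin[2] %in% c(9, 10))
})

test_that("top variable boundaries rank by cross-stage strength SD", {
  bins <- 0:9
  mkProf <- function(strength) data.frame(bin = bins, start = bins * 4e4,
                                          score = -strength,
                                          strength = strength)
  base <- rep(1, 10)
  profs <- list(s1 = mkProf(base), s2 = mkProf(base), s3 = mkProf(base),
                s4 = mkProf(replace(base, 3, 5)))  # bin 2 varies
  bl <- lapply(profs, function(p) data.frame(bin = c(2, 7)))
  top <- topVariableBoundaries(profs, bl, k = 2)
  expect_equal(top$bin[1], 2)
  # SD against a two-pass oracle on random series
  set.seed(41)
  for (i in 1:10) {
    v <- rnorm(4)
    twoPass <- sqrt(sum((v - mean(v))^2) / 3)
    expect_equal(sd(v), twoPass, tolerance = 1e-12)
  }
  # all stages identical: SDs zero, first k by coordinate
  profs0 <- list(s1 = mkProf(base), s2 = mkProf(base), s3 = mkProf(base),
                 s4 = mkProf(base))
  top0 <- topVariableBoundaries(profs0, bl, k = 2)
  expect_equal(top0$bin, c(2, 7))
  expect_warning(topVariableBoundaries(profs0, bl, k = 5), "exceeds")
})

test_that("domain score equals exhaustive pair enumeration", {
  set.seed(42)
  m <- matrix(rpois(36, 6), 6)
  m <- m + t(m)
  cm <- ContactMatrix(m, binSize = 4e4)
  # TAD = bins 0-2 (first three bins)
  got <- domainScore(cm, data.frame(start = 0, end = 3 * 4e4))
  expect_equal(got, domainScoreOracle(m, 1, 3), tolerance = 1e-12)
  # random TADs against the oracle
  for (i in 1:10) {
    a <- sample(1:4, 1); b <- sample(a:6, 1)
    got <- domainScore(cm, data.frame(start = (a - 1) * 4e4, end = b * 4e4))
    expect_equal(got, domainScoreOracle(m, a, b), tolerance = 1e-12)
  }
  # whole chromosome: exactly 1
  expect_equal(domainScore(cm, data.frame(start = 0, end = 6 * 4e4)), 1)
  # TAD with zero associated counts: NA
  z <- matrix(0, 6, 6)
  z[5, 6] <- z[6, 5] <- 3
  expect_true(is.na(domainScore(ContactMatrix(z, binSize = 4e4),
                                data.frame(start = 0, end = 2 * 4e4))))
})

test_that("randomized-TAD normalization is centered on pure decay", {
  gm <- simulateGenome(1, 12e6, 4e4, 10, seed = 1)
  libs <- lapply(1:2, function(s)
    simulateContactMatrix(gm, NULL, binSize = 4e4, depthPairs = 8e5,
                          seed = 600 + s))
  names(libs) <- c("l1", "l2")
  edges <- c(0, 2e6, 4.8e6, 7.2e6, 9.6e6, 12e6)
  tt <- data.frame(chrom = "chr1", start = edges[-6], end = edges[-1])
  ds <- normalizeDomainScores(libs, tt, nSim = 1000, seed = 9)
  # step-1 ratio near 1 means centered scores near 0
  expect_lt(max(abs(colMeans(ds$normalized))), 0.05)
  expect_lt(max(abs(ds$normalized)), 0.2)
  # identical libraries: quantile normalization is the identity
  ds2 <- normalizeDomainScores(list(a = libs[[1]], b = libs[[1]]), tt,
                               nSim = 100, seed = 9)
  expect_equal(ds2$normalized[, 1], ds2$normalized[, 2])
  # chromosome shorter than the TAD errors
  small <- ContactMatrix(matrix(1, 10, 10), binSize = 4e4)
  expect_error(normalizeDomainScores(list(a = small, b = small),
                                     data.frame(chrom = "chr1", start = 0,
                                                end = 20 * 4e4),
                                     nSim = 10, seed = 1), "shorter")
})

test_that("ANOVA selection controls the null and finds strong effects", {
  set.seed(51)
  null <- matrix(rnorm(1000 * 8), 1000)
  stageOf <- rep(paste0("s", 1:4), each = 2)
  vt <- variableTads(null, stageOf, fdrCutoff = 0.001, k = 1000)
  expect_lte(length(vt$selected) / 1000, 0.001 + 0.002)
  # stage means (0,0,0,10), within-SD 0.1, n=2: passes FDR < 0.001
  strong <- rbind(c(0.05, -0.05, 0.02, -0.02, 0.03, -0.03, 10.1, 9.9),
                  null[1:99, ])
  vt2 <- variableTads(strong, stageOf, fdrCutoff = 0.001, k = 10)
  expect_true(1 %in% vt2$selected)
  # k larger than survivors returns all survivors
  expect_lte(length(vt2$selected), 10)
})

test_that("stage-series clustering recovers planted archetypes", {
  set.seed(61)
  up <- t(replicate(50, c(0, 1, 2, 3) + rnorm(4, sd = 0.1)))
  dn <- t(replicate(50, c(3, 2, 1, 0) + rnorm(4, sd = 0.1)))
  mat <- rbind(up, dn)
  cl <- clusterStageSeries(mat, 2)
  purity <- max(mean(cl[1:50] == cl[1]), mean(cl[51:100] == cl[51]))
  expect_gte(mean(cl[1:50] == cl[1]), 0.95)
  expect_gte(mean(cl[51:100] == cl[51]), 0.95)
  expect_true(cl[1] != cl[51])
  # permutation equivariance
  perm <- sample(100)
  cl2 <- clusterStageSeries(mat[perm, ], 2)
  agree <- mean((cl2 == cl2[which(perm == 1)]) == (cl[perm] == cl[1]))
  expect_equal(agree, 1)
  # singleton clusters when n_clusters = n_features
  small <- mat[1:4, ]
  expect_equal(sort(unique(clusterStageSeries(small, 4))), 1:4)
  # constant rows under scaling are tolerated
  cst <- rbind(c(1, 1, 1, 1), up[1:3, ])
  expect_equal(length(clusterStageSeries(cst, 2)), 4)
})

test_that("adjacent-stage log2 fold changes follow the definition", {
  expect_equal(adjacentStageLfc(c(1, 2, 4, 8)), c(1, 1, 1), tolerance = 1e-5)
  expect_equal(adjacentStageLfc(c(8, 4, 2, 1)), c(-1, -1, -1),
               tolerance = 1e-5)
  expect_equal(adjacentStageLfc(c(3, 3, 3, 3)), c(0, 0, 0))
  expect_equal(adjacentStageLfc(c(0, 0, 0, 0)), c(0, 0, 0))
  m <- adjacentStageLfc(rbind(c(1, 2, 4, 8), c(8, 4, 2, 1)))
  expect_equal(dim(m), c(2, 3))
})
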