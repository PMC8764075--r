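test_that("simulated genome has the requested bins, genes and determinism", {
  gm <- simulateGenome(1, 20e6, 40e3, 200, seed = 1)
  expect_equal(unname(ceiling(chromLengths(gm) / binSize(gm))), 500)
  expect_equal(nrow(genes(gm)), 200)
  expect_true(all(genes(gm)$tss >= 0 & genes(gm)$tss < 20e6))
  # degenerate single-bin genome
  g1 <- simulateGenome(1, 1e6, 1e6, 1, seed = 7)
  expect_equal(unname(ceiling(chromLengths(g1) / binSize(g1))), 1)
  # determinism
  expect_identical(simulateGenome(2, 10e6, 40e3, 50, seed = 3),
                   simulateGenome(2, 10e6, 40e3, 50, seed = 3))
  expect_error(simulateGenome(0, 1e6, 1e4, 1, seed = 1), "positive")
})

test_that("planted architecture honors flip fraction and trajectory mix", {
  gm <- tinyGenome()
  tr0 <- simulateArchitecture(gm, flipFraction = 0, seed = 4)
  labs <- compartmentLabels(tr0)
  expect_true(all(apply(labs, 2, function(s) length(unique(s)) == 1)))
  expect_equal(realizedFlipFraction(tr0), 0)

  tr <- simulateArchitecture(gm, flipFraction = 0.10, seed = 5)
  nb <- ncol(compartmentLabels(tr))
  flipped <- sum(apply(compartmentLabels(tr), 2,
                       function(s) length(unique(s)) > 1))
  expect_lte(abs(flipped - round(0.10 * nb)), 1)

  trInc <- simulateArchitecture(gm, trajectoryMix = c(increasing = 1),
                                seed = 6)
  expect_true(all(apply(trInc@loopMultipliers, 1,
                        function(v) all(diff(v) >= 0))))
  # TADs tile the chromosome
  td <- tads(trInc)
  expect_equal(td$start[1], 0)
  expect_equal(td$end[nrow(td)], unname(chromLengths(gm)))
  expect_true(all(td$end[-nrow(td)] == td$start[-1]))
  expect_error(simulateArchitecture(gm, tadCount = 1e5, seed = 1), "tadCount")
})

test_that("contact simulator follows decay, plants loops, respects depth", {
  gm <- simulateGenome(1, 5e6, 50e3, 10, seed = 1)  # 100 bins
  # pure decay: mean count at distance d proportional to d^-1
  cm <- simulateContactMatrix(gm, NULL, depthPairs = 5e5, decayExponent = 1,
                              seed = 2)
  m <- contactCounts(cm)
  meanAt <- function(d) { i <- seq_len(100 - d); mean(m[cbind(i, i + d)]) }
  r21 <- meanAt(1) / meanAt(2)
  r42 <- meanAt(2) / meanAt(4)
  expect_equal(r21, 2, tolerance = 0.1)
  expect_equal(r42, 2, tolerance = 0.1)
  # symmetry, integrality, non-negativity
  expect_identical(m, t(m))
  expect_true(all(m >= 0) && all(m == round(m)))
  # conservation: total within 3 SD of depth (Poisson)
  expect_lt(abs(totalCount(cm) - 5e5), 3 * sqrt(5e5))
  # determinism
  cm2 <- simulateContactMatrix(gm, NULL, depthPairs = 5e5, decayExponent = 1,
                               seed = 2)
  expect_identical(contactCounts(cm), contactCounts(cm2))
  # depth 0 -> all-zero matrix
  cm0 <- simulateContactMatrix(gm, NULL, depthPairs = 0, seed = 3)
  expect_true(all(contactCounts(cm0) == 0))
  expect_error(simulateContactMatrix(gm, NULL, decayExponent = 0, seed = 1),
               "decayExponent")
})

test_that("a planted loop multiplies the local decay expectation", {
  gm <- simulateGenome(1, 5e6, 50e3, 10, seed = 1)
  # hand-built truth: one loop with multiplier 5 at bins (20, 50), no other
  # structure
  tr <- simulateArchitecture(gm, flipFraction = 0, tadCount = 1,
                             loopCount = 0, nEnhancers = 5, seed = 1)
  tr@tadEnrichment[] <- 1
  tr@loopTable <- data.frame(chrom = "chr1", anchor1 = 19 * 50e3,
                             anchor2 = 49 * 50e3, class = "E-P",
                             elem1 = 1L, elem2 = 2L,
                             trajectory = "stable")
  tr@loopMultipliers <- matrix(5, 1, 4)
  tot <- 0; bgTot <- 0
  for (s in 1:100) {
    cm <- simulateContactMatrix(gm, tr, stage = 1, depthPairs = 2e5,
                                seed = 1000 + s)
    m <- contactCounts(cm)
    tot <- tot + m[20, 50]
    i <- seq_len(100 - 30)
    bgTot <- bgTot + (sum(m[cbind(i, i + 30)]) - m[20, 50]) / (length(i) - 1)
  }
  expect_equal(tot / bgTot, 5, tolerance = 0.25)
})

test_that("stage outside the truth errors", {
  gm <- simulateGenome(1, 5e6, 50e3, 10, seed = 1)
  tr <- simulateArchitecture(gm, seed = 2)
  expect_error(simulateContactMatrix(gm, tr, stage = 9, seed = 1), "stage")
})

test_that("chip emission follows intensities, occupancy and the lag", {
  gm <- tinyGenome(genes = 100, seed = 2)
  tr <- simulateArchitecture(gm, trajectoryMix = c(increasing = 1), seed = 3)
  chip <- simulateChipExpression(gm, tr, seed = 4)
  st <- stages(tr)
  # peaks exactly where intensity > 0
  for (s in seq_along(st)) {
    inten <- tr@markIntensity$H3K27ac[, s]
    expect_equal(length(chip$peaks[[st[s]]]$H3K27ac), sum(inten > 0))
  }
  # TF occupancy all false -> empty TF peak files
  tr0 <- tr
  tr0@tfOccupancy[] <- FALSE
  chip0 <- simulateChipExpression(gm, tr0, seed = 4)
  expect_true(all(vapply(chip0$tfPeaks, length, integer(1)) == 0))
  # genes within 20 kb of an increasing anchor rise stage 1 -> 4
  lt <- loops(tr)
  g <- genes(gm)
  near <- unique(unlist(lapply(seq_len(nrow(lt)), function(i)
    which(g$chrom == lt$chrom[i] &
            (abs(g$tss - lt$anchor1[i]) <= 20e3 |
               abs(g$tss - lt$anchor2[i]) <= 20e3)))))
  expect_gt(length(near), 0)
  m1 <- rowMeans(chip$expression[near, chip$cellStage == st[1], drop = FALSE])
  m4 <- rowMeans(chip$expression[near, chip$cellStage == st[4], drop = FALSE])
  expect_gt(mean(m4 - m1), 0)
  expect_gt(mean(m4 > m1), 0.8)
})

test_that("truth round-trips through JSON exactly", {
  gm <- tinyGenome(genes = 50, seed = 5)
  tr <- simulateArchitecture(gm, seed = 6)
  path <- tempfile(fileext = ".json")
  writeTruth(tr, path)
  tr2 <- readTruth(path)
  expect_equal(tr2@stages, tr@stages)
  expect_equal(tr2@compartments[[1]], unname(tr@compartments[[1]]),
               ignore_attr = TRUE)
  expect_equal(tr2@tadTable, tr@tadTable)
  expect_equal(tr2@tadEnrichment, tr@tadEnrichment, ignore_attr = TRUE)
  expect_equal(tr2@loopTable, tr@loopTable)
  expect_equal(tr2@loopMultipliers, tr@loopMultipliers, ignore_attr = TRUE)
  expect_equal(tr2@elementTable, tr@elementTable)
  expect_equal(tr2@tfOccupancy, tr@tfOccupancy, ignore_attr = TRUE)
  expect_equal(realizedFlipFraction(tr2), realizedFlipFraction(tr))
})

test_that("contact matrix round-trips through bins + triplet TSV", {
  gm <- simulateGenome(1, 2e6, 1e5, 5, seed = 1)
  cm <- simulateContactMatrix(gm, NULL, depthPairs = 1e4, seed = 2)
  b <- tempfile(); trp <- tempfile()
  writeContactMatrix(cm, b, trp)
  cm2 <- readContactMatrix(b, trp)
  expect_identical(contactCounts(cm2), contactCounts(cm))
  expect_equal(binSize(cm2), binSize(cm))
  expect_equal(chromName(cm2), chromName(cm))
})
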