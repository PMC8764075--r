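gr <- function(chrom, start0, end0, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1,
                                                 end = end0), ...)
}

test_that("enhancer definition applies whole-peak TSS exclusion", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 100e3,
                      strand = "+")
  peaks <- c(gr("chr1", 99e3, 100.5e3),    # inside TSS +/- 5 kb: dropped
             gr("chr1", 106e3, 107e3),     # 6 kb away, no overlap: kept
             gr("chr1", 104.9e3, 106e3),   # straddles the edge by 1+ bp: dropped
             gr("chr1", 300e3, 301e3))     # far: kept
  anno <- buildAnnotation(genes, peaks)
  expect_equal(length(anno$enhancers), 2)
  expect_equal(GenomicRanges::start(anno$enhancers) - 1,
               c(106e3, 300e3))
  # promoters span TSS +/- 5 kb
  expect_equal(GenomicRanges::width(anno$promoters), 10e3)
  # disjoint by construction
  expect_equal(sum(GenomicRanges::countOverlaps(anno$enhancers,
                                                anno$promoters)), 0)
})

test_that("interaction classes follow anchor labels with promoter precedence", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      tss = c(100e3, 500e3), strand = "+")
  peaks <- c(gr("chr1", 200e3, 201e3), gr("chr1", 300e3, 301e3),
             gr("chr1", 98e3, 99e3))  # overlaps promoter window: excluded
  anno <- buildAnnotation(genes, peaks)
  loopDf <- data.frame(chrom = "chr1",
                       anchor1 = c(200e3, 100e3, 200e3, 700e3, 101e3),
                       anchor2 = c(500e3, 500e3, 300e3, 800e3, 300e3))
  out <- classifyInteractions(loopDf, anno, anchorWidth = 1e4)
  expect_equal(out$class, c("E-P", "P-P", "E-E", "other", "E-P"))
  # anchor overlapping both a promoter window and a valid enhancer is
  # labelled P (promoter precedence): anchor5 = 101-111 kb covers the g1
  # promoter window (95-105 kb) and an enhancer at 106-107 kb
  peaks2 <- c(peaks, gr("chr1", 106e3, 107e3))
  out5 <- classifyInteractions(loopDf[5, , drop = FALSE],
                               buildAnnotation(genes, peaks2), 1e4)
  expect_equal(out5$anchor1Label, "P")
})

test_that("TF engagement subtypes follow occupancy location", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 100e3,
                      strand = "+")
  peaks <- gr("chr1", 300e3, 301e3)
  anno <- buildAnnotation(genes, peaks)
  ep <- classifyInteractions(
    data.frame(chrom = "chr1", anchor1 = 95e3, anchor2 = 300e3),
    anno, 1e4)
  expect_equal(ep$class, "E-P")
  # TF on the promoter anchor only
  r <- tfEngagement(ep, gr("chr1", 99e3, 99.5e3), anno, 1e4)
  expect_true(r$engaged)
  expect_equal(r$subtype, "promoter-only")
  # TF on both anchors
  r2 <- tfEngagement(ep, c(gr("chr1", 99e3, 99.5e3),
                           gr("chr1", 300.2e3, 300.4e3)), anno, 1e4)
  expect_equal(r2$subtype, "both")
  # no TF overlap
  r3 <- tfEngagement(ep, gr("chr1", 900e3, 901e3), anno, 1e4)
  expect_false(r3$engaged)
  expect_equal(r3$subtype, "none")
  # non-E-P input errors
  pp <- ep; pp$class <- "P-P"
  expect_error(tfEngagement(pp, peaks, anno, 1e4), "E-P")
})

test_that("engagement summary recovers the planted fraction exactly", {
  gm <- tinyGenome(genes = 150, seed = 9)
  tr <- simulateArchitecture(gm, loopCount = 100, epEngagedFraction = 0.40,
                             seed = 10)
  lt <- loops(tr)
  el <- elements(tr)
  # noise-free annotation straight from the truth
  k27 <- gr(el$chrom, el$start, el$end)
  anno <- buildAnnotation(genes(gm), k27[el$type == "enhancer"])
  occ <- which(tr@tfOccupancy[, 1])
  tf <- gr(el$chrom[occ], el$start[occ], el$end[occ])
  classed <- classifyInteractions(lt, anno, tr@loopBinSize)
  # classification equals the planted classes exactly
  expect_equal(classed$class, lt$class)
  es <- engagementSummary(classed, tf, tr@loopBinSize)
  nEP <- sum(lt$class == "E-P")
  expect_equal(es$byClass$n[es$byClass$class == "E-P"], nEP)
  expect_equal(es$byClass$fractionEngaged[es$byClass$class == "E-P"],
               round(0.40 * nEP) / nEP)
  # all E-P anchors bound -> fraction 1; empty set -> NA fraction
  ep <- classed[classed$class == "E-P", ]
  allB <- engagementSummary(ep, gr(ep$chrom, ep$anchor1, ep$anchor1 + 1e4),
                            tr@loopBinSize)
  expect_equal(allB$byClass$fractionEngaged[allB$byClass$class == "E-P"], 1)
  none <- engagementSummary(classed[0, ], tf, tr@loopBinSize)
  expect_true(is.na(none$byClass$fractionEngaged[2]))
})

test_that("gene assignment respects the 20 kb TSS-to-anchor rule", {
  genes <- data.frame(gene_id = c("near", "far", "inside"),
                      chrom = "chr1",
                      tss = c(100e3 + 1e4 + 15e3,  # 15 kb past anchor end
                              100e3 + 1e4 + 25e3,  # 25 kb past anchor end
                              105e3),              # inside anchor1
                      strand = "+")
  loopDf <- data.frame(chrom = "chr1", anchor1 = 100e3, anchor2 = 500e3)
  asg <- assignGenes(loopDf, genes, anchorWidth = 1e4, maxDist = 20e3)
  expect_setequal(asg$gene_id, c("near", "inside"))
  expect_equal(asg$distance[asg$gene_id == "inside"], 0)
})

test_that("peak-restricted signal is linear and peak-gated", {
  cov <- gr("chr1", 0, 10e3, score = 50 / 1e3)  # 50 reads over 1 kb? no:
  # coverage density 0.05/bp over 10 kb = 500 reads total
  peaks <- gr("chr1", 2e3, 3e3)                 # 1 kb peak -> 50 reads on it
  region <- gr("chr1", 0, 10e3)
  s <- signalOnRegions(cov, peaks, region, librarySize = 1e6)
  expect_equal(s, 50)
  # doubling library size halves the signal
  expect_equal(signalOnRegions(cov, peaks, region, 2e6), 25)
  # region disjoint from all peaks is 0 regardless of coverage
  expect_equal(signalOnRegions(cov, peaks, gr("chr1", 5e3, 8e3), 1e6), 0)
  # additive over disjoint regions
  r2 <- c(gr("chr1", 0, 2.5e3), gr("chr1", 2.5e3, 10e3))
  expect_equal(sum(signalOnRegions(cov, peaks, r2, 1e6)), 50)
  # homogeneous in coverage scaling
  cov3 <- cov
  S4Vectors::mcols(cov3)$score <- S4Vectors::mcols(cov)$score * 3
  expect_equal(signalOnRegions(cov3, peaks, region, 1e6), 150)
  expect_error(signalOnRegions(cov, peaks, region, 0), "librarySize")
})

test_that("boundary metaprofile peaks at planted boundary signal", {
  # uniform peak-restricted signal -> flat curve
  cov <- gr("chr1", 0, 5e6, score = 0.01)
  peaks <- gr("chr1", 0, 5e6)
  bounds <- data.frame(chrom = "chr1", center = c(1.5e6, 2.5e6, 3.5e6))
  mp <- boundaryMetaprofile(cov, peaks, bounds, 1e6, c(chr1 = 5e6))
  expect_equal(nrow(mp$curve), 101)
  expect_lt(diff(range(mp$curve$signal)), 1e-9)
  # planted mark at boundary centers: center exceeds the outer flanks
  mk <- do.call(c, lapply(bounds$center, function(ctr)
    gr("chr1", ctr - 2e3, ctr + 2e3, score = 1)))
  mp2 <- boundaryMetaprofile(mk, mk, bounds, 1e6, c(chr1 = 5e6))
  ctr <- mp2$curve$signal[mp2$curve$offset == 0]
  flank <- mean(mp2$curve$signal[abs(mp2$curve$offset) >= 400e3])
  expect_gt(ctr, flank)
  # boundaries too close to the edge are skipped and counted
  b2 <- rbind(bounds, data.frame(chrom = "chr1", center = 100e3))
  mp3 <- boundaryMetaprofile(cov, peaks, b2, 1e6, c(chr1 = 5e6))
  expect_equal(mp3$nSkipped, 1)
  expect_error(boundaryMetaprofile(cov, peaks, bounds[0, ], 1e6,
                                   c(chr1 = 5e6)), "empty")
})
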