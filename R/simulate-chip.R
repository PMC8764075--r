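#' Simulate per-stage ChIP peaks, coverage tracks and single-cell expression
#'
#' Emits, for each stage, one peak set and one coverage track per histone
#' mark plus a TF (RUNX1-like) peak set, and a single-cell expression table
#' on the `log2(TPM/10 + 1)` scale. Peaks appear exactly at planted elements
#' whose mark intensity at that stage is positive, with read counts
#' proportional to intensity; TF peaks appear only where the truth's
#' occupancy flag is set. Genes whose TSS lies within 20 kb of an anchor of
#' an increasing-trajectory loop respond with a one-stage lag: their
#' expression multiplier at stage t is the loop multiplier at stage t-1,
#' encoding a delayed transcriptional response to loop strengthening.
#'
#' @param genome a [GenomeModel-class].
#' @param truth an [ArchitectureTruth-class] carrying element intensities.
#' @param cellsPerStage cells sampled per stage in the expression table.
#' @param readsPerIntensityUnit reads emitted per intensity unit at a peak.
#' @param noiseSd lognormal expression noise SD (log scale).
#' @param seed RNG seed.
#' @return list with components `peaks` (stage -> mark -> GRanges with the
#'   read count in `score`), `tfPeaks` (stage -> GRanges), `coverage`
#'   (stage -> mark -> GRanges with per-bp read density in `score`),
#'   `librarySize` (stage -> mark -> total reads), `expression` (genes x
#'   cells matrix, log2(TPM/10+1)) and `cellStage` (stage label per cell).
#' @export
simulateChipExpression <- function(genome, truth,
                                   cellsPerStage = c(42, 33, 50, 16),
                                   readsPerIntensityUnit = 100,
                                   noiseSd = 0.3, seed) {
  stopifnot(methods::is(truth, "ArchitectureTruth"))
  st <- stages(truth)
  nS <- length(st)
  cellsPerStage <- rep_len(cellsPerStage, nS)
  el <- elements(truth)
  marks <- names(truth@markIntensity)
  withSeed(seed, {
    peaks <- list(); coverage <- list(); tfPeaks <- list(); libSize <- list()
    for (s in seq_len(nS)) {
      pk <- list(); cv <- list(); ls <- list()
      for (mk in marks) {
        inten <- truth@markIntensity[[mk]][, s]
        keep <- which(inten > 0)
        reads <- round(inten[keep] * readsPerIntensityUnit)
        gr <- GenomicRanges::GRanges(
          el$chrom[keep],
          IRanges::IRanges(start = el$start[keep] + 1L, end = el$end[keep]),
          score = reads)
        pk[[mk]] <- gr
        cvg <- gr
        # per-bp read density so that score * width recovers the read count
        S4Vectors::mcols(cvg)$score <- reads / GenomicRanges::width(gr)
        cv[[mk]] <- cvg
        ls[[mk]] <- sum(reads)
      }
      occ <- which(truth@tfOccupancy[, s])
      tfPeaks[[st[s]]] <- GenomicRanges::GRanges(
        el$chrom[occ],
        IRanges::IRanges(start = el$start[occ] + 1L, end = el$end[occ]),
        score = rep(100, length(occ)))
      peaks[[st[s]]] <- pk
      coverage[[st[s]]] <- cv
      libSize[[st[s]]] <- ls
    }
    ## --- expression with a one-stage lag at increasing loop anchors ------
    g <- genes(genome)
    mult <- matrix(1, nrow(g), nS)
    lt <- loops(truth)
    for (li in which(lt$trajectory %in% c("increasing", "decreasing"))) {
      anchors <- c(lt$anchor1[li], lt$anchor2[li])
      near <- which(g$chrom == lt$chrom[li] &
                      (abs(g$tss - anchors[1]) <= 20e3 |
                         abs(g$tss - (anchors[1] + truth@loopBinSize)) <= 20e3 |
                         abs(g$tss - anchors[2]) <= 20e3 |
                         abs(g$tss - (anchors[2] + truth@loopBinSize)) <= 20e3))
      if (!length(near)) next
      lagged <- truth@loopMultipliers[li, c(1L, seq_len(nS - 1L))]
      lagged <- lagged / lagged[1]
      for (gi in near) mult[gi, ] <- mult[gi, ] * lagged
    }
    baseTPM <- stats::rlnorm(nrow(g), meanlog = log(10), sdlog = 1)
    cellStage <- rep(st, times = cellsPerStage)
    expr <- matrix(NA_real_, nrow(g), length(cellStage),
                   dimnames = list(g$gene_id,
                                   sprintf("cell%03d", seq_along(cellStage))))
    for (ci in seq_along(cellStage)) {
      s <- match(cellStage[ci], st)
      tpm <- baseTPM * mult[, s] *
        stats::rlnorm(nrow(g), meanlog = 0, sdlog = noiseSd)
      expr[, ci] <- log2(tpm / 10 + 1)
    }
    list(peaks = peaks, tfPeaks = tfPeaks, coverage = coverage,
         librarySize = libSize, expression = expr, cellStage = cellStage)
  })
}
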