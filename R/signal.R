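#' Peak-restricted, library-normalized signal on regions
#'
#' For each region, sums the coverage falling inside the intersection of
#' the region with the mark's peaks (only reads on peaks contribute) and
#' normalizes per million: `signal = reads_on(region & peaks) * 1e6 /
#' librarySize`. Coverage is a bedGraph-style track whose `score` is read
#' density per bp, so `score * width` is a read count; the quantity is
#' additive over disjoint regions and homogeneous in coverage scaling.
#'
#' @param coverage GRanges with per-bp read density in `score`.
#' @param peaks GRanges of the mark's peaks (same stage).
#' @param regions GRanges of query regions.
#' @param librarySize total mapped reads of the library (> 0).
#' @return numeric vector, one signal per region (0 where a region meets
#'   no peak).
#' @export
signalOnRegions <- function(coverage, peaks, regions, librarySize) {
  if (librarySize <= 0) stop("librarySize must be positive")
  n <- length(regions)
  out <- numeric(n)
  if (!length(coverage) || !length(peaks) || !n) return(out)
  inPeaks <- GenomicRanges::intersect(GenomicRanges::granges(coverage),
                                      GenomicRanges::reduce(peaks))
  # carry the density of the originating coverage interval
  ov <- GenomicRanges::findOverlaps(inPeaks, coverage)
  seg <- IRanges::pintersect(inPeaks[S4Vectors::queryHits(ov)],
                             coverage[S4Vectors::subjectHits(ov)])
  dens <- S4Vectors::mcols(coverage)$score[S4Vectors::subjectHits(ov)]
  ov2 <- GenomicRanges::findOverlaps(regions, seg)
  if (length(ov2)) {
    pieces <- IRanges::pintersect(regions[S4Vectors::queryHits(ov2)],
                                  seg[S4Vectors::subjectHits(ov2)])
    contrib <- GenomicRanges::width(pieces) * dens[S4Vectors::subjectHits(ov2)]
    agg <- tapply(contrib, S4Vectors::queryHits(ov2), sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out * 1e6 / librarySize
}

#' Aggregate peak-restricted signal around boundary centers
#'
#' Mean peak-restricted, per-million signal in `binBp` offset bins over a
#' `+/- flank` window around each boundary center (101 bins at the
#' defaults of 500 kb / 10 kb). Boundaries whose window extends past the
#' chromosome are skipped and counted.
#'
#' @param coverage,peaks,librarySize as in [signalOnRegions()].
#' @param boundaries data.frame with `chrom` and `center` (bp).
#' @param chromLength named chromosome lengths (bp).
#' @param flank half-window in bp (default 500 kb).
#' @param binBp offset bin size in bp (default 10 kb).
#' @return list with `curve` (data.frame `offset` in bp, `signal`),
#'   `nUsed`, `nSkipped`.
#' @export
boundaryMetaprofile <- function(coverage, peaks, boundaries, librarySize,
                                chromLength, flank = 500e3, binBp = 10e3) {
  if (!nrow(boundaries)) stop("empty boundary list")
  half <- flank / binBp
  offsets <- (-half:half) * binBp
  acc <- numeric(length(offsets))
  used <- 0L; skipped <- 0L
  for (r in seq_len(nrow(boundaries))) {
    ctr <- boundaries$center[r]
    ch <- boundaries$chrom[r]
    if (ctr - flank - binBp / 2 < 0 ||
        ctr + flank + binBp / 2 > chromLength[[ch]]) {
      skipped <- skipped + 1L
      next
    }
    starts <- ctr + offsets - binBp / 2
    regions <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(start = starts + 1, width = binBp))
    acc <- acc + signalOnRegions(coverage, peaks, regions, librarySize)
    used <- used + 1L
  }
  if (used == 0) stop("no boundary had a full window inside the chromosome")
  list(curve = data.frame(offset = offsets, signal = acc / used),
       nUsed = used, nSkipped = skipped)
}
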