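# Expected (pre-Poisson) contact intensity matrix for one chromosome at one
# stage: power-law distance decay modulated multiplicatively by compartment
# concordance, intra-TAD enrichment and loop multipliers.
expectedContactWeights <- function(genome, truth, stage, chrom, binSize,
                                   decayExponent) {
  len <- chromLengths(genome)[[chrom]]
  n <- nBinsFor(len, binSize)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  W <- ifelse(d == 0, 1, d^(-decayExponent))
  mids <- ((seq_len(n) - 1) + 0.5) * binSize
  if (!is.null(truth)) {
    st <- if (is.character(stage)) match(stage, truth@stages) else stage
    if (is.na(st) || st < 1 || st > length(truth@stages))
      stop("stage outside the truth's stage series")
    labs <- truth@compartments[[chrom]]
    if (!is.null(labs)) {
      cb <- pmin(binOf(mids, truth@compartmentBinSize) + 1L, ncol(labs))
      lab <- labs[st, cb]
      cf <- truth@params$compartmentFactor
      if (is.null(cf)) cf <- 1.5
      # compartmentalization is a long-range effect: modulate only pairs
      # beyond the TAD scale so block edges do not mimic TAD boundaries
      minSep <- truth@params$compartmentMinSeparation
      if (is.null(minSep)) minSep <- 2e6
      far <- d * binSize > minSep
      fac <- ifelse(outer(lab, lab, "=="), cf, 1 / cf)
      W <- W * ifelse(far, fac, 1)
    }
    td <- truth@tadTable[truth@tadTable$chrom == chrom, , drop = FALSE]
    if (nrow(td)) {
      enr <- truth@tadEnrichment[truth@tadTable$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(td))) {
        inT <- which(mids >= td$start[i] & mids < td$end[i])
        W[inT, inT] <- W[inT, inT] * enr[i, st]
      }
    }
    lt <- truth@loopTable
    sel <- which(lt$chrom == chrom)
    for (li in sel) {
      a <- binOf(lt$anchor1[li], binSize) + 1L
      b <- binOf(lt$anchor2[li], binSize) + 1L
      if (a != b && a <= n && b <= n) {
        m <- truth@loopMultipliers[li, st]
        W[a, b] <- W[a, b] * m
        W[b, a] <- W[b, a] * m
      }
    }
  }
  W
}

#' Simulate a binned cis contact matrix
#'
#' Draws a symmetric integer contact matrix from the generative model:
#' expected contact proportional to `distance^-decayExponent`, multiplied by
#' the compartment checkerboard factor (same-label 100 kb bins x c,
#' different-label x 1/c), the per-TAD per-stage intra-TAD enrichment, and
#' the loop multipliers of the planted truth, then Poisson-sampled so that
#' the expected total cis pair count equals `depthPairs`.
#'
#' @param genome a [GenomeModel-class].
#' @param truth an [ArchitectureTruth-class], or `NULL` for a pure
#'   distance-decay matrix with no planted structure.
#' @param stage stage index or name within the truth's series.
#' @param chrom chromosome to simulate.
#' @param binSize resolution in bp.
#' @param depthPairs expected total number of cis read pairs; 0 yields an
#'   all-zero matrix.
#' @param decayExponent power-law decay exponent (> 0).
#' @param seed RNG seed; a fixed seed gives a byte-identical matrix.
#' @return A [ContactMatrix-class] with integer counts.
#' @export
simulateContactMatrix <- function(genome, truth, stage = 1L,
                                  chrom = names(chromLengths(genome))[1],
                                  binSize = NULL,
                                  depthPairs = 1e6, decayExponent = 1.0,
                                  seed) {
  if (is.null(binSize)) binSize <- genome@binSize
  if (depthPairs < 0) stop("depthPairs must be >= 0")
  if (decayExponent <= 0) stop("decayExponent must be > 0")
  W <- expectedContactWeights(genome, truth, stage, chrom, binSize,
                              decayExponent)
  n <- nrow(W)
  lambda <- W * (depthPairs / pairSum(W))
  counts <- matrix(0, n, n)
  if (depthPairs > 0) {
    up <- upper.tri(lambda, diag = TRUE)
    counts[up] <- withSeed(seed, stats::rpois(sum(up), lambda[up]))
    counts <- counts + t(counts) - diag(diag(counts))
  }
  methods::new("ContactMatrix", chrom = chrom, binSize = binSize,
               bins = makeBinTable(chromLengths(genome)[[chrom]], binSize),
               counts = counts)
}
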