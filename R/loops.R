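# Donut background: for each pixel, the mean of counts over the
# (2w+1)x(2w+1) neighborhood excluding the center row and column (the peak
# and its cross), edge-aware.
donutMean <- function(m, w) {
  n <- nrow(m)
  S <- matrix(0, n, n)
  C <- matrix(0, n, n)
  for (di in -w:w) {
    for (dj in -w:w) {
      if (di == 0 || dj == 0) next
      si <- seq_len(n) + di
      sj <- seq_len(n) + dj
      oki <- si >= 1 & si <= n
      okj <- sj >= 1 & sj <= n
      S[oki, okj] <- S[oki, okj] + m[si[oki], sj[okj]]
      C[oki, okj] <- C[oki, okj] + 1
    }
  }
  S / pmax(C, 1)
}

#' Detect chromatin loops by local enrichment
#'
#' Scans cis pixels in a separation window for local enrichment over a
#' donut background (the neighborhood mean excluding the candidate pixel's
#' row and column), tests each candidate's raw count against a Poisson
#' upper tail with the donut mean as rate, applies Benjamini-Hochberg
#' correction over the candidates, and merges adjacent significant pixels
#' (8-neighborhood) into single loops keeping the maximum-enrichment pixel.
#'
#' @param x a [ContactMatrix-class], typically 10 kb, raw counts.
#' @param minDist,maxDist anchor separation window in bp.
#' @param neighborhoodBins donut half-width in bins.
#' @param foldMin candidate threshold: observed > foldMin x donut mean.
#' @param pMax BH-adjusted significance level.
#' @param minLambda floor on the Poisson rate, guarding near-empty donuts.
#' @return data.frame (one row per loop): `chrom`, `bin1`, `bin2`
#'   (0-based), `anchor1`, `anchor2` (bp starts), `observed`, `expectedLocal`,
#'   `fold`, `p`, `fdr`, `nPixels` (merged pixel count).
#' @export
detectLoops <- function(x, minDist = 50e3, maxDist = 2e6,
                        neighborhoodBins = 5L, foldMin = 1.5, pMax = 0.05,
                        minLambda = 0.01) {
  if (maxDist <= minDist) stop("maxDist must exceed minDist")
  m <- contactCounts(x)
  n <- nrow(m)
  bs <- binSize(x)
  bg <- donutMean(m, neighborhoodBins)
  dmin <- ceiling(minDist / bs)
  dmax <- floor(maxDist / bs)
  empty <- data.frame(chrom = character(0), bin1 = integer(0), bin2 = integer(0),
                      anchor1 = numeric(0), anchor2 = numeric(0),
                      observed = numeric(0), expectedLocal = numeric(0),
                      fold = numeric(0), p = numeric(0), fdr = numeric(0),
                      nPixels = integer(0))
  if (dmin >= n) return(empty)
  ij <- which(upper.tri(m), arr.ind = TRUE)
  sep <- ij[, 2] - ij[, 1]
  inWin <- sep >= dmin & sep <= dmax
  ij <- ij[inWin, , drop = FALSE]
  obs <- m[ij]
  lam <- pmax(bg[ij], minLambda)
  cand <- obs > foldMin * lam & obs >= 2
  if (!any(cand)) return(empty)
  ij <- ij[cand, , drop = FALSE]
  obs <- obs[cand]; lam <- lam[cand]
  p <- stats::ppois(obs - 1, lam, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  sig <- fdr < pMax
  if (!any(sig)) return(empty)
  ij <- ij[sig, , drop = FALSE]
  obs <- obs[sig]; lam <- lam[sig]; p <- p[sig]; fdr <- fdr[sig]
  fold <- obs / lam
  ## merge 8-adjacent significant pixels
  k <- nrow(ij)
  comp <- seq_len(k)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (a in seq_len(k)) {
    near <- which(abs(ij[, 1] - ij[a, 1]) <= 1 & abs(ij[, 2] - ij[a, 2]) <= 1)
    for (b in near) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) comp[ra] <- rb
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  out <- do.call(rbind, lapply(unique(roots), function(r) {
    idx <- which(roots == r)
    best <- idx[which.max(fold[idx])]
    data.frame(chrom = chromName(x), bin1 = ij[best, 1] - 1L,
               bin2 = ij[best, 2] - 1L,
               anchor1 = (ij[best, 1] - 1L) * bs,
               anchor2 = (ij[best, 2] - 1L) * bs,
               observed = obs[best], expectedLocal = lam[best],
               fold = fold[best], p = p[best], fdr = fdr[best],
               nPixels = length(idx), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$bin1, out$bin2), ]
  rownames(out) <- NULL
  out
}

#' Loop strength in counts per million (CPM)
#'
#' CPM of a loop pixel: raw count x 1e6 / total mapped cis pairs in the
#' library.
#'
#' @param x a [ContactMatrix-class] with raw counts.
#' @param loopDf data.frame with 0-based `bin1`, `bin2` columns.
#' @return numeric vector of CPM values.
#' @export
loopStrengthCpm <- function(x, loopDf) {
  tot <- totalCount(x)
  if (tot <= 0) stop("zero-total library")
  m <- contactCounts(x)
  m[cbind(loopDf$bin1 + 1L, loopDf$bin2 + 1L)] * 1e6 / tot
}

#' Aggregate contact analysis (APA) over anchor pairs
#'
#' Averages the obs/exp window centered at each anchor pair; pairs whose
#' window does not lie fully inside the chromosome are skipped and
#' counted. Center enrichment is the center value of the mean window
#' divided by the mean of its four corner pixels.
#'
#' @param x a [ContactMatrix-class] with obs/exp computed.
#' @param anchorPairs data.frame with 0-based `bin1`, `bin2`.
#' @param flankBins window half-width in bins (window is 2*flank+1 square).
#' @return list with `apa` (mean window), `nUsed`, `nSkipped`,
#'   `centerEnrichment`.
#' @export
aggregateContacts <- function(x, anchorPairs, flankBins = 5L) {
  oe <- oeMatrix(x)
  if (is.null(oe)) stop("obs/exp matrix required; run observedOverExpected()")
  if (!nrow(anchorPairs)) stop("empty anchor pair list")
  n <- nrow(oe)
  w <- flankBins
  size <- 2L * w + 1L
  acc <- matrix(0, size, size)
  cnt <- matrix(0, size, size)
  used <- 0L; skipped <- 0L
  for (r in seq_len(nrow(anchorPairs))) {
    i <- anchorPairs$bin1[r] + 1L
    j <- anchorPairs$bin2[r] + 1L
    if (i - w < 1 || j - w < 1 || i + w > n || j + w > n) {
      skipped <- skipped + 1L
      next
    }
    win <- oe[(i - w):(i + w), (j - w):(j + w)]
    okv <- !is.na(win)
    acc[okv] <- acc[okv] + win[okv]
    cnt <- cnt + okv
    used <- used + 1L
  }
  if (used == 0) stop("no anchor pair had a full window inside the chromosome")
  apa <- acc / pmax(cnt, 1)
  apa[cnt == 0] <- NA_real_
  center <- apa[w + 1L, w + 1L]
  # corner background over the four k x k corner blocks (k <= 3) for a
  # stable normalizer
  k <- min(3L, w)
  lo <- seq_len(k); hi <- size - k + seq_len(k)
  corners <- mean(c(apa[lo, lo], apa[lo, hi], apa[hi, lo], apa[hi, hi]),
                  na.rm = TRUE)
  list(apa = apa, nUsed = used, nSkipped = skipped,
       centerEnrichment = center / corners)
}

#' Mean obs/exp between two regions
#'
#' Mean of the obs/exp values over all bin pairs (a in A, b in B); bins
#' overlap a region if they intersect it. Overlapping regions are computed
#' but flagged.
#'
#' @param x a [ContactMatrix-class] with obs/exp computed (typically 5 kb).
#' @param regionA,regionB numeric `c(start, end)` in bp (0-based half-open)
#'   on this chromosome.
#' @return numeric scalar with attribute `overlapFlag`.
#' @export
quantifyRegionPair <- function(x, regionA, regionB) {
  oe <- oeMatrix(x)
  if (is.null(oe)) stop("obs/exp matrix required; run observedOverExpected()")
  bt <- binTable(x)
  binsIn <- function(r) which(bt$start < r[2] & bt$end > r[1])
  a <- binsIn(regionA)
  b <- binsIn(regionB)
  if (!length(a) || !length(b)) stop("region covers no bins")
  val <- mean(oe[a, b, drop = FALSE], na.rm = TRUE)
  overlap <- regionA[1] < regionB[2] && regionB[1] < regionA[2]
  if (overlap)
    warning("regions overlap; mean includes within-overlap pairs")
  attr(val, "overlapFlag") <- overlap
  val
}

#' Sliding-window region-pair quantification
#'
#' Mean obs/exp between a fixed region A and a series of windows tiling
#' `c(from, to)`, as in scanning loop strength relative to a fixed
#' promoter.
#'
#' @param x a [ContactMatrix-class] with obs/exp computed.
#' @param regionA fixed `c(start, end)` region in bp.
#' @param from,to scan interval in bp.
#' @param windowBp window width in bp (default one bin).
#' @return data.frame `start`, `end`, `meanOE`.
#' @export
quantifyRegionSeries <- function(x, regionA, from, to,
                                 windowBp = binSize(x)) {
  starts <- seq(from, to - windowBp, by = windowBp)
  vals <- vapply(starts, function(s) {
    suppressWarnings(as.numeric(quantifyRegionPair(x, regionA,
                                                   c(s, s + windowBp))))
  }, numeric(1))
  data.frame(start = starts, end = starts + windowBp, meanOE = vals)
}

#' Distance-matched random anchor pairs
#'
#' Samples pairs uniformly with the same separation distribution as a
#' query set (sampling separations with replacement), for APA controls.
#'
#' @param x a [ContactMatrix-class] (for the bin range).
#' @param anchorPairs data.frame with 0-based `bin1`, `bin2`.
#' @param nPairs number of pairs to draw (default: size of the query set).
#' @param seed RNG seed.
#' @return data.frame with 0-based `bin1`, `bin2`.
#' @export
randomMatchedPairs <- function(x, anchorPairs, nPairs = nrow(anchorPairs),
                               seed) {
  n <- nbins(x)
  seps <- anchorPairs$bin2 - anchorPairs$bin1
  withSeed(seed, {
    sep <- sample(seps, nPairs, replace = TRUE)
    b1 <- vapply(sep, function(s) sample.int(n - s, 1L) - 1L, integer(1))
    data.frame(bin1 = b1, bin2 = b1 + sep)
  })
}
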