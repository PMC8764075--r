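# Per-distance z-score matrix: contacts at each separation standardized by
# the mean and SD over all pairs at that separation (SD 0 -> z = 0).
distanceZscores <- function(m) {
  n <- nrow(m)
  Z <- matrix(0, n, n)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    v <- m[cbind(i, i + d)]
    mu <- mean(v)
    s <- stats::sd(v)
    z <- if (is.na(s) || s == 0) rep(0, length(v)) else (v - mu) / s
    Z[cbind(i, i + d)] <- z
    Z[cbind(i + d, i)] <- z
  }
  Z
}

#' Insulation profile and boundary strength
#'
#' The insulation score of bin b is the mean distance-stratified z-score of
#' all contacts between the `windowBins` bins to its left and the
#' `windowBins` bins to its right (the square block of contacts crossing
#' b). Boundary strength is minus the insulation score. Bins whose window
#' extends past a chromosome edge are `NA`. Because z-scores are used, the
#' profile is invariant to a global scaling of the counts.
#'
#' @param x a [ContactMatrix-class], typically at 40 kb.
#' @param windowBins flank size in bins (default 5, i.e. 200 kb at 40 kb).
#' @return data.frame with `bin` (0-based), `start`, `score`, `strength`.
#' @export
insulationProfile <- function(x, windowBins = 5L) {
  if (windowBins < 1) stop("windowBins must be >= 1")
  m <- contactCounts(x)
  n <- nrow(m)
  score <- rep(NA_real_, n)
  if (n >= 2 * windowBins + 1) {
    Z <- distanceZscores(m)
    for (b in (windowBins + 1):(n - windowBins)) {
      left <- (b - windowBins):(b - 1)
      right <- (b + 1):(b + windowBins)
      score[b] <- mean(Z[left, right])
    }
  }
  data.frame(bin = seq_len(n) - 1L, start = binTable(x)$start,
             score = score, strength = -score)
}

# Prominence of a local minimum at index i of series s: the smaller of the
# highest values reached walking left/right before hitting a value lower
# than s[i] (chromosome ends count as walls).
minimumProminence <- function(s, i) {
  walk <- function(idx) {
    hi <- -Inf
    for (j in idx) {
      if (is.na(s[j])) break
      if (s[j] < s[i]) break
      hi <- max(hi, s[j])
    }
    hi
  }
  l <- walk(rev(seq_len(i - 1)))
  r <- walk(if (i < length(s)) (i + 1):length(s) else integer(0))
  min(l, r) - s[i]
}

#' Call TAD boundaries from an insulation profile
#'
#' Boundaries are local minima of the insulation score passing a prominence
#' threshold and, optionally, a strength quantile threshold.
#'
#' @param profile output of [insulationProfile()].
#' @param minProminence minimum prominence of the insulation minimum.
#' @param strengthQuantile keep only boundaries whose strength is at or
#'   above this quantile of the per-bin strengths (0 disables).
#' @return data.frame `bin`, `start`, `score`, `strength`, `prominence`
#'   (possibly empty).
#' @export
callBoundaries <- function(profile, minProminence = 0.1,
                           strengthQuantile = 0) {
  s <- profile$score
  n <- length(s)
  idx <- which(!is.na(s))
  cand <- integer(0)
  for (i in idx) {
    lv <- if (i > 1) s[i - 1] else NA
    rv <- if (i < n) s[i + 1] else NA
    if ((is.na(lv) || s[i] < lv) && (is.na(rv) || s[i] <= rv) &&
        !(is.na(lv) && is.na(rv)))
      cand <- c(cand, i)
  }
  if (!length(cand))
    return(data.frame(bin = integer(0), start = numeric(0), score = numeric(0),
                      strength = numeric(0), prominence = numeric(0)))
  prom <- vapply(cand, function(i) minimumProminence(s, i), numeric(1))
  keep <- prom >= minProminence
  if (strengthQuantile > 0) {
    thr <- stats::quantile(profile$strength, strengthQuantile, na.rm = TRUE,
                           names = FALSE)
    keep <- keep & profile$strength[cand] >= thr
  }
  cand <- cand[keep]; prom <- prom[keep]
  data.frame(bin = profile$bin[cand], start = profile$start[cand],
             score = s[cand], strength = -s[cand], prominence = prom)
}

#' Top-k boundaries by cross-stage strength variability
#'
#' Takes the union of per-stage boundary calls, reads each boundary's
#' strength from every stage's insulation profile, and ranks by the
#' standard deviation across stages (raw strengths; row scaling is left to
#' display/clustering). Ties break by ascending genomic coordinate.
#'
#' @param profiles named list (one per stage) of [insulationProfile()]
#'   outputs over the same bins.
#' @param boundaryList list (same names) of [callBoundaries()] outputs.
#' @param k number of boundaries to keep.
#' @return data.frame `bin`, `start`, one strength column per stage, `sd`,
#'   ordered by decreasing SD.
#' @export
topVariableBoundaries <- function(profiles, boundaryList, k = 1000L) {
  stageNames <- names(profiles)
  bins <- sort(unique(unlist(lapply(boundaryList, function(b) b$bin))))
  if (!length(bins))
    return(data.frame(bin = integer(0), start = numeric(0), sd = numeric(0)))
  S <- vapply(stageNames, function(st) {
    p <- profiles[[st]]
    p$strength[match(bins, p$bin)]
  }, numeric(length(bins)))
  S <- matrix(S, nrow = length(bins),
              dimnames = list(NULL, paste0("strength_", stageNames)))
  sds <- apply(S, 1, stats::sd, na.rm = TRUE)
  ord <- order(-sds, bins)
  if (k > length(bins)) {
    warning("k exceeds available boundaries; returning all")
    k <- length(bins)
  }
  sel <- ord[seq_len(k)]
  p1 <- profiles[[1]]
  out <- data.frame(bin = bins[sel], start = p1$start[match(bins[sel], p1$bin)])
  out <- cbind(out, S[sel, , drop = FALSE])
  out$sd <- sds[sel]
  rownames(out) <- NULL
  out
}

# O(1)-per-query domain scorer over a fixed count matrix, via 2D prefix
# sums. Queries are inclusive 1-based bin ranges.
makeDomainScorer <- function(m) {
  n <- nrow(m)
  P <- matrix(0, n + 1L, n + 1L)
  P[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  cd <- cumsum(diag(m))
  rt <- cumsum(rowSums(m))
  at0 <- function(v, i) ifelse(i >= 1, v[pmax(i, 1)], 0)
  # a, b may be vectors (element-wise queries)
  function(a, b) {
    blk <- P[cbind(b + 1L, b + 1L)] - P[cbind(a, b + 1L)] -
      P[cbind(b + 1L, a)] + P[cbind(a, a)]
    dg <- at0(cd, b) - at0(cd, a - 1L)
    intra <- (blk + dg) / 2
    denom <- intra + (at0(rt, b) - at0(rt, a - 1L)) - blk
    ifelse(denom > 0, intra / denom, NA_real_)
  }
}

#' Raw domain score of TADs
#'
#' The domain score of a TAD is the ratio of intra-TAD paired-end tags
#' (both ends inside the TAD) to all TAD paired-end tags (at least one end
#' inside, cis only). It lies in `[0, 1]`; a TAD with no associated counts
#' is `NA`. With `denominator = "chromosome"` the alternative reading
#' (all cis pairs on the chromosome) is used.
#'
#' @param x a [ContactMatrix-class].
#' @param tadTable data.frame `start`, `end` in bp (0-based half-open),
#'   on this chromosome.
#' @param denominator `"tad"` (default: pairs with >= 1 end in the TAD) or
#'   `"chromosome"` (all cis pairs).
#' @return numeric vector of scores, one per TAD.
#' @export
domainScore <- function(x, tadTable, denominator = c("tad", "chromosome")) {
  denominator <- match.arg(denominator)
  m <- contactCounts(x)
  bs <- binSize(x)
  n <- nrow(m)
  scorer <- makeDomainScorer(m)
  tot <- pairSum(m)
  vapply(seq_len(nrow(tadTable)), function(i) {
    a <- binOf(tadTable$start[i], bs) + 1L
    b <- min(ceiling(tadTable$end[i] / bs), n)
    if (a > b || a < 1) stop("TAD outside chromosome")
    if (denominator == "tad") {
      scorer(a, b)
    } else {
      blk <- sum(m[a:b, a:b])
      intra <- (blk + sum(diag(m)[a:b])) / 2
      if (tot > 0) intra / tot else NA_real_
    }
  }, numeric(1))
}

#' Normalize domain scores against a randomized-TAD null
#'
#' Per library: (1) each TAD's raw score is divided by the mean score of
#' `nSim` random placements of a same-size TAD uniformly on the same
#' chromosome (with replacement, fully inside the chromosome); (2) the mean
#' over all TADs in the library is subtracted; (3) the per-library score
#' vectors are quantile-normalized across libraries (mean-of-sorted-values
#' reference, ties averaged). Random placements are derived from `seed`
#' per TAD, so all libraries share the same null placements.
#'
#' @param matrices named list of [ContactMatrix-class] libraries over the
#'   same chromosome/bins (stages, or stage replicates).
#' @param tadTable data.frame `start`, `end` in bp.
#' @param nSim number of random placements per TAD.
#' @param seed RNG seed for the placements.
#' @return list with `raw` and `normalized` (TADs x libraries matrices).
#' @export
normalizeDomainScores <- function(matrices, tadTable, nSim = 1000L, seed) {
  nT <- nrow(tadTable)
  libNames <- names(matrices)
  if (is.null(libNames)) libNames <- paste0("lib", seq_along(matrices))
  n <- nbins(matrices[[1]])
  bs <- binSize(matrices[[1]])
  sizes <- vapply(seq_len(nT), function(i) {
    b <- ceiling(tadTable$end[i] / bs) - binOf(tadTable$start[i], bs)
    if (b < 1) stop("degenerate TAD")
    as.integer(b)
  }, integer(1))
  if (any(sizes > n))
    stop("chromosome shorter than a TAD; cannot simulate the null")
  starts <- lapply(seq_len(nT), function(i) {
    withSeed(deriveSeed(seed, paste0("tadnull", i)),
             sample.int(n - sizes[i] + 1L, nSim, replace = TRUE))
  })
  raw <- matrix(NA_real_, nT, length(matrices),
                dimnames = list(NULL, libNames))
  centered <- raw
  for (li in seq_along(matrices)) {
    scorer <- makeDomainScorer(contactCounts(matrices[[li]]))
    rawScores <- vapply(seq_len(nT), function(i) {
      a <- binOf(tadTable$start[i], bs) + 1L
      scorer(a, a + sizes[i] - 1L)
    }, numeric(1))
    nullMean <- vapply(seq_len(nT), function(i) {
      mean(scorer(starts[[i]], starts[[i]] + sizes[i] - 1L), na.rm = TRUE)
    }, numeric(1))
    ratio <- rawScores / nullMean
    raw[, li] <- rawScores
    centered[, li] <- ratio - mean(ratio, na.rm = TRUE)
  }
  normalized <- if (nT >= 2)
    limma::normalizeQuantiles(centered, ties = TRUE) else centered
  dimnames(normalized) <- dimnames(centered)
  list(raw = raw, normalized = normalized)
}

#' Significantly varying features across stages, top-k by variance
#'
#' One-way ANOVA per feature across stage groups (requiring replicates),
#' Benjamini-Hochberg adjustment, selection at `fdrCutoff`, then ranking of
#' the survivors by the variance of the per-stage means, keeping the top
#' `k` (ties break by ascending feature order, i.e. genomic coordinate).
#'
#' @param scoreMatrix features x libraries matrix.
#' @param stageOf factor/character of length `ncol(scoreMatrix)` giving each
#'   library's stage.
#' @param fdrCutoff BH-adjusted significance cutoff (default 0.001).
#' @param k maximum number of features to keep.
#' @return list with `stats` (data.frame `F`, `p`, `fdr`, `stageVar`) and
#'   `selected` (row indices, ranked).
#' @export
variableTads <- function(scoreMatrix, stageOf, fdrCutoff = 0.001, k = 1000L) {
  stageOf <- as.factor(stageOf)
  if (nlevels(stageOf) < 2) stop("need >= 2 stages")
  if (min(table(stageOf)) < 2) stop("need >= 2 replicates per stage for ANOVA")
  res <- anovaBH(scoreMatrix, stageOf)
  stageMeans <- vapply(levels(stageOf), function(s)
    rowMeans(scoreMatrix[, stageOf == s, drop = FALSE], na.rm = TRUE),
    numeric(nrow(scoreMatrix)))
  stageVar <- apply(stageMeans, 1, stats::var)
  surv <- which(!is.na(res$fdr) & res$fdr < fdrCutoff)
  ord <- surv[order(-stageVar[surv], surv)]
  selected <- ord[seq_len(min(k, length(ord)))]
  list(stats = cbind(res, stageVar = stageVar), selected = selected)
}

#' Hierarchical clustering of stage series
#'
#' Rows are optionally z-scaled (constant rows become all-zero), then
#' clustered with Euclidean distance and Ward linkage (`ward.D2`) and the
#' tree is cut to `nClusters`. Deterministic; permuting rows permutes
#' labels identically.
#'
#' @param mat features x stages matrix.
#' @param nClusters number of clusters (>= 2).
#' @param rowScale z-scale rows first (default TRUE).
#' @return integer cluster labels, one per row.
#' @export
clusterStageSeries <- function(mat, nClusters, rowScale = TRUE) {
  if (nClusters < 2) stop("nClusters must be >= 2")
  x <- as.matrix(mat)
  if (rowScale) {
    mu <- rowMeans(x)
    s <- apply(x, 1, stats::sd)
    x <- (x - mu) / ifelse(s > 0, s, 1)
    x[s == 0, ] <- 0
  }
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  stats::cutree(hc, k = min(nClusters, nrow(x)))
}

#' Adjacent-stage log2 fold changes
#'
#' For a 4-stage series v, returns the three values
#' `log2((v[t+1]+eps) / (v[t]+eps))`. If the series contains non-positive
#' values and `shiftPositive` is set, the whole series is first shifted so
#' its minimum is `eps` (normalized domain scores are centered and can be
#' negative).
#'
#' @param v numeric stage series (length >= 2) or a features x stages
#'   matrix (row-wise).
#' @param eps pseudocount (default 1e-6).
#' @param shiftPositive shift series containing non-positive values.
#' @return numeric vector of length `stages - 1`, or a matrix for matrix
#'   input.
#' @export
adjacentStageLfc <- function(v, eps = 1e-6, shiftPositive = TRUE) {
  if (is.matrix(v))
    return(t(apply(v, 1, adjacentStageLfc, eps = eps,
                   shiftPositive = shiftPositive)))
  if (shiftPositive && any(v <= 0, na.rm = TRUE)) v <- v - min(v, na.rm = TRUE)
  log2((v[-1] + eps) / (v[-length(v)] + eps))
}
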