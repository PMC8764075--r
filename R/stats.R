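#' Two-sample Wilcoxon rank-sum test
#'
#' Exact enumeration of all rank-sum assignments when the combined sample
#' size is at most `exactMax` (ties handled by average ranks; the
#' two-sided p is the permutation probability of a rank sum at least as
#' far from its mean as observed). Larger samples use the normal
#' approximation with tie correction and continuity correction. Identical
#' samples give p = 1.
#'
#' @param x,y numeric samples (non-empty).
#' @param exactMax combined-size threshold for exact enumeration
#'   (default 12).
#' @return list with `statistic` (rank sum of `x`), `p.value` and
#'   `method` ("exact" or "normal").
#' @export
wilcoxonRankSum <- function(x, y, exactMax = 12L) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  EW <- nx * (n + 1) / 2
  if (stats::sd(c(x, y)) == 0 || isTRUE(all.equal(max(c(x, y)), min(c(x, y)))))
    return(list(statistic = W, p.value = 1, method = "degenerate"))
  if (n <= exactMax) {
    sets <- utils::combn(n, nx)
    Ws <- colSums(matrix(r[sets], nrow = nx))
    p <- mean(abs(Ws - EW) >= abs(W - EW) - 1e-9)
    return(list(statistic = W, p.value = p, method = "exact"))
  }
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (W - EW - sign(W - EW) * 0.5) / sqrt(sigma2)
  list(statistic = W, p.value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Per-feature one-way ANOVA with Benjamini-Hochberg correction
#'
#' Vectorized one-way fixed-effects ANOVA across group columns for every
#' row of a matrix, with BH step-up adjustment across features. Features
#' with zero total variance have undefined p and are flagged `NA` (with a
#' warning); adjusted values are monotone in the raw p-values.
#'
#' @param mat features x samples matrix.
#' @param groups factor/character of length `ncol(mat)`.
#' @return data.frame with `F`, `p`, `fdr` (one row per feature).
#' @export
anovaBH <- function(mat, groups) {
  mat <- as.matrix(mat)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (min(table(groups)) < 2) stop("need >= 2 values per group")
  k <- nlevels(groups)
  N <- ncol(mat)
  gm <- rowMeans(mat)
  ssb <- 0; ssw <- 0
  for (g in levels(groups)) {
    sub <- mat[, groups == g, drop = FALSE]
    m <- rowMeans(sub)
    ssb <- ssb + ncol(sub) * (m - gm)^2
    ssw <- ssw + rowSums((sub - m)^2)
  }
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  degenerate <- (ssb + ssw) < .Machine$double.eps * N
  if (any(degenerate)) {
    warning(sum(degenerate), " feature(s) with zero total variance skipped")
    Fstat[degenerate] <- NA_real_
    p[degenerate] <- NA_real_
  }
  fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  fdr[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(F = Fstat, p = p, fdr = fdr)
}

#' Classify a four-stage expression trend
#'
#' Computes the three adjacent-stage deltas of the stage means (on the
#' log2(TPM/10+1) scale) and applies a dead-band of width `eps`: deltas
#' within `+/- eps` count as no change. All-no-change is `flat`; positive
#' changes only is `up`; negative only is `down`; both directions is
#' `transient`.
#'
#' @param stageMeans numeric vector of exactly 4 stage means (no NA).
#' @param eps dead-band on the log2 scale (default 0.25).
#' @return one of "up", "down", "transient", "flat".
#' @export
expressionTrend <- function(stageMeans, eps = 0.25) {
  if (length(stageMeans) != 4L || anyNA(stageMeans))
    stop("expressionTrend requires 4 non-missing stage means")
  d <- diff(stageMeans)
  s <- ifelse(d > eps, 1L, ifelse(d < -eps, -1L, 0L))
  if (all(s == 0)) "flat"
  else if (any(s > 0) && !any(s < 0)) "up"
  else if (any(s < 0) && !any(s > 0)) "down"
  else "transient"
}
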