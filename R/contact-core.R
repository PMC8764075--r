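#' Construct a ContactMatrix
#'
#' @param counts full symmetric non-negative matrix of binned cis contacts.
#' @param chrom chromosome name.
#' @param binSize bin size in bp.
#' @param bins optional bin table (`start`, `end`, 0-based half-open);
#'   derived from `binSize` when omitted.
#' @return A [ContactMatrix-class].
#' @export
ContactMatrix <- function(counts, chrom = "chr1", binSize, bins = NULL) {
  if (is.null(bins)) {
    n <- nrow(counts)
    start <- (seq_len(n) - 1) * binSize
    bins <- data.frame(start = start, end = start + binSize)
  }
  methods::new("ContactMatrix", chrom = chrom, binSize = binSize,
               bins = bins, counts = counts)
}

# Knight-Ruiz inner-outer Newton iteration for symmetric matrix balancing
# (conjugate-gradient inner solves). Returns the scaling vector x with
# rowSums(diag(x) %*% A %*% diag(x)) = 1 within tol, or signals
# non-convergence.
krScaling <- function(A, tol = 1e-6, maxIter = 1000L) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  delta <- 0.1; Delta <- 3
  g <- 0.9; etamax <- 0.1; eta <- etamax
  rt <- tol^2
  v <- x * as.vector(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  it <- 0L
  while (rout > rt) {
    it <- it + 1L
    if (it > maxIter) return(NULL)
    k <- 0L; y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1L
      if (k == 1L) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        ind <- which(ap < 0)
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- which(ynew > Delta)
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (k > 200L) break
    }
    x <- x * y
    v <- x * as.vector(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta; eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), 0.5 * tol / max(res_norm, .Machine$double.eps))
  }
  x
}

#' Knight-Ruiz balancing of a contact matrix
#'
#' Filters low-count bins (marginal below a configurable quantile of the
#' non-zero marginals, plus all zero-marginal bins), then runs the
#' Knight-Ruiz Newton-type iteration on the remaining submatrix so that
#' every unfiltered row of `diag(w) M diag(w)` sums to 1 within `tol`.
#' Filtered bins receive `NA` weights.
#'
#' @param x a [ContactMatrix-class].
#' @param filterLowCountQuantile drop bins whose marginal falls strictly
#'   below this quantile of the positive marginals (default 0.05); zero
#'   marginals are always dropped.
#' @param tol convergence tolerance on the row-sum residual.
#' @param maxIter maximum outer Newton iterations.
#' @return the ContactMatrix with the `weights` slot filled.
#' @export
krBalance <- function(x, filterLowCountQuantile = 0.05, tol = 1e-6,
                      maxIter = 1000L) {
  stopifnot(methods::is(x, "ContactMatrix"))
  if (tol <= 0) stop("tol must be > 0")
  m <- contactCounts(x)
  n <- nrow(m)
  marg <- rowSums(m)
  keep <- marg > 0
  if (filterLowCountQuantile > 0 && any(keep)) {
    thr <- stats::quantile(marg[keep], filterLowCountQuantile, names = FALSE)
    keep <- keep & marg >= thr
  }
  w <- rep(NA_real_, n)
  if (sum(keep) >= 2) {
    s <- krScaling(m[keep, keep, drop = FALSE], tol = tol, maxIter = maxIter)
    if (is.null(s))
      stop(sprintf("KR balancing did not converge on %s within %d iterations",
                   chromName(x), maxIter))
    w[keep] <- s
  } else if (sum(keep) == 1) {
    w[keep] <- 1 / sqrt(m[keep, keep])
  }
  x@weights <- w
  methods::validObject(x)
  x
}

#' Balanced contact values
#'
#' `w_i * m_ij * w_j` with `NA` rows/columns for filtered bins; requires
#' [krBalance()] to have been run.
#'
#' @param x a balanced [ContactMatrix-class].
#' @return numeric matrix.
#' @export
balancedCounts <- function(x) {
  w <- balancingWeights(x)
  if (!length(w)) stop("matrix has not been balanced; run krBalance() first")
  outer(w, w) * contactCounts(x)
}

#' Scale a set of libraries to the smallest total count
#'
#' Each matrix is multiplied by `min(total)/total`, so all totals equal the
#' smallest library afterwards and the smallest matrix is unchanged.
#'
#' @param matrices list of [ContactMatrix-class] over identical bins.
#' @return list of scaled ContactMatrix objects (weights and obs/exp slots
#'   are cleared, as they refer to the unscaled counts).
#' @export
normalizeToSmallest <- function(matrices) {
  if (length(matrices) < 2) stop("need at least two matrices")
  b1 <- binTable(matrices[[1]])
  for (m in matrices[-1]) {
    if (!identical(dim(contactCounts(m)), dim(contactCounts(matrices[[1]]))) ||
        !isTRUE(all.equal(binTable(m), b1)))
      stop("matrices must share an identical bin table")
  }
  totals <- vapply(matrices, totalCount, numeric(1))
  target <- min(totals)
  lapply(seq_along(matrices), function(i) {
    x <- matrices[[i]]
    x@counts <- x@counts * (target / totals[i])
    x@weights <- numeric(0)
    x@oe <- NULL
    x
  })
}

#' Distance-decay expectation
#'
#' Mean contact value over all bin pairs at each genomic separation within
#' the chromosome (NA-aware). The expectation is per-chromosome, matching
#' the cis-only analysis.
#'
#' @param x a [ContactMatrix-class].
#' @param use `"balanced"` (requires [krBalance()]; filtered bins excluded)
#'   or `"raw"`. `"auto"` picks balanced when weights exist.
#' @return data.frame with columns `distance` (bp) and `expected`, one row
#'   per separation from 0 to (bins-1) steps.
#' @export
expectedByDistance <- function(x, use = c("auto", "balanced", "raw")) {
  use <- match.arg(use)
  n <- nbins(x)
  if (n == 0) stop("empty matrix")
  if (use == "auto") use <- if (length(balancingWeights(x))) "balanced" else "raw"
  m <- if (use == "balanced") balancedCounts(x) else contactCounts(x)
  expd <- vapply(0:(n - 1), function(d) {
    i <- seq_len(n - d)
    mean(m[cbind(i, i + d)], na.rm = TRUE)
  }, numeric(1))
  data.frame(distance = (0:(n - 1)) * binSize(x), expected = expd)
}

#' Observed/expected transform
#'
#' Divides each contact value by the decay expectation at its separation.
#' Pairs whose expectation is zero or undefined become `NA`; a zero
#' observation over a positive expectation is 0.
#'
#' @param x a [ContactMatrix-class].
#' @param curve decay curve from [expectedByDistance()]; computed from `x`
#'   itself when omitted (so the per-distance mean of obs/exp is 1).
#' @param use which values to transform, matching the curve's source.
#' @return the ContactMatrix with the `oe` slot filled.
#' @export
observedOverExpected <- function(x, curve = NULL,
                                 use = c("auto", "balanced", "raw")) {
  use <- match.arg(use)
  if (use == "auto") use <- if (length(balancingWeights(x))) "balanced" else "raw"
  if (is.null(curve)) curve <- expectedByDistance(x, use = use)
  n <- nbins(x)
  dists <- (0:(n - 1)) * binSize(x)
  if (!all(dists %in% curve$distance))
    stop("decay curve does not cover all distances present in the matrix")
  ev <- curve$expected[match(dists, curve$distance)]
  m <- if (use == "balanced") balancedCounts(x) else contactCounts(x)
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- matrix(ev[D + 1L], n, n)
  oe <- m / E
  oe[!is.finite(oe) & !(is.na(m))] <- NA_real_
  oe[is.na(m)] <- NA_real_
  x@oe <- oe
  x
}

#' Cumulative contact-distance profile and short/long-range split
#'
#' Cumulative fraction of paired counts as a function of genomic distance
#' (distance > 0), plus the fractions of counts falling in the short
#' (0, `shortMax`] and long (`shortMax`, `longMax`] ranges, both relative
#' to all counts within (0, `longMax`].
#'
#' @param x a [ContactMatrix-class] (intended at 10 kb resolution).
#' @param shortMax short-range upper bound in bp (default 2 Mb).
#' @param longMax long-range upper bound in bp (default 10 Mb).
#' @return list with `curve` (data.frame distance/cumFraction),
#'   `shortFraction` and `longFraction`.
#' @export
contactDistanceProfile <- function(x, shortMax = 2e6, longMax = 10e6) {
  n <- nbins(x)
  if (n == 0) stop("empty matrix")
  m <- contactCounts(x)
  perDist <- vapply(1:(n - 1), function(d) {
    i <- seq_len(n - d)
    sum(m[cbind(i, i + d)], na.rm = TRUE)
  }, numeric(1))
  if (sum(perDist) == 0) stop("matrix has no off-diagonal counts")
  dist <- (1:(n - 1)) * binSize(x)
  cum <- cumsum(perDist) / sum(perDist)
  inLong <- dist <= longMax
  denom <- sum(perDist[inLong])
  shortFraction <- if (denom > 0) sum(perDist[dist <= shortMax]) / denom else NA_real_
  longFraction <- if (denom > 0)
    sum(perDist[dist > shortMax & inLong]) / denom else NA_real_
  list(curve = data.frame(distance = dist, cumFraction = cum),
       shortFraction = shortFraction, longFraction = longFraction)
}
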