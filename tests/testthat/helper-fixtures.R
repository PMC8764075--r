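# Shared in-code fixtures for the test suite.

# Small genome used by most synthetic tests.
tinyGenome <- function(len = 20e6, bin = 40e3, genes = 200, seed = 1) {
  simulateGenome(1, len, bin, genes, seed = seed)
}

# Symmetric matrix from an upper-triangle specification.
symFromUpper <- function(n, entries) {
  m <- matrix(0, n, n)
  for (e in entries) m[e[1], e[2]] <- m[e[2], e[1]] <- e[3]
  m
}

# Deterministic two-block matrix: within-block value `hi`, between `lo`.
twoBlockMatrix <- function(n1, n2, hi = 10, lo = 1) {
  n <- n1 + n2
  m <- matrix(lo, n, n)
  m[seq_len(n1), seq_len(n1)] <- hi
  m[n1 + seq_len(n2), n1 + seq_len(n2)] <- hi
  m
}

# Independent fixed-point oracle for symmetric matrix balancing: iterate
# w <- w / sqrt(rowSums(diag(w) A diag(w))) to machine precision.
krFixedPointOracle <- function(A, iter = 10000, tol = 1e-12) {
  w <- rep(1, nrow(A))
  for (i in seq_len(iter)) {
    r <- as.vector((w * A) %*% w)
    wNew <- w / sqrt(r)
    if (max(abs(wNew - w)) < tol) return(wNew)
    w <- wNew
  }
  w
}

# Brute-force insulation oracle: z-scores per separation, then the mean of
# the crossing block, by direct enumeration.
insulationOracle <- function(m, w) {
  n <- nrow(m)
  Z <- matrix(NA_real_, n, n)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    v <- m[cbind(i, i + d)]
    s <- stats::sd(v)
    z <- if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    Z[cbind(i, i + d)] <- z
    Z[cbind(i + d, i)] <- z
  }
  sapply(seq_len(n), function(b) {
    if (b - w < 1 || b + w > n) return(NA_real_)
    mean(Z[(b - w):(b - 1), (b + 1):(b + w)])
  })
}

# Brute-force domain-score oracle over all bin pairs.
domainScoreOracle <- function(m, a, b) {
  n <- nrow(m)
  intra <- 0; atLeast <- 0
  for (i in seq_len(n)) for (j in i:n) {
    inI <- i >= a && i <= b
    inJ <- j >= a && j <= b
    if (inI && inJ) intra <- intra + m[i, j]
    if (inI || inJ) atLeast <- atLeast + m[i, j]
  }
  if (atLeast == 0) NA_real_ else intra / atLeast
}

# Brute-force BH step-up adjustment.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# Two-sided permutation p-value for the rank-sum statistic by full
# enumeration (independent of the package implementation).
wilcoxPermOracle <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  EW <- nx * (n + 1) / 2
  sets <- utils::combn(n, nx)
  Ws <- apply(sets, 2, function(s) sum(r[s]))
  mean(abs(Ws - EW) >= abs(W - EW) - 1e-9)
}
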