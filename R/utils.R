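# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards. All stochastic entry points route through this
# so that a given (config, seed) is reproducible without clobbering the
# session RNG.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number")
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Derive a child seed from a base seed and a label, deterministically and
# within 32-bit integer range (polynomial rolling hash over the label,
# folded with the seed).
deriveSeed <- function(seed, label) {
  h <- 0
  for (b in utf8ToInt(paste0(label))) h <- (h * 31 + b) %% (2^31 - 1)
  as.integer((as.numeric(seed) + h) %% (2^31 - 1))
}

# Short stable hex hash of a character scalar (polynomial rolling hash);
# used for config hashes in run manifests.
fnvHash <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

# Number of bins covering `length` bp at `binSize` (last partial bin kept).
nBinsFor <- function(length, binSize) as.integer(ceiling(length / binSize))

# Bin table (0-based half-open) for one chromosome.
makeBinTable <- function(length, binSize) {
  n <- nBinsFor(length, binSize)
  start <- (seq_len(n) - 1) * binSize
  data.frame(start = start, end = pmin(start + binSize, length))
}

# 0-based bin index of a bp position.
binOf <- function(pos, binSize) as.integer(floor(pos / binSize))

# Upper-triangle (incl. diagonal) sum of a full symmetric matrix, i.e. the
# number of pairs counted once.
pairSum <- function(m) (sum(m) + sum(diag(m))) / 2
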