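#' @include AllGenerics.R
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' ContactMatrix: binned cis Hi-C contacts for one chromosome
#'
#' Symmetric, non-negative binned contact counts for a single chromosome,
#' with the bin table (0-based half-open coordinates), optional Knight-Ruiz
#' balancing weights (NA for filtered bins) and an optional observed/expected
#' transform. Counts are stored as a full symmetric dense matrix; all
#' operations treat the matrix as cis-only.
#'
#' @slot chrom chromosome name.
#' @slot binSize bin size in bp.
#' @slot bins data.frame with columns `start`, `end` (0-based half-open bp).
#' @slot counts symmetric numeric matrix of contact counts (raw or scaled).
#' @slot weights per-bin balancing weights, `NA` for filtered bins;
#'   length 0 when the matrix has not been balanced.
#' @slot oe observed/expected matrix, or `NULL` before
#'   [observedOverExpected()] has been applied.
#'
#' @seealso [ContactMatrix()], [krBalance()], [observedOverExpected()]
#' @export
setClass("ContactMatrix",
  slots = c(
    chrom = "character",
    binSize = "numeric",
    bins = "data.frame",
    counts = "matrix",
    weights = "numeric",
    oe = "matrixOrNULL"
  ),
  prototype = list(weights = numeric(0), oe = NULL)
)

setValidity("ContactMatrix", function(object) {
  msg <- character(0)
  n <- nrow(object@counts)
  if (length(object@chrom) != 1L) msg <- c(msg, "chrom must be a single name")
  if (length(object@binSize) != 1L || object@binSize <= 0)
    msg <- c(msg, "binSize must be a single positive number")
  if (ncol(object@counts) != n) msg <- c(msg, "counts must be square")
  if (nrow(object@bins) != n) msg <- c(msg, "bin table must match matrix dimension")
  if (n > 0) {
    if (any(object@counts < 0, na.rm = TRUE)) msg <- c(msg, "counts must be non-negative")
    if (max(abs(object@counts - t(object@counts)), na.rm = TRUE) > 1e-8)
      msg <- c(msg, "counts must be symmetric")
  }
  if (length(object@weights) && length(object@weights) != n)
    msg <- c(msg, "weights length must equal bin count")
  if (length(object@weights) && any(!is.na(object@weights) & object@weights <= 0))
    msg <- c(msg, "defined weights must be positive")
  if (!is.null(object@oe) && (nrow(object@oe) != n || ncol(object@oe) != n))
    msg <- c(msg, "oe matrix must match counts dimension")
  if (length(msg)) msg else TRUE
})

#' GenomeModel: coordinate frame for the synthetic genome
#'
#' Chromosome names and lengths, the working bin size, and gene records
#' (TSS positions). The last partial bin of each chromosome is kept.
#'
#' @slot chromLengths named numeric vector of chromosome lengths (bp).
#' @slot binSize working bin size (bp).
#' @slot genes data.frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
setClass("GenomeModel",
  slots = c(
    chromLengths = "numeric",
    binSize = "numeric",
    genes = "data.frame"
  )
)

setValidity("GenomeModel", function(object) {
  msg <- character(0)
  if (is.null(names(object@chromLengths)) || any(object@chromLengths <= 0))
    msg <- c(msg, "chromLengths must be a named vector of positive lengths")
  if (length(object@binSize) != 1L || object@binSize <= 0)
    msg <- c(msg, "binSize must be a single positive number")
  g <- object@genes
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(g))) {
    msg <- c(msg, "genes must have gene_id, chrom, tss, strand")
  } else if (nrow(g)) {
    if (!all(g$chrom %in% names(object@chromLengths)))
      msg <- c(msg, "gene chrom not in chromLengths")
    else if (any(g$tss < 0 | g$tss >= object@chromLengths[g$chrom]))
      msg <- c(msg, "TSS outside chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' ArchitectureTruth: planted multi-stage genome architecture
#'
#' Ground-truth record of the structures the synthetic generator plants:
#' per-stage A/B compartment labels on 100 kb bins, a TAD partition tiling
#' each chromosome with per-stage intra-TAD enrichment factors, loops with
#' per-stage strength multipliers and a trajectory class, enhancer/promoter
#' elements with per-stage mark intensities, and TF occupancy flags. The
#' whole object round-trips through JSON ([writeTruth()], [readTruth()]),
#' so every planted structure is recoverable from the truth file alone.
#'
#' @slot stages ordered stage names (the analysis assumes four).
#' @slot compartmentBinSize bin size (bp) of the compartment labels.
#' @slot compartments list per chromosome of stage x bin character matrices
#'   with entries "A"/"B".
#' @slot tadTable data.frame `chrom`, `start`, `end` (bp, 0-based half-open),
#'   tiling each chromosome.
#' @slot tadEnrichment numeric matrix, TADs x stages, intra-TAD contact
#'   enrichment factors (1 = none).
#' @slot loopTable data.frame `chrom`, `anchor1`, `anchor2` (bp start of the
#'   anchor bin at `loopBinSize`), `trajectory` in
#'   increasing/decreasing/ephemeral/stable.
#' @slot loopBinSize bin size (bp) at which loop anchors are defined.
#' @slot loopMultipliers numeric matrix, loops x stages.
#' @slot elementTable data.frame `chrom`, `start`, `end`, `type`
#'   ("promoter"/"enhancer"), `gene_id` (NA for enhancers).
#' @slot markIntensity list per mark of element x stage intensity matrices.
#' @slot tfOccupancy logical matrix, elements x stages.
#' @slot params list of generator parameters (flip fraction, factors, seed).
#' @export
setClass("ArchitectureTruth",
  slots = c(
    stages = "character",
    compartmentBinSize = "numeric",
    compartments = "list",
    tadTable = "data.frame",
    tadEnrichment = "matrix",
    loopTable = "data.frame",
    loopBinSize = "numeric",
    loopMultipliers = "matrix",
    elementTable = "data.frame",
    markIntensity = "list",
    tfOccupancy = "matrix",
    params = "list"
  )
)

setValidity("ArchitectureTruth", function(object) {
  msg <- character(0)
  if (length(object@stages) < 2) msg <- c(msg, "need at least two stages")
  td <- object@tadTable
  if (nrow(td)) {
    for (ch in unique(td$chrom)) {
      d <- td[td$chrom == ch, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      if (any(d$end[-nrow(d)] != d$start[-1]))
        msg <- c(msg, sprintf("TADs do not tile chromosome %s without gaps/overlap", ch))
    }
    if (nrow(object@tadEnrichment) != nrow(td))
      msg <- c(msg, "tadEnrichment rows must match TAD count")
  }
  lt <- object@loopTable
  if (nrow(lt)) {
    if (any(lt$anchor2 <= lt$anchor1))
      msg <- c(msg, "loop anchors must be ordered anchor1 < anchor2")
    if (nrow(object@loopMultipliers) != nrow(lt))
      msg <- c(msg, "loopMultipliers rows must match loop count")
  }
  if (nrow(object@elementTable) &&
      nrow(object@tfOccupancy) != nrow(object@elementTable))
    msg <- c(msg, "tfOccupancy rows must match element count")
  if (length(msg)) msg else TRUE
})

#' @describeIn ContactMatrix-class chromosome name
#' @export
setMethod("chromName", "ContactMatrix", function(x) x@chrom)

#' @describeIn ContactMatrix-class bin size in bp
#' @export
setMethod("binSize", "ContactMatrix", function(x) x@binSize)

#' @describeIn ContactMatrix-class bin table (start/end, 0-based half-open)
#' @export
setMethod("binTable", "ContactMatrix", function(x) x@bins)

#' @describeIn ContactMatrix-class number of bins
#' @export
setMethod("nbins", "ContactMatrix", function(x) nrow(x@counts))

#' @describeIn ContactMatrix-class symmetric count matrix
#' @export
setMethod("contactCounts", "ContactMatrix", function(x) x@counts)

#' @describeIn ContactMatrix-class balancing weights (length 0 if unbalanced)
#' @export
setMethod("balancingWeights", "ContactMatrix", function(x) x@weights)

#' @describeIn ContactMatrix-class observed/expected matrix or NULL
#' @export
setMethod("oeMatrix", "ContactMatrix", function(x) x@oe)

#' @describeIn ContactMatrix-class total cis pair count (upper triangle
#'   including the diagonal, so each pair is counted once)
#' @export
setMethod("totalCount", "ContactMatrix", function(x) {
  m <- x@counts
  (sum(m) + sum(diag(m))) / 2
})

setMethod("show", "ContactMatrix", function(object) {
  cat(sprintf(
    "ContactMatrix: %s, %d bins of %s bp, %.0f cis pairs%s%s\n",
    object@chrom, nrow(object@counts), format(object@binSize, big.mark = ","),
    totalCount(object),
    if (length(object@weights)) ", balanced" else "",
    if (!is.null(object@oe)) ", obs/exp computed" else ""
  ))
})

#' @describeIn GenomeModel-class chromosome lengths (bp)
#' @export
setMethod("chromLengths", "GenomeModel", function(x) x@chromLengths)

#' @describeIn GenomeModel-class bin size (bp)
#' @export
setMethod("binSize", "GenomeModel", function(x) x@binSize)

#' @describeIn GenomeModel-class gene records
#' @export
setMethod("genes", "GenomeModel", function(x) x@genes)

setMethod("show", "GenomeModel", function(object) {
  cat(sprintf(
    "GenomeModel: %d chromosome(s), %s bp bins, %d genes\n",
    length(object@chromLengths), format(object@binSize, big.mark = ","),
    nrow(object@genes)
  ))
})

#' @describeIn ArchitectureTruth-class ordered stage names
#' @export
setMethod("stages", "ArchitectureTruth", function(x) x@stages)

#' @describeIn ArchitectureTruth-class TAD partition table
#' @export
setMethod("tads", "ArchitectureTruth", function(x) x@tadTable)

#' @describeIn ArchitectureTruth-class loop table
#' @export
setMethod("loops", "ArchitectureTruth", function(x) x@loopTable)

#' @describeIn ArchitectureTruth-class enhancer/promoter element table
#' @export
setMethod("elements", "ArchitectureTruth", function(x) x@elementTable)

#' @describeIn ArchitectureTruth-class stage x bin compartment label matrix
#'   for one chromosome
#' @param chrom chromosome name (default: first)
#' @export
setMethod("compartmentLabels", "ArchitectureTruth", function(x, chrom = NULL) {
  if (is.null(chrom)) chrom <- names(x@compartments)[1]
  x@compartments[[chrom]]
})

setMethod("show", "ArchitectureTruth", function(object) {
  cat(sprintf(
    "ArchitectureTruth: %d stages (%s)\n  %d TADs, %d loops, %d elements, flip fraction %.4f\n",
    length(object@stages), paste(object@stages, collapse = " > "),
    nrow(object@tadTable), nrow(object@loopTable), nrow(object@elementTable),
    realizedFlipFraction(object)
  ))
})
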