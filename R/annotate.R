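# GRanges for loop anchors (0-based half-open bp starts -> 1-based ranges).
anchorRanges <- function(loopDf, anchorWidth, which = c("1", "2")) {
  which <- match.arg(which)
  s <- loopDf[[paste0("anchor", which)]]
  GenomicRanges::GRanges(loopDf$chrom,
                         IRanges::IRanges(start = s + 1L, end = s + anchorWidth))
}

#' Build the regulatory annotation (promoters and distal enhancers)
#'
#' Promoters are TSS +/- `promoterHalfWidth` windows (one per gene);
#' enhancers are the H3K27ac peaks that do not touch any promoter window
#' (whole-peak exclusion: a peak overlapping a promoter window by even
#' 1 bp is dropped entirely, not trimmed). Enhancers and promoters are
#' therefore disjoint by construction.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `tss` (0-based bp),
#'   `strand`.
#' @param h3k27acPeaks GRanges of H3K27ac peaks.
#' @param promoterHalfWidth half-width of the promoter window (default
#'   5 kb).
#' @return list with `promoters` (GRanges, `gene_id` column) and
#'   `enhancers` (GRanges).
#' @export
buildAnnotation <- function(genes, h3k27acPeaks, promoterHalfWidth = 5e3) {
  promoters <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(1, genes$tss - promoterHalfWidth + 1L),
                     end = genes$tss + promoterHalfWidth),
    gene_id = genes$gene_id)
  hit <- GenomicRanges::countOverlaps(h3k27acPeaks, promoters) > 0
  list(promoters = promoters, enhancers = h3k27acPeaks[!hit])
}

#' Classify interactions as E-E, E-P, P-P or other
#'
#' Each anchor is labelled `P` if it overlaps any promoter window, else
#' `E` if it overlaps any enhancer, else `other` (promoter precedence
#' keeps the classes a partition when an anchor touches both). The
#' interaction class follows from the two anchor labels; interactions with
#' any `other` anchor are classed `other`.
#'
#' @param loopDf data.frame with `chrom`, `anchor1`, `anchor2` (bp starts).
#' @param annotation output of [buildAnnotation()].
#' @param anchorWidth anchor width in bp (the loop resolution).
#' @return `loopDf` with added `anchor1Label`, `anchor2Label`, `class`.
#' @export
classifyInteractions <- function(loopDf, annotation, anchorWidth) {
  lab <- function(gr) {
    p <- GenomicRanges::countOverlaps(gr, annotation$promoters) > 0
    e <- GenomicRanges::countOverlaps(gr, annotation$enhancers) > 0
    ifelse(p, "P", ifelse(e, "E", "other"))
  }
  l1 <- lab(anchorRanges(loopDf, anchorWidth, "1"))
  l2 <- lab(anchorRanges(loopDf, anchorWidth, "2"))
  cls <- ifelse(l1 == "other" | l2 == "other", "other",
                ifelse(l1 == "P" & l2 == "P", "P-P",
                       ifelse(l1 == "E" & l2 == "E", "E-E", "E-P")))
  loopDf$anchor1Label <- l1
  loopDf$anchor2Label <- l2
  loopDf$class <- cls
  loopDf
}

#' TF engagement of E-P interactions
#'
#' An E-P interaction is TF-engaged iff a TF peak overlaps at least one
#' anchor; the subtype records whether occupancy falls on the promoter
#' anchor, the enhancer anchor, or both. With `elementRestricted`, TF
#' occupancy must fall on the promoter/enhancer intervals inside the
#' anchor rather than anywhere in the anchor window.
#'
#' @param loopDf classified interactions (see [classifyInteractions()]);
#'   every row must be class `E-P`.
#' @param tfPeaks GRanges of TF (e.g. RUNX1) peaks.
#' @param annotation output of [buildAnnotation()] (used for
#'   `elementRestricted`).
#' @param anchorWidth anchor width in bp.
#' @param elementRestricted restrict occupancy to the anchors' E/P
#'   elements (default FALSE, matching the anchor-overlap definition).
#' @return `loopDf` with added logical `engaged` and `subtype` in
#'   promoter-only/enhancer-only/both/none.
#' @export
tfEngagement <- function(loopDf, tfPeaks, annotation, anchorWidth,
                         elementRestricted = FALSE) {
  if (!nrow(loopDf)) {
    loopDf$engaged <- logical(0)
    loopDf$subtype <- character(0)
    return(loopDf)
  }
  if (any(loopDf$class != "E-P"))
    stop("tfEngagement() is defined for E-P interactions only")
  a1 <- anchorRanges(loopDf, anchorWidth, "1")
  a2 <- anchorRanges(loopDf, anchorWidth, "2")
  tfOn <- function(gr) {
    if (!elementRestricted)
      return(GenomicRanges::countOverlaps(gr, tfPeaks) > 0)
    # occupancy must hit the element intervals within the anchor
    elems <- c(GenomicRanges::granges(annotation$promoters),
               GenomicRanges::granges(annotation$enhancers))
    onElem <- IRanges::subsetByOverlaps(elems, tfPeaks)
    GenomicRanges::countOverlaps(gr, onElem) > 0
  }
  tf1 <- tfOn(a1)
  tf2 <- tfOn(a2)
  promIs1 <- loopDf$anchor1Label == "P"
  tfProm <- ifelse(promIs1, tf1, tf2)
  tfEnh <- ifelse(promIs1, tf2, tf1)
  loopDf$engaged <- tf1 | tf2
  loopDf$subtype <- ifelse(tfProm & tfEnh, "both",
                           ifelse(tfProm, "promoter-only",
                                  ifelse(tfEnh, "enhancer-only", "none")))
  loopDf
}

#' Per-class TF engagement summary
#'
#' Counts and engaged fractions (TF peak on >= 1 anchor) per interaction
#' class, plus subtype counts for E-P interactions.
#'
#' @param loopDf classified interactions.
#' @param tfPeaks GRanges of TF peaks.
#' @param anchorWidth anchor width in bp.
#' @return list with `byClass` (data.frame `class`, `n`, `nEngaged`,
#'   `fractionEngaged`; NA fraction for empty classes) and `epSubtypes`
#'   (named counts).
#' @export
engagementSummary <- function(loopDf, tfPeaks, anchorWidth) {
  classes <- c("E-E", "E-P", "P-P", "other")
  if (nrow(loopDf)) {
    tf1 <- GenomicRanges::countOverlaps(anchorRanges(loopDf, anchorWidth, "1"),
                                        tfPeaks) > 0
    tf2 <- GenomicRanges::countOverlaps(anchorRanges(loopDf, anchorWidth, "2"),
                                        tfPeaks) > 0
    eng <- tf1 | tf2
  } else eng <- logical(0)
  byClass <- do.call(rbind, lapply(classes, function(cl) {
    idx <- which(loopDf$class == cl)
    data.frame(class = cl, n = length(idx), nEngaged = sum(eng[idx]),
               fractionEngaged = if (length(idx)) mean(eng[idx]) else NA_real_)
  }))
  ep <- loopDf[loopDf$class == "E-P", , drop = FALSE]
  subtypes <- c(`promoter-only` = 0L, `enhancer-only` = 0L, both = 0L,
                none = 0L)
  if (nrow(ep) && !is.null(ep$subtype)) {
    tb <- table(factor(ep$subtype, levels = names(subtypes)))
    subtypes[] <- as.integer(tb)
  }
  list(byClass = byClass, epSubtypes = subtypes)
}

#' Assign genes to interactions by TSS-to-anchor distance
#'
#' A gene is assigned to an interaction iff the minimum distance from its
#' TSS to either anchor interval is at most `maxDist` (0 when the TSS lies
#' inside an anchor).
#'
#' @param loopDf data.frame with `chrom`, `anchor1`, `anchor2` (bp starts).
#' @param genes data.frame with `gene_id`, `chrom`, `tss`.
#' @param anchorWidth anchor width in bp.
#' @param maxDist maximum TSS-to-anchor distance (default 20 kb).
#' @return data.frame `loop`, `gene_id`, `distance` (long form; one row
#'   per assignment).
#' @export
assignGenes <- function(loopDf, genes, anchorWidth, maxDist = 20e3) {
  out <- list()
  for (r in seq_len(nrow(loopDf))) {
    g <- genes[genes$chrom == loopDf$chrom[r], , drop = FALSE]
    if (!nrow(g)) next
    dTo <- function(a0) {
      lo <- a0; hi <- a0 + anchorWidth
      ifelse(g$tss >= lo & g$tss < hi, 0,
             pmin(abs(g$tss - hi + 1), abs(lo - g$tss)))
    }
    d <- pmin(dTo(loopDf$anchor1[r]), dTo(loopDf$anchor2[r]))
    hit <- which(d <= maxDist)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(loop = r,
                                            gene_id = g$gene_id[hit],
                                            distance = d[hit])
  }
  if (!length(out))
    return(data.frame(loop = integer(0), gene_id = character(0),
                      distance = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
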