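#' Write a ContactMatrix as bins + triplet TSV
#'
#' The bins table has columns `chrom`, `start`, `end` (0-based half-open);
#' the triplet file has `bin1_id`, `bin2_id`, `count` with 0-based bin ids,
#' upper triangle only (bin1_id <= bin2_id), zero pixels omitted.
#'
#' @param x a [ContactMatrix-class].
#' @param binsPath,tripletsPath output paths.
#' @export
writeContactMatrix <- function(x, binsPath, tripletsPath) {
  bins <- cbind(chrom = chromName(x), binTable(x))
  utils::write.table(bins, binsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  m <- contactCounts(x)
  up <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  trip <- data.frame(bin1_id = up[, 1] - 1L, bin2_id = up[, 2] - 1L,
                     count = m[up])
  trip <- trip[order(trip$bin1_id, trip$bin2_id), ]
  utils::write.table(trip, tripletsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(binsPath, tripletsPath))
}

#' Read a ContactMatrix from bins + triplet TSV
#'
#' @param binsPath,tripletsPath paths written by [writeContactMatrix()].
#' @return A [ContactMatrix-class].
#' @export
readContactMatrix <- function(binsPath, tripletsPath) {
  bins <- utils::read.table(binsPath, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (length(unique(bins$chrom)) != 1L)
    stop("bins table must cover a single chromosome")
  trip <- utils::read.table(tripletsPath, header = TRUE, sep = "\t")
  n <- nrow(bins)
  m <- matrix(0, n, n)
  if (nrow(trip)) {
    if (any(trip$bin1_id < 0 | trip$bin2_id >= n))
      stop("triplet bin ids outside the bin table")
    i <- trip$bin1_id + 1L; j <- trip$bin2_id + 1L
    m[cbind(i, j)] <- trip$count
    m[cbind(j, i)] <- trip$count
  }
  methods::new("ContactMatrix", chrom = bins$chrom[1],
               binSize = max(bins$end - bins$start),
               bins = bins[, c("start", "end")], counts = m)
}

#' Serialize a planted truth to JSON
#'
#' Every planted structure is recoverable from the file alone;
#' [readTruth()] inverts this exactly.
#'
#' @param truth an [ArchitectureTruth-class].
#' @param path output path.
#' @export
writeTruth <- function(truth, path) {
  x <- list(
    stages = truth@stages,
    compartmentBinSize = truth@compartmentBinSize,
    compartments = truth@compartments,
    tadTable = truth@tadTable,
    tadEnrichment = truth@tadEnrichment,
    loopTable = truth@loopTable,
    loopBinSize = truth@loopBinSize,
    loopMultipliers = truth@loopMultipliers,
    elementTable = truth@elementTable,
    markIntensity = truth@markIntensity,
    tfOccupancy = truth@tfOccupancy,
    params = truth@params
  )
  jsonlite::write_json(x, path, digits = NA, auto_unbox = FALSE,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' Read a planted truth back from JSON
#'
#' @param path file written by [writeTruth()].
#' @return An [ArchitectureTruth-class].
#' @export
readTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fixdf <- function(d) { d <- as.data.frame(d); rownames(d) <- NULL; d }
  methods::new("ArchitectureTruth",
               stages = x$stages,
               compartmentBinSize = x$compartmentBinSize,
               compartments = lapply(x$compartments, as.matrix),
               tadTable = fixdf(x$tadTable),
               tadEnrichment = as.matrix(x$tadEnrichment),
               loopTable = fixdf(x$loopTable),
               loopBinSize = x$loopBinSize,
               loopMultipliers = as.matrix(x$loopMultipliers),
               elementTable = fixdf(x$elementTable),
               markIntensity = lapply(x$markIntensity, as.matrix),
               tfOccupancy = as.matrix(x$tfOccupancy),
               params = x$params)
}

#' Write peaks as BED6 with the signal in the score column
#'
#' @param gr a GRanges with a numeric `score` column.
#' @param path output path.
#' @export
writePeaksBed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (length(gr)) sprintf("peak%05d", seq_along(gr)) else character(0),
    score = if (length(gr)) S4Vectors::mcols(gr)$score else numeric(0),
    strand = rep(".", length(gr))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of peaks into GRanges
#'
#' Uses `rtracklayer` for the standard format; the score column (BED
#' column 5) is kept as the peak signal.
#'
#' @param path BED file.
#' @return GRanges with a `score` column.
#' @export
readPeaksBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(S4Vectors::mcols(gr)$score))
    S4Vectors::mcols(gr)$score <- rep(0, length(gr))
  gr
}

#' Write a coverage track as bedGraph
#'
#' @param gr GRanges with per-bp read density in `score`.
#' @param path output path.
#' @export
writeBedGraph <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph file.
#' @return GRanges with `score`.
#' @export
readBedGraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' Write loops as BEDPE (0-based half-open anchors)
#'
#' @param loopDf data.frame with `chrom`, `anchor1`, `anchor2` (bp starts)
#'   and any extra columns, plus an anchor width.
#' @param anchorWidth anchor width in bp.
#' @param path output path.
#' @export
writeLoopsBedpe <- function(loopDf, anchorWidth, path) {
  extra <- setdiff(names(loopDf), c("chrom", "anchor1", "anchor2"))
  df <- data.frame(
    chrom1 = loopDf$chrom, start1 = loopDf$anchor1,
    end1 = loopDf$anchor1 + anchorWidth,
    chrom2 = loopDf$chrom, start2 = loopDf$anchor2,
    end2 = loopDf$anchor2 + anchorWidth,
    loopDf[, extra, drop = FALSE]
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the single-cell expression table
#'
#' TSV, genes x cells, with a header row of cell ids and a second header
#' row of stage labels.
#'
#' @param expr genes x cells matrix (log2(TPM/10+1)).
#' @param cellStage stage label per cell.
#' @param path output path.
#' @export
writeExpressionTable <- function(expr, cellStage, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(expr)), collapse = "\t"), con)
  writeLines(paste(c("stage", cellStage), collapse = "\t"), con)
  utils::write.table(cbind(gene_id = rownames(expr), as.data.frame(expr)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
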