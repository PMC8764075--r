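#' Simulate a genome coordinate frame
#'
#' Creates chromosome(s) of the requested length, a working bin size, and
#' gene records with TSS positions placed uniformly at random. The last
#' partial bin of a chromosome is kept.
#'
#' @param nChroms number of chromosomes (named chr1, chr2, ...).
#' @param chromLength chromosome length in bp (recycled across chromosomes).
#' @param binSize working bin size in bp.
#' @param nGenes total number of genes, distributed across chromosomes
#'   proportionally to length.
#' @param seed RNG seed (required; the model is reproducible for a fixed
#'   seed).
#' @return A [GenomeModel-class] object.
#' @examples
#' gm <- simulateGenome(1, 20e6, 40e3, 200, seed = 1)
#' nBins <- ceiling(chromLengths(gm) / binSize(gm))  # 500
#' @export
simulateGenome <- function(nChroms = 1L, chromLength = 20e6, binSize = 40e3,
                           nGenes = 200L, seed) {
  if (nChroms < 1 || any(chromLength <= 0) || binSize <= 0 || nGenes < 1)
    stop("nChroms, chromLength, binSize and nGenes must all be positive")
  lens <- rep_len(chromLength, nChroms)
  names(lens) <- paste0("chr", seq_len(nChroms))
  withSeed(seed, {
    chrom <- sample(names(lens), nGenes, replace = TRUE, prob = lens)
    tss <- floor(runif(nGenes) * lens[chrom])
    strand <- sample(c("+", "-"), nGenes, replace = TRUE)
    g <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(nGenes)),
      chrom = chrom, tss = as.numeric(tss), strand = strand,
      stringsAsFactors = FALSE
    )
    g <- g[order(g$chrom, g$tss), ]
    rownames(g) <- NULL
    methods::new("GenomeModel", chromLengths = lens, binSize = binSize,
                 genes = g)
  })
}

# Partition n bins into blocks with lengths drawn uniformly from
# minLen..maxLen (last block truncated).
sampleBlocks <- function(n, minLen, maxLen) {
  lens <- integer(0)
  tot <- 0L
  while (tot < n) {
    l <- sample(minLen:maxLen, 1L)
    lens <- c(lens, min(l, n - tot))
    tot <- tot + lens[length(lens)]
  }
  lens
}

# Canonical per-stage strength multipliers for the four loop trajectory
# classes (columns = stages 1..4).
loopTrajectoryMultipliers <- function(trajectory) {
  switch(trajectory,
    increasing = c(1, 2, 3.5, 5),
    decreasing = c(5, 3.5, 2, 1),
    ephemeral  = c(1, 4, 4, 1),
    stable     = c(3, 3, 3, 3),
    stop("unknown trajectory class: ", trajectory)
  )
}

#' Simulate multi-stage genome architecture (the planted truth)
#'
#' Plants, for each stage, A/B compartment labels on 100 kb bins (a fixed
#' fraction of bins flips label along the stage series), a TAD partition
#' tiling each chromosome with per-stage intra-TAD enrichment, loops between
#' enhancer/promoter elements with trajectory-classed strength multipliers,
#' per-stage histone-mark intensities on the elements, and TF occupancy
#' flags arranged so that a fixed fraction of enhancer-promoter loops is
#' TF-engaged.
#'
#' Compartment blocks are labelled A where gene density is high, so the
#' orientation convention used by [callCompartments()] holds on the planted
#' data. The realized flip fraction equals `round(flipFraction * bins)`
#' bins over the total, i.e. matches the request to within one bin quantum.
#'
#' @param genome a [GenomeModel-class].
#' @param stageCount number of stages; the flip taxonomy and trend logic
#'   assume 4.
#' @param flipFraction fraction of 100 kb bins whose A/B label changes
#'   across the stage series.
#' @param tadCount TADs per chromosome.
#' @param loopCount loops per chromosome.
#' @param trajectoryMix named probabilities over
#'   increasing/decreasing/ephemeral/stable; must sum to 1.
#' @param compartmentFactor checkerboard factor c: same-label 100 kb bin
#'   pairs have contacts scaled by c, different-label by 1/c.
#' @param nEnhancers enhancer elements per chromosome, placed at least
#'   25 kb from any TSS so enhancer anchors never overlap promoter windows.
#' @param epEngagedFraction fraction of enhancer-promoter loops whose
#'   anchors carry TF occupancy.
#' @param tadTrendMix named probabilities over flat/increasing/decreasing
#'   intra-TAD enrichment trends.
#' @param loopBinSize resolution (bp) at which loop anchors are defined.
#' @param minLoopSeparation,maxLoopSeparation anchor separation range (bp).
#' @param seed RNG seed.
#' @return An [ArchitectureTruth-class] object.
#' @export
simulateArchitecture <- function(genome, stageCount = 4L, flipFraction = 0.10,
                                 tadCount = 10L, loopCount = 100L,
                                 trajectoryMix = c(increasing = 0.3,
                                                   decreasing = 0.3,
                                                   ephemeral = 0.2,
                                                   stable = 0.2),
                                 compartmentFactor = 1.5,
                                 nEnhancers = 150L,
                                 epEngagedFraction = 0.40,
                                 tadTrendMix = c(flat = 0.5, increasing = 0.25,
                                                 decreasing = 0.25),
                                 loopBinSize = 10e3,
                                 minLoopSeparation = 100e3,
                                 maxLoopSeparation = 1e6,
                                 seed) {
  stopifnot(methods::is(genome, "GenomeModel"))
  if (flipFraction < 0 || flipFraction > 1) stop("flipFraction must be in [0,1]")
  if (abs(sum(trajectoryMix) - 1) > 1e-8) stop("trajectoryMix must sum to 1")
  cbs <- 100e3
  lens <- chromLengths(genome)
  if (any(tadCount > floor(lens / 400e3)))
    stop("tadCount too large for chromosome length")
  stageNames <- if (stageCount == 4L) c("eAEC", "HEC", "preHSC", "LTHSC")
                else paste0("stage", seq_len(stageCount))
  withSeed(seed, {
    comps <- list()
    tadRows <- list(); tadEnr <- list()
    loopRows <- list(); loopMult <- list()
    elemRows <- list()
    for (ch in names(lens)) {
      len <- lens[[ch]]
      nb <- nBinsFor(len, cbs)
      ## --- compartments: blocks labelled by gene density -----------------
      gd <- tabulate(binOf(genome@genes$tss[genome@genes$chrom == ch], cbs) + 1L,
                     nbins = nb)
      blockLens <- sampleBlocks(nb, 4L, 12L)
      blockId <- rep(seq_along(blockLens), blockLens)
      blockDens <- tapply(gd, blockId, mean)
      lab0 <- ifelse(blockDens[blockId] >= stats::median(blockDens), "A", "B")
      labels <- matrix(rep(lab0, each = stageCount), nrow = stageCount)
      ## --- flips: contiguous segments totalling round(f * nb) bins -------
      target <- round(flipFraction * nb)
      flipped <- logical(nb)
      guard <- 0L
      while (sum(flipped) < target && guard < 10000L) {
        guard <- guard + 1L
        segLen <- min(sample(2:5, 1L), target - sum(flipped))
        start <- sample(seq_len(nb - segLen + 1L), 1L)
        idx <- start:(start + segLen - 1L)
        if (any(flipped[idx])) next
        flipped[idx] <- TRUE
        base <- lab0[start]
        other <- if (base == "A") "B" else "A"
        kind <- sample(c("directional", "transient"), 1L, prob = c(0.7, 0.3))
        if (kind == "directional") {
          t0 <- sample(2:stageCount, 1L)
          seqLab <- c(rep(base, t0 - 1L), rep(other, stageCount - t0 + 1L))
        } else {
          t0 <- sample(2:(stageCount - 1L), 1L)
          seqLab <- rep(base, stageCount)
          seqLab[t0] <- other
        }
        labels[, idx] <- matrix(rep(seqLab, length(idx)), nrow = stageCount)
      }
      comps[[ch]] <- labels
      ## --- TADs tiling the chromosome on a 200 kb grrid ------------------
      grid <- 200e3
      w <- stats::runif(tadCount, 0.5, 1.5)
      edges <- round(cumsum(w) / sum(w) * len / grid) * grid
      edges[tadCount] <- len
      edges <- c(0, edges)
      edges <- edges[!duplicated(edges)]
      tadRows[[ch]] <- data.frame(chrom = ch, start = edges[-length(edges)],
                                  end = edges[-1], stringsAsFactors = FALSE)
      nT <- nrow(tadRows[[ch]])
      trend <- sample(names(tadTrendMix), nT, replace = TRUE, prob = tadTrendMix)
      e <- matrix(NA_real_, nT, stageCount)
      for (i in seq_len(nT)) {
        e[i, ] <- switch(trend[i],
          flat = rep(stats::runif(1, 1.8, 2.6), stageCount),
          increasing = seq(stats::runif(1, 1.5, 1.8), stats::runif(1, 2.6, 3.0),
                           length.out = stageCount),
          decreasing = seq(stats::runif(1, 2.6, 3.0), stats::runif(1, 1.5, 1.8),
                           length.out = stageCount))
      }
      tadEnr[[ch]] <- e
      ## --- elements: promoters at TSS, enhancers away from TSS -----------
      gch <- genome@genes[genome@genes$chrom == ch, ]
      prom <- data.frame(chrom = ch,
                         start = pmax(0, gch$tss - 1000),
                         end = pmin(len, gch$tss + 1000),
                         type = "promoter", gene_id = gch$gene_id,
                         stringsAsFactors = FALSE)
      enh <- matrix(NA_real_, 0, 1)
      pos <- numeric(0)
      guard <- 0L
      while (length(pos) < nEnhancers && guard < 50L * nEnhancers) {
        guard <- guard + 1L
        p <- floor(stats::runif(1) * (len - 1000))
        if (nrow(gch) == 0 || min(abs(gch$tss - p)) >= 25e3) pos <- c(pos, p)
      }
      enh <- data.frame(chrom = ch, start = pos, end = pos + 1000,
                        type = "enhancer", gene_id = NA_character_,
                        stringsAsFactors = FALSE)
      elemRows[[ch]] <- rbind(prom, enh)
      ## --- loops between elements ----------------------------------------
      el <- elemRows[[ch]]
      mid <- (el$start + el$end) / 2
      classPick <- c("E-P", "E-E", "P-P")
      classProb <- c(0.5, 0.25, 0.25)
      taken <- matrix(NA_real_, 0, 2)
      lrows <- list()
      tries <- 0L
      while (length(lrows) < loopCount && tries < 200L * loopCount) {
        tries <- tries + 1L
        cls <- sample(classPick, 1L, prob = classProb)
        t1 <- if (substr(cls, 1, 1) == "E") "enhancer" else "promoter"
        t2 <- if (substr(cls, 3, 3) == "E") "enhancer" else "promoter"
        i <- sample(which(el$type == t1), 1L)
        cand <- which(el$type == t2 &
                        abs(mid - mid[i]) >= minLoopSeparation &
                        abs(mid - mid[i]) <= maxLoopSeparation)
        cand <- setdiff(cand, i)
        if (!length(cand)) next
        j <- if (length(cand) == 1L) cand else sample(cand, 1L)
        b1 <- binOf(min(mid[i], mid[j]), loopBinSize)
        b2 <- binOf(max(mid[i], mid[j]), loopBinSize)
        if (b2 - b1 < ceiling(minLoopSeparation / loopBinSize)) next
        # keep planted loop pixels Chebyshev-separated so detected loops
        # never merge across distinct planted loops, and anchor bins
        # exclusive so TF occupancy on one loop cannot engage another
        if (nrow(taken) &&
            (any(pmax(abs(taken[, 1] - b1), abs(taken[, 2] - b2)) < 3) ||
               any(c(b1, b2) %in% taken))) next
        taken <- rbind(taken, c(b1, b2))
        ei <- if (mid[i] <= mid[j]) i else j
        ej <- if (mid[i] <= mid[j]) j else i
        lrows[[length(lrows) + 1L]] <- data.frame(
          chrom = ch, anchor1 = b1 * loopBinSize, anchor2 = b2 * loopBinSize,
          class = cls, elem1 = ei, elem2 = ej,
          trajectory = sample(names(trajectoryMix), 1L, prob = trajectoryMix),
          stringsAsFactors = FALSE)
      }
      lt <- do.call(rbind, lrows)
      if (is.null(lt)) lt <- data.frame(chrom = character(0), anchor1 = numeric(0),
                                        anchor2 = numeric(0), class = character(0),
                                        elem1 = integer(0), elem2 = integer(0),
                                        trajectory = character(0))
      loopRows[[ch]] <- lt
      loopMult[[ch]] <- t(vapply(lt$trajectory, loopTrajectoryMultipliers,
                                 numeric(stageCount)))
    }
    tadTable <- do.call(rbind, tadRows); rownames(tadTable) <- NULL
    elementTable <- do.call(rbind, elemRows); rownames(elementTable) <- NULL
    # reindex loop element references into the concatenated element table
    offs <- c(0, cumsum(vapply(elemRows, nrow, integer(1))))
    names(offs) <- c(names(elemRows), "end")
    loopTable <- do.call(rbind, lapply(names(loopRows), function(ch) {
      lt <- loopRows[[ch]]
      if (nrow(lt)) {
        lt$elem1 <- lt$elem1 + offs[[ch]]
        lt$elem2 <- lt$elem2 + offs[[ch]]
      }
      lt
    }))
    rownames(loopTable) <- NULL
    loopMultipliers <- do.call(rbind, loopMult)
    if (is.null(loopMultipliers)) loopMultipliers <- matrix(0, 0, stageCount)
    ## --- TF occupancy: exact engaged fraction of E-P loops ---------------
    nElem <- nrow(elementTable)
    tf <- matrix(FALSE, nElem, stageCount)
    ep <- which(loopTable$class == "E-P")
    nEngaged <- round(epEngagedFraction * length(ep))
    engaged <- if (nEngaged) sample(ep, nEngaged) else integer(0)
    epAnchorElems <- unique(c(loopTable$elem1[ep], loopTable$elem2[ep]))
    for (li in engaged) {
      e1 <- loopTable$elem1[li]; e2 <- loopTable$elem2[li]
      promElem <- if (elementTable$type[e1] == "promoter") e1 else e2
      enhElem <- if (elementTable$type[e1] == "enhancer") e1 else e2
      site <- sample(c("promoter", "enhancer", "both"), 1L,
                     prob = c(0.5, 0.2, 0.3))
      if (site %in% c("promoter", "both")) tf[promElem, ] <- TRUE
      if (site %in% c("enhancer", "both")) tf[enhElem, ] <- TRUE
    }
    # background occupancy only on elements outside every E-P anchor bin,
    # so the planted engaged fraction stays exact at anchor resolution
    elemBin <- paste(elementTable$chrom,
                     binOf((elementTable$start + elementTable$end) / 2,
                           loopBinSize))
    epBins <- character(0)
    if (length(ep))
      epBins <- c(paste(loopTable$chrom[ep],
                        binOf(loopTable$anchor1[ep], loopBinSize)),
                  paste(loopTable$chrom[ep],
                        binOf(loopTable$anchor2[ep], loopBinSize)))
    bg <- setdiff(which(!(elemBin %in% epBins)), epAnchorElems)
    bg <- bg[stats::runif(length(bg)) < 0.05]
    tf[bg, ] <- TRUE
    ## --- mark intensities -------------------------------------------------
    isProm <- elementTable$type == "promoter"
    onset <- ifelse(isProm, 1L, sample(1:3, nElem, replace = TRUE,
                                       prob = c(0.6, 0.25, 0.15)))
    stageMat <- matrix(rep(seq_len(stageCount), each = nElem), nElem)
    active <- stageMat >= onset
    base <- stats::runif(nElem, 2, 8)
    drift <- matrix(stats::runif(nElem * stageCount, 0.8, 1.25), nElem)
    markIntensity <- list(
      H3K27ac = base * drift * active,
      H3K4me1 = ifelse(isProm, 0, 1) * base * drift * active * 0.8,
      H3K4me3 = ifelse(isProm, 1, 0) * (base + 4) * drift,
      H3K27me3 = (stats::runif(nElem) < 0.2) * stats::runif(nElem, 0.5, 2) *
        (!active)
    )
    params <- list(flipFraction = flipFraction, compartmentFactor = compartmentFactor,
                   epEngagedFraction = epEngagedFraction, seed = seed,
                   minLoopSeparation = minLoopSeparation,
                   maxLoopSeparation = maxLoopSeparation,
                   compartmentMinSeparation = 2e6)
    methods::new("ArchitectureTruth",
                 stages = stageNames, compartmentBinSize = cbs,
                 compartments = comps, tadTable = tadTable,
                 tadEnrichment = do.call(rbind, tadEnr),
                 loopTable = loopTable, loopBinSize = loopBinSize,
                 loopMultipliers = loopMultipliers,
                 elementTable = elementTable, markIntensity = markIntensity,
                 tfOccupancy = tf, params = params)
  })
}

#' Realized compartment flip fraction of a planted truth
#'
#' Fraction of compartment bins whose A/B label changes at least once along
#' the stage series, over all chromosomes.
#'
#' @param truth an [ArchitectureTruth-class].
#' @return numeric scalar in `[0, 1]`.
#' @export
realizedFlipFraction <- function(truth) {
  tot <- 0L; flip <- 0L
  for (m in truth@compartments) {
    tot <- tot + ncol(m)
    flip <- flip + sum(apply(m, 2, function(s) length(unique(s)) > 1))
  }
  if (tot == 0) return(NA_real_)
  flip / tot
}
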