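# Parse a bp quantity that may be written as 40000, "40kb" or "2Mb".
parseBp <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.character(x) && length(x) == 1L) {
    m <- regmatches(x, regexec("^([0-9.]+)\\s*([kKmM]?)[bB]?$", x))[[1]]
    if (length(m) == 3L) {
      mult <- switch(tolower(m[3]), k = 1e3, m = 1e6, 1)
      return(as.numeric(m[2]) * mult)
    }
  }
  stop("cannot parse bp quantity: ", x)
}

#' Default pipeline configuration
#'
#' The full default configuration of the four-stage synthetic analysis:
#' stage names, resolutions (5/10/40/100 kb), generator parameters and all
#' module parameters. [validateConfig()] merges user settings over these
#' defaults.
#'
#' @return nested named list.
#' @export
defaultConfig <- function() {
  list(
    stages = c("eAEC", "HEC", "preHSC", "LTHSC"),
    seed = 1L,
    genome = list(nChroms = 1L, chromLength = 20e6, nGenes = 200L),
    resolutions = list(finescale = 5e3, loops = 10e3, domains = 40e3,
                       compartments = 100e3),
    architecture = list(flipFraction = 0.10, tadCount = 10L, loopCount = 60L,
                        compartmentFactor = 1.5, nEnhancers = 150L,
                        epEngagedFraction = 0.40,
                        trajectoryMix = c(increasing = 0.3, decreasing = 0.3,
                                          ephemeral = 0.2, stable = 0.2)),
    hic = list(depthPairs = 2e6, decayExponent = 1.0, replicates = 2L),
    balance = list(filterLowCountQuantile = 0.05, tol = 1e-6, maxIter = 1000L),
    insulation = list(windowBins = 5L, minProminence = 0.1),
    domainScore = list(nSim = 1000L, fdrCutoff = 0.001, topK = 1000L,
                       nClusters = 3L),
    loops = list(minDist = 50e3, maxDist = 2e6, neighborhoodBins = 5L,
                 foldMin = 1.5, pMax = 0.05, apaFlankBins = 5L),
    annotation = list(promoterHalfWidth = 5e3, geneMaxDist = 20e3),
    trend = list(eps = 0.25),
    finescale = list(enabled = TRUE, scanFlank = 200e3)
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Merges the supplied (possibly partial) configuration over
#' [defaultConfig()], normalizes bp quantities given as strings
#' ("40kb" -> 40000), rejects unknown top-level keys, and enforces the
#' structural invariants: exactly four stages (the flip and trend logic is
#' four-stage), positive sizes, and resolutions ordered
#' finescale <= loops <= domains <= compartments.
#'
#' @param config named list (possibly empty).
#' @return the normalized full configuration.
#' @export
validateConfig <- function(config = list()) {
  def <- defaultConfig()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  cfg$resolutions <- lapply(cfg$resolutions, parseBp)
  cfg$genome$chromLength <- parseBp(cfg$genome$chromLength)
  if (length(cfg$stages) != 4L)
    stop("the stage-series logic requires exactly 4 stages")
  r <- cfg$resolutions
  if (any(unlist(r) <= 0)) stop("resolutions must be positive")
  if (!(r$finescale <= r$loops && r$loops <= r$domains &&
        r$domains <= r$compartments))
    stop("contradictory resolutions: need finescale <= loops <= domains <= compartments")
  if (cfg$genome$chromLength <= 0 || cfg$genome$nGenes < 1)
    stop("genome sizes must be positive")
  if (cfg$hic$depthPairs < 0) stop("depthPairs must be >= 0")
  cfg
}

# Simulate, balance and O/E-transform one library.
.simLibrary <- function(genome, truth, stage, binSize, depth, cfg, seedLabel) {
  cm <- simulateContactMatrix(genome, truth, stage = stage,
                              binSize = binSize, depthPairs = depth,
                              decayExponent = cfg$hic$decayExponent,
                              seed = deriveSeed(cfg$seed, seedLabel))
  cm <- krBalance(cm, cfg$balance$filterLowCountQuantile,
                  cfg$balance$tol, cfg$balance$maxIter)
  observedOverExpected(cm)
}

#' Run the full four-stage synthetic analysis
#'
#' Simulates the synthetic genome, architecture, ChIP and expression data,
#' generates stage libraries at each resolution, and runs the complete
#' analysis: compartment calling and flip classification (100 kb),
#' insulation/boundary/domain-score analysis with the randomized-TAD null
#' and ANOVA selection (40 kb), loop detection, CPM strengths and APA
#' (10 kb), enhancer-promoter classification with TF engagement, gene
#' assignment, expression trends, and the short/long-range contact split.
#' All randomness derives from `config$seed`; a rerun with the same
#' configuration produces an identical summary.
#'
#' @param config configuration list (see [validateConfig()]).
#' @param outdir output directory; created if needed. `NULL` skips all
#'   file output and returns the summary invisibly.
#' @return the summary list (invisibly when `outdir` is given).
#' @export
runPipeline <- function(config = list(), outdir = NULL) {
  cfg <- validateConfig(config)
  cfgJson <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  cfgHash <- fnvHash(as.character(cfgJson))
  msg <- function(mod, ...) message(sprintf("[%s] ", mod), ...)
  st <- cfg$stages
  ## ---- synthetic inputs --------------------------------------------------
  msg("simulate", "genome + architecture + chip/expression")
  genome <- simulateGenome(cfg$genome$nChroms, cfg$genome$chromLength,
                           cfg$resolutions$domains, cfg$genome$nGenes,
                           seed = deriveSeed(cfg$seed, "genome"))
  truth <- simulateArchitecture(
    genome, stageCount = 4L,
    flipFraction = cfg$architecture$flipFraction,
    tadCount = cfg$architecture$tadCount,
    loopCount = cfg$architecture$loopCount,
    trajectoryMix = cfg$architecture$trajectoryMix,
    compartmentFactor = cfg$architecture$compartmentFactor,
    nEnhancers = cfg$architecture$nEnhancers,
    epEngagedFraction = cfg$architecture$epEngagedFraction,
    loopBinSize = cfg$resolutions$loops,
    seed = deriveSeed(cfg$seed, "architecture"))
  truth@stages <- st
  chip <- simulateChipExpression(genome, truth,
                                 seed = deriveSeed(cfg$seed, "chip"))
  chrom <- names(chromLengths(genome))[1]
  chromLen <- chromLengths(genome)[[chrom]]
  summary <- list(configHash = cfgHash, seed = cfg$seed, stages = st)
  ## ---- compartments at 100 kb -------------------------------------------
  msg("compartments", "calling A/B per stage at ",
      cfg$resolutions$compartments, " bp")
  nComp <- nBinsFor(chromLen, cfg$resolutions$compartments)
  gd <- tabulate(binOf(genes(genome)$tss[genes(genome)$chrom == chrom],
                       cfg$resolutions$compartments) + 1L, nbins = nComp)
  labelMat <- matrix(NA_character_, 4L, nComp)
  for (s in seq_along(st)) {
    cm <- .simLibrary(genome, truth, s, cfg$resolutions$compartments,
                      cfg$hic$depthPairs, cfg, paste0("comp", s))
    track <- callCompartments(cm, gd)
    labelMat[s, ] <- track$label
  }
  flips <- classifyFlips(labelMat)
  summary$compartments <- list(flipFraction = flips$flipFraction,
                               counts = as.list(flips$counts),
                               classified = flips$classified,
                               plantedFlipFraction = realizedFlipFraction(truth))
  ## ---- domains at 40 kb --------------------------------------------------
  msg("domains", "insulation, boundaries and domain scores")
  nRep <- cfg$hic$replicates
  domLibs <- list()
  for (s in seq_along(st)) for (rp in seq_len(nRep))
    domLibs[[paste0(st[s], "_rep", rp)]] <-
      simulateContactMatrix(genome, truth, stage = s,
                            binSize = cfg$resolutions$domains,
                            depthPairs = cfg$hic$depthPairs,
                            decayExponent = cfg$hic$decayExponent,
                            seed = deriveSeed(cfg$seed, paste0("dom", s, "_", rp)))
  domLibs <- normalizeToSmallest(domLibs) |>
    stats::setNames(paste0(rep(st, each = nRep), "_rep", seq_len(nRep)))
  profiles <- list(); boundaryList <- list()
  for (s in seq_along(st)) {
    profiles[[st[s]]] <- insulationProfile(domLibs[[(s - 1) * nRep + 1L]],
                                           cfg$insulation$windowBins)
    boundaryList[[st[s]]] <- callBoundaries(profiles[[st[s]]],
                                            cfg$insulation$minProminence)
  }
  topBounds <- suppressWarnings(
    topVariableBoundaries(profiles, boundaryList, k = cfg$domainScore$topK))
  pooled <- domLibs[[1]]
  for (i in seq_along(domLibs)[-1]) pooled@counts <- pooled@counts +
    contactCounts(domLibs[[i]])
  consBounds <- callBoundaries(insulationProfile(pooled,
                                                 cfg$insulation$windowBins),
                               cfg$insulation$minProminence)
  edges <- sort(unique(c(0, consBounds$start, chromLen)))
  tadTable <- data.frame(chrom = chrom, start = edges[-length(edges)],
                         end = edges[-1])
  ds <- normalizeDomainScores(domLibs, tadTable,
                              nSim = cfg$domainScore$nSim,
                              seed = deriveSeed(cfg$seed, "tadnull"))
  stageOf <- rep(st, each = nRep)
  vt <- tryCatch(variableTads(ds$normalized, stageOf,
                              cfg$domainScore$fdrCutoff,
                              cfg$domainScore$topK),
                 error = function(e) NULL)
  stageMeans <- vapply(st, function(s)
    rowMeans(ds$normalized[, stageOf == s, drop = FALSE]),
    numeric(nrow(tadTable)))
  clusters <- if (nrow(tadTable) > cfg$domainScore$nClusters)
    clusterStageSeries(stageMeans, cfg$domainScore$nClusters) else
      rep(1L, nrow(tadTable))
  adjWilcox <- vapply(seq_len(3), function(i)
    wilcoxonRankSum(stageMeans[, i], stageMeans[, i + 1])$p.value, numeric(1))
  summary$domains <- list(
    nBoundariesPerStage = lapply(boundaryList, nrow) |> stats::setNames(st),
    nTopVariableBoundaries = nrow(topBounds),
    nConsensusTads = nrow(tadTable),
    nSignificantTads = if (is.null(vt)) NA_integer_ else
      sum(!is.na(vt$stats$fdr) & vt$stats$fdr < cfg$domainScore$fdrCutoff),
    clusterSizes = as.list(table(clusters)),
    adjacentStageWilcoxP = adjWilcox)
  ## ---- loops at 10 kb ----------------------------------------------------
  msg("loops", "detection, CPM and APA")
  loopLibs <- list()
  for (s in seq_along(st))
    loopLibs[[st[s]]] <-
      simulateContactMatrix(genome, truth, stage = s,
                            binSize = cfg$resolutions$loops,
                            depthPairs = cfg$hic$depthPairs,
                            decayExponent = cfg$hic$decayExponent,
                            seed = deriveSeed(cfg$seed, paste0("loop", s)))
  loopLibs <- normalizeToSmallest(loopLibs) |> stats::setNames(st)
  pooledL <- loopLibs[[1]]
  for (i in 2:4) pooledL@counts <- pooledL@counts + contactCounts(loopLibs[[i]])
  pooledL@counts <- round(pooledL@counts)
  called <- detectLoops(pooledL, cfg$loops$minDist, cfg$loops$maxDist,
                        cfg$loops$neighborhoodBins, cfg$loops$foldMin,
                        cfg$loops$pMax)
  cpm <- vapply(st, function(s) loopStrengthCpm(loopLibs[[s]], called),
                numeric(nrow(called)))
  cpm <- matrix(cpm, nrow = nrow(called),
                dimnames = list(NULL, paste0("cpm_", st)))
  apaEnrich <- rep(NA_real_, 4)
  if (nrow(called)) {
    for (s in seq_along(st)) {
      cmS <- observedOverExpected(loopLibs[[s]])
      apaEnrich[s] <- aggregateContacts(cmS, called,
                                        cfg$loops$apaFlankBins)$centerEnrichment
    }
  }
  profile10 <- contactDistanceProfile(loopLibs[[1]])
  shortFrac <- vapply(st, function(s)
    contactDistanceProfile(loopLibs[[s]])$shortFraction, numeric(1))
  ## ---- annotation and integration ---------------------------------------
  msg("annotate", "classification, engagement, genes, trends")
  k27Union <- GenomicRanges::reduce(do.call(
    c, lapply(st, function(s) GenomicRanges::granges(chip$peaks[[s]]$H3K27ac))))
  anno <- buildAnnotation(genes(genome), k27Union,
                          cfg$annotation$promoterHalfWidth)
  tfUnion <- GenomicRanges::reduce(do.call(
    c, lapply(st, function(s) GenomicRanges::granges(chip$tfPeaks[[s]]))))
  classed <- classifyInteractions(called, anno, cfg$resolutions$loops)
  engSum <- engagementSummary(classed, tfUnion, cfg$resolutions$loops)
  ep <- classed[classed$class == "E-P", , drop = FALSE]
  if (nrow(ep))
    ep <- tfEngagement(ep, tfUnion, anno, cfg$resolutions$loops)
  geneAssign <- assignGenes(classed, genes(genome), cfg$resolutions$loops,
                            cfg$annotation$geneMaxDist)
  exprMeans <- vapply(st, function(s)
    rowMeans(chip$expression[, chip$cellStage == s, drop = FALSE]),
    numeric(nrow(chip$expression)))
  trends <- apply(exprMeans, 1, expressionTrend, eps = cfg$trend$eps)
  summary$loops <- list(
    nLoops = nrow(called),
    classCounts = as.list(table(factor(classed$class,
                                       levels = c("E-E", "E-P", "P-P", "other")))),
    epEngagedFraction = engSum$byClass$fractionEngaged[
      engSum$byClass$class == "E-P"],
    epSubtypes = as.list(engSum$epSubtypes),
    apaCenterEnrichment = apaEnrich,
    meanCpmByStage = as.list(colMeans(cpm)),
    shortRangeFractionByStage = as.list(shortFrac),
    nAssignedGenes = length(unique(geneAssign$gene_id)))
  summary$expression <- list(trendCounts = as.list(table(
    factor(trends, levels = c("up", "down", "transient", "flat")))))
  ## ---- finescale region-pair scan ----------------------------------------
  if (isTRUE(cfg$finescale$enabled) && nrow(loops(truth))) {
    msg("finescale", "region-pair scan at ", cfg$resolutions$finescale, " bp")
    inc <- which(loops(truth)$trajectory == "increasing")
    li <- if (length(inc)) inc[1] else 1L
    a1 <- loops(truth)$anchor1[li]
    regionA <- c(a1 - 2.5e3, a1 + 7.5e3)
    scan <- matrix(NA_real_, 0, 0)
    series <- list()
    for (s in seq_along(st)) {
      cmF <- simulateContactMatrix(genome, truth, stage = s,
                                   binSize = cfg$resolutions$finescale,
                                   depthPairs = cfg$hic$depthPairs,
                                   decayExponent = cfg$hic$decayExponent,
                                   seed = deriveSeed(cfg$seed, paste0("fine", s)))
      cmF <- observedOverExpected(cmF)
      partner <- loops(truth)$anchor2[li]
      series[[st[s]]] <- quantifyRegionPair(
        cmF, regionA, c(partner - 2.5e3, partner + 7.5e3))[1]
      rm(cmF); gc(verbose = FALSE)
    }
    summary$finescale <- list(regionA = regionA,
                              partnerMeanOE = series)
  }
  ## ---- outputs -----------------------------------------------------------
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeTruth(truth, file.path(outdir, "truth.json"))
    writeLoopsBedpe(classed, cfg$resolutions$loops,
                    file.path(outdir, "loops_annotated.bedpe"))
    utils::write.table(cbind(tadTable, ds$normalized),
                       file.path(outdir, "domain_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(topBounds, file.path(outdir, "top_boundaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeExpressionTable(chip$expression, chip$cellStage,
                         file.path(outdir, "expression.tsv"))
    manifest <- list(configHash = cfgHash, seed = cfg$seed,
                     created = "run", files = list.files(outdir))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    return(invisible(summary))
  }
  summary
}
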