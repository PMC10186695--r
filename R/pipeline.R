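#' Configuration for a full two-condition comparison
#'
#' @param pairs1,pairs2 contact pair lists (data.frame chrom/pos1/pos2) or
#'   paths to pair text files, condition 1 (reference/normal) first.
#' @param chromSizes named chromosome lengths or a chrom.sizes path.
#' @param genes gene table (data.frame or TSV path) with geneId, chrom,
#'   start, end, strand, fpkm1, fpkm2, degLabel.
#' @param markPeaks named list of peak tables/BED paths (expects at least
#'   H3K27ac for compartment orientation; H3K27me3 optional).
#' @param dhs DHS intervals (data.frame or BED path), optional.
#' @param compartmentRes,tadRes bin sizes in bp for the compartment and
#'   TAD/loop-APA stages (defaults 50 kb and 5 kb).
#' @param delta,boundaryFdr insulation boundary thresholds.
#' @param loopQ loop-calling q cutoff; \code{diffLoopP} differential-loop p
#'   cutoff.
#' @param shiftBins consensus boundary shift tolerance.
#' @param topFraction mark-enriched TAD quantile share.
#' @param nPerm permutations for the anchor-DHS test.
#' @param minFraction low-coverage masking threshold.
#' @param seed master seed for every stochastic step.
#' @return a validated list of class \code{ComparisonConfig}.
#' @export
comparisonConfig <- function(pairs1, pairs2, chromSizes, genes,
                             markPeaks = list(), dhs = NULL,
                             compartmentRes = 5e4, tadRes = 5e3,
                             delta = 0.01, boundaryFdr = 0.01,
                             loopQ = 0.01, diffLoopP = 0.01,
                             shiftBins = 2, topFraction = 0.25,
                             nPerm = 1000, minFraction = 0.1, seed = 1L) {
  thr <- c(delta = delta, boundaryFdr = boundaryFdr, loopQ = loopQ,
           diffLoopP = diffLoopP, topFraction = topFraction)
  if (any(thr <= 0 | thr >= 1))
    stop("thresholds must lie in (0, 1)")
  if (compartmentRes %% tadRes != 0)
    stop("compartmentRes must be a multiple of tadRes")
  structure(list(pairs1 = pairs1, pairs2 = pairs2, chromSizes = chromSizes,
                 genes = genes, markPeaks = markPeaks, dhs = dhs,
                 compartmentRes = compartmentRes, tadRes = tadRes,
                 delta = delta, boundaryFdr = boundaryFdr, loopQ = loopQ,
                 diffLoopP = diffLoopP, shiftBins = shiftBins,
                 topFraction = topFraction, nPerm = nPerm,
                 minFraction = minFraction, seed = as.integer(seed)),
            class = "ComparisonConfig")
}

loadDf <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Run the full two-condition architecture comparison
#'
#' Executes matrix preparation (binning, masking, depth normalization, KR
#' balancing), compartment calling with saddle strengths and switch
#' classification, insulation-score TAD calling with consensus and
#' differential domains plus histone-mark annotation, loop calling with
#' APA and depth-matched differential loops, and the gene-integration
#' reports. Fully deterministic given the config seed.
#'
#' @param config a \code{\link{comparisonConfig}}.
#' @param outDir optional directory for per-stage files and the JSON
#'   report.
#' @return a nested report list (also written as \code{report.json} when
#'   \code{outDir} is given).
#' @export
runComparison <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "ComparisonConfig"))
  cs <- if (is.character(config$chromSizes)) readChromSizes(config$chromSizes)
        else config$chromSizes
  genes <- loadDf(config$genes, readGeneTable)
  marks <- lapply(config$markPeaks, loadDf, reader = readBed)
  dhs <- if (!is.null(config$dhs)) loadDf(config$dhs, readBed)
  pairs1 <- loadDf(config$pairs1, function(p) {
    tab <- data.table::fread(p, header = FALSE)
    data.frame(chrom = as.character(tab[[1]]), pos1 = as.numeric(tab[[2]]),
               pos2 = as.numeric(tab[[3]]))
  })
  pairs2 <- loadDf(config$pairs2, function(p) {
    tab <- data.table::fread(p, header = FALSE)
    data.frame(chrom = as.character(tab[[1]]), pos1 = as.numeric(tab[[2]]),
               pos2 = as.numeric(tab[[3]]))
  })

  gridT <- binnedGenome(cs, config$tadRes)
  fac <- as.integer(config$compartmentRes / config$tadRes)
  message("stage: matrices")
  cmT1 <- contactsFromPairs(pairs1, gridT)
  cmT2 <- contactsFromPairs(pairs2, gridT)
  dn <- depthNormalize(cmT1, cmT2)
  mT1 <- maskLowCoverage(dn[[1]], config$minFraction)
  mT2 <- maskLowCoverage(dn[[2]], config$minFraction)
  balT1 <- krBalance(mT1); balT2 <- krBalance(mT2)
  cmC1 <- maskLowCoverage(coarsenContacts(dn[[1]], fac), config$minFraction)
  cmC2 <- maskLowCoverage(coarsenContacts(dn[[2]], fac), config$minFraction)
  balC1 <- krBalance(cmC1); balC2 <- krBalance(cmC2)
  gridC <- binGrid(cmC1)

  message("stage: compartments")
  acTrack <- if (!is.null(marks$H3K27ac))
    binCoverageTrack(gridC, marks$H3K27ac, "H3K27ac")
  else geneDensityTrack(gridC, genes)
  gdTrack <- geneDensityTrack(gridC, genes)
  prof1 <- orientSign(compartmentEigenvector(balC1), acTrack, gdTrack)
  prof2 <- orientSign(compartmentEigenvector(balC2), acTrack, gdTrack)
  frac1 <- compartmentFractions(prof1)
  frac2 <- compartmentFractions(prof2)
  oeC1 <- oeTransform(balC1); oeC2 <- oeTransform(balC2)
  sad1 <- saddle(oeC1, prof1); sad2 <- saddle(oeC2, prof2)
  sw <- classifySwitches(prof1, prof2)

  message("stage: TADs")
  ins1 <- insulationProfile(balT1); ins2 <- insulationProfile(balT2)
  bd1 <- callBoundaries(ins1, balT1, config$delta, config$boundaryFdr)
  bd2 <- callBoundaries(ins2, balT2, config$delta, config$boundaryFdr)
  tads1 <- segmentTads(bd1, gridT); tads2 <- segmentTads(bd2, gridT)
  cons <- consensusBoundaries(bd1, bd2, config$shiftBins)
  bsc <- boundaryStrengthCompare(ins1, ins2, cons)
  dtads <- differentialTads(tads1, dn[[1]], dn[[2]], mode = "all")
  markSummary <- list()
  for (mk in names(marks)) {
    tr <- binCoverageTrack(gridT, marks[[mk]], mk)
    a1 <- annotateTadsByMark(tads1, marks[[mk]], tr, config$topFraction, mk)
    a2 <- annotateTadsByMark(tads2, marks[[mk]], tr, config$topFraction, mk)
    markSummary[[mk]] <- list(
      enrichedPercent1 = 100 * mean(a1[[paste0(mk, "Enriched")]]),
      enrichedPercent2 = 100 * mean(a2[[paste0(mk, "Enriched")]]))
  }

  message("stage: loops")
  loops1 <- loopSignificance(clusterLoops(pairs1), pairs1, gridT,
                             qMax = config$loopQ)
  loops2 <- loopSignificance(clusterLoops(pairs2), pairs2, gridT,
                             qMax = config$loopQ)
  apa1 <- apa(balT1, loops1); apa2 <- apa(balT2, loops2)
  uni <- unionLoops(loops1, loops2)
  dl <- differentialLoops(pairs1, pairs2, uni, gridT,
                          pMax = config$diffLoopP, seed = config$seed)
  gained <- dl[dl$label == "gained", ]
  lost <- dl[dl$label == "lost", ]
  common <- dl[dl$label == "common", ]
  dclass <- distanceClassify(gained, lost, common)
  dhsRes <- if (!is.null(dhs) && nrow(loops1)) {
    ov <- anchorDhsOverlap(loops1, dhs)
    anchors <- rbind(
      data.frame(chrom = loops1$chrom, start = loops1$startA, end = loops1$endA),
      data.frame(chrom = loops1$chrom, start = loops1$startB, end = loops1$endB))
    perm <- permutationEnrichment(anchors, dhs, cs, nPerm = config$nPerm,
                                  seed = config$seed)
    list(fraction = ov$fraction, permutationP = perm$p, fold = perm$fold)
  }

  message("stage: integration")
  bdeg <- boundaryDegReport(cons, genes, gridT)
  loopDeg <- lapply(list(lost = lost, gained = gained), function(set) {
    if (!nrow(set)) return(NULL)
    anchors <- rbind(
      data.frame(chrom = set$chrom, start = set$startA, end = set$endA),
      data.frame(chrom = set$chrom, start = set$startB, end = set$endB))
    idx <- overlapGenes(anchors, genes, "promoter")
    if (!length(idx)) return(NULL)
    k <- sum(genes$degLabel[idx] != "ns")
    fisherEnrichment(k, length(idx), sum(genes$degLabel != "ns"), nrow(genes))
  })
  switchIv <- do.call(rbind, lapply(chromNames(gridC), function(ch) {
    cat_ <- sw$perBin[[ch]]
    swb <- which(!is.na(cat_) & cat_ %in% c("A-to-B", "B-to-A")) - 1L
    if (!length(swb)) return(NULL)
    data.frame(chrom = ch, start = swb * config$compartmentRes,
               end = (swb + 1) * config$compartmentRes)
  }))
  if (is.null(switchIv))
    switchIv <- data.frame(chrom = character(), start = numeric(),
                           end = numeric())
  specB <- rbind(cons$specific1, cons$specific2)
  reorg <- reorgDegSummary(switchIv, specB, dl[dl$label != "common", ],
                           genes, gridT)

  report <- list(
    schemaVersion = "1.0",
    parameters = config[c("compartmentRes", "tadRes", "delta", "boundaryFdr",
                          "loopQ", "diffLoopP", "shiftBins", "topFraction",
                          "nPerm", "minFraction", "seed")],
    matrices = list(totalContacts1 = totalContacts(cmT1),
                    totalContacts2 = totalContacts(cmT2),
                    sccBetweenConditions = tryCatch(
                      scc(dn[[1]], dn[[2]]), error = function(e) NA_real_)),
    compartments = list(
      fractions1 = frac1, fractions2 = frac2,
      strength1 = compartmentStrength(sad1),
      strength2 = compartmentStrength(sad2),
      switchSummary = sw$summary,
      switchedPercent = attr(sw$summary, "switchedPercent")),
    tads = list(
      nBoundaries1 = nrow(bd1), nBoundaries2 = nrow(bd2),
      nTads1 = nrow(tads1), nTads2 = nrow(tads2),
      consensusCounts = as.list(cons$counts),
      conservedPercentOfSet1 = 100 * cons$counts[["conserved"]] /
        max(1, cons$counts[["conserved"]] + cons$counts[["specific1"]]),
      nChangedTads = sum(dtads$label == "changed", na.rm = TRUE),
      meanTadSize1 = mean(tads1$sizeBp), meanTadSize2 = mean(tads2$sizeBp),
      markEnrichment = markSummary,
      boundaryStrength = bsc),
    loops = list(
      nLoops1 = nrow(loops1), nLoops2 = nrow(loops2),
      apaScore1 = apa1$score, apaScore2 = apa2$score,
      nGained = nrow(gained), nLost = nrow(lost), nCommon = nrow(common),
      distanceClasses = dclass$table,
      longRange = dclass$longRange,
      anchorDhs = dhsRes),
    integration = list(
      boundaryDeg = lapply(bdeg, function(x) {
        if (is.null(x$enrichment)) return(x)
        x$enrichment <- unclass(x$enrichment); x
      }),
      loopDeg = lapply(loopDeg, function(x) if (is.null(x)) NULL else unclass(x)),
      reorg = reorg[c("nAssociated", "nDeg", "fraction")]))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeBedGraph(pc1(prof1), file.path(outDir, "pc1_condition1.bedGraph"),
                  grid = gridC)
    writeBedGraph(pc1(prof2), file.path(outDir, "pc1_condition2.bedGraph"),
                  grid = gridC)
    writeBed(data.frame(chrom = bd1$chrom, start = bd1$bin * config$tadRes,
                        end = (bd1$bin + 1) * config$tadRes,
                        name = "boundary", score = bd1$score),
             file.path(outDir, "boundaries_condition1.bed"))
    writeBed(data.frame(chrom = bd2$chrom, start = bd2$bin * config$tadRes,
                        end = (bd2$bin + 1) * config$tadRes,
                        name = "boundary", score = bd2$score),
             file.path(outDir, "boundaries_condition2.bed"))
    if (nrow(loops1)) writeBedpe(loops1, file.path(outDir, "loops_condition1.bedpe"))
    if (nrow(loops2)) writeBedpe(loops2, file.path(outDir, "loops_condition2.bedpe"))
    data.table::fwrite(dl, file.path(outDir, "differential_loops.tsv"),
                       sep = "\t")
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null", force = TRUE)
  }
  report
}
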