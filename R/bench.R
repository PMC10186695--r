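#' Majority-vote coarsening of planted compartment labels
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param factor fine bins per coarse bin.
#' @return named list of per-chromosome label vectors at the coarse grid.
#' @export
coarsenLabels <- function(truth, factor) {
  out <- list()
  for (ch in chromNames(truth@grid)) {
    lab <- truth@compartments[[ch]]
    grp <- (seq_along(lab) - 1) %/% factor
    out[[ch]] <- vapply(split(lab, grp), function(v) {
      if (sum(v == "A") >= length(v) / 2) "A" else "B"
    }, character(1), USE.NAMES = FALSE)
  }
  out
}

#' Recovery of planted boundaries by a called boundary set
#'
#' Greedy one-to-one matching within \code{tol} bins (closest first).
#'
#' @param called data.frame chrom, bin (from \code{\link{callBoundaries}}).
#' @param truth a \linkS4class{GroundTruth} (or named list of boundary
#'   bins).
#' @param tol match tolerance in bins (default 2).
#' @return list: recall, precision, nCalled, nTruth, nMatched.
#' @export
scoreBoundaryRecovery <- function(called, truth, tol = 2) {
  tb <- if (is(truth, "GroundTruth")) truth@boundaries else truth
  truthDf <- data.frame(chrom = rep(names(tb), lengths(tb)),
                        bin = unlist(tb, use.names = FALSE))
  cons <- consensusBoundaries(called, truthDf, shiftBins = tol)
  nM <- nrow(cons$conserved)
  list(recall = nM / nrow(truthDf), precision = nM / max(1, nrow(called)),
       nCalled = nrow(called), nTruth = nrow(truthDf), nMatched = nM)
}

#' Recovery of planted loops by a called loop set
#'
#' A planted loop is recovered when a called loop's anchor midpoints both
#' fall within \code{tolBp} of the planted anchor bin centers; matching is
#' one-to-one, closest first.
#'
#' @param called loop table with bp anchors.
#' @param truthLoops data.frame chrom, binI, binJ (planted loops).
#' @param grid the planting \linkS4class{BinnedGenome}.
#' @param tolBp matching tolerance in bp (default 3 bins).
#' @return list: recall, precision, nCalled, nTruth, nMatched, matched
#'   (logical per planted loop).
#' @export
scoreLoopRecovery <- function(called, truthLoops, grid,
                              tolBp = 3 * binSize(grid)) {
  bs <- binSize(grid)
  tI <- truthLoops$binI * bs + bs / 2
  tJ <- truthLoops$binJ * bs + bs / 2
  cI <- (called$startA + called$endA) / 2
  cJ <- (called$startB + called$endB) / 2
  usedC <- logical(nrow(called))
  matched <- logical(nrow(truthLoops))
  for (t in order(truthLoops$chrom)) {
    cand <- which(!usedC & called$chrom == truthLoops$chrom[t] &
                  abs(cI - tI[t]) <= tolBp & abs(cJ - tJ[t]) <= tolBp)
    if (length(cand)) {
      best <- cand[which.min(abs(cI[cand] - tI[t]) + abs(cJ[cand] - tJ[t]))]
      usedC[best] <- TRUE
      matched[t] <- TRUE
    }
  }
  list(recall = mean(matched), precision = sum(usedC) / max(1, nrow(called)),
       nCalled = nrow(called), nTruth = nrow(truthLoops),
       nMatched = sum(matched), matched = matched)
}

#' Jaccard index of called vs planted compartment switches
#'
#' @param switches output of \code{\link{classifySwitches}}.
#' @param truth1,truth2 the two \linkS4class{GroundTruth} objects.
#' @param factor fine bins per profile bin.
#' @return bin-level Jaccard index of the switched sets.
#' @export
scoreSwitchRecovery <- function(switches, truth1, truth2, factor) {
  l1 <- coarsenLabels(truth1, factor)
  l2 <- coarsenLabels(truth2, factor)
  inter <- 0; uni <- 0
  for (ch in names(l1)) {
    truthSw <- l1[[ch]] != l2[[ch]]
    cat_ <- switches$perBin[[ch]]
    calledSw <- !is.na(cat_) & cat_ %in% c("A-to-B", "B-to-A")
    n <- min(length(truthSw), length(calledSw))
    inter <- inter + sum(truthSw[1:n] & calledSw[1:n])
    uni <- uni + sum(truthSw[1:n] | calledSw[1:n])
  }
  if (uni == 0) return(1)
  inter / uni
}

#' Fraction of profile bins with correctly recovered compartment label
#'
#' @param profile an oriented \linkS4class{CompartmentProfile}.
#' @param truth the planting \linkS4class{GroundTruth}.
#' @param factor fine bins per profile bin.
#' @return fraction of unmasked profile bins whose label matches the
#'   (majority-coarsened) planted label.
#' @export
scoreLabelRecovery <- function(profile, truth, factor) {
  lt <- coarsenLabels(truth, factor)
  hit <- 0; tot <- 0
  for (ch in chromNames(profile@grid)) {
    called <- compartmentLabels(profile, ch)
    planted <- lt[[ch]]
    n <- min(length(called), length(planted))
    ok <- !is.na(called[1:n])
    hit <- hit + sum(called[1:n][ok] == planted[1:n][ok])
    tot <- tot + sum(ok)
  }
  hit / tot
}

#' Write the standard track files of a GroundTruth
#'
#' Emits chrom.sizes, compartment labels (bedGraph, +1/-1), boundary and
#' TAD-boundary BED, loops BEDPE, gene TSV, per-mark peak BEDs and DHS BED
#' into a directory.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeGroundTruthTracks <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- truth@grid
  bs <- binSize(grid)
  writeChromSizes(grid, file.path(dir, "chrom.sizes"))
  compVals <- lapply(truth@compartments, function(l) ifelse(l == "A", 1, -1))
  writeBedGraph(compVals, file.path(dir, "compartments.bedGraph"), grid = grid)
  bdf <- data.frame(chrom = rep(names(truth@boundaries),
                                lengths(truth@boundaries)),
                    bin = unlist(truth@boundaries, use.names = FALSE))
  writeBed(data.frame(chrom = bdf$chrom, start = bdf$bin * bs,
                      end = (bdf$bin + 1) * bs),
           file.path(dir, "boundaries.bed"))
  if (nrow(truth@loops))
    writeBedpe(data.frame(chrom = truth@loops$chrom,
                          startA = truth@loops$binI * bs,
                          endA = (truth@loops$binI + 1) * bs,
                          startB = truth@loops$binJ * bs,
                          endB = (truth@loops$binJ + 1) * bs),
               file.path(dir, "loops.bedpe"))
  writeGeneTable(truth@genes, file.path(dir, "genes.tsv"))
  for (mk in names(truth@markPeaks))
    writeBed(truth@markPeaks[[mk]], file.path(dir, paste0(mk, "_peaks.bed")))
  writeBed(truth@dhs, file.path(dir, "dhs.bed"))
  invisible(dir)
}
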