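#' Strand-aware promoter intervals
#'
#' The promoter of a gene is the 2 kb immediately upstream of its TSS: for
#' a plus-strand gene \code{[start - 2000, start)}, for a minus-strand gene
#' \code{[end, end + 2000)} in genome coordinates (0-based half-open).
#'
#' @param genes data.frame with chrom, start, end, strand.
#' @param width promoter width in bp (default 2000).
#' @return data.frame chrom, start, end aligned with the input rows.
#' @export
promoterIntervals <- function(genes, width = 2000) {
  plus <- genes$strand == "+"
  data.frame(chrom = genes$chrom,
             start = ifelse(plus, pmax(0, genes$start - width), genes$end),
             end = ifelse(plus, genes$start, genes$end + width))
}

#' Genes overlapping a feature set
#'
#' Interval intersection (>= 1 bp, 0-based half-open) between features
#' (e.g. boundary flanks or loop anchors) and either gene bodies or
#' promoters. Each gene is reported once per feature set.
#'
#' @param features data.frame chrom, start, end.
#' @param genes gene table.
#' @param mode \code{"gene_body"} or \code{"promoter"}.
#' @return integer vector of unique gene row indices hitting any feature.
#' @export
overlapGenes <- function(features, genes, mode = c("gene_body", "promoter")) {
  mode <- match.arg(mode)
  if (!nrow(features) || !nrow(genes)) return(integer(0))
  iv <- if (mode == "promoter") promoterIntervals(genes)
        else genes[, c("chrom", "start", "end")]
  hits <- GenomicRanges::findOverlaps(grIntervals(iv), grIntervals(features))
  sort(unique(S4Vectors::queryHits(hits)))
}

#' Fisher-test enrichment of a foreground rate over a background rate
#'
#' @param kFg,nFg foreground successes and total.
#' @param kBg,nBg background successes and total. By default the
#'   background includes the foreground (the genome-wide prevalence is the
#'   control); set \code{excludeForeground = TRUE} to subtract the
#'   foreground counts from the background margin of the 2x2 table.
#' @param excludeForeground see above.
#' @return list of class \code{enrichmentResult}: kFg, nFg, kBg, nBg,
#'   fgRate, bgRate, fold, p (two-sided Fisher exact), method.
#' @export
fisherEnrichment <- function(kFg, nFg, kBg, nBg, excludeForeground = FALSE) {
  if (nFg == 0) stop("empty foreground")
  stopifnot(kFg >= 0, kFg <= nFg, kBg >= 0, kBg <= nBg)
  k2 <- if (excludeForeground) kBg - kFg else kBg
  n2 <- if (excludeForeground) nBg - nFg else nBg
  tab <- matrix(c(kFg, nFg - kFg, k2, n2 - k2), 2)
  res <- list(kFg = kFg, nFg = nFg, kBg = kBg, nBg = nBg,
              fgRate = kFg / nFg, bgRate = kBg / nBg,
              fold = (kFg / nFg) / (kBg / nBg),
              p = fisher.test(tab)$p.value,
              method = "fisher")
  class(res) <- "enrichmentResult"
  res
}

#' @export
print.enrichmentResult <- function(x, ...) {
  cat(sprintf("%s enrichment: %d/%d (%.1f%%) vs %d/%d (%.1f%%), fold %.2f, p = %.3g\n",
              x$method, x$kFg, x$nFg, 100 * x$fgRate,
              x$kBg, x$nBg, 100 * x$bgRate, x$fold, x$p))
  invisible(x)
}

#' Permutation test of interval overlap enrichment
#'
#' The observed statistic is the fraction of query intervals overlapping
#' any target. Each permutation relocates every query interval uniformly
#' at random within its own chromosome, preserving its length (no
#' constraint against overlaps among placed intervals). The empirical p is
#' \code{(1 + #permutations >= observed) / (nPerm + 1)}.
#'
#' @param query data.frame chrom, start, end (0-based half-open).
#' @param targets data.frame chrom, start, end.
#' @param chromSizes named chromosome lengths (or a
#'   \linkS4class{BinnedGenome}).
#' @param nPerm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return list of class \code{enrichmentResult}: observed fraction,
#'   permutation mean, fold, the conservative empirical p, a tie-corrected
#'   \code{pMid}, and nPerm.
#' @export
permutationEnrichment <- function(query, targets, chromSizes, nPerm = 1000,
                                  seed = 1L) {
  if (is(chromSizes, "BinnedGenome")) chromSizes <- chromSizes(chromSizes)
  if (nPerm < 100) stop("nPerm must be >= 100")
  len <- query$end - query$start
  if (any(len > chromSizes[query$chrom]))
    stop("query interval longer than its chromosome")
  # merged target intervals per chromosome, for a vectorized overlap test
  merged <- lapply(stats::setNames(nm = names(chromSizes)), function(ch) {
    sub <- targets[targets$chrom == ch, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    r <- IRanges::reduce(IRanges::IRanges(sub$start + 1, sub$end))
    list(ts = IRanges::start(r) - 1, te = IRanges::end(r))
  })
  hitAny <- function(chrom, s, e) {
    out <- logical(length(s))
    for (ch in unique(chrom)) {
      mg <- merged[[ch]]
      if (is.null(mg)) next
      rows <- chrom == ch
      k <- findInterval(s[rows], mg$ts)
      ov <- (k >= 1 & mg$te[pmax(k, 1)] > s[rows]) |
            (k < length(mg$ts) & mg$ts[pmin(k + 1, length(mg$ts))] < e[rows])
      out[rows] <- ov
    }
    out
  }
  kObs <- sum(hitAny(query$chrom, query$start, query$end))
  observed <- kObs / nrow(query)
  maxStart <- chromSizes[query$chrom] - len
  perm <- withSeed(seed, vapply(seq_len(nPerm), function(i) {
    s <- floor(runif(nrow(query)) * (maxStart + 1))
    mean(hitAny(query$chrom, s, s + len))
  }, numeric(1)))
  res <- list(observed = observed, permMean = mean(perm),
              fold = observed / mean(perm),
              p = (1 + sum(perm >= observed)) / (nPerm + 1),
              # mid-p: half-weight on ties; the overlap fraction is a
              # discrete statistic, so the conservative p is biased above
              # uniform under the null while the mid-p is calibrated
              pMid = (0.5 + sum(perm > observed) +
                        0.5 * sum(perm == observed)) / (nPerm + 1),
              nPerm = nPerm, method = "permutation",
              kFg = kObs, nFg = nrow(query), fgRate = observed,
              bgRate = mean(perm))
  class(res) <- "enrichmentResult"
  res
}

#' Loop-anchor DHS overlap and aggregate accessibility profile
#'
#' @param loops loop table with bp anchors.
#' @param dhs data.frame chrom, start, end of accessible sites.
#' @param flank profile half-width around anchor centers in bp (default
#'   50 kb).
#' @param profileBin profile bin width in bp (default 1 kb).
#' @return list: \code{fraction} of anchors overlapping a DHS,
#'   \code{profile} (mean DHS coverage per offset bin), \code{offsets}
#'   (bin center offsets in bp), \code{perAnchor} matrix.
#' @export
anchorDhsOverlap <- function(loops, dhs, flank = 5e4, profileBin = 1e3) {
  anchors <- rbind(
    data.frame(chrom = loops$chrom, start = loops$startA, end = loops$endA),
    data.frame(chrom = loops$chrom, start = loops$startB, end = loops$endB))
  dGr <- grIntervals(dhs)
  frac <- if (nrow(anchors))
    mean(GenomicRanges::countOverlaps(grIntervals(anchors), dGr) > 0)
  else NaN
  nb <- as.integer(2 * flank / profileBin)
  prof <- matrix(0, nrow(anchors), nb)
  ctr <- floor((anchors$start + anchors$end) / 2)
  for (ch in unique(anchors$chrom)) {
    sub <- dhs[dhs$chrom == ch, , drop = FALSE]
    rows <- which(anchors$chrom == ch)
    if (!nrow(sub)) next
    maxPos <- max(sub$end, ctr[rows] + flank) + 1
    cov <- IRanges::coverage(IRanges::IRanges(sub$start + 1, sub$end),
                             width = maxPos)
    covv <- as.numeric(cov)
    for (r in rows) {
      edges <- ctr[r] - flank + (0:nb) * profileBin
      for (k in seq_len(nb)) {
        a <- edges[k] + 1; b <- edges[k + 1]
        if (b < 1 || a > length(covv)) next
        a <- max(a, 1); b <- min(b, length(covv))
        prof[r, k] <- mean(covv[a:b])
      }
    }
  }
  list(fraction = frac,
       profile = colMeans(prof),
       offsets = seq(-flank + profileBin / 2, flank - profileBin / 2,
                     by = profileBin),
       perAnchor = prof)
}

boundaryFlankIntervals <- function(boundaries, grid, flankBins = 2) {
  bs <- binSize(grid)
  data.frame(chrom = boundaries$chrom,
             start = pmax(0, (boundaries$bin - flankBins) * bs),
             end = (boundaries$bin + flankBins) * bs)
}

#' DEG content of condition-specific TAD boundaries
#'
#' Genes are assigned to specific boundaries by gene-body overlap with the
#' boundary bin +- \code{flankBins} bins. Reports, per specificity class
#' and pooled, the DEG fraction against the genome background (Fisher
#' exact) and the up:down DEG ratio normalized to the overall up:down
#' ratio.
#'
#' @param consensus output of \code{\link{consensusBoundaries}};
#'   \code{specific1} is read as condition-1(normal)-specific (boundary
#'   lost in condition 2) and \code{specific2} as gained.
#' @param genes gene table with degLabel.
#' @param grid the boundary-calling \linkS4class{BinnedGenome}.
#' @param flankBins flank in bins (default 2).
#' @return list with per-class gene counts, enrichment results and up/down
#'   fold ratios.
#' @export
boundaryDegReport <- function(consensus, genes, grid, flankBins = 2) {
  nDeg <- sum(genes$degLabel != "ns")
  nUp <- sum(genes$degLabel == "up"); nDown <- sum(genes$degLabel == "down")
  classes <- list(lost = consensus$specific1, gained = consensus$specific2)
  out <- list()
  allIdx <- integer(0)
  for (cl in names(classes)) {
    iv <- boundaryFlankIntervals(classes[[cl]], grid, flankBins)
    idx <- overlapGenes(iv, genes, "gene_body")
    allIdx <- union(allIdx, idx)
    k <- sum(genes$degLabel[idx] != "ns")
    ku <- sum(genes$degLabel[idx] == "up")
    kd <- sum(genes$degLabel[idx] == "down")
    upDownFold <- if (kd > 0 && nDown > 0 && nUp > 0)
      (ku / kd) / (nUp / nDown) else NaN
    out[[cl]] <- list(
      nGenes = length(idx), nDeg = k, nUp = ku, nDown = kd,
      enrichment = if (length(idx))
        fisherEnrichment(k, length(idx), nDeg, nrow(genes)) else NULL,
      upDownFoldVsBackground = upDownFold)
  }
  kAll <- sum(genes$degLabel[allIdx] != "ns")
  out$pooled <- list(
    nGenes = length(allIdx), nDeg = kAll,
    enrichment = if (length(allIdx))
      fisherEnrichment(kAll, length(allIdx), nDeg, nrow(genes)) else NULL)
  out
}

#' DEGs explained by genome reorganization
#'
#' The deduplicated union of DEGs that (i) reside in switched compartment
#' bins, (ii) lie within condition-specific boundaries, or (iii) have
#' their promoter at a differential (gained or lost) loop anchor, as a
#' fraction of all DEGs.
#'
#' @param switchBins data.frame chrom, start, end of switched compartment
#'   intervals (bp).
#' @param specificBoundaries data.frame chrom, bin of condition-specific
#'   boundaries.
#' @param diffLoops differential loop table (rows with label != "common").
#' @param genes gene table with degLabel.
#' @param grid the boundary-calling \linkS4class{BinnedGenome}.
#' @param flankBins boundary flank in bins (default 2).
#' @return list: per-component DEG index sets, union count, total DEGs and
#'   fraction.
#' @export
reorgDegSummary <- function(switchBins, specificBoundaries, diffLoops, genes,
                            grid, flankBins = 2) {
  degIdx <- which(genes$degLabel != "ns")
  inSwitch <- intersect(degIdx, overlapGenes(switchBins, genes, "gene_body"))
  inBoundary <- intersect(
    degIdx,
    overlapGenes(boundaryFlankIntervals(specificBoundaries, grid, flankBins),
                 genes, "gene_body"))
  anchors <- rbind(
    data.frame(chrom = diffLoops$chrom, start = diffLoops$startA,
               end = diffLoops$endA),
    data.frame(chrom = diffLoops$chrom, start = diffLoops$startB,
               end = diffLoops$endB))
  inLoop <- intersect(degIdx, overlapGenes(anchors, genes, "promoter"))
  assoc <- sort(unique(c(inSwitch, inBoundary, inLoop)))
  list(inSwitch = inSwitch, inBoundary = inBoundary, inLoop = inLoop,
       nAssociated = length(assoc), nDeg = length(degIdx),
       fraction = length(assoc) / length(degIdx))
}

#' Read a tab-separated gene table
#'
#' Columns: geneId, chrom, start, end, strand, fpkm1, fpkm2, degLabel.
#' @param path TSV path.
#' @return data.frame.
#' @export
readGeneTable <- function(path) {
  as.data.frame(data.table::fread(path, header = TRUE))
}

#' Write a gene table as TSV
#' @param genes gene data.frame.
#' @param path output path.
#' @export
writeGeneTable <- function(genes, path) {
  data.table::fwrite(genes, path, sep = "\t", scipen = 50)
  invisible(path)
}
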