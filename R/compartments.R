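#' @rdname binGrid
#' @export
setMethod("binGrid", "CompartmentProfile", function(x) x@grid)

#' @rdname pc1
#' @export
setMethod("pc1", "CompartmentProfile", function(x, chrom = NULL) {
  if (is.null(chrom)) x@pc1 else x@pc1[[chrom]]
})

#' @rdname compartmentLabels
#' @export
setMethod("compartmentLabels", "CompartmentProfile", function(x, chrom = NULL) {
  if (is.null(chrom)) x@label else x@label[[chrom]]
})

setMethod("show", "CompartmentProfile", function(object) {
  lab <- unlist(object@label)
  cat(sprintf("CompartmentProfile (%s): %d bins (%d A, %d B, %d masked), bin size %g bp\n",
              if (object@oriented) "oriented" else "unoriented",
              length(lab), sum(lab == "A", na.rm = TRUE),
              sum(lab == "B", na.rm = TRUE), sum(is.na(lab)),
              binSize(object@grid)))
})

labelFromPc1 <- function(v) ifelse(is.na(v) | v == 0, NA_character_,
                                   ifelse(v > 0, "A", "B"))

#' A/B compartment eigenvector
#'
#' Per chromosome, the leading eigenvector of the Pearson correlation
#' matrix of the observed/expected map, scaled by the square root of its
#' eigenvalue. The sign is arbitrary until fixed with
#' \code{\link{orientSign}}. Masked bins are NA.
#'
#' @param cm a balanced \linkS4class{ContactMatrix} (typically at 50 kb).
#' @param minBins minimum unmasked bins per chromosome (default 20).
#' @return an unoriented \linkS4class{CompartmentProfile}.
#' @export
compartmentEigenvector <- function(cm, minBins = 20) {
  oe <- if (normalization(cm) == "oe") cm else oeTransform(cm)
  pc <- list(); lab <- list()
  for (ch in chromNames(binGrid(cm))) {
    m <- contactMatrices(oe, ch)
    keep <- binMask(oe, ch)
    n <- nrow(m)
    v <- rep(NA_real_, n)
    if (sum(keep) < minBins)
      stop(sprintf("fewer than %d unmasked bins on %s", minBins, ch))
    sub <- m[keep, keep, drop = FALSE]
    sub[!is.finite(sub)] <- NA
    cc <- suppressWarnings(cor(sub, use = "pairwise.complete.obs"))
    if (all(is.na(cc))) {
      warning("degenerate correlation matrix on ", ch, "; bins masked")
    } else {
      cc[is.na(cc)] <- 0
      eg <- eigen(cc, symmetric = TRUE)
      if (length(eg$values) > 1 && eg$values[1] - eg$values[2] < 1e-8)
        warning("nearly degenerate leading eigenvalue on ", ch)
      v[keep] <- eg$vectors[, 1] * sqrt(max(eg$values[1], 0))
    }
    pc[[ch]] <- v
    lab[[ch]] <- labelFromPc1(v)
  }
  new("CompartmentProfile", grid = binGrid(cm), pc1 = pc, label = lab,
      oriented = FALSE)
}

#' Orient compartment signs by an active chromatin track
#'
#' Per chromosome, the eigenvector is negated when its Pearson correlation
#' with the active-mark track (e.g. H3K27ac) is negative, so that positive
#' values mark the A compartment. Falls back to a gene-density track when
#' the active track has zero variance on a chromosome.
#'
#' @param profile an unoriented \linkS4class{CompartmentProfile}.
#' @param activeTrack a \linkS4class{SignalTrack} on the same grid.
#' @param fallbackTrack optional second \linkS4class{SignalTrack} (e.g.
#'   gene density) used when the active track is degenerate.
#' @return an oriented \linkS4class{CompartmentProfile} with the
#'   per-chromosome orientation correlations recorded.
#' @export
orientSign <- function(profile, activeTrack, fallbackTrack = NULL) {
  pc <- profile@pc1; lab <- list()
  ev <- numeric(0)
  for (ch in chromNames(profile@grid)) {
    v <- pc[[ch]]
    r <- NA_real_
    for (track in c(list(activeTrack), if (!is.null(fallbackTrack)) list(fallbackTrack))) {
      tv <- trackValues(track, ch)
      ok <- !is.na(v) & !is.na(tv)
      if (sum(ok) >= 3 && sd(tv[ok]) > 0 && sd(v[ok]) > 0) {
        r <- cor(v[ok], tv[ok])
        break
      }
    }
    if (is.na(r)) stop("no usable orientation track on ", ch)
    if (r < 0) { v <- -v; r <- -r }
    pc[[ch]] <- v
    lab[[ch]] <- labelFromPc1(v)
    ev[ch] <- r
  }
  new("CompartmentProfile", grid = profile@grid, pc1 = pc, label = lab,
      oriented = TRUE, orientationEvidence = ev)
}

#' Genomic share of the A and B compartments
#'
#' @param profile an oriented \linkS4class{CompartmentProfile}.
#' @return data.frame with label, bp (partial last bins counted at true
#'   length) and percent of the unmasked genome.
#' @export
compartmentFractions <- function(profile) {
  bp <- c(A = 0, B = 0)
  for (ch in chromNames(profile@grid)) {
    w <- binWidths(profile@grid, ch)
    l <- profile@label[[ch]]
    bp["A"] <- bp["A"] + sum(w[!is.na(l) & l == "A"])
    bp["B"] <- bp["B"] + sum(w[!is.na(l) & l == "B"])
  }
  data.frame(label = names(bp), bp = as.numeric(bp),
             percent = 100 * as.numeric(bp) / sum(bp))
}

#' Classify per-bin compartment switches between two conditions
#'
#' @param profile1,profile2 oriented \linkS4class{CompartmentProfile}s on
#'   the same grid (condition 1 first).
#' @return list with \code{perBin} (named list of per-bin category strings,
#'   NA where either condition is masked) and \code{summary} (data.frame of
#'   bp and percent per category over jointly unmasked bins, plus the
#'   pooled switched percentage as attribute \code{switchedPercent}).
#' @export
classifySwitches <- function(profile1, profile2) {
  if (!sameGrid(profile1@grid, profile2@grid)) stop("grids differ")
  perBin <- list()
  bp <- c("A-to-A" = 0, "A-to-B" = 0, "B-to-A" = 0, "B-to-B" = 0)
  for (ch in chromNames(profile1@grid)) {
    l1 <- profile1@label[[ch]]; l2 <- profile2@label[[ch]]
    cat_ <- ifelse(is.na(l1) | is.na(l2), NA_character_,
                   paste0(l1, "-to-", l2))
    perBin[[ch]] <- cat_
    w <- binWidths(profile1@grid, ch)
    for (k in names(bp))
      bp[k] <- bp[k] + sum(w[!is.na(cat_) & cat_ == k])
  }
  summary <- data.frame(category = names(bp), bp = as.numeric(bp),
                        percent = 100 * as.numeric(bp) / sum(bp))
  attr(summary, "switchedPercent") <-
    100 * sum(bp[c("A-to-B", "B-to-A")]) / sum(bp)
  list(perBin = perBin, summary = summary)
}

#' @rdname compartmentStrength
#' @export
setMethod("compartmentStrength", "SaddleSummary", function(x) x@strength)

setMethod("show", "SaddleSummary", function(object) {
  cat(sprintf("SaddleSummary: %d percentile classes, strength %.3f\n",
              nrow(object@matrix), object@strength))
})

#' Saddle plot and compartment strength
#'
#' Bins are ranked by PC1 per chromosome (eigenvectors carry an arbitrary
#' per-chromosome scale, so genome-wide ranking would let one chromosome
#' monopolize the extreme classes) and cut into percentile classes;
#' saddle(q1, q2) is the mean unmasked O/E over intra-chromosomal bin pairs
#' in those classes (all distances >= \code{minSep} bins pooled). With AA
#' the mean over the strongest-A corner block, BB the strongest-B corner
#' and AB the two off-corner blocks pooled, the compartment strength is
#' \code{log(AA * BB / AB^2)}. Classes are ordered from strongest B (most
#' negative PC1) to strongest A.
#'
#' @param cm an O/E (or balanced) \linkS4class{ContactMatrix}.
#' @param profile an oriented \linkS4class{CompartmentProfile} on the same
#'   grid.
#' @param percentileStep class width in percent (default 2, i.e. 50
#'   classes).
#' @param cornerShare fraction of classes pooled into each corner (default
#'   0.2, the 10 extreme classes each side at step 2).
#' @param minSep minimum bin separation included (default 2).
#' @return a \linkS4class{SaddleSummary}.
#' @export
saddle <- function(cm, profile, percentileStep = 2, cornerShare = 0.2,
                   minSep = 2) {
  if (!sameGrid(binGrid(cm), profile@grid)) stop("grids differ")
  oe <- if (normalization(cm) == "oe") cm else oeTransform(cm)
  nq <- round(100 / percentileStep)
  sums <- matrix(0, nq, nq); cnts <- matrix(0, nq, nq)
  for (ch in chromNames(profile@grid)) {
    v <- pc1(profile, ch)
    usable <- !is.na(v)
    cls <- rep(NA_integer_, length(v))
    if (any(usable)) {
      cls[usable] <- ceiling(rank(v[usable], ties.method = "first") /
                               (sum(usable) / nq))
      cls[usable] <- pmin(pmax(cls[usable], 1L), nq)
    }
    m <- contactMatrices(oe, ch)
    ok <- !is.na(cls) & binMask(oe, ch)
    idx <- which(ok)
    if (length(idx) < 2) next
    sub <- m[idx, idx, drop = FALSE]
    ci <- cls[idx]
    D <- abs(outer(idx, idx, "-"))
    val <- is.finite(sub) & D >= minSep
    grp <- (ci[row(sub)] - 1L) * nq + ci[col(sub)]
    sel <- which(val)
    sums <- sums + matrix(tabulate2(grp[sel], sub[sel], nq * nq), nq, nq)
    cnts <- cnts + matrix(tabulate(grp[sel], nbins = nq * nq), nq, nq)
  }
  sad <- sums / cnts
  nc <- max(1L, round(cornerShare * nq))
  aCls <- (nq - nc + 1):nq; bCls <- 1:nc
  AA <- mean(sad[aCls, aCls], na.rm = TRUE)
  BB <- mean(sad[bCls, bCls], na.rm = TRUE)
  AB <- mean(c(sad[aCls, bCls], sad[bCls, aCls]), na.rm = TRUE)
  if (!is.finite(AA) || !is.finite(BB) || !is.finite(AB))
    stop(sprintf("empty saddle corner (class pair counts: AA %d, BB %d, AB %d)",
                 sum(cnts[aCls, aCls]), sum(cnts[bCls, bCls]),
                 sum(cnts[aCls, bCls]) + sum(cnts[bCls, aCls])))
  new("SaddleSummary", percentiles = seq(percentileStep, 100, percentileStep),
      matrix = sad, strength = saddleStrength(AA, BB, AB),
      cornerShare = cornerShare, counts = cnts)
}

tabulate2 <- function(bin, w, nbins) {
  # weighted tabulate (keeps empty bins, which rowsum would drop)
  out <- numeric(nbins)
  agg <- rowsum(w, bin)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Compartment strength from saddle corner means
#'
#' \code{log(AA * BB / AB^2)}: 0 for a structureless map, positive when
#' same-type contacts dominate.
#'
#' @param AA,BB,AB corner means of a saddle matrix.
#' @return the natural-log strength.
#' @export
saddleStrength <- function(AA, BB, AB) log(AA * BB / AB^2)

#' Gene density and expression by compartment, and PC1 by gene class
#'
#' Genes are assigned to bins by midpoint. Returns per-label gene counts,
#' density per Mb and FPKM with a Wilcoxon rank-sum comparison, plus the
#' PC1 value distributions for up/down/ns gene classes.
#'
#' @param profile an oriented \linkS4class{CompartmentProfile}.
#' @param genes data.frame with chrom, start, end, fpkm columns and
#'   degLabel.
#' @param fpkmColumn which FPKM column to summarize (default "fpkm1").
#' @return list with \code{byLabel} (data.frame), \code{fpkmP} (rank-sum p,
#'   A vs B), and \code{pc1ByClass} (data.frame gene class / pc1).
#' @export
compartmentGeneSummary <- function(profile, genes, fpkmColumn = "fpkm1") {
  grid <- profile@grid
  mid <- floor((genes$start + genes$end) / 2)
  lab <- rep(NA_character_, nrow(genes))
  pcv <- rep(NA_real_, nrow(genes))
  for (ch in chromNames(grid)) {
    sel <- genes$chrom == ch
    b <- binOf(grid, mid[sel]) + 1L
    lab[sel] <- profile@label[[ch]][b]
    pcv[sel] <- profile@pc1[[ch]][b]
  }
  fr <- compartmentFractions(profile)
  mb <- stats::setNames(fr$bp / 1e6, fr$label)
  fp <- genes[[fpkmColumn]]
  byLabel <- do.call(rbind, lapply(c("A", "B"), function(l) {
    sel <- !is.na(lab) & lab == l
    data.frame(label = l, nGenes = sum(sel),
               genesPerMb = sum(sel) / mb[[l]],
               medianFpkm = median(fp[sel]))
  }))
  fpkmP <- tryCatch(
    wilcox.test(fp[lab == "A"], fp[lab == "B"])$p.value,
    error = function(e) NA_real_)
  list(byLabel = byLabel, fpkmP = fpkmP,
       pc1ByClass = data.frame(degLabel = genes$degLabel, pc1 = pcv,
                               label = lab))
}
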