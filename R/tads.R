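#' @rdname binGrid
#' @export
setMethod("binGrid", "InsulationProfile", function(x) x@grid)

#' @rdname insulationScore
#' @export
setMethod("insulationScore", "InsulationProfile", function(x, chrom = NULL) {
  if (is.null(chrom)) x@combined else x@combined[[chrom]]
})

setMethod("show", "InsulationProfile", function(object) {
  cat(sprintf("InsulationProfile: %d chromosome(s), %d window(s) %g-%g bp, bin size %g bp\n",
              length(object@combined), length(object@windows),
              min(object@windows), max(object@windows),
              binSize(object@grid)))
})

satSums <- function(S, r1, r2, c1, c2) {
  # rectangle sums [r1, r2] x [c1, c2] (vectors) from a padded SAT
  S[cbind(r2 + 1, c2 + 1)] - S[cbind(r1, c2 + 1)] -
    S[cbind(r2 + 1, c1)] + S[cbind(r1, c1)]
}

paddedSat <- function(m) {
  S <- matrix(0, nrow(m) + 1, ncol(m) + 1)
  S[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  S
}

#' Multi-window insulation score
#'
#' For each window w and bin i, the mean unmasked contact in the square
#' upstream x downstream of the bin edge at i (rows \code{[i-w, i)},
#' columns \code{[i, i+w)}, 0-based). The combined per-bin score is the
#' mean over windows of the per-chromosome z-scaled log2 ratio of the raw
#' insulation to its chromosome mean. Lower combined scores mean stronger
#' insulation; NaN within the largest window of the chromosome ends.
#'
#' @param cm a balanced (or depth-normalized) \linkS4class{ContactMatrix}
#'   at TAD-calling resolution, typically 5 kb.
#' @param minWindow,maxWindow,step insulation square sizes in bp (defaults
#'   20 kb to 300 kb in 5 kb steps).
#' @return an \linkS4class{InsulationProfile}.
#' @export
insulationProfile <- function(cm, minWindow = 2e4, maxWindow = 3e5,
                              step = 5e3) {
  grid <- binGrid(cm)
  bs <- binSize(grid)
  ws <- unique(pmax(2L, as.integer(round(seq(minWindow, maxWindow, by = step) / bs))))
  rawL <- list(); comb <- list()
  for (ch in chromNames(grid)) {
    n <- nBins(grid)[[ch]]
    raw <- matrix(NA_real_, n, length(ws))
    if (n < 2 * max(ws)) {
      warning("chromosome ", ch, " shorter than twice the largest window; skipped")
      rawL[[ch]] <- raw
      comb[[ch]] <- rep(NaN, n)
      next
    }
    m <- contactMatrices(cm, ch)
    keep <- binMask(cm, ch)
    mz <- m; mz[!keep, ] <- 0; mz[, !keep] <- 0
    S <- paddedSat(mz)
    V <- paddedSat(tcrossprod(as.numeric(keep)))
    for (k in seq_along(ws)) {
      w <- ws[k]
      i <- w:(n - w)  # 0-based bin index; 1-based rows i-w+1..i, cols i+1..i+w
      tot <- satSums(S, i - w + 1, i, i + 1, i + w)
      cnt <- satSums(V, i - w + 1, i, i + 1, i + w)
      raw[i + 1, k] <- ifelse(cnt > 0, tot / cnt, NA)
    }
    z <- matrix(NA_real_, n, length(ws))
    for (k in seq_along(ws)) {
      v <- suppressWarnings(log2(raw[, k] / mean(raw[, k], na.rm = TRUE)))
      v[!is.finite(v)] <- NA
      sdv <- sd(v, na.rm = TRUE)
      z[, k] <- if (is.na(sdv) || sdv == 0) ifelse(is.na(v), NA, 0)
        else (v - mean(v, na.rm = TRUE)) / sdv
    }
    cb <- suppressWarnings(rowMeans(z, na.rm = TRUE))  # ends: available windows
    cb[!is.finite(cb)] <- NaN
    rawL[[ch]] <- raw
    comb[[ch]] <- cb
  }
  new("InsulationProfile", grid = grid, raw = rawL, combined = comb,
      windows = ws * bs)
}

#' Call TAD boundaries from an insulation profile
#'
#' Boundary candidates are local minima of the combined insulation score.
#' Each candidate's delta is the mean score over the flanking
#' \code{flankBins} bins each side minus the minimum. Significance is a
#' one-sided Wilcoxon rank-sum test of the crossing-square contacts against
#' the pooled flanking-triangle contacts at the largest window, computed on
#' the observed/expected transform (the crossing square spans larger
#' genomic distances than the triangles, so raw contacts would look
#' depleted everywhere under distance decay) at a fixed test window
#' (default 40 kb; a domain-scale window keeps power for small TADs, which
#' a chromosome-scale window would dilute). The test runs at every
#' eligible bin and is BH-adjusted genome-wide (so the FDR guarantee is
#' not biased by minimum selection). Kept boundaries need
#' \code{delta >= deltaMin} and \code{q <= qMax}.
#'
#' @param profile an \linkS4class{InsulationProfile}.
#' @param cm the \linkS4class{ContactMatrix} the profile was computed from.
#' @param deltaMin minimum delta (default 0.01).
#' @param qMax BH-adjusted p-value cutoff (default 0.01).
#' @param flankBins flank width for delta (default 10).
#' @param testWindowBp window for the rank-sum contact test (default
#'   40 kb).
#' @return data.frame (chrom, bin, score, delta, p, q), sorted; one row per
#'   kept boundary. The bin index is 0-based; the boundary sits between
#'   bins \code{bin - 1} and \code{bin}.
#' @export
callBoundaries <- function(profile, cm, deltaMin = 0.01, qMax = 0.01,
                           flankBins = 10, testWindowBp = 4e4) {
  grid <- profile@grid
  w <- max(2L, as.integer(round(testWindowBp / binSize(grid))))
  oe <- if (normalization(cm) == "oe") cm else oeTransform(cm)
  rows <- list()
  for (ch in chromNames(grid)) {
    s <- profile@combined[[ch]]
    n <- length(s)
    if (all(is.na(s))) next
    m <- contactMatrices(oe, ch)
    elig <- which(!is.na(s) & seq_len(n) - 1L >= w & seq_len(n) - 1L <= n - w)
    pv <- rep(NA_real_, n)
    for (i in elig) {
      b <- i - 1L  # 0-based boundary bin
      rI <- (b - w + 1):b; cI <- (b + 1):(b + w)
      cross <- as.vector(m[rI, cI])
      lt <- m[rI, rI]; rt <- m[cI, cI]
      flank <- c(lt[upper.tri(lt)], rt[upper.tri(rt)])
      cross <- cross[is.finite(cross)]
      flank <- flank[is.finite(flank)]
      if (length(cross) < 3 || length(flank) < 3) next
      pv[i] <- suppressWarnings(
        wilcox.test(cross, flank, alternative = "less",
                    exact = FALSE)$p.value)
    }
    loc <- rep(FALSE, n)
    idx <- 2:(n - 1)
    loc[idx] <- !is.na(s[idx]) & !is.na(s[idx - 1]) & !is.na(s[idx + 1]) &
      s[idx] < s[idx - 1] & s[idx] <= s[idx + 1]
    delta <- rep(NA_real_, n)
    for (i in which(loc)) {
      fl <- s[c(max(1, i - flankBins):(i - 1), (i + 1):min(n, i + flankBins))]
      delta[i] <- mean(fl, na.rm = TRUE) - s[i]
    }
    rows[[ch]] <- data.frame(chrom = ch, bin = seq_len(n) - 1L, score = s,
                             delta = delta, p = pv, isMin = loc)
  }
  all <- do.call(rbind, c(rows, make.row.names = FALSE))
  all$q <- NA_real_
  ok <- !is.na(all$p)
  all$q[ok] <- bhAdjust(all$p[ok])
  out <- all[all$isMin & !is.na(all$delta) & all$delta >= deltaMin &
               !is.na(all$q) & all$q <= qMax, ]
  out <- out[order(out$chrom, out$bin), c("chrom", "bin", "score", "delta", "p", "q")]
  rownames(out) <- NULL
  out
}

#' Segment a chromosome into TADs between boundaries
#'
#' @param boundaries data.frame (chrom, bin) as returned by
#'   \code{\link{callBoundaries}}.
#' @param grid the \linkS4class{BinnedGenome}.
#' @return data.frame of domains: chrom, startBin, endBin (0-based,
#'   half-open), start, end, sizeBp, atChromEnd (segments touching a
#'   chromosome end are kept but flagged). Domains tile each chromosome.
#' @export
segmentTads <- function(boundaries, grid) {
  bs <- binSize(grid)
  rows <- list()
  for (ch in chromNames(grid)) {
    n <- nBins(grid)[[ch]]
    b <- sort(boundaries$bin[boundaries$chrom == ch])
    edges <- c(0L, b, n)
    st <- head(edges, -1); en <- tail(edges, -1)
    rows[[ch]] <- data.frame(
      chrom = ch, startBin = st, endBin = en,
      start = st * bs, end = pmin(en * bs, chromSizes(grid)[[ch]]),
      atChromEnd = st == 0L | en == n)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$sizeBp <- out$end - out$start
  out
}

#' Shift-tolerant consensus of two boundary sets
#'
#' Boundaries of the two conditions are matched greedily by increasing
#' shift (closest pairs first, leftmost-first tie-breaking), each boundary
#' matched at most once; pairs within \code{shiftBins} bins are conserved,
#' the rest condition-specific. The conserved count is symmetric in the
#' input order.
#'
#' @param set1,set2 boundary data.frames (chrom, bin) from
#'   \code{\link{callBoundaries}}.
#' @param shiftBins maximum allowed shift in bins (default 2).
#' @return list: conserved (chrom, bin1, bin2), specific1, specific2
#'   (chrom, bin), and counts.
#' @export
consensusBoundaries <- function(set1, set2, shiftBins = 2) {
  consRows <- list(); sp1 <- list(); sp2 <- list()
  for (ch in union(unique(set1$chrom), unique(set2$chrom))) {
    b1 <- sort(set1$bin[set1$chrom == ch])
    b2 <- sort(set2$bin[set2$chrom == ch])
    matched1 <- matched2 <- integer(0)
    if (length(b1) && length(b2)) {
      cand <- expand.grid(i = seq_along(b1), j = seq_along(b2))
      cand$d <- abs(b1[cand$i] - b2[cand$j])
      cand <- cand[cand$d <= shiftBins, , drop = FALSE]
      cand <- cand[order(cand$d, b1[cand$i], b2[cand$j]), , drop = FALSE]
      used1 <- logical(length(b1)); used2 <- logical(length(b2))
      keep <- integer(0)
      for (r in seq_len(nrow(cand))) {
        i <- cand$i[r]; j <- cand$j[r]
        if (!used1[i] && !used2[j]) {
          used1[i] <- used2[j] <- TRUE
          keep <- c(keep, r)
        }
      }
      mt <- cand[keep, , drop = FALSE]
      if (nrow(mt)) {
        consRows[[ch]] <- data.frame(chrom = ch, bin1 = b1[mt$i], bin2 = b2[mt$j])
        matched1 <- b1[mt$i]; matched2 <- b2[mt$j]
      }
    }
    if (length(setdiff(b1, matched1)))
      sp1[[ch]] <- data.frame(chrom = ch, bin = setdiff(b1, matched1))
    if (length(setdiff(b2, matched2)))
      sp2[[ch]] <- data.frame(chrom = ch, bin = setdiff(b2, matched2))
  }
  bindOr <- function(l) {
    out <- if (length(l)) do.call(rbind, c(l, make.row.names = FALSE))
    if (is.null(out) || !nrow(out)) data.frame(chrom = character(), bin = integer())
    else out
  }
  conserved <- if (length(consRows))
    do.call(rbind, c(consRows, make.row.names = FALSE))
  if (is.null(conserved))
    conserved <- data.frame(chrom = character(), bin1 = integer(), bin2 = integer())
  list(conserved = conserved, specific1 = bindOr(sp1), specific2 = bindOr(sp2),
       counts = c(conserved = nrow(conserved),
                  specific1 = sum(vapply(sp1, nrow, integer(1))),
                  specific2 = sum(vapply(sp2, nrow, integer(1)))))
}

#' Compare insulation strength of conserved and specific boundaries
#'
#' @param profile1,profile2 \linkS4class{InsulationProfile}s of the two
#'   conditions.
#' @param consensus output of \code{\link{consensusBoundaries}}.
#' @return data.frame: condition, class, n, meanScore, p (rank-sum p of
#'   conserved vs specific scores within the condition). Lower scores mean
#'   stronger insulation.
#' @export
boundaryStrengthCompare <- function(profile1, profile2, consensus) {
  scoreAt <- function(profile, df, binCol) {
    if (!nrow(df)) return(numeric(0))
    vapply(seq_len(nrow(df)), function(r)
      profile@combined[[df$chrom[r]]][df[[binCol]][r] + 1L], numeric(1))
  }
  rows <- list(); k <- 0
  for (cond in 1:2) {
    prof <- if (cond == 1) profile1 else profile2
    cons <- scoreAt(prof, consensus$conserved, paste0("bin", cond))
    spec <- scoreAt(prof, consensus[[paste0("specific", cond)]], "bin")
    p <- if (length(cons) && length(spec))
      suppressWarnings(wilcox.test(cons, spec)$p.value) else NA_real_
    for (cl in c("conserved", "specific")) {
      v <- if (cl == "conserved") cons else spec
      k <- k + 1
      rows[[k]] <- data.frame(condition = cond, class = cl, n = length(v),
                              meanScore = if (length(v)) mean(v, na.rm = TRUE) else NaN,
                              p = p)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Differential TAD test between conditions
#'
#' Per TAD, Wilcoxon rank-sum tests compare the condition-1 and condition-2
#' contact value distributions for the intra-TAD triangle and the left and
#' right inter-TAD flanking rectangles. Mode \code{"all"} labels a TAD
#' changed only when every available test has \code{p < pMax}; mode
#' \code{"one"} when any does. TADs under 3 bins are skipped.
#'
#' @param tads data.frame from \code{\link{segmentTads}} (condition-1
#'   domains).
#' @param cm1,cm2 depth-normalized \linkS4class{ContactMatrix} objects.
#' @param pMax significance threshold (default 0.05).
#' @param mode \code{"all"} or \code{"one"}.
#' @return the tads data.frame with pIntra, pLeft, pRight and label
#'   (\code{"conserved"}/\code{"changed"}; NA for skipped TADs).
#' @export
differentialTads <- function(tads, cm1, cm2, pMax = 0.05,
                             mode = c("all", "one")) {
  mode <- match.arg(mode)
  res <- tads
  res$pIntra <- res$pLeft <- res$pRight <- NA_real_
  res$label <- NA_character_
  for (r in seq_len(nrow(tads))) {
    ch <- tads$chrom[r]
    m1 <- contactMatrices(cm1, ch); m2 <- contactMatrices(cm2, ch)
    n <- nrow(m1)
    s <- tads$startBin[r] + 1L; e <- tads$endBin[r]
    len <- e - s + 1L
    if (len < 3) next
    idx <- s:e
    wt <- function(a, b) if (length(a) >= 3)
      suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value) else NA_real_
    ut <- upper.tri(m1[idx, idx])
    res$pIntra[r] <- wt(m1[idx, idx][ut], m2[idx, idx][ut])
    lidx <- max(1L, s - len):(s - 1L)
    if (length(lidx) && lidx[1] >= 1 && s > 1)
      res$pLeft[r] <- wt(as.vector(m1[lidx, idx]), as.vector(m2[lidx, idx]))
    ridx <- (e + 1L):min(n, e + len)
    if (e < n)
      res$pRight[r] <- wt(as.vector(m1[idx, ridx]), as.vector(m2[idx, ridx]))
    ps <- c(res$pIntra[r], res$pLeft[r], res$pRight[r])
    ps <- ps[!is.na(ps)]
    res$label[r] <- if (!length(ps)) NA_character_
      else if (mode == "all" && all(ps < pMax)) "changed"
      else if (mode == "one" && any(ps < pMax)) "changed"
      else "conserved"
  }
  res
}

#' Annotate TADs by histone-mark enrichment
#'
#' A TAD is mark-enriched when it overlaps at least one peak by >= 1 bp AND
#' its mean signal ranks in the top \code{topFraction} across all TADs.
#'
#' @param tads data.frame from \code{\link{segmentTads}}.
#' @param peaks data.frame (chrom, start, end, 0-based half-open) of peak
#'   calls for the mark.
#' @param signal a \linkS4class{SignalTrack} of the mark.
#' @param topFraction quantile share defining "enriched" (default 0.25).
#' @param markName column prefix (default the track label).
#' @return the tads data.frame with \code{<mark>Signal} and
#'   \code{<mark>Enriched} columns.
#' @export
annotateTadsByMark <- function(tads, peaks, signal, topFraction = 0.25,
                               markName = signal@label) {
  grid <- binGrid(signal)
  meanSig <- vapply(seq_len(nrow(tads)), function(r) {
    v <- trackValues(signal, tads$chrom[r])[(tads$startBin[r] + 1L):tads$endBin[r]]
    mean(v, na.rm = TRUE)
  }, numeric(1))
  tadGr <- GenomicRanges::GRanges(tads$chrom,
                                  IRanges::IRanges(tads$start + 1, tads$end))
  ov <- rep(FALSE, nrow(tads))
  if (nrow(peaks)) {
    hits <- GenomicRanges::findOverlaps(tadGr, grIntervals(peaks))
    ov[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  nTop <- floor(topFraction * nrow(tads) + 1e-9)
  inTop <- rank(-meanSig, ties.method = "min") <= nTop
  tads[[paste0(markName, "Signal")]] <- meanSig
  tads[[paste0(markName, "Enriched")]] <- ov & inTop
  tads
}
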