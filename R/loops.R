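#' @useDynLib chromarch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

orientPairs <- function(pairs) {
  data.frame(chrom = pairs$chrom,
             x = pmin(pairs$pos1, pairs$pos2),
             y = pmax(pairs$pos1, pairs$pos2))
}

distanceClass <- function(dbp) {
  cut(dbp, breaks = c(-Inf, 1e5, 5e5, 1e6, Inf),
      labels = c("<100kb", "100-500kb", "500kb-1Mb", ">1Mb"), right = FALSE)
}

#' Candidate loop calling by multi-resolution density clustering
#'
#' Contact pairs are clustered in (pos1, pos2) space with a DBSCAN run for
#' every (eps, minPts) combination (Chebyshev/box metric). Cluster bounding
#' boxes give candidate anchors; all runs' candidates are returned and the
#' cross-run merge (tightest/smallest-eps box wins) happens after the
#' significance stage in \code{\link{loopSignificance}}, so that weak noise
#' clusters cannot shadow a genuine loop found at another resolution.
#' Self-ligation is removed by requiring the pair distance to exceed
#' \code{2 * max(epsList)}, and diffuse clusters whose anchor span exceeds
#' \code{maxAnchorSpan} are discarded as not loop-like (at deep coverage
#' the near-diagonal background otherwise forms one giant cluster).
#'
#' @param pairs data.frame with chrom, pos1, pos2 (bp).
#' @param epsList neighbourhood radii in bp (default 2000, 5000, 10000).
#' @param minPtsList core-point thresholds (default 20, 50).
#' @param maxAnchorSpan maximum anchor width in bp (default 6 * max eps).
#' @return data.frame of candidates: chrom, startA, endA, startB, endB
#'   (0-based half-open bp), pet, eps, minPts, distance (anchor midpoint
#'   separation). Attribute \code{nPairsUsed} records the pair count after
#'   the self-ligation filter.
#' @export
clusterLoops <- function(pairs, epsList = c(2000, 5000, 10000),
                         minPtsList = c(20, 50),
                         maxAnchorSpan = 6 * max(epsList)) {
  op <- orientPairs(pairs)
  op <- op[op$y - op$x > 2 * max(epsList), , drop = FALSE]
  accepted <- list()
  for (ch in unique(op$chrom)) {
    sub <- op[op$chrom == ch, ]
    acc <- NULL
    for (eps in sort(epsList)) {
      for (minPts in sort(minPtsList)) {
        lab <- .dbscanChebyshev(sub$x, sub$y, eps, minPts)
        if (!any(lab > 0)) next
        dt <- data.table::data.table(x = sub$x, y = sub$y, lab = lab)[lab > 0]
        cl <- as.data.frame(dt[, list(startA = min(x), endA = max(x) + 1,
                                      startB = min(y), endB = max(y) + 1,
                                      pet = .N), by = "lab"])[, -1]
        cl <- cl[(cl$endA - cl$startA) <= maxAnchorSpan &
                 (cl$endB - cl$startB) <= maxAnchorSpan &
                 cl$startB >= cl$endA, , drop = FALSE]
        if (!nrow(cl)) next
        cl$eps <- eps; cl$minPts <- minPts
        acc <- rbind(acc, cl)
      }
    }
    if (!is.null(acc) && nrow(acc))
      accepted[[ch]] <- data.frame(chrom = ch, acc)
  }
  out <- if (length(accepted))
    do.call(rbind, c(accepted, make.row.names = FALSE))
  else data.frame(chrom = character(), startA = numeric(), endA = numeric(),
                  startB = numeric(), endB = numeric(), pet = integer(),
                  eps = numeric(), minPts = numeric())
  if (nrow(out))
    out$distance <- (out$startB + out$endB) / 2 - (out$startA + out$endA) / 2
  attr(out, "nPairsUsed") <- nrow(op)
  out
}

mergeCandidates <- function(cand) {
  # greedy cross-run merge: smallest eps, then minPts, then smallest p
  # first; later boxes overlapping an accepted one are dropped
  ord <- order(cand$eps, cand$minPts, cand$p)
  keep <- logical(nrow(cand))
  for (ch in unique(cand$chrom)) {
    rows <- ord[cand$chrom[ord] == ch]
    accI <- integer(0)
    for (r in rows) {
      if (!length(accI) ||
          !any(cand$padStartA[r] < cand$padEndA[accI] &
               cand$padStartA[accI] < cand$padEndA[r] &
               cand$padStartB[r] < cand$padEndB[accI] &
               cand$padStartB[accI] < cand$padEndB[r])) {
        keep[r] <- TRUE
        accI <- c(accI, r)
      }
    }
  }
  keep
}

sortPairs <- function(op) {
  # pre-sorted (pos1, pos2) store for repeated rectangle counting
  o <- order(op$x)
  list(xs = op$x[o], ys = op$y[o])
}

countInBoxes <- function(sp, boxes) {
  # sp: sortPairs() of ONE chromosome; boxes: startA/endA/startB/endB
  xs <- sp$xs; ys <- sp$ys
  i1 <- findInterval(boxes$startA - 0.5, xs) + 1
  i2 <- findInterval(boxes$endA - 0.5, xs)
  sB <- boxes$startB; eB <- boxes$endB
  vapply(seq_len(nrow(boxes)), function(r) {
    if (i2[r] < i1[r]) return(0L)
    yy <- ys[i1[r]:i2[r]]
    sum(yy >= sB[r] & yy < eB[r])
  }, integer(1))
}

decayRateModel <- function(op, chromLen, nLogBins = 40) {
  # empirical pair rate per bp^2 as a step function of distance
  d <- op$y - op$x
  d <- d[d > 0]
  if (!length(d)) return(function(dist) rep(0, length(dist)))
  breaks <- exp(seq(log(max(min(d) * 0.999, 1)), log(max(d) * 1.001),
                    length.out = nLogBins + 1))
  cnt <- tabulate(findInterval(d, breaks, rightmost.closed = TRUE), nLogBins)
  mid <- sqrt(breaks[-1] * breaks[-(nLogBins + 1)])
  area <- pmax(chromLen - mid, 1) * diff(breaks)
  rate <- cnt / area
  function(dist) {
    k <- findInterval(dist, breaks, rightmost.closed = TRUE)
    out <- rep(0, length(dist))
    ok <- k >= 1 & k <= nLogBins
    out[ok] <- rate[k[ok]]
    out
  }
}

#' Score loop candidates against a local + decay background
#'
#' Candidate boxes are first padded to a standardized minimum window
#' (\code{padTo}, by default 1.5x the largest clustering eps) so that the
#' counting window is not shrink-wrapped around the cluster's own points
#' (an uncorrected scan-statistic bias that otherwise promotes random
#' clumps). For each padded candidate the expected count blends (50/50) a
#' local background (mean count over same-size boxes shifted along the
#' diagonal by +-5 and +-10 anchor widths, those inside the chromosome)
#' with a distance-decay expectation from the empirical pair-rate curve.
#' The p-value is the Poisson upper tail of the observed count,
#' BH-adjusted; kept loops need \code{q <= qMax} and observed/expected
#' \code{>= minFold}. Surviving candidates from the different (eps,
#' minPts) runs are then merged: smallest eps (tightest box) first, later
#' overlapping boxes dropped.
#'
#' @param candidates data.frame from \code{\link{clusterLoops}}.
#' @param pairs the pair list the candidates came from.
#' @param grid a \linkS4class{BinnedGenome} (for chromosome bounds).
#' @param qMax BH-adjusted cutoff (default 0.01).
#' @param minFold minimum observed/expected (default 2).
#' @param minExpected floor on the expected count (default 0.25).
#' @param padTo minimum counting-window width in bp (default 1.5x the
#'   largest eps among the candidates).
#' @return the significant merged loops with observed, expected, p, q,
#'   class columns; the unfiltered scored table is attached as attribute
#'   \code{allCandidates}.
#' @export
loopSignificance <- function(candidates, pairs, grid, qMax = 0.01,
                             minFold = 2, minExpected = 0.25, padTo = NULL) {
  if (!nrow(candidates)) {
    candidates$observed <- candidates$expected <- candidates$p <- candidates$q <- numeric(0)
    return(candidates)
  }
  if (is.null(padTo))
    padTo <- if (!is.null(candidates$eps)) 1.5 * max(candidates$eps) else 15000
  op <- orientPairs(pairs)
  res <- candidates
  padSide <- function(s, e) {
    grow <- pmax(0, padTo - (e - s)) / 2
    list(s = s - grow, e = e + grow)
  }
  pA <- padSide(res$startA, res$endA)
  pB <- padSide(res$startB, res$endB)
  res$padStartA <- pA$s; res$padEndA <- pA$e
  res$padStartB <- pB$s; res$padEndB <- pB$e
  res$observed <- NA_real_; res$expected <- NA_real_
  res$p <- NA_real_; res$pScan <- NA_real_
  for (ch in unique(res$chrom)) {
    sel <- which(res$chrom == ch)
    sub <- op[op$chrom == ch, ]
    L <- chromSizes(grid)[[ch]]
    rateFn <- decayRateModel(sub, L)
    sp <- sortPairs(sub)
    boxes <- data.frame(startA = res$padStartA[sel], endA = res$padEndA[sel],
                        startB = res$padStartB[sel], endB = res$padEndB[sel])
    obs <- countInBoxes(sp, boxes)
    wA <- boxes$endA - boxes$startA
    wB <- boxes$endB - boxes$startB
    w <- pmax(wA, wB)
    shifts <- rep(c(-10, -5, 5, 10), each = length(sel)) * rep(w, 4)
    bg <- data.frame(id = rep(seq_along(sel), 4),
                     startA = rep(boxes$startA, 4) + shifts,
                     endA = rep(boxes$endA, 4) + shifts,
                     startB = rep(boxes$startB, 4) + shifts,
                     endB = rep(boxes$endB, 4) + shifts)
    bg <- bg[bg$startA >= 0 & bg$endB <= L, , drop = FALSE]
    bgCnt <- countInBoxes(sp, bg)
    local <- rep(NA_real_, length(sel))
    if (nrow(bg)) {
      agg <- rowsum(bgCnt, bg$id) / rowsum(rep(1, nrow(bg)), bg$id)
      local[as.integer(rownames(agg))] <- agg
    }
    decay <- rateFn(res$distance[sel]) * wA * wB
    expd <- ifelse(is.na(local), decay, 0.5 * local + 0.5 * decay)
    res$expected[sel] <- pmax(expd, minExpected)
    res$observed[sel] <- obs
    res$p[sel] <- ppois(obs - 1, res$expected[sel], lower.tail = FALSE)
    # scan-statistic correction: the clustering stage effectively scans
    # every possible window position, so a candidate's Poisson tail is
    # Bonferroni-scaled by the number of window-sized tiles on the
    # chromosome before FDR control across candidates
    nWin <- pmax(1, (L^2 / 2) / (wA * wB))
    res$pScan[sel] <- pmin(1, res$p[sel] * nWin)
  }
  res$q <- bhAdjust(res$pScan)
  res$class <- distanceClass(res$distance)
  keep <- res$q <= qMax & res$observed / res$expected >= minFold
  out <- res[keep, , drop = FALSE]
  if (nrow(out)) out <- out[mergeCandidates(out), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "allCandidates") <- res
  out
}

loopCenterBins <- function(loops, grid) {
  bs <- binSize(grid)
  if (!is.null(loops$binI))
    return(data.frame(chrom = loops$chrom, bi = loops$binI, bj = loops$binJ))
  data.frame(chrom = loops$chrom,
             bi = floor((loops$startA + loops$endA) / 2 / bs),
             bj = floor((loops$startB + loops$endB) / 2 / bs))
}

#' Aggregate peak analysis
#'
#' Averages O/E submatrices centered on each loop's bin pair. The APA score
#' is the center pixel over the mean of the 3x3 corner block at shorter
#' distance (lower-left), the standard conservative background.
#'
#' @param cm a balanced or O/E \linkS4class{ContactMatrix} (typically 5 kb).
#' @param loops loop table (either bp anchors or binI/binJ columns).
#' @param flankBins half-width of the aggregated window in bins (default
#'   10). Loops closer than \code{2 * flankBins} bins or too near a
#'   chromosome end are dropped.
#' @return list: \code{matrix} (the (2f+1)^2 aggregate), \code{score},
#'   \code{nLoops} used.
#' @export
apa <- function(cm, loops, flankBins = 10) {
  oe <- if (normalization(cm) == "oe") cm else oeTransform(cm)
  grid <- binGrid(oe)
  ctr <- loopCenterBins(loops, grid)
  f <- flankBins
  acc <- matrix(0, 2 * f + 1, 2 * f + 1)
  cnt <- matrix(0, 2 * f + 1, 2 * f + 1)
  used <- 0L
  for (r in seq_len(nrow(ctr))) {
    ch <- ctr$chrom[r]
    if (!ch %in% chromNames(grid)) next
    n <- nBins(grid)[[ch]]
    bi <- ctr$bi[r] + 1L; bj <- ctr$bj[r] + 1L
    if (bj - bi <= 2 * f) next
    if (bi - f < 1 || bj + f > n) next
    m <- contactMatrices(oe, ch)[(bi - f):(bi + f), (bj - f):(bj + f)]
    ok <- is.finite(m)
    acc[ok] <- acc[ok] + m[ok]
    cnt <- cnt + ok
    used <- used + 1L
  }
  if (used < 5) warning("fewer than 5 usable loops for APA")
  agg <- acc / cnt
  ctrPix <- agg[f + 1, f + 1]
  corner <- agg[(2 * f - 1):(2 * f + 1), 1:3]  # anchor1 downstream, anchor2 upstream
  list(matrix = agg, score = ctrPix / mean(corner, na.rm = TRUE),
       nLoops = used)
}

#' Merge two loop sets into a union
#'
#' Loops are matched across sets by anchor-box overlap (after padding by
#' \code{tol}); unmatched loops of the second set are appended.
#'
#' @param set1,set2 loop data.frames with bp anchors.
#' @param tol padding in bp when testing anchor overlap (default 5000).
#' @return the union table with columns from set1 plus \code{inSet1},
#'   \code{inSet2}.
#' @export
unionLoops <- function(set1, set2, tol = 5000) {
  cols <- c("chrom", "startA", "endA", "startB", "endB")
  u <- set1[, cols, drop = FALSE]
  u$inSet1 <- TRUE; u$inSet2 <- FALSE
  for (r in seq_len(nrow(set2))) {
    hit <- which(u$chrom == set2$chrom[r] &
                 set2$startA[r] - tol < u$endA & u$startA - tol < set2$endA[r] &
                 set2$startB[r] - tol < u$endB & u$startB - tol < set2$endB[r])
    if (length(hit)) u$inSet2[hit[1]] <- TRUE
    else u <- rbind(u, data.frame(set2[r, cols, drop = FALSE],
                                  inSet1 = FALSE, inSet2 = TRUE))
  }
  u$distance <- (u$startB + u$endB) / 2 - (u$startA + u$endA) / 2
  rownames(u) <- NULL
  u
}

#' Depth-matched differential loop calling
#'
#' Both pair lists are subsampled without replacement to the smaller total
#' (seeded), then for each union loop the two conditions' anchor-box counts
#' (n1, n2) are compared against the local background counts (b1, b2, from
#' diagonal-shifted boxes) with a two-sided Fisher exact test on the
#' [n1 n2; b1 b2] table, the conditional form of the two-sample Poisson
#' rate comparison that also propagates the sampling noise of the
#' background ratio. Loops with a significant decrease in condition 2 are
#' \code{"lost"}, a significant increase \code{"gained"}, the rest
#' \code{"common"}. Swapping the conditions swaps the gained and lost
#' labels.
#'
#' @param pairs1,pairs2 contact pair lists of the two conditions.
#' @param loopsUnion union loop table (see \code{\link{unionLoops}}).
#' @param grid a \linkS4class{BinnedGenome}.
#' @param pMax raw p-value threshold (default 0.01); BH-adjusted values are
#'   also emitted.
#' @param seed subsampling seed.
#' @param padTo minimum counting-window width in bp (default 15 kb); the
#'   called anchor boxes are shrink-wrapped around one condition's points,
#'   so counting in unpadded boxes would bias that condition's count up.
#' @return the union table with n1, n2, p, q and label columns.
#' @export
differentialLoops <- function(pairs1, pairs2, loopsUnion, grid, pMax = 0.01,
                              seed = 1L, padTo = 15000) {
  withSeed(seed, {
    n1 <- nrow(pairs1); n2 <- nrow(pairs2)
    target <- min(n1, n2)
    if (n1 > target) pairs1 <- pairs1[sample.int(n1, target), ]
    if (n2 > target) pairs2 <- pairs2[sample.int(n2, target), ]
  })
  op1 <- orientPairs(pairs1); op2 <- orientPairs(pairs2)
  res <- loopsUnion
  res$n1 <- res$n2 <- 0L
  res$p <- NA_real_
  res$bgShare <- NA_real_
  grow <- function(s, e) pmax(0, padTo - (e - s)) / 2
  gA <- grow(res$startA, res$endA)
  gB <- grow(res$startB, res$endB)
  padded <- data.frame(chrom = res$chrom,
                       startA = res$startA - gA, endA = res$endA + gA,
                       startB = res$startB - gB, endB = res$endB + gB)
  for (ch in unique(res$chrom)) {
    sel <- which(res$chrom == ch)
    sp1 <- sortPairs(op1[op1$chrom == ch, ])
    sp2 <- sortPairs(op2[op2$chrom == ch, ])
    L <- chromSizes(grid)[[ch]]
    boxes <- padded[sel, , drop = FALSE]
    res$n1[sel] <- countInBoxes(sp1, boxes)
    res$n2[sel] <- countInBoxes(sp2, boxes)
    w <- pmax(boxes$endA - boxes$startA, boxes$endB - boxes$startB)
    shifts <- rep(c(-10, -5, 5, 10), each = length(sel)) * rep(w, 4)
    bg <- data.frame(id = rep(seq_along(sel), 4),
                     startA = rep(boxes$startA, 4) + shifts,
                     endA = rep(boxes$endA, 4) + shifts,
                     startB = rep(boxes$startB, 4) + shifts,
                     endB = rep(boxes$endB, 4) + shifts)
    bg <- bg[bg$startA >= 0 & bg$endB <= L, , drop = FALSE]
    b1 <- b2 <- rep(0, length(sel))
    if (nrow(bg)) {
      a1 <- rowsum(countInBoxes(sp1, bg), bg$id)
      a2 <- rowsum(countInBoxes(sp2, bg), bg$id)
      b1[as.integer(rownames(a1))] <- a1
      b2[as.integer(rownames(a2))] <- a2
    }
    pr <- (b1 + 0.5) / (b1 + b2 + 1)
    res$bgShare[sel] <- pr
    for (k in seq_along(sel)) {
      r <- sel[k]
      tot <- res$n1[r] + res$n2[r]
      res$p[r] <- if (tot == 0) 1 else
        fisher.test(matrix(c(res$n1[r], res$n2[r],
                             round(b1[k]), round(b2[k])), 2,
                           byrow = TRUE))$p.value
    }
  }
  res$q <- bhAdjust(res$p)
  share <- ifelse(res$n1 + res$n2 > 0, res$n1 / (res$n1 + res$n2), NA)
  res$label <- "common"
  sig <- !is.na(res$p) & res$p < pMax & !is.na(share)
  res$label[sig & share > res$bgShare] <- "lost"
  res$label[sig & share < res$bgShare] <- "gained"
  res
}

#' Distance-class composition of differential loop sets
#'
#' Fractions of gained, lost and common loops in the four distance classes
#' (< 100 kb, 100-500 kb, 500 kb-1 Mb, > 1 Mb), plus the lost/gained fold
#' ratio for the > 1 Mb class with a Fisher exact test on the count table.
#'
#' @param gained,lost,common loop tables with a \code{distance} column (bp).
#' @return list: \code{table} (set, class, count, fraction) and
#'   \code{longRange} (lostFraction, gainedFraction, fold, p).
#' @export
distanceClassify <- function(gained, lost, common) {
  sets <- list(gained = gained, lost = lost, common = common)
  rows <- list()
  for (s in names(sets)) {
    cl <- distanceClass(sets[[s]]$distance)
    tab <- table(cl)
    rows[[s]] <- data.frame(set = s, class = names(tab),
                            count = as.integer(tab),
                            fraction = if (sum(tab)) as.numeric(tab) / sum(tab)
                                       else NaN)
  }
  tabl <- do.call(rbind, c(rows, make.row.names = FALSE))
  lostLong <- sum(distanceClass(lost$distance) == ">1Mb")
  gainLong <- sum(distanceClass(gained$distance) == ">1Mb")
  fl <- if (nrow(lost)) lostLong / nrow(lost) else NaN
  fg <- if (nrow(gained)) gainLong / nrow(gained) else NaN
  p <- if (nrow(lost) && nrow(gained))
    fisher.test(matrix(c(lostLong, nrow(lost) - lostLong,
                         gainLong, nrow(gained) - gainLong), 2))$p.value
    else NA_real_
  list(table = tabl,
       longRange = list(lostFraction = fl, gainedFraction = fg,
                        fold = fl / fg, p = p))
}

#' Write loops as BEDPE
#' @param loops loop table with bp anchors; score column = -log10(q) when
#'   available.
#' @param path output path.
#' @export
writeBedpe <- function(loops, path) {
  sc <- if (!is.null(loops$q)) round(-log10(pmax(loops$q, 1e-300)), 3) else 0
  dt <- data.table::data.table(
    chrom1 = loops$chrom, start1 = loops$startA, end1 = loops$endA,
    chrom2 = loops$chrom, start2 = loops$startB, end2 = loops$endB,
    name = sprintf("loop%d", seq_len(nrow(loops))), score = sc,
    class = if (!is.null(loops$class)) as.character(loops$class) else ".")
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, scipen = 50)
  invisible(path)
}
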