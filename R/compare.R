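distanceStats <- function(m, maskv) {
  n <- nrow(m)
  s <- rep(NA_real_, n); cnt <- integer(n)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    ok <- maskv[i] & maskv[i + d]
    cnt[d + 1] <- sum(ok)
    if (cnt[d + 1]) s[d + 1] <- sum(m[cbind(i[ok], i[ok] + d)])
  }
  data.frame(d = 0:(n - 1), sum = s, n = cnt)
}

#' Contact probability versus genomic distance
#'
#' Mean unmasked contact per log-spaced distance bin, pooled over
#' chromosomes; the P(s) curve. Distance bins with no pairs are omitted.
#'
#' @param cm a raw or depth-normalized \linkS4class{ContactMatrix}.
#' @param nLogBins number of log-spaced distance bins (default 50).
#' @return data.frame with \code{distance} (geometric mid, bp) and
#'   \code{meanContact}.
#' @export
psCurve <- function(cm, nLogBins = 50) {
  bs <- binSize(binGrid(cm))
  per <- lapply(chromNames(binGrid(cm)), function(ch)
    distanceStats(contactMatrices(cm, ch), binMask(cm, ch)))
  maxD <- max(vapply(per, nrow, integer(1))) - 1
  breaks <- exp(seq(log(bs * 0.999), log(maxD * bs * 1.001),
                    length.out = nLogBins + 1))
  sums <- numeric(nLogBins); cnts <- numeric(nLogBins); dsum <- numeric(nLogBins)
  for (st in per) {
    st <- st[st$d > 0 & st$n > 0, ]
    if (!nrow(st)) next
    bin <- findInterval(st$d * bs, breaks, rightmost.closed = TRUE)
    ok <- bin >= 1 & bin <= nLogBins
    sums <- sums + tabulate2(bin[ok], st$sum[ok], nLogBins)
    cnts <- cnts + tabulate2(bin[ok], st$n[ok], nLogBins)
    dsum <- dsum + tabulate2(bin[ok], st$d[ok] * bs * st$n[ok], nLogBins)
  }
  keep <- cnts > 0
  data.frame(distance = dsum[keep] / cnts[keep],
             meanContact = sums[keep] / cnts[keep])
}

#' Log-log slope of a P(s) curve
#'
#' @param ps output of \code{\link{psCurve}}.
#' @param minDistance,maxDistance fit range in bp (default: full curve).
#' @return the fitted slope (a pure power law of exponent a gives -a).
#' @export
psSlope <- function(ps, minDistance = 0, maxDistance = Inf) {
  sub <- ps[ps$distance >= minDistance & ps$distance <= maxDistance &
              ps$meanContact > 0, ]
  unname(coef(lm(log(meanContact) ~ log(distance), data = sub))[2])
}

#' Log2 differential contact map
#'
#' \code{log2((a + pc) / (b + pc))} per chromosome; bins masked in either
#' input become NaN. Swapping the inputs negates the map.
#'
#' @param cmA,cmB depth-normalized \linkS4class{ContactMatrix} objects on
#'   the same grid (condition of interest first).
#' @param pseudocount added to both maps before the ratio (default 1, i.e.
#'   one raw-count equivalent after depth scaling).
#' @return named list of dense signed matrices.
#' @export
log2RatioMap <- function(cmA, cmB, pseudocount = 1) {
  if (!sameGrid(binGrid(cmA), binGrid(cmB))) stop("grids differ")
  out <- list()
  for (ch in chromNames(binGrid(cmA))) {
    r <- log2((contactMatrices(cmA, ch) + pseudocount) /
              (contactMatrices(cmB, ch) + pseudocount))
    bad <- !(binMask(cmA, ch) & binMask(cmB, ch))
    r[bad, ] <- NaN; r[, bad] <- NaN
    out[[ch]] <- r
  }
  out
}

meanFilter2d <- function(m, h) {
  if (h <= 0) return(m)
  n <- nrow(m)
  S <- matrix(0, n + 1, n + 1)
  S[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  i1 <- pmax(seq_len(n) - h, 1); i2 <- pmin(seq_len(n) + h, n)
  tot <- S[i2 + 1, , drop = FALSE][, i2 + 1, drop = FALSE] -
         S[i1, , drop = FALSE][, i2 + 1, drop = FALSE] -
         S[i2 + 1, , drop = FALSE][, i1, drop = FALSE] +
         S[i1, , drop = FALSE][, i1, drop = FALSE]
  cnt <- outer(i2 - i1 + 1, i2 - i1 + 1)
  tot / cnt
}

#' Stratum-adjusted correlation coefficient
#'
#' Distance-stratified reproducibility score for two contact maps: Pearson
#' correlations are computed per distance stratum (after optional 2D mean
#' filter smoothing) and combined as a weighted mean with weights
#' \code{N_d * sqrt(var_a * var_b)}, the stratum pair count times the
#' geometric mean of the stratum variances.
#'
#' @param cmA,cmB \linkS4class{ContactMatrix} objects on the same grid, both
#'   raw or both depth-normalized.
#' @param maxDistance largest stratum distance in bp (default 5 Mb).
#' @param smoothH mean-filter radius in bins (default 1; 0 disables).
#' @return a single correlation in [-1, 1].
#' @export
scc <- function(cmA, cmB, maxDistance = 5e6, smoothH = 1) {
  if (!sameGrid(binGrid(cmA), binGrid(cmB))) stop("grids differ")
  bs <- binSize(binGrid(cmA))
  maxD <- max(1L, as.integer(floor(maxDistance / bs)))
  wsum <- 0; wr <- 0; usable <- 0L
  for (ch in chromNames(binGrid(cmA))) {
    a <- meanFilter2d(contactMatrices(cmA, ch), smoothH)
    b <- meanFilter2d(contactMatrices(cmB, ch), smoothH)
    ok <- binMask(cmA, ch) & binMask(cmB, ch)
    n <- nrow(a)
    for (d in seq_len(min(maxD, n - 1))) {
      i <- seq_len(n - d)
      sel <- ok[i] & ok[i + d]
      if (sum(sel) < 3) next
      va <- a[cbind(i[sel], i[sel] + d)]
      vb <- b[cbind(i[sel], i[sel] + d)]
      sa <- var(va); sb <- var(vb)
      if (sa <= 0 || sb <= 0) next
      r <- cor(va, vb)
      w <- length(va) * sqrt(sa * sb)
      wsum <- wsum + w; wr <- wr + w * r
      usable <- usable + 1L
    }
  }
  if (usable < 2) stop("fewer than 2 usable strata with >= 3 pairs")
  wr / wsum
}

ssimIndex <- function(wa, wb) {
  ok <- is.finite(wa) & is.finite(wb)
  a <- wa[ok]; b <- wb[ok]
  if (length(a) < 4) return(NA_real_)
  L <- max(max(a, b) - min(a, b), 1e-8)
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  mu_a <- mean(a); mu_b <- mean(b)
  va <- mean((a - mu_a)^2); vb <- mean((b - mu_b)^2)
  cab <- mean((a - mu_a) * (b - mu_b))
  ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
}

#' Sliding-window structural-similarity z-scores
#'
#' For sliding windows along the diagonal, the structural-similarity index
#' (luminance-contrast-structure form with stabilizing constants) between
#' the log2 O/E submatrices of two conditions, z-normalized per chromosome.
#' Lower z means a greater structural difference. The z-normalization is
#' per chromosome (recorded in the output).
#'
#' @param cmA,cmB depth-normalized \linkS4class{ContactMatrix} objects.
#' @param windowBp window size in bp (must span >= 3 bins).
#' @param stepBp step between window starts in bp.
#' @return data.frame: chrom, start, end (bp), ssim, z; attribute
#'   \code{zScope = "per-chromosome"}.
#' @export
windowSimilarityZ <- function(cmA, cmB, windowBp = 5e5, stepBp = 5e4) {
  bs <- binSize(binGrid(cmA))
  W <- as.integer(round(windowBp / bs))
  if (W < 3) stop("window spans fewer than 3 bins")
  step <- max(1L, as.integer(round(stepBp / bs)))
  oeA <- oeTransform(cmA); oeB <- oeTransform(cmB)
  out <- list()
  for (ch in chromNames(binGrid(cmA))) {
    la <- suppressWarnings(log2(contactMatrices(oeA, ch)))
    lb <- suppressWarnings(log2(contactMatrices(oeB, ch)))
    la[!is.finite(la)] <- NA; lb[!is.finite(lb)] <- NA
    n <- nrow(la)
    if (n < W) next
    starts <- seq(1L, n - W + 1L, by = step)
    ss <- vapply(starts, function(s) {
      idx <- s:(s + W - 1L)
      ssimIndex(la[idx, idx], lb[idx, idx])
    }, numeric(1))
    sdv <- sd(ss, na.rm = TRUE)
    mu <- mean(ss, na.rm = TRUE)
    z <- if (is.na(sdv) || sdv == 0) rep(0, length(ss)) else (ss - mu) / sdv
    z[is.na(ss)] <- NA
    out[[ch]] <- data.frame(chrom = ch, start = (starts - 1) * bs,
                            end = pmin((starts - 1 + W) * bs,
                                       chromSizes(binGrid(cmA))[[ch]]),
                            ssim = ss, z = z)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(res, "zScope") <- "per-chromosome"
  res
}

defaultDistanceClasses <- function() {
  data.frame(name = c("20-50kb", "50-100kb", "100-500kb", "500kb-1Mb", ">1Mb"),
             lo = c(2e4, 5e4, 1e5, 5e5, 1e6),
             hi = c(5e4, 1e5, 5e5, 1e6, Inf))
}

#' Promoter-distal contact change by distance class
#'
#' For each gene set (all / up / down DEGs) and distance band, the mean over
#' genes of the log2 ratio of summed contacts between the promoter bin and
#' all bins in that band. Promoters are the 2 kb upstream of the TSS
#' (strand-aware); genes whose promoter falls off the grid are skipped and
#' tallied.
#'
#' @param cmA,cmB depth-normalized \linkS4class{ContactMatrix} objects
#'   (condition of interest first).
#' @param genes data.frame with chrom, start, end, strand, degLabel.
#' @param distanceClasses data.frame name/lo/hi in bp (half-open bands);
#'   default 20-50 kb, 50-100 kb, 100-500 kb, 500 kb-1 Mb, >1 Mb.
#' @param pseudocount added to both sums before the ratio.
#' @return data.frame: geneSet, class, meanLog2Change, nGenes; attribute
#'   \code{skipped} = genes off the grid.
#' @export
promoterDistalChange <- function(cmA, cmB, genes,
                                 distanceClasses = defaultDistanceClasses(),
                                 pseudocount = 1) {
  grid <- binGrid(cmA)
  bs <- binSize(grid)
  prom <- promoterIntervals(genes)
  pmid <- floor((prom$start + prom$end) / 2)
  skipped <- 0L
  perGene <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    ch <- genes$chrom[g]
    if (!ch %in% chromNames(grid) || pmid[g] < 0 ||
        pmid[g] >= chromSizes(grid)[[ch]]) { skipped <- skipped + 1L; next }
    p <- binOf(grid, pmid[g]) + 1L
    m1 <- contactMatrices(cmA, ch); m2 <- contactMatrices(cmB, ch)
    dists <- abs(seq_len(nrow(m1)) - p) * bs
    lfc <- vapply(seq_len(nrow(distanceClasses)), function(k) {
      sel <- dists >= distanceClasses$lo[k] & dists < distanceClasses$hi[k]
      log2((sum(m1[p, sel]) + pseudocount) / (sum(m2[p, sel]) + pseudocount))
    }, numeric(1))
    perGene[[g]] <- lfc
  }
  got <- !vapply(perGene, is.null, logical(1))
  sets <- list(all = got,
               up = got & genes$degLabel == "up",
               down = got & genes$degLabel == "down")
  rows <- list()
  for (s in names(sets)) {
    sel <- which(sets[[s]])
    mat <- do.call(rbind, perGene[sel])
    for (k in seq_len(nrow(distanceClasses)))
      rows[[length(rows) + 1]] <- data.frame(
        geneSet = s, class = distanceClasses$name[k],
        meanLog2Change = if (length(sel)) mean(mat[, k]) else NaN,
        nGenes = length(sel))
  }
  res <- do.call(rbind, rows)
  attr(res, "skipped") <- skipped
  res
}
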