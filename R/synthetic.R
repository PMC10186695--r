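#' Configuration for the synthetic architecture generator
#'
#' Bundles all knobs of the two-condition synthetic Hi-C generator. The
#' defaults describe the benchmark genome used throughout the package: a
#' 10 Mb two-chromosome genome binned at 5 kb, sampled to 5e6 contact
#' pairs, with power-law distance decay of exponent 1, megabase-scale
#' alternating compartment blocks, ~200 kb TADs at 3-fold enrichment, 80
#' focal loops at 5-fold enrichment, and a paired condition carrying 15.5%
#' compartment switching (A-to-B favored 9:1), 30% boundary turnover and
#' 30% loop loss.
#'
#' @param chromSizes named chromosome lengths in bp.
#' @param binSize bin width in bp.
#' @param decayExponent power-law slope of contact probability P(s).
#' @param compartmentAmplitude checkerboard contrast (>= 0): same-label bin
#'   pairs get rate x (1 + amplitude), opposite pairs / (1 + amplitude).
#' @param compartmentBlockMean mean compartment block length in bins
#'   (geometric block process).
#' @param tadMeanSize mean TAD size in bins.
#' @param tadMinSize minimum TAD size in bins (default 6, i.e. 30 kb at a
#'   5 kb bin: domains below the smallest insulation window cannot exist
#'   at the emulated resolution).
#' @param tadEnrichment fold enrichment of intra-TAD contacts (>= 1).
#' @param nLoops number of planted loops in condition 1.
#' @param loopEnrichment fold enrichment on each loop's 3x3 bin
#'   neighborhood (>= 1).
#' @param loopMinSep,loopMaxSep loop anchor separation range in bins
#'   (log-uniform draw).
#' @param depth expected total contact pairs per condition.
#' @param switchFraction fraction of bins flipping compartment label in
#'   condition 2 (flipped in whole blocks).
#' @param abBias share of switched blocks going A-to-B (default 0.9).
#' @param boundaryChangeFraction fraction of boundaries lost, and the same
#'   fraction gained, in condition 2.
#' @param loopLossFraction fraction of loops removed in condition 2; lost
#'   loops are drawn with probability proportional to distance squared,
#'   mimicking the preferential loss of long-range loops.
#' @param loopGainRatio gained loops per lost loop (< 1; gains are drawn
#'   short-range biased).
#' @param genesPerMb gene density; genes land 70% in A bins.
#' @param degFraction baseline fraction of genes that are DEGs.
#' @param degUpShare fraction of baseline DEGs that are upregulated.
#' @param degBoost DEG-rate multiplier applied to genes at gained/lost
#'   boundaries and lost-loop anchors in condition 2.
#' @param seed integer seed; all outputs are deterministic given the
#'   config.
#' @return a validated list of class \code{ArchitectureConfig}.
#' @export
architectureConfig <- function(chromSizes = c(chr1 = 5e6, chr2 = 5e6),
                               binSize = 5000,
                               decayExponent = 1,
                               compartmentAmplitude = 0.5,
                               compartmentBlockMean = 200,
                               tadMeanSize = 40,
                               tadMinSize = 6,
                               tadEnrichment = 3,
                               nLoops = 80,
                               loopEnrichment = 5,
                               loopMinSep = 12,
                               loopMaxSep = 300,
                               depth = 5e6,
                               switchFraction = 0.155,
                               abBias = 0.9,
                               boundaryChangeFraction = 0.3,
                               loopLossFraction = 0.3,
                               loopGainRatio = 0.8,
                               genesPerMb = 125,
                               degFraction = 0.095,
                               degUpShare = 0.44,
                               degBoost = 2,
                               seed = 1L) {
  cfg <- list(chromSizes = chromSizes, binSize = binSize,
              decayExponent = decayExponent,
              compartmentAmplitude = compartmentAmplitude,
              compartmentBlockMean = compartmentBlockMean,
              tadMeanSize = tadMeanSize, tadMinSize = tadMinSize,
              tadEnrichment = tadEnrichment,
              nLoops = nLoops, loopEnrichment = loopEnrichment,
              loopMinSep = loopMinSep, loopMaxSep = loopMaxSep,
              depth = depth, switchFraction = switchFraction,
              abBias = abBias,
              boundaryChangeFraction = boundaryChangeFraction,
              loopLossFraction = loopLossFraction,
              loopGainRatio = loopGainRatio, genesPerMb = genesPerMb,
              degFraction = degFraction, degUpShare = degUpShare,
              degBoost = degBoost, seed = as.integer(seed))
  if (cfg$binSize <= 0) stop("binSize must be positive")
  fr <- c(cfg$switchFraction, cfg$boundaryChangeFraction,
          cfg$loopLossFraction, cfg$degFraction, cfg$degUpShare, cfg$abBias)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  if (cfg$depth < 0) stop("depth must be >= 0")
  if (any(cfg$chromSizes < 10 * cfg$binSize))
    stop("chromosome lengths must be >= 10 * binSize")
  if (cfg$tadEnrichment < 1 || cfg$loopEnrichment < 1)
    stop("enrichment factors must be >= 1")
  if (cfg$compartmentAmplitude < 0) stop("compartmentAmplitude must be >= 0")
  if (cfg$tadMinSize < 2) stop("tadMinSize must be >= 2 bins")
  if (cfg$tadMeanSize <= cfg$tadMinSize)
    stop("tadMeanSize must exceed tadMinSize")
  class(cfg) <- "ArchitectureConfig"
  cfg
}

geometricBlocks <- function(n, mean) {
  # alternating-run lengths, geometric with the given mean (minimum 1)
  lens <- integer(0)
  while (sum(lens) < n)
    lens <- c(lens, rgeom(max(8L, ceiling(n / mean)), 1 / mean) + 1L)
  lens <- lens[cumsum(lens) - lens < n]
  lens[length(lens)] <- n - sum(head(lens, -1))
  lens
}

tadInterior <- function(nb, bounds) {
  # bins at least 2 bins inside a TAD (not adjacent to a boundary or end)
  edges <- c(0L, bounds, nb)
  bad <- unique(unlist(lapply(edges, function(b) (b - 2L):(b + 1L))))
  setdiff(0:(nb - 1L), bad[bad >= 0 & bad < nb])
}

placeLoops <- function(nb, bounds, nLoops, loopMinSep, loopMaxSep, existing = NULL) {
  interior <- tadInterior(nb, bounds)
  loops <- existing
  tries <- 0
  while (NROW(loops) < nLoops + NROW(existing) && tries < 50 * (nLoops + 1)) {
    tries <- tries + 1
    d <- round(exp(runif(1, log(loopMinSep), log(min(loopMaxSep, nb - 5)))))
    d <- max(d, max(2L, loopMinSep))
    cand <- interior[(interior + d) %in% interior]
    if (!length(cand)) next
    bi <- sample(cand, 1)
    bj <- bi + d
    if (!is.null(loops) && nrow(loops) &&
        any(abs(loops$binI - bi) <= 2 & abs(loops$binJ - bj) <= 2)) next
    loops <- rbind(loops, data.frame(binI = as.integer(bi), binJ = as.integer(bj)))
  }
  loops
}

#' Generate a planted chromatin architecture
#'
#' Draws condition-1 ground truth from an \code{\link{architectureConfig}}:
#' alternating A/B compartment blocks (geometric block lengths), TAD
#' boundaries (geometric inter-boundary gaps, independent of compartment
#' edges), focal loops whose anchors sit in TAD interiors, genes (70% in A
#' bins, A genes more highly expressed), H3K27ac peaks at TSSs of
#' high-expression genes, H3K27me3 domains over low-expression gene blocks,
#' and DHSs at every loop anchor plus random background sites. All draws
#' are deterministic given \code{config$seed}.
#'
#' @param config an \code{\link{architectureConfig}}.
#' @return a \linkS4class{GroundTruth}.
#' @export
generateArchitecture <- function(config) {
  grid <- binnedGenome(config$chromSizes, config$binSize)
  nb <- nBins(grid)
  if (any(nb < config$compartmentBlockMean))
    stop("chromosome shorter than one compartment block")
  withSeed(config$seed, {
    comps <- list(); bounds <- list(); loopL <- list()
    totalBins <- sum(nb)
    for (ch in chromNames(grid)) {
      n <- nb[[ch]]
      lens <- geometricBlocks(n, config$compartmentBlockMean)
      start <- sample(c("A", "B"), 1)
      labs <- rep(rep(c(start, setdiff(c("A", "B"), start)),
                      length.out = length(lens)), lens)
      comps[[ch]] <- labs
      mg <- config$tadMinSize
      gapMean <- max(config$tadMeanSize - mg, 1e-6)
      gaps <- mg + rgeom(ceiling(3 * n / config$tadMeanSize) + 8L, 1 / gapMean)
      b <- cumsum(gaps)
      bounds[[ch]] <- b[b >= 2 & b <= n - 2]
      nl <- round(config$nLoops * n / totalBins)
      lp <- placeLoops(n, bounds[[ch]], nl, config$loopMinSep, config$loopMaxSep)
      if (!is.null(lp) && nrow(lp))
        loopL[[ch]] <- data.frame(chrom = ch, lp)
    }
    loops <- if (length(loopL)) do.call(rbind, c(loopL, make.row.names = FALSE))
             else data.frame(chrom = character(), binI = integer(), binJ = integer())
    genes <- synthGenes(grid, comps, config)
    marks <- synthMarks(grid, genes)
    dhs <- synthDhs(grid, loops, config)
    new("GroundTruth", grid = grid, compartments = comps,
        boundaries = bounds, loops = loops, genes = genes,
        markPeaks = marks, dhs = dhs, changes = list())
  })
}

synthGenes <- function(grid, comps, config) {
  bs <- binSize(grid)
  rows <- list()
  for (ch in chromNames(grid)) {
    n <- nBins(grid)[[ch]]
    nGenes <- round(config$genesPerMb * chromSizes(grid)[[ch]] / 1e6)
    if (!nGenes) next
    labs <- comps[[ch]]
    aBins <- which(labs == "A") - 1L
    bBins <- which(labs == "B") - 1L
    # per-bin density 2:1 in favour of A (~70% of genes in A when the
    # genome is half A), so density enrichment holds whatever the realized
    # A share is
    pA <- 2 * length(aBins) / (2 * length(aBins) + length(bBins))
    inA <- runif(nGenes) < pA
    if (!length(aBins)) inA[] <- FALSE
    if (!length(bBins)) inA[] <- TRUE
    bin <- integer(nGenes)
    bin[inA] <- sample(aBins, sum(inA), replace = TRUE)
    bin[!inA] <- sample(bBins, sum(!inA), replace = TRUE)
    len <- round(runif(nGenes, 1000, 4000))
    start <- pmax(0, pmin(bin * bs + round(runif(nGenes, 0, bs - 1)),
                          chromSizes(grid)[[ch]] - len - 1))
    fpkm1 <- ifelse(inA, rlnorm(nGenes, meanlog = 2, sdlog = 1),
                    rlnorm(nGenes, meanlog = 0.5, sdlog = 1))
    isDeg <- runif(nGenes) < config$degFraction
    up <- runif(nGenes) < config$degUpShare
    lfc <- ifelse(isDeg, ifelse(up, 1, -1) * runif(nGenes, 1.5, 4),
                  runif(nGenes, -0.8, 0.8))
    rows[[ch]] <- data.frame(
      chrom = ch, start = as.integer(start),
      end = as.integer(start + len),
      strand = sample(c("+", "-"), nGenes, replace = TRUE),
      fpkm1 = fpkm1, fpkm2 = fpkm1 * 2^lfc)
  }
  genes <- do.call(rbind, c(rows, make.row.names = FALSE))
  genes <- genes[order(genes$chrom, genes$start), ]
  genes$geneId <- sprintf("gene%05d", seq_len(nrow(genes)))
  lfc <- log2(genes$fpkm2 / genes$fpkm1)
  genes$degLabel <- ifelse(abs(lfc) > 1, ifelse(lfc > 0, "up", "down"), "ns")
  rownames(genes) <- NULL
  genes[, c("geneId", "chrom", "start", "end", "strand",
            "fpkm1", "fpkm2", "degLabel")]
}

synthMarks <- function(grid, genes) {
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  hi <- genes$fpkm1 > median(genes$fpkm1)
  ac <- data.frame(chrom = genes$chrom[hi],
                   start = pmax(0, tss[hi] - 500), end = tss[hi] + 500)
  lo <- genes$fpkm1 < quantile(genes$fpkm1, 0.25)
  me <- data.frame(chrom = genes$chrom[lo],
                   start = pmax(0, genes$start[lo] - 2000),
                   end = genes$end[lo] + 2000)
  mergeIv <- function(df) {
    if (!nrow(df)) return(df)
    gr <- IRanges::reduce(grIntervals(df))
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr))
  }
  list(H3K27ac = mergeIv(ac), H3K27me3 = mergeIv(me))
}

synthDhs <- function(grid, loops, config) {
  bs <- binSize(grid)
  anchor <- function(bin) {
    ctr <- bin * bs + bs / 2
    data.frame(start = as.integer(ctr - 750), end = as.integer(ctr + 750))
  }
  at <- rbind(data.frame(chrom = loops$chrom, anchor(loops$binI)),
              data.frame(chrom = loops$chrom, anchor(loops$binJ)))
  bgRows <- lapply(chromNames(grid), function(ch) {
    nbg <- max(1L, round(chromSizes(grid)[[ch]] / 1e5))
    len <- round(runif(nbg, 500, 1500))
    s <- round(runif(nbg, 0, chromSizes(grid)[[ch]] - len - 1))
    data.frame(chrom = ch, start = as.integer(s), end = as.integer(s + len))
  })
  out <- rbind(at, do.call(rbind, bgRows))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Expected contact intensity of a planted architecture
#'
#' Deterministic per-chromosome rate matrices:
#' \code{rate(i,j) = (|i-j| * binSize)^(-decayExponent) * c(i,j) * t(i,j) *
#' l(i,j)} where c is the compartment checkerboard factor, t the intra-TAD
#' enrichment and l the 3x3 loop-neighborhood enrichment. The diagonal is
#' zero and the matrix symmetric; absolute scale is fixed later by
#' \code{\link{sampleContacts}}.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param config the \code{\link{architectureConfig}} used to generate it.
#' @return named list of dense nonnegative rate matrices.
#' @export
expectedIntensity <- function(truth, config) {
  grid <- truth@grid
  bs <- binSize(grid)
  out <- list()
  for (ch in chromNames(grid)) {
    n <- nBins(grid)[[ch]]
    D <- abs(outer(seq_len(n), seq_len(n), "-"))
    R <- (D * bs)^(-config$decayExponent)
    diag(R) <- 0
    if (config$compartmentAmplitude > 0) {
      lab <- truth@compartments[[ch]]
      same <- outer(lab, lab, "==")
      R <- R * ifelse(same, 1 + config$compartmentAmplitude,
                      1 / (1 + config$compartmentAmplitude))
    }
    if (config$tadEnrichment > 1) {
      tid <- findInterval(0:(n - 1), truth@boundaries[[ch]])
      R <- R * (1 + (config$tadEnrichment - 1) * outer(tid, tid, "=="))
    }
    lp <- truth@loops[truth@loops$chrom == ch, , drop = FALSE]
    if (nrow(lp) && config$loopEnrichment > 1) {
      for (k in seq_len(nrow(lp))) {
        ii <- pmax(1, pmin(n, lp$binI[k] + 0:2))  # binI-1..binI+1, 1-based
        jj <- pmax(1, pmin(n, lp$binJ[k] + 0:2))
        R[ii, jj] <- R[ii, jj] * config$loopEnrichment
        R[jj, ii] <- t(R[ii, jj])
      }
    }
    out[[ch]] <- R
  }
  out
}

#' Poisson-sample a contact map from rate matrices
#'
#' Upper-triangle counts are drawn independently Poisson with means scaled
#' so the expected total equals \code{depth}, then mirrored. Optionally also
#' returns a raw pair list with each pair placed uniformly within its bin.
#'
#' @param rates named list of rate matrices (see
#'   \code{\link{expectedIntensity}}).
#' @param grid the matching \linkS4class{BinnedGenome}.
#' @param depth expected total number of contact pairs.
#' @param seed integer seed.
#' @param pairs if TRUE, also generate the contact-pair list.
#' @return a \linkS4class{ContactMatrix}, with the pair data.frame (chrom,
#'   pos1, pos2) attached as attribute \code{"pairs"} when requested.
#' @export
sampleContacts <- function(rates, grid, depth, seed = 1L, pairs = FALSE) {
  stopifnot(all(vapply(rates, function(r) all(is.finite(r)) && min(r) >= 0,
                       logical(1))))
  totExp <- sum(vapply(rates, function(r) sum(r[upper.tri(r, diag = TRUE)]),
                       numeric(1)))
  sc <- if (totExp > 0) depth / totExp else 0
  withSeed(seed, {
    mats <- list(); pl <- list()
    bs <- binSize(grid)
    for (ch in names(rates)) {
      r <- rates[[ch]]
      n <- nrow(r)
      up <- upper.tri(r, diag = TRUE)
      cnt <- numeric(length(r))
      cnt[up] <- rpois(sum(up), r[up] * sc)
      m <- matrix(cnt, n, n)
      m <- m + t(m)
      diag(m) <- diag(matrix(cnt, n, n))
      mats[[ch]] <- m
      if (pairs) {
        idx <- which(up & matrix(cnt, n, n) > 0, arr.ind = TRUE)
        k <- matrix(cnt, n, n)[idx]
        i <- rep(idx[, 1] - 1L, k); j <- rep(idx[, 2] - 1L, k)
        lim <- chromSizes(grid)[[ch]] - 1
        pl[[ch]] <- data.frame(
          chrom = ch,
          pos1 = pmin(floor(i * bs + runif(length(i)) * bs), lim),
          pos2 = pmin(floor(j * bs + runif(length(j)) * bs), lim))
      }
    }
    cm <- contactMatrix(grid, mats)
    if (pairs)
      attr(cm, "pairs") <- do.call(rbind, c(pl, make.row.names = FALSE))
    cm
  })
}

#' Perturb a planted architecture into condition 2
#'
#' Applies the configured two-condition changes: flips whole compartment
#' blocks until \code{switchFraction} of bins have switched (A-to-B favored
#' by \code{abBias}), removes and gains \code{boundaryChangeFraction} of TAD
#' boundaries, deletes \code{loopLossFraction} of loops (long-range biased)
#' and adds \code{loopGainRatio} times as many new short-range-biased loops.
#' Genes falling in changed boundaries or lost-loop anchors get an elevated
#' DEG rate (up-biased at gained boundaries, down-biased at lost ones). The
#' exact change sets are recorded in \code{changes} for recovery scoring.
#'
#' @param truth condition-1 \linkS4class{GroundTruth}.
#' @param config the \code{\link{architectureConfig}}.
#' @return condition-2 \linkS4class{GroundTruth} with the \code{changes}
#'   slot filled. Its \code{genes} table carries the final two-condition
#'   expression values and DEG labels for both conditions.
#' @export
perturbCondition <- function(truth, config) {
  grid <- truth@grid
  nb <- nBins(grid)
  withSeed(config$seed + 101L, {
    comps <- truth@compartments
    switched <- switchBlocks(comps, config)
    comps <- switched$labels
    bch <- perturbBoundaries(truth@boundaries, nb, config)
    lch <- perturbLoops(truth@loops, truth@boundaries, bch$boundaries, grid, config)
    genes <- boostDegAtChanges(truth@genes, grid, bch, lch, config)
    changes <- list(switchedBlocks = switched$blocks,
                    lostBoundaries = bch$lost, gainedBoundaries = bch$gained,
                    lostLoops = lch$lost, gainedLoops = lch$gained)
    new("GroundTruth", grid = grid, compartments = comps,
        boundaries = bch$boundaries, loops = lch$loops, genes = genes,
        markPeaks = truth@markPeaks, dhs = truth@dhs, changes = changes)
  })
}

switchBlocks <- function(comps, config) {
  total <- sum(lengths(comps))
  target <- config$switchFraction * total
  blocks <- do.call(rbind, lapply(names(comps), function(ch) {
    r <- rle(comps[[ch]])
    e <- cumsum(r$lengths)
    data.frame(chrom = ch, startBin = c(0L, head(e, -1)), endBin = e,
               label = r$values, stringsAsFactors = FALSE)
  }))
  if (target > total) stop("switchFraction exceeds available bins")
  flippedRows <- integer(0)
  flipped <- 0
  avail <- rep(TRUE, nrow(blocks))
  while (flipped < target) {
    if (!any(avail)) stop("not enough compartment blocks to reach switchFraction")
    want <- if (runif(1) < config$abBias) "A" else "B"
    cand <- which(avail & blocks$label == want)
    if (!length(cand)) cand <- which(avail)
    k <- if (length(cand) == 1) cand else sample(cand, 1)
    avail[k] <- FALSE
    flippedRows <- c(flippedRows, k)
    flipped <- flipped + blocks$endBin[k] - blocks$startBin[k]
  }
  for (k in flippedRows) {
    ch <- blocks$chrom[k]
    idx <- (blocks$startBin[k] + 1):blocks$endBin[k]
    comps[[ch]][idx] <- ifelse(comps[[ch]][idx] == "A", "B", "A")
  }
  blk <- blocks[flippedRows, , drop = FALSE]
  blk$to <- ifelse(blk$label == "A", "B", "A")
  names(blk)[names(blk) == "label"] <- "from"
  rownames(blk) <- NULL
  list(labels = comps, blocks = blk)
}

perturbBoundaries <- function(bounds, nb, config) {
  lost <- list(); gained <- list(); out <- list()
  for (ch in names(bounds)) {
    b <- bounds[[ch]]
    nChange <- round(config$boundaryChangeFraction * length(b))
    if (nChange > length(b)) stop("boundary changes exceed available boundaries")
    drop <- if (nChange) sort(sample(seq_along(b), nChange)) else integer(0)
    lostB <- b[drop]
    keep <- if (length(drop)) b[-drop] else b
    newB <- integer(0)
    guard <- 0
    while (length(newB) < nChange && guard < 200 * (nChange + 1)) {
      guard <- guard + 1
      cand <- sample(2:(nb[[ch]] - 2), 1)
      if (all(abs(cand - c(keep, newB, lostB)) >= config$tadMinSize))
        newB <- c(newB, cand)
    }
    out[[ch]] <- sort(unique(c(keep, newB)))
    lost[[ch]] <- lostB; gained[[ch]] <- sort(newB)
  }
  list(boundaries = out,
       lost = data.frame(chrom = rep(names(lost), lengths(lost)),
                         bin = unlist(lost, use.names = FALSE)),
       gained = data.frame(chrom = rep(names(gained), lengths(gained)),
                           bin = unlist(gained, use.names = FALSE)))
}

perturbLoops <- function(loops, bounds1, bounds2, grid, config) {
  nLost <- round(config$loopLossFraction * nrow(loops))
  if (nLost > nrow(loops)) stop("loop losses exceed available loops")
  lost <- loops[0, ]
  keep <- loops
  if (nLost > 0) {
    d <- (loops$binJ - loops$binI)^2  # long-range biased loss
    drop <- sample(seq_len(nrow(loops)), nLost, prob = d)
    lost <- loops[drop, , drop = FALSE]
    keep <- loops[-drop, , drop = FALSE]
  }
  nGain <- round(nLost * config$loopGainRatio)
  gained <- loops[0, ]
  if (nGain > 0) {
    per <- table(factor(sample(chromNames(grid), nGain, replace = TRUE,
                               prob = nBins(grid)), levels = chromNames(grid)))
    gl <- list()
    for (ch in chromNames(grid)) {
      if (!per[[ch]]) next
      have <- keep[keep$chrom == ch, c("binI", "binJ")]
      # short-range biased gains: squared-uniform exponent draw
      n <- nBins(grid)[[ch]]
      interior <- tadInterior(n, bounds2[[ch]])
      newL <- NULL
      guard <- 0
      while (NROW(newL) < per[[ch]] && guard < 200 * per[[ch]]) {
        guard <- guard + 1
        u <- runif(1)^2
        dsep <- max(config$loopMinSep,
                    round(config$loopMinSep *
                          (min(config$loopMaxSep, n - 5) / config$loopMinSep)^u))
        cand <- interior[(interior + dsep) %in% interior]
        if (!length(cand)) next
        bi <- if (length(cand) == 1) cand else sample(cand, 1)
        bj <- bi + dsep
        allL <- rbind(have, newL)
        if (NROW(allL) && any(abs(allL$binI - bi) <= 2 & abs(allL$binJ - bj) <= 2)) next
        newL <- rbind(newL, data.frame(binI = as.integer(bi), binJ = as.integer(bj)))
      }
      if (NROW(newL)) gl[[ch]] <- data.frame(chrom = ch, newL)
    }
    if (length(gl)) gained <- do.call(rbind, c(gl, make.row.names = FALSE))
  }
  out <- rbind(keep, gained)
  rownames(out) <- NULL; rownames(lost) <- NULL; rownames(gained) <- NULL
  list(loops = out, lost = lost, gained = gained)
}

boostDegAtChanges <- function(genes, grid, bch, lch, config) {
  bs <- binSize(grid)
  flank <- 2 * bs
  iv <- function(chrom, startBp, endBp)
    if (length(chrom)) data.frame(chrom = chrom, start = startBp, end = endBp)
    else data.frame(chrom = character(), start = numeric(), end = numeric())
  regions <- list(
    up = iv(bch$gained$chrom, pmax(0, bch$gained$bin * bs - flank),
            bch$gained$bin * bs + flank),
    down = iv(bch$lost$chrom, pmax(0, bch$lost$bin * bs - flank),
              bch$lost$bin * bs + flank),
    any = iv(rep(lch$lost$chrom, 2),
             pmax(0, c(lch$lost$binI, lch$lost$binJ) * bs - flank),
             c(lch$lost$binI + 1, lch$lost$binJ + 1) * bs + flank))
  gGr <- grIntervals(genes[, c("chrom", "start", "end")])
  pExtra <- min(1, (config$degBoost - 1) * config$degFraction /
                     max(1e-9, 1 - config$degFraction))
  for (dir in names(regions)) {
    reg <- regions[[dir]]
    if (!nrow(reg)) next
    hit <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(gGr, grIntervals(reg))))
    hit <- hit[genes$degLabel[hit] == "ns"]
    conv <- hit[runif(length(hit)) < pExtra]
    if (!length(conv)) next
    upShare <- switch(dir, up = 1.3 / 2.3, down = 1 - 1.4 / 2.4, any = 0.5)
    goUp <- runif(length(conv)) < upShare
    lfc <- ifelse(goUp, 1, -1) * runif(length(conv), 1.5, 4)
    genes$fpkm2[conv] <- genes$fpkm1[conv] * 2^lfc
    genes$degLabel[conv] <- ifelse(goUp, "up", "down")
  }
  genes
}
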