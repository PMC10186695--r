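tadData <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- smallConfig(compartmentAmplitude = 0, tadEnrichment = 3,
                         nLoops = 0, depth = 2e6, seed = 51)
      tr <- generateArchitecture(cfg)
      cm <- sampleContacts(expectedIntensity(tr, cfg), tr@grid, cfg$depth,
                           seed = 52)
      bal <- krBalance(maskLowCoverage(cm))
      ins <- insulationProfile(bal, minWindow = 4e4, maxWindow = 1.6e5,
                               step = 2e4)
      cache <<- list(cfg = cfg, truth = tr, bal = bal, ins = ins)
    }
    cache
  }
})

test_that("raw insulation equals the window mean computed by brute force", {
  cm <- randomSymmetricMatrix(n = 40, seed = 6)
  prof <- insulationProfile(cm, minWindow = 2e4, maxWindow = 2e4, step = 1e4)
  m <- contactMatrices(cm, "chrR")
  w <- 2
  for (i in c(5, 17, 30)) {  # 0-based bins
    direct <- mean(m[(i - w + 1):i, (i + 1):(i + w)])
    expect_equal(prof@raw$chrR[i + 1, 1], direct)
  }
})

test_that("uniform matrices give a flat combined score", {
  prof <- insulationProfile(uniformMatrix(n = 80), minWindow = 4e4,
                            maxWindow = 1.2e5, step = 4e4)
  s <- insulationScore(prof, "chrU")
  expect_true(all(abs(s[!is.na(s)]) < 1e-9))
})

test_that("planted boundaries are insulation minima and the caller recovers them", {
  d <- tadData()
  s <- insulationScore(d$ins, "chrA")
  for (b in d$truth@boundaries$chrA) {
    win <- s[(b - 2):(b + 4)]  # 0-based bin b sits at index b+1
    if (all(!is.na(win)))
      expect_lte(min(s[b:(b + 2)], na.rm = TRUE), min(win, na.rm = TRUE))
  }
  bd <- callBoundaries(d$ins, d$bal)
  sc <- scoreBoundaryRecovery(bd, d$truth)
  expect_gte(sc$recall, 0.85)
  expect_gte(sc$precision, 0.85)
  # raising the delta threshold never increases the boundary count
  bdStrict <- callBoundaries(d$ins, d$bal, deltaMin = 1)
  expect_lte(nrow(bdStrict), nrow(bd))
  bdLoose <- callBoundaries(d$ins, d$bal, deltaMin = 0.001, qMax = 0.05)
  expect_gte(nrow(bdLoose), nrow(bd))
})

test_that("TAD segmentation tiles chromosomes and flags end segments", {
  grid <- binnedGenome(c(c1 = 3e5), 1e4)
  bd <- data.frame(chrom = "c1", bin = c(10L, 20L))
  tads <- segmentTads(bd, grid)
  expect_equal(nrow(tads), 3)
  expect_equal(sum(tads$sizeBp), 3e5)
  expect_equal(tads$atChromEnd, c(TRUE, FALSE, TRUE))
  none <- segmentTads(data.frame(chrom = character(), bin = integer()), grid)
  expect_equal(nrow(none), 1)
  expect_true(none$atChromEnd)
})

test_that("consensus matching respects the shift window and is symmetric", {
  s1 <- data.frame(chrom = "c1", bin = c(10L, 30L, 50L))
  s2 <- data.frame(chrom = "c1", bin = c(12L, 33L, 50L))
  cons <- consensusBoundaries(s1, s2, shiftBins = 2)
  expect_equal(nrow(cons$conserved), 2)       # 10~12 and 50~50; 30 vs 33 too far
  expect_equal(cons$specific1$bin, 30L)
  expect_equal(cons$specific2$bin, 33L)
  consEdge <- consensusBoundaries(data.frame(chrom = "c1", bin = 10L),
                                  data.frame(chrom = "c1", bin = 13L),
                                  shiftBins = 2)
  expect_equal(nrow(consEdge$conserved), 0)
  swapped <- consensusBoundaries(s2, s1, shiftBins = 2)
  expect_equal(swapped$counts[["conserved"]], cons$counts[["conserved"]])
  same <- consensusBoundaries(s1, s1)
  expect_equal(same$counts[["specific1"]], 0L)
  expect_equal(same$counts[["conserved"]], 3L)
})

test_that("boundary strength comparison returns the 2x2 class table", {
  grid <- binnedGenome(c(c1 = 1e6), 1e4)
  mkIns <- function(scores) new("InsulationProfile", grid = grid,
                                raw = list(c1 = matrix(0, 100, 1)),
                                combined = list(c1 = scores), windows = 2e4)
  s <- rep(0, 100); s[c(11, 31)] <- -3; s[51] <- -1
  ins <- mkIns(s)
  cons <- list(conserved = data.frame(chrom = "c1", bin1 = c(10L, 30L),
                                      bin2 = c(10L, 30L)),
               specific1 = data.frame(chrom = "c1", bin = 50L),
               specific2 = data.frame(chrom = character(), bin = integer()))
  out <- boundaryStrengthCompare(ins, ins, cons)
  expect_equal(nrow(out), 4)
  expect_equal(out$meanScore[out$condition == 1 & out$class == "conserved"], -3)
  expect_equal(out$meanScore[out$condition == 1 & out$class == "specific"], -1)
})

test_that("differential TADs are conserved on identical matrices and mode one is a superset", {
  d <- tadData()
  bd <- callBoundaries(d$ins, d$bal)
  tads <- segmentTads(bd, binGrid(d$bal))
  same <- differentialTads(head(tads, 12), d$bal, d$bal)
  expect_true(all(same$label[!is.na(same$label)] == "conserved"))

  # perturb: double one TAD's intra contacts
  mats <- contactMatrices(d$bal)
  t1 <- tads[!tads$atChromEnd & tads$chrom == "chrA", ][2, ]
  idx <- (t1$startBin + 1):t1$endBin
  mats$chrA[idx, idx] <- mats$chrA[idx, idx] * 2
  cm2 <- contactMatrix(binGrid(d$bal), mats, mask = d$bal@mask,
                       normalization = "balanced")
  dtOne <- differentialTads(tads[tads$chrom == "chrA", ], d$bal, cm2,
                            mode = "one")
  hit <- dtOne[dtOne$startBin == t1$startBin, ]
  expect_equal(hit$label, "changed")
  expect_lt(hit$pIntra, 0.05)
  dtAll <- differentialTads(tads[tads$chrom == "chrA", ], d$bal, cm2,
                            mode = "all")
  expect_true(all(which(dtAll$label == "changed") %in%
                    which(dtOne$label == "changed")))
})

test_that("mark-enriched TADs need both a peak and a top-quantile signal", {
  grid <- binnedGenome(c(c1 = 1e7), 1e4)
  tads <- segmentTads(data.frame(chrom = "c1",
                                 bin = as.integer(seq(10, 990, by = 10))),
                      grid)[1:100, ]
  sig <- signalTrack(grid, list(c1 = rep(seq_len(100), each = 10)[1:1000]))
  peaksAll <- data.frame(chrom = "c1", start = tads$start, end = tads$end)
  ann <- annotateTadsByMark(tads, peaksAll, sig, topFraction = 0.25,
                            markName = "mk")
  expect_equal(sum(ann$mkEnriched), 25)
  # no peaks anywhere -> nothing enriched regardless of signal
  ann0 <- annotateTadsByMark(tads, peaksAll[0, ], sig, markName = "mk")
  expect_equal(sum(ann0$mkEnriched), 0)
})

test_that("planted repressive domains are annotated with high precision", {
  cfg <- smallConfig(compartmentAmplitude = 0, tadEnrichment = 3, nLoops = 0,
                     depth = 2e6, seed = 53)
  tr <- generateArchitecture(cfg)
  tads <- segmentTads(
    data.frame(chrom = rep(names(tr@boundaries), lengths(tr@boundaries)),
               bin = unlist(tr@boundaries, use.names = FALSE)), tr@grid)
  me3 <- tr@markPeaks$H3K27me3
  sig <- binCoverageTrack(tr@grid, me3, "H3K27me3")
  ann <- annotateTadsByMark(tads, me3, sig)
  enr <- ann[ann$H3K27me3Enriched, ]
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(enr$chrom, IRanges::IRanges(enr$start + 1, enr$end)),
    GenomicRanges::GRanges(me3$chrom, IRanges::IRanges(me3$start + 1, me3$end)))
  expect_gte(length(unique(S4Vectors::queryHits(hits))) / nrow(enr), 0.9)
  # repressive TADs carry lower expression than active TADs
  sigAc <- binCoverageTrack(tr@grid, tr@markPeaks$H3K27ac, "H3K27ac")
  ann2 <- annotateTadsByMark(ann, tr@markPeaks$H3K27ac, sigAc)
  g <- tr@genes
  fpOf <- function(tt) {
    idx <- overlapGenes(tt[, c("chrom", "start", "end")], g, "gene_body")
    g$fpkm1[idx]
  }
  me3F <- fpOf(ann2[ann2$H3K27me3Enriched, ])
  acF <- fpOf(ann2[ann2$H3K27acEnriched, ])
  expect_lt(wilcox.test(me3F, acF, alternative = "less")$p.value, 0.05)
})
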