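test_that("P(s) slope recovers the planted decay exponent", {
  cfg <- smallConfig(compartmentAmplitude = 0, tadEnrichment = 1, nLoops = 0,
                     decayExponent = 1, depth = 2e6, seed = 21)
  d <- smallDataset(cfg, seed = 22)
  ps <- psCurve(d$cm)
  expect_true(all(diff(ps$distance) > 0))
  expect_equal(psSlope(ps), -1, tolerance = 0.1)
  # doubling depth leaves the slope unchanged within noise
  cm2 <- sampleContacts(expectedIntensity(d$truth, cfg), d$truth@grid,
                        2 * cfg$depth, seed = 23)
  expect_equal(psSlope(psCurve(cm2)), psSlope(ps), tolerance = 0.05)
})

test_that("log2 ratio maps are zero on identity and antisymmetric under swap", {
  d <- smallDataset(seed = 24)
  r0 <- log2RatioMap(d$cm, d$cm)
  expect_true(all(abs(r0$chrA) < 1e-12, na.rm = TRUE))
  other <- sampleContacts(expectedIntensity(d$truth, d$cfg), d$truth@grid,
                          d$cfg$depth, seed = 25)
  ab <- log2RatioMap(d$cm, other)
  ba <- log2RatioMap(other, d$cm)
  expect_equal(ab$chrA, -ba$chrA)
})

test_that("SCC is 1 on self, high for replicates, lower for unrelated maps", {
  cfg <- smallConfig(depth = 1.5e6, seed = 26)
  tr <- generateArchitecture(cfg)
  r <- expectedIntensity(tr, cfg)
  a <- sampleContacts(r, tr@grid, cfg$depth, seed = 27)
  b <- sampleContacts(r, tr@grid, cfg$depth, seed = 28)
  expect_equal(scc(a, a), 1, tolerance = 1e-12)
  reps <- scc(a, b)
  expect_gt(reps, 0.9)
  cfgU <- smallConfig(depth = 1.5e6, seed = 29, compartmentAmplitude = 0.8,
                      tadMeanSize = 12)
  trU <- generateArchitecture(cfgU)
  u <- sampleContacts(expectedIntensity(trU, cfgU), trU@grid, cfgU$depth,
                      seed = 30)
  expect_lt(scc(a, u), reps)
  # scale invariance
  a10 <- contactMatrix(binGrid(a), lapply(contactMatrices(a), `*`, 10))
  expect_equal(scc(a, a10), 1, tolerance = 1e-12)
})

test_that("window similarity is 1 with z 0 on identical maps and symmetric", {
  d <- smallDataset(seed = 31)
  ws <- windowSimilarityZ(d$cm, d$cm, windowBp = 3e5, stepBp = 1e5)
  expect_true(all(abs(ws$ssim - 1) < 1e-9, na.rm = TRUE))
  expect_true(all(ws$z == 0, na.rm = TRUE))
  other <- sampleContacts(expectedIntensity(d$truth, d$cfg), d$truth@grid,
                          d$cfg$depth, seed = 32)
  w1 <- windowSimilarityZ(d$cm, other, windowBp = 3e5, stepBp = 1e5)
  w2 <- windowSimilarityZ(other, d$cm, windowBp = 3e5, stepBp = 1e5)
  expect_equal(w1$ssim, w2$ssim, tolerance = 1e-12)
  expect_error(windowSimilarityZ(d$cm, other, windowBp = 2e4), "3 bins")
})

test_that("windows with planted structural changes score lower z", {
  cfg <- architectureConfig(chromSizes = c(chr1 = 5e6), seed = 61,
                            depth = 2.5e6)
  tr1 <- generateArchitecture(cfg)
  tr2 <- perturbCondition(tr1, cfg)
  cmA <- sampleContacts(expectedIntensity(tr1, cfg), tr1@grid, cfg$depth,
                        seed = 62)
  cm2 <- sampleContacts(expectedIntensity(tr2, cfg), tr2@grid, cfg$depth,
                        seed = 64)
  dn <- depthNormalize(cmA, cm2)
  ws <- windowSimilarityZ(dn[[2]], dn[[1]], windowBp = 5e5, stepBp = 5e4)
  ch <- tr2@changes
  bs <- binSize(tr1@grid)
  chg <- rbind(
    data.frame(chrom = rep(ch$switchedBlocks$chrom, 2),
               pos = c(ch$switchedBlocks$startBin,
                       ch$switchedBlocks$endBin) * bs),
    data.frame(chrom = c(ch$lostBoundaries$chrom, ch$gainedBoundaries$chrom),
               pos = c(ch$lostBoundaries$bin, ch$gainedBoundaries$bin) * bs))
  margin <- 1e5
  hasChange <- vapply(seq_len(nrow(ws)), function(r)
    any(chg$chrom == ws$chrom[r] & chg$pos >= ws$start[r] + margin &
          chg$pos <= ws$end[r] - margin), logical(1))
  wt <- wilcox.test(ws$z[hasChange], ws$z[!hasChange], alternative = "less")
  expect_lt(wt$p.value, 0.05)
})

test_that("promoter-distal change recovers a planted distance-band fold", {
  cfg <- smallConfig(seed = 33, depth = 1.5e6)
  d <- smallDataset(cfg, seed = 34)
  m <- contactMatrices(d$cm, "chrA")
  n <- nrow(m)
  D <- abs(outer(seq_len(n), seq_len(n), "-")) * binSize(d$truth@grid)
  boost <- ifelse(D >= 5e4 & D < 1e5, 2, 1)
  mats <- contactMatrices(d$cm)
  mats$chrA <- m * boost
  mB <- contactMatrices(d$cm, "chrB")
  DB <- abs(outer(seq_len(nrow(mB)), seq_len(nrow(mB)), "-")) *
    binSize(d$truth@grid)
  mats$chrB <- mB * ifelse(DB >= 5e4 & DB < 1e5, 2, 1)
  boosted <- contactMatrix(binGrid(d$cm), mats)
  pd <- promoterDistalChange(boosted, d$cm, d$truth@genes)
  all50 <- pd[pd$geneSet == "all" & pd$class == "50-100kb", "meanLog2Change"]
  expect_equal(all50, 1, tolerance = 0.05)
  others <- pd[pd$geneSet == "all" & pd$class != "50-100kb", "meanLog2Change"]
  expect_true(all(abs(others) < 0.1))
  # identity: all zero
  pd0 <- promoterDistalChange(d$cm, d$cm, d$truth@genes)
  expect_true(all(pd0$meanLog2Change == 0))
})

test_that("promoters are strand-aware", {
  genes <- data.frame(chrom = "chr1", start = 10000, end = 13000,
                      strand = c("+", "-"))
  pr <- promoterIntervals(genes)
  expect_equal(pr$start, c(8000, 13000))
  expect_equal(pr$end, c(10000, 15000))
})
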