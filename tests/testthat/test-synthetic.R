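test_that("configs are validated and degenerate settings behave", {
  expect_error(architectureConfig(switchFraction = 1.2), "fractions")
  expect_error(architectureConfig(depth = -1), "depth")
  expect_error(architectureConfig(chromSizes = c(c1 = 5e4), binSize = 1e4),
               "10 \\* binSize")
  expect_error(architectureConfig(tadEnrichment = 0.5), "enrichment")

  cfg0 <- smallConfig(nLoops = 0)
  tr0 <- generateArchitecture(cfg0)
  expect_equal(nrow(tr0@loops), 0L)

  # chromosome shorter than one compartment block
  cfgS <- architectureConfig(chromSizes = c(c1 = 2e5), binSize = 1e4,
                             compartmentBlockMean = 100)
  expect_error(generateArchitecture(cfgS), "compartment block")
})

test_that("generation is deterministic given the seed", {
  cfg <- smallConfig(seed = 42)
  t1 <- generateArchitecture(cfg)
  t2 <- generateArchitecture(cfg)
  expect_identical(t1@compartments, t2@compartments)
  expect_identical(t1@boundaries, t2@boundaries)
  expect_identical(t1@loops, t2@loops)
  expect_identical(t1@genes, t2@genes)

  r <- expectedIntensity(t1, cfg)
  s1 <- sampleContacts(r, t1@grid, cfg$depth, seed = 9)
  s2 <- sampleContacts(r, t1@grid, cfg$depth, seed = 9)
  expect_identical(contactMatrices(s1), contactMatrices(s2))
})

test_that("expected intensity composes decay, compartment, TAD and loop factors", {
  cfg <- smallConfig(compartmentAmplitude = 0, tadEnrichment = 1, nLoops = 0,
                     decayExponent = 1, seed = 2)
  tr <- generateArchitecture(cfg)
  r <- expectedIntensity(tr, cfg)$chrA
  # structureless: depends on |i-j| only, and follows the power law
  expect_equal(r[1, 3], r[10, 12])
  expect_equal(r[1, 3] / r[1, 5], 2, tolerance = 1e-12)
  expect_equal(r, t(r))
  expect_true(all(diag(r) == 0))

  cfgT <- smallConfig(compartmentAmplitude = 0, tadEnrichment = 3, nLoops = 0,
                      seed = 2)
  trT <- generateArchitecture(cfgT)
  rT <- expectedIntensity(trT, cfgT)$chrA
  b <- trT@boundaries$chrA[1]
  # same-TAD pair vs equidistant pair straddling the boundary
  inside <- rT[b + 2, b + 4]   # bins b+1, b+3 (0-based), same TAD
  across <- rT[b - 1, b + 1]   # bins b-2, b (0-based), straddling
  expect_equal(inside / across, 3, tolerance = 1e-12)

  cfgL <- smallConfig(nLoops = 8, loopEnrichment = 5, seed = 2)
  trL <- generateArchitecture(cfgL)
  rL <- expectedIntensity(trL, cfgL)
  rNo <- expectedIntensity(trL, smallConfig(nLoops = 8, loopEnrichment = 1, seed = 2))
  lp <- trL@loops[1, ]
  expect_equal(rL[[lp$chrom]][lp$binI + 1, lp$binJ + 1] /
                 rNo[[lp$chrom]][lp$binI + 1, lp$binJ + 1], 5)
})

test_that("planted loop neighbourhoods beat the same-distance background", {
  # loop-only architecture: the invariant compares against a background
  # that carries no other planted structure
  cfg <- smallConfig(nLoops = 10, loopEnrichment = 4, seed = 6,
                     compartmentAmplitude = 0, tadEnrichment = 1)
  tr <- generateArchitecture(cfg)
  r <- expectedIntensity(tr, cfg)
  for (k in seq_len(nrow(tr@loops))) {
    lp <- tr@loops[k, ]
    m <- r[[lp$chrom]]
    d <- lp$binJ - lp$binI
    nbh <- m[lp$binI + 0:2, lp$binJ + 0:2]  # 1-based rows of the 3x3 block
    i <- seq_len(nrow(m) - d)
    # background excludes every planted 3x3 neighbourhood at this distance
    sameCh <- tr@loops[tr@loops$chrom == lp$chrom, ]
    inLoop <- vapply(i, function(ii) any(sameCh$binI <= ii & ii <= sameCh$binI + 2 &
                                         sameCh$binJ <= ii + d & ii + d <= sameCh$binJ + 2),
                     logical(1))
    bgMean <- mean(m[cbind(i[!inLoop], i[!inLoop] + d)])
    expect_gte(mean(nbh) / bgMean, 4 * 0.9)
  }
})

test_that("Poisson sampling conserves depth and handles depth zero", {
  cfg <- smallConfig(seed = 3)
  tr <- generateArchitecture(cfg)
  r <- expectedIntensity(tr, cfg)
  cm <- sampleContacts(r, tr@grid, cfg$depth, seed = 8, pairs = TRUE)
  upTot <- sum(vapply(contactMatrices(cm), function(m)
    sum(m[upper.tri(m, diag = TRUE)]), numeric(1)))
  # total is a Poisson sum with mean = depth; 3 sd window
  expect_lt(abs(upTot - cfg$depth), 3 * sqrt(cfg$depth))
  expect_equal(nrow(attr(cm, "pairs")), upTot)

  cm0 <- sampleContacts(r, tr@grid, 0, seed = 8)
  expect_equal(totalContacts(cm0), 0)
})

test_that("perturbation honours fractions, records change sets, and is an identity at zero", {
  cfg0 <- smallConfig(switchFraction = 0, boundaryChangeFraction = 0,
                      loopLossFraction = 0, seed = 11)
  tr <- generateArchitecture(cfg0)
  tr2 <- perturbCondition(tr, cfg0)
  expect_identical(tr2@compartments, tr@compartments)
  expect_identical(tr2@boundaries, tr@boundaries)
  expect_identical(tr2@loops, tr@loops)
  expect_identical(tr2@genes, tr@genes)

  cfg1 <- smallConfig(loopLossFraction = 1, loopGainRatio = 0, seed = 11)
  trA <- generateArchitecture(cfg1)
  trB <- perturbCondition(trA, cfg1)
  expect_equal(nrow(trB@loops), 0L)

  cfg <- smallConfig(seed = 12, switchFraction = 0.2)
  trC <- generateArchitecture(cfg)
  trD <- perturbCondition(trC, cfg)
  blk <- trD@changes$switchedBlocks
  flipped <- sum(blk$endBin - blk$startBin)
  total <- sum(nBins(trC@grid))
  # flipped-bin total reaches the target, overshooting by less than a block
  expect_gte(flipped, 0.2 * total)
  expect_lt(flipped - 0.2 * total, max(blk$endBin - blk$startBin))
  # recorded blocks match the label changes
  for (r in seq_len(nrow(blk))) {
    idx <- (blk$startBin[r] + 1):blk$endBin[r]
    expect_true(all(trC@compartments[[blk$chrom[r]]][idx] == blk$from[r]))
    expect_true(all(trD@compartments[[blk$chrom[r]]][idx] == blk$to[r]))
  }
  # A->B bias: most flipped blocks come from A
  expect_gt(mean(blk$from == "A"), 0.5)
})

test_that("gene, mark and DHS tracks are consistent with the planted architecture", {
  cfg <- smallConfig(seed = 13)
  tr <- generateArchitecture(cfg)
  g <- tr@genes
  lfc <- log2(g$fpkm2 / g$fpkm1)
  expect_identical(g$degLabel,
                   ifelse(abs(lfc) > 1, ifelse(lfc > 0, "up", "down"), "ns"))
  # ~70% of genes in A bins
  mid <- floor((g$start + g$end) / 2)
  lab <- vapply(seq_len(nrow(g)), function(i)
    tr@compartments[[g$chrom[i]]][binOf(tr@grid, mid[i]) + 1], character(1))
  expect_gt(mean(lab == "A"), 0.6)
  expect_lt(mean(lab == "A"), 0.8)
  # every loop anchor carries a DHS
  bs <- binSize(tr@grid)
  anchors <- c(tr@loops$binI, tr@loops$binJ) * bs + bs / 2
  anchorChrom <- rep(tr@loops$chrom, 2)
  hit <- vapply(seq_along(anchors), function(i) {
    sub <- tr@dhs[tr@dhs$chrom == anchorChrom[i], ]
    any(sub$start <= anchors[i] & sub$end >= anchors[i])
  }, logical(1))
  expect_true(all(hit))
})

test_that("ground-truth track files round-trip through standard formats", {
  cfg <- smallConfig(seed = 14)
  tr <- generateArchitecture(cfg)
  dir <- file.path(tempdir(), "gt")
  writeGroundTruthTracks(tr, dir)
  cs <- readChromSizes(file.path(dir, "chrom.sizes"))
  expect_equal(cs, chromSizes(tr@grid))
  genes <- readGeneTable(file.path(dir, "genes.tsv"))
  expect_equal(genes$geneId, tr@genes$geneId)
  expect_equal(genes$fpkm1, tr@genes$fpkm1, tolerance = 1e-12)
  bed <- readBed(file.path(dir, "dhs.bed"))
  expect_equal(bed$start, tr@dhs$start)
  expect_equal(bed$end, tr@dhs$end)
})
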