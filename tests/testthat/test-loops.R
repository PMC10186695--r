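test_that("density clustering finds point clusters above minPts only", {
  mkPairs <- function(n, x, y, chrom = "c1")
    data.frame(chrom = rep(chrom, n), pos1 = rep(x, n) + seq_len(n) %% 3,
               pos2 = rep(y, n) + seq_len(n) %% 5)
  # 30 PETs piled at one far-from-diagonal point -> one candidate
  cand <- clusterLoops(mkPairs(30, 1e5, 5e5), epsList = c(2000, 5000, 10000),
                       minPtsList = 20)
  expect_equal(nrow(cand), 3)  # found in each eps run, merged later
  expect_true(all(cand$pet == 30))
  # 10 PETs -> below minPts, no candidate
  cand0 <- clusterLoops(mkPairs(10, 1e5, 5e5), minPtsList = 20)
  expect_equal(nrow(cand0), 0)
  # self-ligation: distance below 2*max(eps) is filtered out entirely
  near <- clusterLoops(mkPairs(30, 1e5, 1e5 + 15000), minPtsList = 20)
  expect_equal(nrow(near), 0)
  expect_equal(attr(near, "nPairsUsed"), 0L)
  # empty input
  none <- clusterLoops(mkPairs(0, 0, 0))
  expect_equal(nrow(none), 0)
})

test_that("Poisson upper tails match an exact summation oracle", {
  for (lambda in c(0.5, 3, 10, 40)) {
    for (k in c(1, 5, 20, 60, 100)) {
      oracle <- sum(dpois(k:(k + 2000), lambda))
      expect_equal(ppois(k - 1, lambda, lower.tail = FALSE), oracle,
                   tolerance = 1e-12)
    }
  }
})

test_that("significance keeps strong candidates and rejects observed == expected", {
  set.seed(77)
  # homogeneous background of pairs on a 2 Mb chromosome
  n <- 40000
  pos1 <- runif(n, 0, 1.9e6)
  pairs <- data.frame(chrom = "c1", pos1 = pos1,
                      pos2 = pos1 + runif(n, 5e4, 1e5))
  # plant one dense focal cluster
  hot <- data.frame(chrom = "c1", pos1 = runif(400, 5e5, 5.1e5),
                    pos2 = runif(400, 5.8e5, 5.9e5))
  grid <- binnedGenome(c(c1 = 2e6), 5e3)
  cand <- data.frame(chrom = "c1",
                     startA = c(5e5, 1e6), endA = c(5.1e5, 1.01e6),
                     startB = c(5.8e5, 1.08e6), endB = c(5.9e5, 1.09e6),
                     pet = c(400L, 10L), eps = 5000, minPts = 20)
  cand$distance <- (cand$startB + cand$endB) / 2 - (cand$startA + cand$endA) / 2
  res <- loopSignificance(cand, rbind(pairs, hot), grid)
  all <- attr(res, "allCandidates")
  expect_equal(nrow(res), 1)           # only the planted cluster survives
  expect_equal(res$startA, 5e5)
  expect_lt(res$p, 1e-15)
  # background box: observed close to expected, p near 0.5, rejected
  bgRow <- all[all$startA == 1e6, ]
  expect_gt(bgRow$p, 0.01)
  expect_lt(bgRow$observed / bgRow$expected, 2)
})

test_that("APA has the right shape and responds to planted loops", {
  cfg <- smallConfig(nLoops = 10, loopEnrichment = 5, depth = 2e6, seed = 55)
  tr <- generateArchitecture(cfg)
  cm <- sampleContacts(expectedIntensity(tr, cfg), tr@grid, cfg$depth,
                       seed = 56)
  bal <- krBalance(maskLowCoverage(cm))
  res <- apa(bal, tr@loops, flankBins = 4)
  expect_equal(dim(res$matrix), c(9, 9))
  expect_gt(res$score, 2)
  # distance-matched random anchors: near-neutral score
  set.seed(57)
  rnd <- tr@loops
  for (k in seq_len(nrow(rnd))) {
    d <- rnd$binJ[k] - rnd$binI[k]
    n <- nBins(tr@grid)[[rnd$chrom[k]]]
    rnd$binI[k] <- sample(6:(n - d - 6), 1)
    rnd$binJ[k] <- rnd$binI[k] + d
  }
  nul <- apa(bal, rnd, flankBins = 4)
  expect_gt(nul$score, 0.7)
  expect_lt(nul$score, 1.4)
  expect_warning(apa(bal, tr@loops[1:2, ], flankBins = 4), "fewer than 5")
})

test_that("differential loops: identity gives no calls and swap exchanges labels", {
  set.seed(58)
  n <- 20000
  pos1 <- runif(n, 0, 1.9e6)
  pairs <- data.frame(chrom = "c1", pos1 = pos1,
                      pos2 = pos1 + runif(n, 4e4, 2e5))
  extra <- data.frame(chrom = "c1", pos1 = runif(300, 5e5, 5.1e5),
                      pos2 = runif(300, 6.4e5, 6.5e5))
  grid <- binnedGenome(c(c1 = 2e6), 5e3)
  uni <- data.frame(chrom = "c1", startA = 5e5, endA = 5.1e5,
                    startB = 6.4e5, endB = 6.5e5,
                    inSet1 = TRUE, inSet2 = FALSE, distance = 1.4e5)
  same <- differentialLoops(pairs, pairs, uni, grid, seed = 1)
  expect_equal(same$label, "common")

  a <- rbind(pairs, extra)
  ab <- differentialLoops(a, pairs, uni, grid, seed = 1)
  ba <- differentialLoops(pairs, a, uni, grid, seed = 1)
  expect_equal(ab$label, "lost")
  expect_equal(ba$label, "gained")
  # deterministic given the seed
  ab2 <- differentialLoops(a, pairs, uni, grid, seed = 1)
  expect_identical(ab[c("n1", "n2", "p", "label")],
                   ab2[c("n1", "n2", "p", "label")])
})

test_that("distance classes partition loops and report long-range folds", {
  mk <- function(d) data.frame(chrom = "c1", startA = 0, endA = 1e4,
                               startB = d, endB = d + 1e4,
                               distance = d)
  lost <- do.call(rbind, lapply(c(5e4, 2e5, 2e6, 3e6), mk))
  gained <- do.call(rbind, lapply(c(5e4, 6e4, 2e5, 1.2e6), mk))
  common <- do.call(rbind, lapply(c(5e4, 8e5), mk))
  dc <- distanceClassify(gained, lost, common)
  tab <- dc$table
  for (s in unique(tab$set))
    expect_equal(sum(tab$fraction[tab$set == s]), 1)
  expect_equal(dc$longRange$lostFraction, 0.5)
  expect_equal(dc$longRange$gainedFraction, 0.25)
  expect_equal(dc$longRange$fold, 2)
  shortOnly <- do.call(rbind, lapply(c(5e4, 6e4), mk))
  dc2 <- distanceClassify(shortOnly, shortOnly, shortOnly)
  expect_equal(dc2$longRange$lostFraction, 0)
})

test_that("loop union deduplicates overlapping anchor pairs", {
  a <- data.frame(chrom = "c1", startA = 1e5, endA = 1.1e5,
                  startB = 5e5, endB = 5.1e5)
  b <- rbind(data.frame(chrom = "c1", startA = 1.02e5, endA = 1.12e5,
                        startB = 5.01e5, endB = 5.12e5),
             data.frame(chrom = "c1", startA = 8e5, endA = 8.1e5,
                        startB = 1.2e6, endB = 1.21e6))
  u <- unionLoops(a, b)
  expect_equal(nrow(u), 2)
  expect_true(u$inSet1[1] && u$inSet2[1])
  expect_false(u$inSet1[2])
})
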