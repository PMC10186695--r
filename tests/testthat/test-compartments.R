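balancedSmall <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- smallConfig(tadEnrichment = 1, nLoops = 0, depth = 2e6, seed = 41)
      tr <- generateArchitecture(cfg)
      cm <- sampleContacts(expectedIntensity(tr, cfg), tr@grid, cfg$depth,
                           seed = 42)
      c2 <- maskLowCoverage(coarsenContacts(cm, 2))
      cache <<- list(cfg = cfg, truth = tr, bal = krBalance(c2))
    }
    cache
  }
})

test_that("eigenvector sign partitions a planted checkerboard and orientation fixes it", {
  d <- balancedSmall()
  prof <- compartmentEigenvector(d$bal)
  expect_false(prof@oriented)
  ac <- binCoverageTrack(binGrid(d$bal), d$truth@markPeaks$H3K27ac, "H3K27ac")
  gd <- geneDensityTrack(binGrid(d$bal), d$truth@genes)
  oriented <- orientSign(prof, ac, gd)
  expect_true(oriented@oriented)
  expect_gt(scoreLabelRecovery(oriented, d$truth, 2), 0.95)
  # after orientation, mean active signal over A bins exceeds B bins
  for (ch in chromNames(binGrid(d$bal))) {
    lab <- compartmentLabels(oriented, ch)
    tv <- trackValues(ac, ch)
    expect_gt(mean(tv[!is.na(lab) & lab == "A"]),
              mean(tv[!is.na(lab) & lab == "B"]))
  }
  # orienting with the flipped profile returns the same labels
  flipped <- new("CompartmentProfile", grid = prof@grid,
                 pc1 = lapply(prof@pc1, function(v) -v),
                 label = lapply(prof@pc1, function(v)
                   ifelse(is.na(v) | v == 0, NA, ifelse(-v > 0, "A", "B"))),
                 oriented = FALSE)
  expect_equal(compartmentLabels(orientSign(flipped, ac, gd)),
               compartmentLabels(oriented))
  # scale invariance of the eigenvector up to sign
  scaled <- contactMatrix(binGrid(d$bal),
                          lapply(contactMatrices(d$bal), `*`, 3),
                          mask = d$bal@mask, normalization = "balanced")
  p2 <- compartmentEigenvector(scaled)
  for (ch in chromNames(binGrid(d$bal))) {
    a <- pc1(prof, ch); b <- pc1(p2, ch)
    ok <- !is.na(a)
    expect_equal(abs(a[ok]), abs(b[ok]), tolerance = 1e-6)
  }
})

test_that("compartment fractions use true bin widths and sum to 100%", {
  grid <- binnedGenome(c(c1 = 95000), 1e4)
  mkProf <- function(v) new("CompartmentProfile", grid = grid,
                            pc1 = list(c1 = v),
                            label = list(c1 = ifelse(is.na(v), NA,
                                                     ifelse(v > 0, "A", "B"))),
                            oriented = TRUE)
  prof <- mkProf(c(1, 1, 1, -1, -1, 1, 1, -1, 1, 1))
  fr <- compartmentFractions(prof)
  expect_equal(sum(fr$percent), 100)
  expect_equal(fr$bp[fr$label == "A"], 6 * 1e4 + 5000)  # partial last bin
  allA <- mkProf(rep(1, 10))
  frA <- compartmentFractions(allA)
  expect_equal(frA$percent, c(100, 0))
})

test_that("switch classification is definitional and identity yields zero switching", {
  grid <- binnedGenome(c(c1 = 4e4), 1e4)
  mkProf <- function(v) new("CompartmentProfile", grid = grid,
                            pc1 = list(c1 = v),
                            label = list(c1 = ifelse(v > 0, "A", "B")),
                            oriented = TRUE)
  p1 <- mkProf(c(1, 1, -1, -1))
  p2 <- mkProf(c(1, -1, 1, -1))
  sw <- classifySwitches(p1, p2)
  expect_equal(sw$perBin$c1, c("A-to-A", "A-to-B", "B-to-A", "B-to-B"))
  expect_equal(attr(sw$summary, "switchedPercent"), 50)
  swSelf <- classifySwitches(p1, p1)
  expect_equal(attr(swSelf$summary, "switchedPercent"), 0)
  expect_equal(sum(swSelf$summary$bp), 4e4)
})

test_that("saddle strength follows the corner formula and is zero for flat maps", {
  expect_equal(saddleStrength(1, 1, 1), 0)
  expect_equal(saddleStrength(2, 2, 1), log(4))

  cmU <- uniformMatrix(n = 120)
  grid <- binGrid(cmU)
  set.seed(7)
  v <- rnorm(120)
  prof <- new("CompartmentProfile", grid = grid,
              pc1 = list(chrU = v),
              label = list(chrU = ifelse(v > 0, "A", "B")),
              oriented = TRUE)
  sad <- saddle(oeTransform(krBalance(maskLowCoverage(cmU))), prof)
  expect_equal(compartmentStrength(sad), 0, tolerance = 1e-9)
  expect_equal(dim(sad@matrix), c(50, 50))
})

test_that("saddle strength detects planted compartmentalization", {
  d <- balancedSmall()
  ac <- binCoverageTrack(binGrid(d$bal), d$truth@markPeaks$H3K27ac, "H3K27ac")
  gd <- geneDensityTrack(binGrid(d$bal), d$truth@genes)
  prof <- orientSign(compartmentEigenvector(d$bal), ac, gd)
  sad <- saddle(oeTransform(d$bal), prof)
  expect_gt(compartmentStrength(sad), 0.3)
  # scale invariance
  scaled <- contactMatrix(binGrid(d$bal),
                          lapply(contactMatrices(d$bal), `*`, 4),
                          mask = d$bal@mask, normalization = "balanced")
  sad2 <- saddle(oeTransform(scaled), prof)
  expect_equal(compartmentStrength(sad2), compartmentStrength(sad),
               tolerance = 1e-9)
})

test_that("gene summaries separate A and B compartments as planted", {
  d <- balancedSmall()
  ac <- binCoverageTrack(binGrid(d$bal), d$truth@markPeaks$H3K27ac, "H3K27ac")
  gd <- geneDensityTrack(binGrid(d$bal), d$truth@genes)
  prof <- orientSign(compartmentEigenvector(d$bal), ac, gd)
  gs <- compartmentGeneSummary(prof, d$truth@genes)
  a <- gs$byLabel[gs$byLabel$label == "A", ]
  b <- gs$byLabel[gs$byLabel$label == "B", ]
  expect_gt(a$genesPerMb, b$genesPerMb)
  expect_gt(a$medianFpkm, b$medianFpkm)
  expect_lt(gs$fpkmP, 0.01)
})
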