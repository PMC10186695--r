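test_that("gene-feature overlap matches a brute-force all-pairs scan", {
  set.seed(91)
  genes <- data.frame(chrom = sample(c("c1", "c2"), 60, replace = TRUE),
                      start = round(runif(60, 0, 9.5e5)))
  genes$end <- genes$start + round(runif(60, 500, 5000))
  genes$strand <- sample(c("+", "-"), 60, replace = TRUE)
  feats <- data.frame(chrom = sample(c("c1", "c2"), 25, replace = TRUE),
                      start = round(runif(25, 0, 9.5e5)))
  feats$end <- feats$start + round(runif(25, 1000, 20000))
  for (mode in c("gene_body", "promoter")) {
    iv <- if (mode == "promoter") promoterIntervals(genes)
          else genes[, c("chrom", "start", "end")]
    brute <- which(vapply(seq_len(nrow(iv)), function(g)
      any(feats$chrom == iv$chrom[g] & feats$start < iv$end[g] &
            iv$start[g] < feats$end), logical(1)))
    expect_equal(overlapGenes(feats, genes, mode), brute)
  }
  # explicit arithmetic case: promoter [980, 2980) vs anchor [2900, 3400)
  g1 <- data.frame(chrom = "c1", start = 2980, end = 4000, strand = "+")
  f1 <- data.frame(chrom = "c1", start = 2900, end = 3400)
  expect_equal(overlapGenes(f1, g1, "promoter"), 1L)
})

test_that("Fisher enrichment matches the hypergeometric oracle on small tables", {
  set.seed(92)
  for (i in 1:40) {
    nFg <- sample(5:120, 1); nBg <- sample(nFg:200, 1)
    kBg <- sample.int(nBg, 1); kFg <- sample(0:min(kBg, nFg), 1)
    if ((kBg - kFg) > (nBg - nFg)) next
    res <- fisherEnrichment(kFg, nFg, kBg, nBg, excludeForeground = TRUE)
    # oracle: two-sided Fisher p by summing hypergeometric point masses
    m <- kBg; n <- nBg - kBg; k <- nFg
    support <- max(0, k - n):min(k, m)
    dens <- dhyper(support, m, n, k)
    oracle <- sum(dens[dens <= dhyper(kFg, m, n, k) * (1 + 1e-7)])
    expect_equal(res$p, oracle, tolerance = 1e-8)
  }
  r <- fisherEnrichment(20, 100, 200, 1000)
  expect_equal(r$fold, 1)
  expect_error(fisherEnrichment(0, 0, 10, 100), "foreground")
})

test_that("permutation enrichment saturates, is seeded, and flags planted overlap", {
  cs <- c(c1 = 1e6)
  # target covers the whole chromosome: everything overlaps, p = 1
  sat <- permutationEnrichment(
    data.frame(chrom = "c1", start = c(1e3, 5e5), end = c(2e3, 5.1e5)),
    data.frame(chrom = "c1", start = 0, end = 1e6), cs,
    nPerm = 100, seed = 4)
  expect_equal(sat$observed, 1)
  expect_equal(sat$p, 1)

  set.seed(93)
  targets <- data.frame(chrom = "c1", start = round(runif(60, 0, 9.8e5)))
  targets$end <- targets$start + 1500
  query <- targets[sample.int(60, 25), ]  # planted: queries ARE targets
  pe <- permutationEnrichment(query, targets, cs, nPerm = 500, seed = 7)
  expect_equal(pe$observed, 1)
  expect_lt(pe$p, 0.01)
  pe2 <- permutationEnrichment(query, targets, cs, nPerm = 500, seed = 7)
  expect_identical(pe$p, pe2$p)
  expect_error(permutationEnrichment(
    data.frame(chrom = "c1", start = 0, end = 2e6), targets, cs,
    nPerm = 100, seed = 1), "longer than")
})

test_that("anchor-DHS overlap reports fractions and a centered profile", {
  loops <- data.frame(chrom = "c1", startA = c(1e5, 3e5), endA = c(1.1e5, 3.1e5),
                      startB = c(6e5, 8e5), endB = c(6.1e5, 8.1e5))
  dhs <- data.frame(chrom = "c1",
                    start = c(1.04e5, 3.04e5, 6.04e5, 8.04e5),
                    end = c(1.06e5, 3.06e5, 6.06e5, 8.06e5))
  res <- anchorDhsOverlap(loops, dhs)
  expect_equal(res$fraction, 1)
  nb <- length(res$profile)
  expect_gt(mean(res$profile[(nb / 2 - 1):(nb / 2 + 2)]),
            mean(res$profile[c(1:5, (nb - 4):nb)]))
  none <- anchorDhsOverlap(loops, dhs[0, ])
  expect_equal(none$fraction, 0)
})

test_that("boundary DEG report counts and reorg union behave set-theoretically", {
  grid <- binnedGenome(c(c1 = 1e6), 1e4)
  genes <- data.frame(geneId = sprintf("g%02d", 1:40), chrom = "c1",
                      start = seq(0, 975000, length.out = 40),
                      end = seq(0, 975000, length.out = 40) + 3000,
                      strand = "+", fpkm1 = 10, fpkm2 = 10,
                      degLabel = rep(c("up", "ns", "down", "ns"), 10))
  cons <- list(conserved = data.frame(chrom = character(), bin1 = integer(),
                                      bin2 = integer()),
               specific1 = data.frame(chrom = "c1", bin = c(10L, 50L)),
               specific2 = data.frame(chrom = "c1", bin = 80L))
  rep <- boundaryDegReport(cons, genes, grid, flankBins = 2)
  expect_true(rep$pooled$nGenes >= rep$lost$nGenes)
  expect_equal(rep$pooled$enrichment$nBg, 40)

  # reorg union: disjoint sets add, overlapping sets dedupe
  sw <- data.frame(chrom = "c1", start = 0, end = 1e5)
  dl <- data.frame(chrom = "c1", startA = 4e5, endA = 4.1e5,
                   startB = 9e5, endB = 9.1e5)
  rs <- reorgDegSummary(sw, cons$specific1, dl, genes, grid)
  manual <- unique(c(rs$inSwitch, rs$inBoundary, rs$inLoop))
  expect_equal(rs$nAssociated, length(manual))
  expect_lte(rs$nAssociated,
             length(rs$inSwitch) + length(rs$inBoundary) + length(rs$inLoop))
  expect_equal(rs$nDeg, 20)
})
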