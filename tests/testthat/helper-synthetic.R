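# small synthetic datasets shared across test files; sizes chosen so the
# whole unit suite stays fast while every planted feature is still present

smallConfig <- function(...) {
  defaults <- list(
    chromSizes = c(chrA = 2e6, chrB = 1.5e6), binSize = 1e4,
    compartmentBlockMean = 40, tadMeanSize = 20, tadMinSize = 4,
    nLoops = 10, loopMinSep = 8, loopMaxSep = 80, depth = 1e6)
  do.call(architectureConfig, utils::modifyList(defaults, list(...)))
}

smallDataset <- function(cfg = smallConfig(), seed = 5, pairs = FALSE) {
  truth <- generateArchitecture(cfg)
  cm <- sampleContacts(expectedIntensity(truth, cfg), truth@grid, cfg$depth,
                       seed = seed, pairs = pairs)
  list(cfg = cfg, truth = truth, cm = cm,
       pairs = if (pairs) attr(cm, "pairs"))
}

uniformMatrix <- function(n = 60, value = 5, chrom = "chrU", binSize = 1e4) {
  grid <- binnedGenome(stats::setNames(n * binSize, chrom), binSize)
  m <- matrix(value, n, n)
  diag(m) <- value
  contactMatrix(grid, stats::setNames(list(m), chrom))
}

randomSymmetricMatrix <- function(n = 80, seed = 1, chrom = "chrR",
                                  binSize = 1e4) {
  set.seed(seed)
  m <- matrix(rpois(n * n, 20), n, n)
  m <- m + t(m)
  grid <- binnedGenome(stats::setNames(n * binSize, chrom), binSize)
  contactMatrix(grid, stats::setNames(list(m), chrom))
}
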