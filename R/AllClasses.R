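#' @import methods
#' @importFrom stats cor dist ecdf fisher.test ks.test lm median p.adjust
#'   phyper ppois quantile rbinom rgeom rlnorm rnorm rpois runif sd var
#'   wilcox.test coef binom.test setNames
#' @importFrom utils head tail
NULL

#' Binned partition of a genome
#'
#' Tiles each chromosome with consecutive fixed-width bins (the last bin of a
#' chromosome may be partial). Coordinates are 0-based, half-open throughout
#' the package, so base pair \code{p} falls in bin \code{floor(p / binSize)}.
#'
#' @slot chromNames character, chromosome order.
#' @slot chromSizes numeric, chromosome lengths in bp (named).
#' @slot binSize numeric scalar, bin width in bp.
#' @slot nBins integer, bins per chromosome (named).
#'
#' @exportClass BinnedGenome
setClass("BinnedGenome",
  representation(
    chromNames = "character",
    chromSizes = "numeric",
    binSize = "numeric",
    nBins = "integer"
  )
)

setValidity("BinnedGenome", function(object) {
  msg <- character()
  if (length(object@binSize) != 1L || object@binSize <= 0)
    msg <- c(msg, "binSize must be a single positive number")
  if (length(object@chromNames) == 0L)
    msg <- c(msg, "at least one chromosome required")
  if (!identical(names(object@chromSizes), object@chromNames) ||
      !identical(names(object@nBins), object@chromNames))
    msg <- c(msg, "chromSizes and nBins must be named by chromNames")
  if (any(object@chromSizes <= 0))
    msg <- c(msg, "chromosome sizes must be positive")
  if (length(msg)) msg else TRUE
})

#' Binned symmetric contact map
#'
#' Per-chromosome symmetric intra-chromosomal contact matrices on a
#' \linkS4class{BinnedGenome}, together with a per-bin validity mask and a
#' record of the normalization state (\code{"raw"}, \code{"depth"},
#' \code{"balanced"} or \code{"oe"}).
#'
#' @slot grid a \linkS4class{BinnedGenome}.
#' @slot matrices named list of dense symmetric matrices, one per chromosome.
#' @slot mask named list of logical vectors, \code{TRUE} = usable bin.
#' @slot normalization character scalar.
#' @slot balancing named list of KR scaling vectors (empty unless balanced).
#'
#' @exportClass ContactMatrix
setClass("ContactMatrix",
  representation(
    grid = "BinnedGenome",
    matrices = "list",
    mask = "list",
    normalization = "character",
    balancing = "list"
  ),
  prototype(normalization = "raw", balancing = list())
)

setValidity("ContactMatrix", function(object) {
  msg <- character()
  cn <- chromNames(object@grid)
  if (!identical(names(object@matrices), cn) || !identical(names(object@mask), cn))
    msg <- c(msg, "matrices and mask must be named lists matching the grid")
  for (ch in cn) {
    m <- object@matrices[[ch]]
    n <- nBins(object@grid)[[ch]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n) {
      msg <- c(msg, sprintf("matrix for %s must be %d x %d", ch, n, n))
      next
    }
    if (length(object@mask[[ch]]) != n)
      msg <- c(msg, sprintf("mask for %s has wrong length", ch))
    fin <- is.finite(m)
    if (any(m[fin] < 0))
      msg <- c(msg, sprintf("negative contacts on %s", ch))
    if (max(abs(m[fin] - t(m)[fin]), 0) > 1e-6 * (1 + max(abs(m[fin]), 0)))
      msg <- c(msg, sprintf("matrix for %s is not symmetric", ch))
  }
  if (!object@normalization %in% c("raw", "depth", "balanced", "oe"))
    msg <- c(msg, "unknown normalization state")
  if (length(msg)) msg else TRUE
})

#' Per-bin signal aligned to a binned genome
#'
#' @slot grid a \linkS4class{BinnedGenome}.
#' @slot values named list of numeric vectors (one per chromosome; NA =
#'   missing).
#' @slot label character scalar naming the signal source.
#'
#' @exportClass SignalTrack
setClass("SignalTrack",
  representation(grid = "BinnedGenome", values = "list", label = "character")
)

setValidity("SignalTrack", function(object) {
  cn <- chromNames(object@grid)
  if (!identical(names(object@values), cn))
    return("values must be a named list matching the grid")
  n <- nBins(object@grid)
  bad <- cn[vapply(cn, function(ch) length(object@values[[ch]]) != n[[ch]], logical(1))]
  if (length(bad)) return(paste("wrong value length on", paste(bad, collapse = ", ")))
  TRUE
})

#' A/B compartment profile
#'
#' Per-bin leading-eigenvector values of the contact correlation matrix with
#' A/B labels. After orientation, positive values mark the A compartment and
#' negative values the B compartment.
#'
#' @slot grid a \linkS4class{BinnedGenome} (typically at 50 kb).
#' @slot pc1 named list of numeric vectors (NA at masked bins).
#' @slot label named list of character vectors in \code{{"A","B",NA}}.
#' @slot oriented logical, whether the sign has been fixed by an active mark.
#' @slot orientationEvidence named numeric, per-chromosome correlation of pc1
#'   with the orienting track.
#'
#' @exportClass CompartmentProfile
setClass("CompartmentProfile",
  representation(
    grid = "BinnedGenome",
    pc1 = "list",
    label = "list",
    oriented = "logical",
    orientationEvidence = "numeric"
  ),
  prototype(oriented = FALSE, orientationEvidence = numeric())
)

setValidity("CompartmentProfile", function(object) {
  cn <- chromNames(object@grid)
  if (!identical(names(object@pc1), cn) || !identical(names(object@label), cn))
    return("pc1 and label must be named lists matching the grid")
  for (ch in cn) {
    v <- object@pc1[[ch]]; l <- object@label[[ch]]
    if (length(v) != length(l)) return("pc1/label length mismatch")
    ok <- !is.na(v) & v != 0
    if (any(ifelse(v[ok] > 0, "A", "B") != l[ok], na.rm = TRUE))
      return("labels must follow the sign of pc1")
  }
  TRUE
})

#' Saddle plot summary with compartment strength
#'
#' @slot percentiles numeric, upper edges of the PC1 percentile classes.
#' @slot matrix mean O/E per percentile-class pair (classes ordered from
#'   strongest B to strongest A).
#' @slot strength compartment strength, \code{log(AA * BB / AB^2)}.
#' @slot cornerShare fraction of classes pooled into each corner.
#' @slot counts pair counts per class pair.
#'
#' @exportClass SaddleSummary
setClass("SaddleSummary",
  representation(
    percentiles = "numeric",
    matrix = "matrix",
    strength = "numeric",
    cornerShare = "numeric",
    counts = "matrix"
  )
)

#' Multi-window insulation profile
#'
#' @slot grid a \linkS4class{BinnedGenome} (typically at 5 kb).
#' @slot raw named list of matrices (bins x windows) of mean contact in the
#'   sliding insulation square.
#' @slot combined named list of numeric vectors: the per-bin insulation
#'   score, a z-scaled mean over windows of log2 relative insulation. Lower
#'   scores mean stronger insulation.
#' @slot windows numeric, window sizes in bp.
#'
#' @exportClass InsulationProfile
setClass("InsulationProfile",
  representation(grid = "BinnedGenome", raw = "list", combined = "list",
                 windows = "numeric")
)

#' Planted architecture of a synthetic Hi-C dataset
#'
#' Ground truth emitted by \code{\link{generateArchitecture}} and
#' \code{\link{perturbCondition}}: compartment labels, TAD boundaries, loops
#' and matched gene / histone-mark / DHS annotation, plus (for a perturbed
#' condition) the exact change sets for recovery scoring.
#'
#' @slot grid a \linkS4class{BinnedGenome} at the base bin size.
#' @slot compartments named list of per-bin "A"/"B" labels.
#' @slot boundaries named list of sorted boundary bin indices (a boundary at
#'   bin b separates bins b-1 and b; 0-based bins).
#' @slot loops data.frame: chrom, binI, binJ (0-based, binJ - binI >= 2).
#' @slot genes data.frame: geneId, chrom, start, end, strand, fpkm1, fpkm2,
#'   degLabel in \code{{"up","down","ns"}}.
#' @slot markPeaks named list (per mark) of data.frames chrom/start/end.
#' @slot dhs data.frame chrom/start/end.
#' @slot changes list of perturbation change sets (empty for condition 1).
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    grid = "BinnedGenome",
    compartments = "list",
    boundaries = "list",
    loops = "data.frame",
    genes = "data.frame",
    markPeaks = "list",
    dhs = "data.frame",
    changes = "list"
  ),
  prototype(changes = list())
)

setValidity("GroundTruth", function(object) {
  cn <- chromNames(object@grid)
  msg <- character()
  if (!identical(names(object@compartments), cn) ||
      !identical(names(object@boundaries), cn))
    msg <- c(msg, "compartments and boundaries must be named by chromosome")
  for (ch in cn) {
    b <- object@boundaries[[ch]]
    if (is.unsorted(b, strictly = TRUE))
      msg <- c(msg, sprintf("boundaries on %s must be strictly increasing", ch))
    if (length(b) && (min(b) < 1 || max(b) > nBins(object@grid)[[ch]] - 1))
      msg <- c(msg, sprintf("boundaries on %s outside chromosome", ch))
  }
  if (nrow(object@loops)) {
    if (any(object@loops$binJ - object@loops$binI < 2))
      msg <- c(msg, "loop anchors must be >= 2 bins apart")
    n <- nBins(object@grid)[object@loops$chrom]
    if (any(object@loops$binI < 0) || any(object@loops$binJ >= n))
      msg <- c(msg, "loop anchors outside chromosome")
  }
  if (nrow(object@genes)) {
    lfc <- log2(object@genes$fpkm2 / object@genes$fpkm1)
    lab <- ifelse(abs(lfc) > 1, ifelse(lfc > 0, "up", "down"), "ns")
    if (!identical(lab, object@genes$degLabel))
      msg <- c(msg, "degLabel inconsistent with |log2(fpkm2/fpkm1)| > 1 rule")
  }
  if (length(msg)) msg else TRUE
})
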