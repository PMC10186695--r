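#' Construct a BinnedGenome
#'
#' @param chromSizes named numeric vector of chromosome lengths in bp, in
#'   desired order, or a two-column data.frame (chrom, size).
#' @param binSize bin width in bp.
#' @return a \linkS4class{BinnedGenome}.
#' @examples
#' bg <- binnedGenome(c(chr1 = 1e6, chr2 = 5e5), binSize = 5e4)
#' nBins(bg)
#' @export
binnedGenome <- function(chromSizes, binSize) {
  if (is.data.frame(chromSizes)) {
    sz <- as.numeric(chromSizes[[2]])
    names(sz) <- as.character(chromSizes[[1]])
    chromSizes <- sz
  }
  if (is.null(names(chromSizes)) || any(names(chromSizes) == ""))
    stop("chromSizes must be named by chromosome")
  n <- as.integer(ceiling(chromSizes / binSize))
  names(n) <- names(chromSizes)
  new("BinnedGenome", chromNames = names(chromSizes),
      chromSizes = chromSizes, binSize = as.numeric(binSize), nBins = n)
}

#' Read a two-column chrom.sizes file
#'
#' @param path tab-separated file with chromosome name and length.
#' @return named numeric vector of sizes.
#' @export
readChromSizes <- function(path) {
  tab <- data.table::fread(path, header = FALSE)
  if (ncol(tab) < 2) stop("chrom.sizes needs two columns")
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

#' Write a chrom.sizes file
#' @param grid a \linkS4class{BinnedGenome} or named sizes vector.
#' @param path output path.
#' @export
writeChromSizes <- function(grid, path) {
  sz <- if (is(grid, "BinnedGenome")) chromSizes(grid) else grid
  data.table::fwrite(data.table::data.table(names(sz), as.integer(sz)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname BinnedGenome
#' @export
setMethod("binSize", "BinnedGenome", function(x) x@binSize)

#' @rdname BinnedGenome
#' @export
setMethod("chromNames", "BinnedGenome", function(x) x@chromNames)

#' @rdname BinnedGenome
#' @export
setMethod("chromSizes", "BinnedGenome", function(x) x@chromSizes)

#' @rdname BinnedGenome
#' @export
setMethod("nBins", "BinnedGenome", function(x) x@nBins)

setMethod("show", "BinnedGenome", function(object) {
  cat(sprintf("BinnedGenome: %d chromosome(s), %.4g bp total, bin size %g bp (%d bins)\n",
              length(object@chromNames), sum(object@chromSizes),
              object@binSize, sum(object@nBins)))
})

#' True width of each bin on a chromosome
#'
#' All bins have width \code{binSize} except a partial last bin, which is
#' counted at its true length.
#'
#' @param grid a \linkS4class{BinnedGenome}.
#' @param chrom chromosome name.
#' @return numeric vector of widths in bp.
#' @export
binWidths <- function(grid, chrom) {
  n <- nBins(grid)[[chrom]]
  w <- rep(binSize(grid), n)
  w[n] <- chromSizes(grid)[[chrom]] - (n - 1) * binSize(grid)
  w
}

#' Map a base-pair position to its bin
#' @param grid a \linkS4class{BinnedGenome}.
#' @param pos 0-based positions in bp.
#' @return 0-based bin indices, \code{floor(pos / binSize)}.
#' @export
binOf <- function(grid, pos) as.integer(floor(pos / binSize(grid)))

#' Bins of a BinnedGenome as a GRanges
#' @param grid a \linkS4class{BinnedGenome}.
#' @return \link[GenomicRanges]{GRanges} of all bins with metadata columns
#'   \code{chromBin} (0-based bin on its chromosome).
#' @export
binRanges <- function(grid) {
  bs <- binSize(grid)
  grl <- lapply(chromNames(grid), function(ch) {
    n <- nBins(grid)[[ch]]
    starts <- (seq_len(n) - 1) * bs
    ends <- pmin(starts + bs, chromSizes(grid)[[ch]])
    GenomicRanges::GRanges(ch, IRanges::IRanges(starts + 1, ends),
                           chromBin = seq_len(n) - 1L)
  })
  suppressWarnings(do.call(c, grl))
}

grIntervals <- function(df) {
  # 0-based half-open data.frame -> GRanges (1-based closed)
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1, df$end))
}

sameGrid <- function(a, b) {
  identical(chromNames(a), chromNames(b)) &&
    isTRUE(all.equal(chromSizes(a), chromSizes(b))) &&
    isTRUE(all.equal(binSize(a), binSize(b)))
}
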