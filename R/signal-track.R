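#' Construct a SignalTrack
#'
#' @param grid a \linkS4class{BinnedGenome}.
#' @param values named list of per-bin numeric vectors, or a single numeric
#'   vector when the grid has one chromosome.
#' @param label signal name (e.g. "H3K27ac").
#' @return a \linkS4class{SignalTrack}.
#' @export
signalTrack <- function(grid, values, label = "signal") {
  if (!is.list(values)) {
    if (length(chromNames(grid)) != 1L)
      stop("values must be a per-chromosome list for multi-chromosome grids")
    values <- stats::setNames(list(values), chromNames(grid))
  }
  new("SignalTrack", grid = grid, values = values[chromNames(grid)], label = label)
}

#' @rdname trackValues
#' @export
setMethod("trackValues", "SignalTrack", function(x, chrom = NULL) {
  if (is.null(chrom)) x@values else x@values[[chrom]]
})

#' @rdname binGrid
#' @export
setMethod("binGrid", "SignalTrack", function(x) x@grid)

setMethod("show", "SignalTrack", function(object) {
  cat(sprintf("SignalTrack '%s' on %d chromosome(s), bin size %g bp\n",
              object@label, length(object@values), binSize(object@grid)))
})

#' Per-bin coverage of a set of intervals
#'
#' Fraction of each bin covered by the (0-based half-open) intervals;
#' a simple way to turn peak calls into a grid-aligned signal.
#'
#' @param grid a \linkS4class{BinnedGenome}.
#' @param intervals data.frame with chrom, start, end (0-based half-open) or
#'   a GRanges.
#' @param label signal name.
#' @return a \linkS4class{SignalTrack}.
#' @export
binCoverageTrack <- function(grid, intervals, label = "coverage") {
  gr <- if (is.data.frame(intervals)) grIntervals(intervals) else intervals
  vals <- lapply(chromNames(grid), function(ch) {
    n <- nBins(grid)[[ch]]
    v <- numeric(n)
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    if (length(sub)) {
      cov <- IRanges::coverage(IRanges::reduce(GenomicRanges::ranges(sub)),
                               width = chromSizes(grid)[[ch]])
      bs <- binSize(grid)
      starts <- (seq_len(n) - 1) * bs + 1
      ends <- pmin(starts + bs - 1, chromSizes(grid)[[ch]])
      v <- as.numeric(IRanges::viewMeans(IRanges::Views(cov, starts, ends)))
    }
    v
  })
  names(vals) <- chromNames(grid)
  signalTrack(grid, vals, label)
}

#' Gene-density track (genes per bin by midpoint)
#' @param grid a \linkS4class{BinnedGenome}.
#' @param genes data.frame with chrom, start, end.
#' @return a \linkS4class{SignalTrack}.
#' @export
geneDensityTrack <- function(grid, genes) {
  mid <- floor((genes$start + genes$end) / 2)
  bin <- binOf(grid, mid)
  vals <- lapply(chromNames(grid), function(ch) {
    tabulate(bin[genes$chrom == ch] + 1L, nbins = nBins(grid)[[ch]])
  })
  names(vals) <- chromNames(grid)
  signalTrack(grid, vals, "gene_density")
}

#' Read a bedGraph into a grid-aligned SignalTrack
#'
#' Values are averaged over each bin, weighted by overlap length.
#'
#' @param path bedGraph file.
#' @param grid a \linkS4class{BinnedGenome}.
#' @param label signal name.
#' @return a \linkS4class{SignalTrack}.
#' @export
trackFromBedGraph <- function(path, grid, label = basename(path)) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  vals <- lapply(chromNames(grid), function(ch) {
    n <- nBins(grid)[[ch]]
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    v <- rep(NA_real_, n)
    if (length(sub)) {
      cov <- IRanges::coverage(GenomicRanges::ranges(sub),
                               weight = GenomicRanges::mcols(sub)$score,
                               width = chromSizes(grid)[[ch]])
      bs <- binSize(grid)
      starts <- (seq_len(n) - 1) * bs + 1
      ends <- pmin(starts + bs - 1, chromSizes(grid)[[ch]])
      v <- as.numeric(IRanges::viewMeans(IRanges::Views(cov, starts, ends)))
    }
    v
  })
  names(vals) <- chromNames(grid)
  signalTrack(grid, vals, label)
}

#' Write per-bin values as bedGraph
#'
#' @param track a \linkS4class{SignalTrack}, or a named list of per-bin
#'   values with \code{grid} supplied.
#' @param path output path.
#' @param grid required when \code{track} is a plain list.
#' @export
writeBedGraph <- function(track, path, grid = NULL) {
  if (is(track, "SignalTrack")) {
    grid <- binGrid(track)
    vals <- trackValues(track)
  } else vals <- track
  rows <- lapply(chromNames(grid), function(ch) {
    v <- vals[[ch]]
    n <- length(v)
    bs <- binSize(grid)
    data.table::data.table(chrom = ch, start = (seq_len(n) - 1) * bs,
                           end = pmin(seq_len(n) * bs, chromSizes(grid)[[ch]]),
                           score = v)[is.finite(v)]
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                     col.names = FALSE, scipen = 50)
  invisible(path)
}

#' Write 0-based half-open intervals as BED
#' @param df data.frame with chrom, start, end and optional name, score.
#' @param path output path.
#' @export
writeBed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(df))
  out <- df[, cols, drop = FALSE]
  data.table::fwrite(data.table::as.data.table(out), path, sep = "\t",
                     col.names = FALSE, scipen = 50)
  invisible(path)
}

#' Read a BED file as 0-based half-open intervals
#' @param path BED file.
#' @return data.frame with chrom, start, end (plus name/score when present).
#' @export
readBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr))
  mc <- GenomicRanges::mcols(gr)
  if (!is.null(mc$name)) out$name <- mc$name
  if (!is.null(mc$score)) out$score <- mc$score
  out
}
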