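#' Construct a ContactMatrix
#'
#' @param grid a \linkS4class{BinnedGenome}.
#' @param matrices named list of symmetric per-chromosome matrices. Missing
#'   chromosomes get zero matrices.
#' @param mask named list of logical per-bin masks (default: all valid).
#' @param normalization normalization state.
#' @param balancing optional list of KR scaling vectors.
#' @return a \linkS4class{ContactMatrix}.
#' @export
contactMatrix <- function(grid, matrices = NULL, mask = NULL,
                          normalization = "raw", balancing = list()) {
  cn <- chromNames(grid)
  n <- nBins(grid)
  mats <- lapply(cn, function(ch) {
    m <- matrices[[ch]]
    if (is.null(m)) m <- matrix(0, n[[ch]], n[[ch]])
    m
  })
  names(mats) <- cn
  if (is.null(mask)) mask <- lapply(n, function(k) rep(TRUE, k))
  mask <- mask[cn]
  names(mask) <- cn
  new("ContactMatrix", grid = grid, matrices = mats, mask = mask,
      normalization = normalization, balancing = balancing)
}

#' @rdname binGrid
#' @export
setMethod("binGrid", "ContactMatrix", function(x) x@grid)

#' @rdname contactMatrices
#' @export
setMethod("contactMatrices", "ContactMatrix", function(x, chrom = NULL) {
  if (is.null(chrom)) x@matrices else x@matrices[[chrom]]
})

#' @rdname binMask
#' @export
setMethod("binMask", "ContactMatrix", function(x, chrom = NULL) {
  if (is.null(chrom)) x@mask else x@mask[[chrom]]
})

#' @rdname normalization
#' @export
setMethod("normalization", "ContactMatrix", function(x) x@normalization)

#' @rdname totalContacts
#' @export
setMethod("totalContacts", "ContactMatrix", function(x) {
  sum(vapply(x@matrices, function(m) sum(m[is.finite(m)]), numeric(1)))
})

setMethod("show", "ContactMatrix", function(object) {
  nm <- sum(vapply(object@mask, function(m) sum(!m), integer(1)))
  cat(sprintf("ContactMatrix [%s]: %d chromosome(s), bin size %g bp, total %.4g, %d masked bin(s)\n",
              object@normalization, length(object@matrices),
              binSize(object@grid), totalContacts(object), nm))
})

replaceMatrices <- function(cm, mats, normalization = cm@normalization,
                            mask = cm@mask, balancing = cm@balancing) {
  new("ContactMatrix", grid = cm@grid, matrices = mats, mask = mask,
      normalization = normalization, balancing = balancing)
}

#' Read contacts from a pair list or COO text file
#'
#' Accepts either raw contact pairs (columns \code{chrom1 pos1 chrom2 pos2}
#' or intra-chromosomal \code{chrom pos1 pos2}) or binned coordinate-sparse
#' counts (\code{chrom binI binJ count}). Inter-chromosomal pairs are counted
#' and discarded with a message; only intra-chromosomal contacts are stored.
#'
#' @param path input text file (tab- or space-separated, no header).
#' @param grid a \linkS4class{BinnedGenome}.
#' @param format \code{"auto"}, \code{"pairs"} or \code{"coo"}.
#' @return a raw \linkS4class{ContactMatrix}.
#' @export
readContacts <- function(path, grid, format = c("auto", "pairs", "coo")) {
  format <- match.arg(format)
  if (file.size(path) == 0)
    return(contactMatrix(grid))
  tab <- data.table::fread(path, header = FALSE, fill = TRUE)
  if (nrow(tab) == 0)
    return(contactMatrix(grid))
  if (format == "auto") {
    format <- if (ncol(tab) == 4 && is.character(tab[[3]])) "pairs"
      else if (ncol(tab) == 4) "coo"
      else if (ncol(tab) == 3) "pairs"
      else stop("cannot infer contact file format from ", ncol(tab), " columns")
  }
  if (format == "pairs") {
    if (ncol(tab) == 4) {
      inter <- tab[[1]] != tab[[3]]
      if (any(inter))
        message(sum(inter), " inter-chromosomal pair(s) discarded")
      tab <- tab[!inter, ]
      pairs <- data.frame(chrom = as.character(tab[[1]]),
                          pos1 = as.numeric(tab[[2]]), pos2 = as.numeric(tab[[4]]))
    } else if (ncol(tab) == 3) {
      pairs <- data.frame(chrom = as.character(tab[[1]]),
                          pos1 = as.numeric(tab[[2]]), pos2 = as.numeric(tab[[3]]))
    } else stop("pair files need 3 or 4 columns")
    return(contactsFromPairs(pairs, grid))
  }
  # COO: chrom binI binJ count
  bad <- which(!is.finite(tab[[2]]) | !is.finite(tab[[3]]) | !is.finite(tab[[4]]))
  if (length(bad)) stop("malformed COO line ", bad[1])
  unknown <- setdiff(unique(as.character(tab[[1]])), chromNames(grid))
  if (length(unknown)) stop("unknown chromosome: ", unknown[1])
  cm <- contactMatrix(grid)
  mats <- cm@matrices
  for (ch in unique(as.character(tab[[1]]))) {
    sub <- tab[tab[[1]] == ch, ]
    i <- as.integer(sub[[2]]) + 1L
    j <- as.integer(sub[[3]]) + 1L
    n <- nBins(grid)[[ch]]
    if (any(i < 1 | i > n | j < 1 | j > n))
      stop("bin index outside chromosome ", ch)
    m <- mats[[ch]]
    for (k in seq_along(i)) {
      m[i[k], j[k]] <- m[i[k], j[k]] + sub[[4]][k]
      if (i[k] != j[k]) m[j[k], i[k]] <- m[j[k], i[k]] + sub[[4]][k]
    }
    mats[[ch]] <- m
  }
  replaceMatrices(cm, mats)
}

#' Bin an intra-chromosomal pair list into a ContactMatrix
#'
#' @param pairs data.frame with columns chrom, pos1, pos2 (0-based bp).
#' @param grid a \linkS4class{BinnedGenome}.
#' @return a raw \linkS4class{ContactMatrix}.
#' @export
contactsFromPairs <- function(pairs, grid) {
  unknown <- setdiff(unique(pairs$chrom), chromNames(grid))
  if (length(unknown)) stop("unknown chromosome: ", unknown[1])
  cm <- contactMatrix(grid)
  mats <- cm@matrices
  bs <- binSize(grid)
  for (ch in unique(pairs$chrom)) {
    sub <- pairs[pairs$chrom == ch, ]
    n <- nBins(grid)[[ch]]
    if (any(sub$pos1 < 0 | sub$pos2 < 0 |
            sub$pos1 >= chromSizes(grid)[[ch]] | sub$pos2 >= chromSizes(grid)[[ch]]))
      stop("position outside chromosome ", ch)
    i <- pmin(floor(sub$pos1 / bs), floor(sub$pos2 / bs)) + 1
    j <- pmax(floor(sub$pos1 / bs), floor(sub$pos2 / bs)) + 1
    up <- matrix(tabulate(as.integer(i + (j - 1) * n), nbins = n * n), n, n)
    m <- up + t(up)
    diag(m) <- diag(up)
    mats[[ch]] <- mats[[ch]] + m
  }
  replaceMatrices(cm, mats)
}

#' Write a ContactMatrix as COO text
#'
#' Upper-triangle (including diagonal) nonzero entries, one line per entry:
#' \code{chrom binI binJ count} (0-based bins).
#'
#' @param cm a \linkS4class{ContactMatrix}.
#' @param path output path.
#' @export
writeContactsCOO <- function(cm, path) {
  rows <- lapply(chromNames(binGrid(cm)), function(ch) {
    m <- contactMatrices(cm, ch)
    keep <- upper.tri(m, diag = TRUE) & m != 0 & is.finite(m)
    idx <- which(keep, arr.ind = TRUE)
    data.table::data.table(chrom = ch, binI = idx[, 1] - 1L,
                           binJ = idx[, 2] - 1L, count = m[keep])
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Write one chromosome of a ContactMatrix as a dense TSV
#' @param cm a \linkS4class{ContactMatrix}.
#' @param chrom chromosome name.
#' @param path output path.
#' @export
writeContactsDense <- function(cm, chrom, path) {
  data.table::fwrite(data.table::as.data.table(contactMatrices(cm, chrom)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Sum a ContactMatrix into larger bins
#'
#' Aggregates counts of \code{factor} consecutive bins into one; the mask of
#' a coarse bin is valid when at least half of its source bins are valid.
#'
#' @param cm a \linkS4class{ContactMatrix} (raw or depth-normalized).
#' @param factor integer, number of fine bins per coarse bin.
#' @return a \linkS4class{ContactMatrix} at bin size \code{factor * binSize}.
#' @export
coarsenContacts <- function(cm, factor) {
  grid <- binGrid(cm)
  grid2 <- binnedGenome(chromSizes(grid), binSize(grid) * factor)
  mats <- list(); mask <- list()
  for (ch in chromNames(grid)) {
    m <- contactMatrices(cm, ch)
    n <- nrow(m)
    grp <- (seq_len(n) - 1) %/% factor + 1
    agg <- rowsum(t(rowsum(m, grp)), grp)
    mats[[ch]] <- t(agg)
    mask[[ch]] <- as.vector(rowsum(as.numeric(binMask(cm, ch)), grp) >=
                              tabulate(grp) / 2)
  }
  contactMatrix(grid2, mats, mask, normalization = normalization(cm))
}
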