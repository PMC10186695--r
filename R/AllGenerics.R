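#' @rdname BinnedGenome
#' @param x an object with a bin grid.
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname BinnedGenome
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname BinnedGenome
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))

#' @rdname BinnedGenome
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' Extract the bin grid of an object
#' @param x an object carrying a \linkS4class{BinnedGenome}.
#' @return the \linkS4class{BinnedGenome}.
#' @export
setGeneric("binGrid", function(x) standardGeneric("binGrid"))

#' Per-chromosome contact matrices
#' @param x a \linkS4class{ContactMatrix}.
#' @param chrom optional chromosome name; if given, a single matrix.
#' @export
setGeneric("contactMatrices", function(x, chrom = NULL) standardGeneric("contactMatrices"))

#' Per-bin validity mask
#' @param x a \linkS4class{ContactMatrix}.
#' @param chrom optional chromosome name.
#' @export
setGeneric("binMask", function(x, chrom = NULL) standardGeneric("binMask"))

#' Normalization state of a contact map
#' @param x a \linkS4class{ContactMatrix}.
#' @export
setGeneric("normalization", function(x) standardGeneric("normalization"))

#' Total contact sum over all chromosomes
#' @param x a \linkS4class{ContactMatrix}.
#' @export
setGeneric("totalContacts", function(x) standardGeneric("totalContacts"))

#' Per-bin values of a signal track or profile
#' @param x a \linkS4class{SignalTrack} or \linkS4class{CompartmentProfile}.
#' @param chrom optional chromosome name.
#' @export
setGeneric("trackValues", function(x, chrom = NULL) standardGeneric("trackValues"))

#' Eigenvector values of a compartment profile
#' @param x a \linkS4class{CompartmentProfile}.
#' @param chrom optional chromosome name.
#' @export
setGeneric("pc1", function(x, chrom = NULL) standardGeneric("pc1"))

#' A/B labels of a compartment profile
#' @param x a \linkS4class{CompartmentProfile}.
#' @param chrom optional chromosome name.
#' @export
setGeneric("compartmentLabels", function(x, chrom = NULL) standardGeneric("compartmentLabels"))

#' Combined insulation score
#' @param x an \linkS4class{InsulationProfile}.
#' @param chrom optional chromosome name.
#' @export
setGeneric("insulationScore", function(x, chrom = NULL) standardGeneric("insulationScore"))

#' Compartment strength of a saddle summary
#' @param x a \linkS4class{SaddleSummary}.
#' @export
setGeneric("compartmentStrength", function(x) standardGeneric("compartmentStrength"))
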