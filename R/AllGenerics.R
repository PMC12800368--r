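#' @rdname MethylRecords
#' @param x an object.
#' @param ... ignored.
#' @export
setGeneric("modType", function(x, ...) standardGeneric("modType"))

#' @rdname MethylRecords
#' @export
setGeneric("rawCode", function(x, ...) standardGeneric("rawCode"))

#' @rdname MethylRecords
#' @export
setGeneric("validCoverage", function(x, ...) standardGeneric("validCoverage"))

#' @rdname MethylRecords
#' @export
setGeneric("percentModified", function(x, ...) standardGeneric("percentModified"))

#' @rdname ClassifiedSites
#' @param x an object.
#' @param ... ignored.
#' @export
setGeneric("region", function(x, ...) standardGeneric("region"))

#' @rdname ClassifiedSites
#' @export
setGeneric("hostGenes", function(x, ...) standardGeneric("hostGenes"))

#' @rdname ClassifiedSites
#' @export
setGeneric("upstreamGene", function(x, ...) standardGeneric("upstreamGene"))

#' @rdname ClassifiedSites
#' @export
setGeneric("downstreamGene", function(x, ...) standardGeneric("downstreamGene"))

#' @rdname PanGeneTable
#' @param x an object.
#' @param ... ignored.
#' @export
setGeneric("geneNames", function(x, ...) standardGeneric("geneNames"))

#' @rdname PanGeneTable
#' @export
setGeneric("genomeNames", function(x, ...) standardGeneric("genomeNames"))

#' @rdname PanGeneTable
#' @param gene,genome identifiers selecting one cell.
#' @export
setGeneric("locusTags", function(x, gene, genome, ...) standardGeneric("locusTags"))

#' @rdname PanMethylome
#' @param x an object.
#' @param ... ignored.
#' @export
setGeneric("panMode", function(x, ...) standardGeneric("panMode"))

#' @rdname PanMethylome
#' @export
setGeneric("modTypes", function(x, ...) standardGeneric("modTypes"))

#' @rdname PanMethylome
#' @export
setGeneric("binarize", function(x, ...) standardGeneric("binarize"))

#' @rdname ClusteredPanMatrix
#' @param x an object.
#' @param ... ignored.
#' @export
setGeneric("geneOrder", function(x, ...) standardGeneric("geneOrder"))

#' @rdname ClusteredPanMatrix
#' @export
setGeneric("genomeOrder", function(x, ...) standardGeneric("genomeOrder"))
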