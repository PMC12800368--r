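#' @rdname MethylRecords
#' @export
setMethod("modType", "MethylRecords", function(x, ...) mcols(x)$mod_type)

#' @rdname MethylRecords
#' @export
setMethod("rawCode", "MethylRecords", function(x, ...) mcols(x)$raw_code)

#' @rdname MethylRecords
#' @export
setMethod("validCoverage", "MethylRecords",
          function(x, ...) mcols(x)$valid_coverage)

#' @rdname MethylRecords
#' @export
setMethod("percentModified", "MethylRecords",
          function(x, ...) mcols(x)$percent_modified)

#' 0-based site positions (bedMethyl start column)
#'
#' @param x a [MethylRecords] object.
#' @return integer vector of 0-based positions.
#' @export
sitePositions <- function(x) {
  stopifnot(is(x, "GRanges"))
  start(x) - 1L
}

setMethod("show", "MethylRecords", function(object) {
  cat(class(object), "with", length(object), "sites;",
      "modification types:",
      paste(sort(unique(mcols(object)$mod_type)), collapse = ", "), "\n")
  callNextMethod()
})

#' @rdname ClassifiedSites
#' @export
setMethod("region", "ClassifiedSites", function(x, ...) mcols(x)$region)

#' @rdname ClassifiedSites
#' @export
setMethod("hostGenes", "ClassifiedSites", function(x, ...) mcols(x)$host_gene)

#' @rdname ClassifiedSites
#' @export
setMethod("upstreamGene", "ClassifiedSites",
          function(x, ...) mcols(x)$upstream_gene)

#' @rdname ClassifiedSites
#' @export
setMethod("downstreamGene", "ClassifiedSites",
          function(x, ...) mcols(x)$downstream_gene)

#' @rdname PanGeneTable
#' @export
setMethod("geneNames", "PanGeneTable", function(x, ...) x@geneNames)

#' @rdname PanGeneTable
#' @export
setMethod("genomeNames", "PanGeneTable", function(x, ...) x@genomes)

#' @rdname PanGeneTable
#' @export
setMethod("locusTags", "PanGeneTable", function(x, gene, genome, ...) {
  i <- match(gene, x@geneNames)
  j <- match(genome, x@genomes)
  pm_assert(!is.na(i), sprintf("unknown gene '%s'", gene))
  pm_assert(!is.na(j), sprintf("unknown genome '%s'", genome))
  x@tags[[i, j]]
})

setMethod("show", "PanGeneTable", function(object) {
  cat("PanGeneTable:", length(object@geneNames), "genes x",
      length(object@genomes), "genomes\n")
  pres <- vapply(seq_along(object@geneNames), function(i)
    sum(lengths(object@tags[i, ]) > 0L), integer(1))
  cat("  core (present in all):", sum(pres == length(object@genomes)),
      "| unique (one genome):", sum(pres == 1L), "\n")
})

#' @rdname PanMethylome
#' @export
setMethod("panMode", "PanMethylome", function(x, ...) x@mode)

#' @rdname PanMethylome
#' @export
setMethod("modTypes", "PanMethylome",
          function(x, ...) SummarizedExperiment::assayNames(x))

setMethod("show", "PanMethylome", function(object) {
  cat("PanMethylome (", object@mode, " mode): ",
      nrow(object), " genes x ", ncol(object), " genomes; types: ",
      paste(modTypes(object), collapse = ", "), "\n", sep = "")
})

#' @rdname ClusteredPanMatrix
#' @export
setMethod("geneOrder", "ClusteredPanMatrix", function(x, ...) x@geneOrder)

#' @rdname ClusteredPanMatrix
#' @export
setMethod("genomeOrder", "ClusteredPanMatrix", function(x, ...) x@genomeOrder)

setMethod("show", "ClusteredPanMatrix", function(object) {
  cat("ClusteredPanMatrix [", object@modType, "]: ",
      nrow(object@matrix), " genes x ", ncol(object@matrix),
      " genomes, clustered by Hamming/UPGMA\n", sep = "")
})
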