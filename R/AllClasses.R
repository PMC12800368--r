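#' MethylRecords: per-site modified-base calls
#'
#' A [GenomicRanges::GRanges] subclass holding one range per bedMethyl row
#' (single-base records, width 1) with the full set of bedMethyl metadata
#' columns. Genomic positions follow the usual Bioconductor 1-based
#' convention in memory; bedMethyl input/output converts from/to the
#' 0-based half-open coordinates of the file format, and all exported CSV
#' tables report 0-based positions.
#'
#' Metadata columns: `raw_code` (modification code as emitted by the
#' caller), `mod_type` (normalized name, e.g. "6mA"), `valid_coverage`
#' (modified + canonical + other-modified reads), `percent_modified`
#' (0-100), the per-category read counts `n_mod`, `n_canonical`,
#' `n_other_mod`, `n_delete`, `n_fail`, `n_diff`, `n_nocall`, and the
#' carried-through display columns `thick_start`, `thick_end` (0-based, as
#' read) and `color`.
#'
#' @aliases MethylRecords-class
#' @exportClass MethylRecords
setClass("MethylRecords", contains = "GRanges")

.methyl_required_mcols <- c(
  "raw_code", "mod_type", "valid_coverage", "percent_modified",
  "n_mod", "n_canonical", "n_other_mod", "n_delete", "n_fail",
  "n_diff", "n_nocall", "thick_start", "thick_end", "color"
)

setValidity("MethylRecords", function(object) {
  msg <- character(0)
  missing <- setdiff(.methyl_required_mcols, colnames(mcols(object)))
  if (length(missing))
    msg <- c(msg, paste0("missing metadata columns: ",
                         paste(missing, collapse = ", ")))
  if (length(object) && !all(width(object) == 1L))
    msg <- c(msg, "all records must be single-base (width 1)")
  if (!length(msg)) {
    cov <- mcols(object)$valid_coverage
    pct <- mcols(object)$percent_modified
    if (length(cov) && any(cov < 0L, na.rm = TRUE))
      msg <- c(msg, "valid_coverage must be >= 0")
    if (length(pct) && any(pct < 0 | pct > 100, na.rm = TRUE))
      msg <- c(msg, "percent_modified must lie in [0, 100]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct MethylRecords from parallel vectors
#'
#' @param contig character vector of sequence identifiers.
#' @param start0 integer vector of 0-based site positions (bedMethyl start
#'   column); stored internally as 1-based single-base ranges.
#' @param raw_code,strand,color character vectors.
#' @param valid_coverage,n_mod,n_canonical,n_other_mod,n_delete,n_fail,n_diff,n_nocall
#'   integer vectors of read counts.
#' @param percent_modified numeric vector on the 0-100 scale.
#' @param mod_type normalized modification names; defaults to `raw_code`
#'   (run [normalizeModCodes()] to fill in the human-readable names).
#' @param thick_start,thick_end 0-based display coordinates; default to the
#'   site position.
#' @return a [MethylRecords] object.
#' @export
MethylRecords <- function(contig, start0, raw_code, valid_coverage,
                          strand = ".", percent_modified = 0,
                          n_mod = 0L, n_canonical = 0L, n_other_mod = 0L,
                          n_delete = 0L, n_fail = 0L, n_diff = 0L,
                          n_nocall = 0L, mod_type = raw_code,
                          thick_start = start0, thick_end = start0 + 1L,
                          color = "255,0,0") {
  n <- length(start0)
  strand <- rep_len(strand, n)
  strand <- ifelse(strand %in% c("+", "-"), strand, "*")
  gr <- GRanges(
    seqnames = as.character(rep_len(contig, n)),
    ranges = IRanges(start = as.integer(start0) + 1L,
                     width = rep_len(1L, n)),
    strand = strand
  )
  mcols(gr) <- DataFrame(
    raw_code = as.character(rep_len(raw_code, n)),
    mod_type = as.character(rep_len(mod_type, n)),
    valid_coverage = as.integer(rep_len(valid_coverage, n)),
    percent_modified = as.numeric(rep_len(percent_modified, n)),
    n_mod = as.integer(rep_len(n_mod, n)),
    n_canonical = as.integer(rep_len(n_canonical, n)),
    n_other_mod = as.integer(rep_len(n_other_mod, n)),
    n_delete = as.integer(rep_len(n_delete, n)),
    n_fail = as.integer(rep_len(n_fail, n)),
    n_diff = as.integer(rep_len(n_diff, n)),
    n_nocall = as.integer(rep_len(n_nocall, n)),
    thick_start = as.integer(rep_len(thick_start, n)),
    thick_end = as.integer(rep_len(thick_end, n)),
    color = as.character(rep_len(color, n))
  )
  new("MethylRecords", gr)
}

#' ClassifiedSites: filtered methylation sites labelled by genomic context
#'
#' A [MethylRecords] subclass in which every site additionally carries its
#' coding/non-coding call: `region` ("coding" or "non-coding"),
#' `host_gene` (a [IRanges::CharacterList]; possibly several identifiers
#' when coding sequences overlap, empty for non-coding sites), and for
#' non-coding sites the flanking genes in reference-coordinate order:
#' `upstream_gene` / `downstream_gene` with their nearest boundary
#' coordinates `upstream_end0` / `downstream_start0` (0-based; `NA` at
#' contig ends or on contigs absent from the annotation).
#'
#' @aliases ClassifiedSites-class
#' @exportClass ClassifiedSites
setClass("ClassifiedSites", contains = "MethylRecords")

setValidity("ClassifiedSites", function(object) {
  msg <- character(0)
  need <- c("region", "host_gene", "upstream_gene", "downstream_gene",
            "upstream_end0", "downstream_start0")
  missing <- setdiff(need, colnames(mcols(object)))
  if (length(missing))
    return(paste0("missing metadata columns: ",
                  paste(missing, collapse = ", ")))
  region <- mcols(object)$region
  if (length(region) && !all(region %in% c("coding", "non-coding")))
    msg <- c(msg, "region must be 'coding' or 'non-coding'")
  nhost <- lengths(mcols(object)$host_gene)
  if (length(region) && !all((region == "coding") == (nhost > 0L)))
    msg <- c(msg, "region == 'coding' iff host_gene is non-empty")
  if (length(msg)) msg else TRUE
})

#' PanGeneTable: Roary-style gene presence/absence
#'
#' Maps each pangenome gene to the locus tags that carry it in each genome.
#' A cell may hold zero (gene absent), one, or several (paralogs) locus
#' tags.
#'
#' @slot geneNames character vector, one unique name per pangenome gene.
#' @slot genomes character vector of genome identifiers (Roary column
#'   headers).
#' @slot tags a genes-by-genomes `matrix` of mode `list`; each cell a
#'   character vector of locus tags (possibly empty).
#' @aliases PanGeneTable-class
#' @exportClass PanGeneTable
setClass("PanGeneTable", representation(
  geneNames = "character",
  genomes = "character",
  tags = "matrix"
))

setValidity("PanGeneTable", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@geneNames))
    msg <- c(msg, "gene names must be unique")
  if (!identical(dim(object@tags),
                 c(length(object@geneNames), length(object@genomes))))
    msg <- c(msg, "tags matrix dimensions must match genes x genomes")
  if (length(object@tags) && !is.list(object@tags[1]))
    msg <- c(msg, "tags must be a matrix of mode list")
  if (length(msg)) msg else TRUE
})

#' PanMethylome: gene-by-genome methylation matrices
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass with one assay
#' per modification type (e.g. "4mC", "5mC", "6mA"). Rows are pangenome
#' genes, columns are genomes. In `binary` mode a cell is `NA` when the
#' gene is absent from that genome, `0L` when present but unmethylated,
#' `1L` when at least one filtered site of that type falls inside any of
#' its locus tags. In `positions` mode each cell is a sorted integer
#' vector of 0-based site positions (`NULL`-like `NA` marks absence,
#' `integer(0)` a present but unmethylated gene).
#'
#' @slot mode either "binary" or "positions".
#' @aliases PanMethylome-class
#' @exportClass PanMethylome
setClass("PanMethylome",
         contains = "SummarizedExperiment",
         representation(mode = "character"))

setValidity("PanMethylome", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("binary", "positions"))
    msg <- c(msg, "mode must be 'binary' or 'positions'")
  if (length(SummarizedExperiment::assayNames(object)) < 1L)
    msg <- c(msg, "at least one per-modification-type assay is required")
  if (object@mode == "binary") {
    for (nm in SummarizedExperiment::assayNames(object)) {
      a <- SummarizedExperiment::assay(object, nm)
      vals <- a[!is.na(a)]
      if (length(vals) && !all(vals %in% c(0L, 1L))) {
        msg <- c(msg, sprintf("binary assay '%s' must contain only NA/0/1", nm))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' ClusteredPanMatrix: core-gene matrix with clustering results
#'
#' Output of [clusterPanMatrix()]: the core-gene binary matrix together
#' with the average-linkage (UPGMA) merge trees over Hamming distances and
#' the induced leaf orders for rows (genes) and columns (genomes).
#'
#' @slot matrix binary gene-by-genome matrix (NA marks absent genes).
#' @slot modType modification type the matrix describes.
#' @slot geneOrder,genomeOrder integer permutations (dendrogram leaf
#'   order).
#' @slot geneLinkage,genomeLinkage `hclust` objects, or `NULL` when the
#'   corresponding dimension had fewer than 2 elements.
#' @aliases ClusteredPanMatrix-class
#' @exportClass ClusteredPanMatrix
setClass("ClusteredPanMatrix", representation(
  matrix = "matrix",
  modType = "character",
  geneOrder = "integer",
  genomeOrder = "integer",
  geneLinkage = "ANY",
  genomeLinkage = "ANY"
))

setValidity("ClusteredPanMatrix", function(object) {
  msg <- character(0)
  if (!identical(sort(object@geneOrder), seq_len(nrow(object@matrix))))
    msg <- c(msg, "geneOrder must be a permutation of row indices")
  if (!identical(sort(object@genomeOrder), seq_len(ncol(object@matrix))))
    msg <- c(msg, "genomeOrder must be a permutation of column indices")
  for (link in list(object@geneLinkage, object@genomeLinkage)) {
    if (!is.null(link)) {
      if (!inherits(link, "hclust")) {
        msg <- c(msg, "linkages must be hclust objects or NULL")
      } else if (is.unsorted(link$height)) {
        msg <- c(msg, "linkage heights must be non-decreasing")
      }
    }
  }
  if (length(msg)) msg else TRUE
})
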