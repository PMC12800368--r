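## Pangenome-wide integration: Roary gene_presence_absence parsing and
## gene-by-genome methylation matrices.

.ROARY_META_COLS <- c(
  "Gene", "Non-unique Gene name", "Annotation", "No. isolates",
  "No. sequences", "Avg sequences per isolate", "Genome Fragment",
  "Order within Fragment", "Accessory Fragment",
  "Accessory Order with Fragment", "QC", "Min group size nuc",
  "Max group size nuc", "Avg group size nuc"
)

#' Read a Roary gene_presence_absence.csv table
#'
#' Genome columns are auto-detected as everything after Roary's standard
#' metadata columns. Cells holding several locus tags (paralogs,
#' tab- or space-separated inside the quoted field) are split into
#' individual tags. A locus tag appearing under more than one gene in
#' the same genome is logged.
#'
#' @param path the gene_presence_absence.csv file.
#' @return a [PanGeneTable].
#' @export
readGenePresenceAbsence <- function(path) {
  pm_assert(file.exists(path), sprintf("file not found: %s", path))
  dt <- data.table::fread(path, header = TRUE, sep = ",", quote = "\"",
                          colClasses = "character", data.table = FALSE,
                          showProgress = FALSE)
  need <- .ROARY_META_COLS[1:3]
  missing <- setdiff(need, colnames(dt))
  if (length(missing))
    stop(sprintf("not a Roary gene_presence_absence table (%s): missing column(s) %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  genomes <- setdiff(colnames(dt), .ROARY_META_COLS)
  pm_assert(length(genomes) >= 1L, "no genome columns detected")
  genes <- dt$Gene
  pm_assert(!anyDuplicated(genes), "duplicate gene names in Gene column")
  tags <- matrix(vector("list", length(genes) * length(genomes)),
                 nrow = length(genes), ncol = length(genomes),
                 dimnames = list(genes, genomes))
  for (j in seq_along(genomes)) {
    cells <- dt[[genomes[j]]]
    split_tags <- strsplit(cells, "[\t ]+")
    split_tags <- lapply(split_tags, function(v) v[nzchar(v) & !is.na(v)])
    tags[, j] <- split_tags
    all_tags <- unlist(split_tags)
    if (anyDuplicated(all_tags))
      pm_log(sprintf("genome %s: locus tag(s) mapped to more than one gene: %s",
                     genomes[j],
                     paste(unique(all_tags[duplicated(all_tags)]),
                           collapse = ", ")), level = "WARN")
  }
  new("PanGeneTable", geneNames = genes, genomes = genomes, tags = tags)
}

#' Build gene-by-genome methylation matrices
#'
#' For every modification type, crosses the per-genome extended
#' annotations with the pangenome table: a cell is the absent marker
#' (`NA`) when the gene has no locus tag in that genome; otherwise, in
#' binary mode, `1L` if any of the gene's locus tags (paralog copies are
#' merged by union) hosts at least one site of that type and `0L` if
#' none does; in positions mode the cell is the merged sorted 0-based
#' position list. Locus tags listed in the pangenome table but missing
#' from the genome's extended annotation are logged and contribute no
#' methylation evidence.
#'
#' @param extended named list of extended annotations (objects from
#'   [extendAnnotation()] / [readExtendedAnnotation()], or file paths);
#'   names are genome identifiers and must coincide with the pangenome
#'   table's genome columns (a mismatch is a hard error listing both
#'   sets).
#' @param pan a [PanGeneTable].
#' @param mode `"binary"` or `"positions"`.
#' @param types modification types; defaults to the union of types seen
#'   in any extended annotation.
#' @return a [PanMethylome].
#' @export
buildPanMethylome <- function(extended, pan, mode = c("binary", "positions"),
                              types = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(pan, "PanGeneTable"))
  pm_assert(!is.null(names(extended)) && all(nzchar(names(extended))),
            "'extended' must be a named list (names = genome identifiers)")
  if (!setequal(names(extended), genomeNames(pan)))
    stop(sprintf(
      "genome identifiers do not match the pangenome table.\n  pangenome columns: %s\n  extended annotations: %s",
      paste(sort(genomeNames(pan)), collapse = ", "),
      paste(sort(names(extended)), collapse = ", ")), call. = FALSE)
  extended <- lapply(extended, function(e)
    if (is.character(e)) readExtendedAnnotation(e) else e)
  fixed <- c("gene_id", "contig", "start0", "end0", "strand", "product")
  if (is.null(types)) {
    types <- sort(Reduce(union, lapply(extended, function(e)
      setdiff(colnames(e), fixed))))
    pm_assert(length(types) >= 1L, "no modification-type columns found")
  }
  genomes <- genomeNames(pan)
  genes <- geneNames(pan)
  ng <- length(genes)
  assays_bin <- lapply(types, function(t)
    matrix(NA_integer_, ng, length(genomes),
           dimnames = list(genes, genomes)))
  names(assays_bin) <- types
  assays_pos <- NULL
  if (mode == "positions") {
    assays_pos <- lapply(types, function(t)
      matrix(vector("list", ng * length(genomes)), ng, length(genomes),
             dimnames = list(genes, genomes)))
    names(assays_pos) <- types
  }
  for (j in seq_along(genomes)) {
    ext <- extended[[genomes[j]]]
    tagidx <- lapply(pan@tags[, j], function(tg) {
      i <- match(tg, ext$gene_id)
      miss <- tg[is.na(i)]
      if (length(miss))
        pm_log(sprintf("genome %s: locus tag(s) absent from extended annotation (treated as no evidence): %s",
                       genomes[j], paste(miss, collapse = ", ")),
               level = "WARN")
      i[!is.na(i)]
    })
    present <- lengths(pan@tags[, j]) > 0L
    for (t in types) {
      poslists <- if (t %in% colnames(ext)) ext[[t]] else
        IntegerList(rep(list(integer(0)), nrow(ext)))
      cellpos <- lapply(tagidx, function(i)
        sort(unique(unlist(poslists[i]))))
      assays_bin[[t]][present, j] <-
        as.integer(lengths(cellpos[present]) > 0L)
      if (mode == "positions") {
        cellpos[!present] <- list(NA)
        assays_pos[[t]][, j] <- cellpos
      }
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = if (mode == "binary") assays_bin else assays_pos,
    rowData = DataFrame(gene = genes, row.names = genes),
    colData = DataFrame(genome = genomes, row.names = genomes)
  )
  new("PanMethylome", se, mode = mode)
}

#' @rdname PanMethylome
#' @details `binarize()` converts a positions-mode object to binary mode
#'   (non-empty list -> 1, empty -> 0, absent -> NA); binary objects are
#'   returned unchanged.
#' @export
setMethod("binarize", "PanMethylome", function(x, ...) {
  if (x@mode == "binary") return(x)
  assays_bin <- lapply(modTypes(x), function(t) {
    a <- SummarizedExperiment::assay(x, t)
    b <- matrix(vapply(a, function(cell) {
      if (length(cell) == 1L && all(is.na(cell))) NA_integer_
      else as.integer(length(cell) > 0L)
    }, integer(1)), nrow(a), ncol(a), dimnames = dimnames(a))
    b
  })
  names(assays_bin) <- modTypes(x)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays_bin,
    rowData = SummarizedExperiment::rowData(x),
    colData = SummarizedExperiment::colData(x)
  )
  new("PanMethylome", se, mode = "binary")
})

#' Cross-genome methylation count summary
#'
#' Stacks per-genome count summaries ([summarizeCounts()]) into one
#' table with a per-genome row per modification type, followed by
#' `genome == "all"` rows holding the across-genome totals.
#'
#' @param summaries named list of per-genome count-summary data frames.
#' @return a `data.frame` with columns `genome`, `mod_type`, `coding`,
#'   `non_coding`, `total`.
#' @export
summarizePanCounts <- function(summaries) {
  pm_assert(length(summaries) >= 1L && !is.null(names(summaries)),
            "a named list of per-genome count summaries is required")
  rows <- lapply(names(summaries), function(g)
    cbind(genome = g, summaries[[g]]))
  long <- do.call(rbind, rows)
  per <- long[long$mod_type != "total", , drop = FALSE]
  tot <- stats::aggregate(cbind(coding, non_coding, total) ~ mod_type,
                          data = per, FUN = sum,
                          na.action = stats::na.pass)
  grand <- data.frame(mod_type = "total", coding = sum(tot$coding),
                      non_coding = sum(tot$non_coding),
                      total = sum(tot$total))
  rbind(long, cbind(genome = "all", rbind(tot, grand)))
}

#' Genes methylated in at least a given fraction of genomes
#'
#' For one modification type of a binary [PanMethylome], returns the
#' genes whose methylated-genome count divided by the denominator is at
#' least `threshold`, flagging those methylated in every genome. The
#' default denominator is the number of analyzed genomes; with
#' `denominator = "carrier"` only genomes carrying the gene count.
#' Absent cells never contribute to the numerator.
#'
#' @param x a binary-mode [PanMethylome].
#' @param type one of `modTypes(x)`.
#' @param threshold fraction in \[0, 1\] (default 0.95).
#' @param denominator `"all"` (all genome columns) or `"carrier"`.
#' @return a `data.frame` with columns `gene`, `n_methylated`,
#'   `prevalence`, `in_all_genomes`, restricted to genes passing the
#'   threshold, in matrix row order.
#' @export
genePrevalence <- function(x, type, threshold = 0.95,
                           denominator = c("all", "carrier")) {
  stopifnot(is(x, "PanMethylome"))
  if (panMode(x) != "binary")
    stop("genePrevalence needs a binary-mode matrix; run binarize() first",
         call. = FALSE)
  denominator <- match.arg(denominator)
  pm_assert(threshold >= 0 && threshold <= 1,
            "threshold must lie in [0, 1]")
  pm_assert(type %in% modTypes(x),
            sprintf("unknown modification type '%s'; available: %s",
                    type, paste(modTypes(x), collapse = ", ")))
  a <- SummarizedExperiment::assay(x, type)
  nmeth <- rowSums(a == 1L, na.rm = TRUE)
  denom <- if (denominator == "all") rep(ncol(a), nrow(a)) else
    rowSums(!is.na(a))
  prev <- ifelse(denom > 0, nmeth / denom, 0)
  keep <- prev >= threshold
  data.frame(
    gene = rownames(a)[keep],
    n_methylated = as.integer(nmeth[keep]),
    prevalence = prev[keep],
    in_all_genomes = (nmeth == ncol(a))[keep],
    row.names = NULL
  )
}

#' Write per-type pan-methylome matrices to CSV
#'
#' One CSV per modification type (rows = genes, columns = genomes).
#' Absent cells are serialized as empty fields — distinct from `0`
#' (binary) or an empty position list.
#'
#' @param x a [PanMethylome].
#' @param outDir output directory.
#' @param prefix file-name prefix.
#' @return named character vector of written paths, invisibly.
#' @export
writePanMatrices <- function(x, outDir, prefix = "pan_methylome") {
  stopifnot(is(x, "PanMethylome"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (t in modTypes(x)) {
    a <- SummarizedExperiment::assay(x, t)
    if (panMode(x) == "binary") {
      chr <- matrix(as.character(a), nrow(a), ncol(a), dimnames = dimnames(a))
      chr[is.na(a)] <- ""
    } else {
      chr <- matrix(vapply(a, function(cell) {
        if (length(cell) == 1L && all(is.na(cell))) ""
        else pm_join_positions(cell)
      }, character(1)), nrow(a), ncol(a), dimnames = dimnames(a))
      # present-but-unmethylated must remain distinct from absent
      chr[matrix(vapply(a, function(cell)
        length(cell) == 0L, logical(1)), nrow(a), ncol(a))] <- "[]"
    }
    df <- data.frame(Gene = rownames(a), chr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    p <- file.path(outDir, sprintf("%s.%s.csv", prefix, t))
    data.table::fwrite(df, p, quote = "auto")
    paths[t] <- p
  }
  invisible(paths)
}
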