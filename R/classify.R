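## Coding/non-coding classification of filtered methylation sites,
## extended annotations and count statistics.

.CANONICAL_TYPES <- c("4mC", "5mC", "6mA")

#' Classify methylation sites against CDS features
#'
#' A site is *coding* iff its position falls inside at least one CDS
#' interval, strand-agnostically (methylation calls are per-position;
#' the CDS strand does not enter the containment test). Coding sites
#' carry every host gene (overlapping CDS give several). Non-coding
#' sites carry the flanking genes in reference-coordinate order: the
#' nearest CDS ending at or before the site (`upstream_gene`) and the
#' nearest CDS starting after it (`downstream_gene`), with their facing
#' boundary coordinates (0-based) so orientation and distance can be
#' derived. Sites on contigs absent from the annotation are non-coding
#' with empty neighbours and are logged.
#'
#' The implementation uses sorted-interval overlap search
#' ([GenomicRanges::findOverlaps()]), which is output-identical to the
#' exhaustive per-site-per-feature scan.
#'
#' @param x filtered [MethylRecords].
#' @param cds CDS features from [readAnnotation()].
#' @return a [ClassifiedSites] object, same length and order as `x`.
#' @export
classifySites <- function(x, cds) {
  stopifnot(is(x, "MethylRecords"), is(cds, "GRanges"))
  n <- length(x)
  gene_ids <- if (n == 0L || length(cds) == 0L) character(0) else
    mcols(cds)$gene_id

  host <- rep(CharacterList(character(0)), n)
  upstream <- rep(NA_character_, n)
  downstream <- rep(NA_character_, n)
  up_end0 <- rep(NA_integer_, n)
  down_start0 <- rep(NA_integer_, n)

  if (n > 0L && length(cds) > 0L) {
    hits <- findOverlaps(x, cds, ignore.strand = TRUE)
    host <- unname(splitAsList(gene_ids[subjectHits(hits)],
                               factor(queryHits(hits), levels = seq_len(n))))
    noncoding <- which(lengths(host) == 0L)
    if (length(noncoding)) {
      site <- granges(x)[noncoding]
      strand(site) <- "*"
      sub <- granges(cds)
      strand(sub) <- "*"
      prev <- suppressWarnings(follow(site, sub, ignore.strand = TRUE))
      nxt <- suppressWarnings(precede(site, sub, ignore.strand = TRUE))
      hasprev <- !is.na(prev)
      hasnxt <- !is.na(nxt)
      upstream[noncoding[hasprev]] <- gene_ids[prev[hasprev]]
      up_end0[noncoding[hasprev]] <- end(cds)[prev[hasprev]]   # 0-based excl end
      downstream[noncoding[hasnxt]] <- gene_ids[nxt[hasnxt]]
      down_start0[noncoding[hasnxt]] <- start(cds)[nxt[hasnxt]] - 1L
    }
  }
  orphan <- setdiff(as.character(seqnames(x)),
                    as.character(seqnames(cds)))
  if (length(orphan) && n > 0L)
    pm_log(sprintf("%d contig(s) absent from the annotation; their sites are non-coding with empty neighbours: %s",
                   length(orphan), paste(orphan, collapse = ", ")),
           level = "WARN")

  mcols(x)$region <- ifelse(lengths(host) > 0L, "coding", "non-coding")
  mcols(x)$host_gene <- host
  mcols(x)$upstream_gene <- upstream
  mcols(x)$downstream_gene <- downstream
  mcols(x)$upstream_end0 <- up_end0
  mcols(x)$downstream_start0 <- down_start0
  new("ClassifiedSites", x)
}

#' Extended annotation: per-CDS methylated positions by type
#'
#' Produces one row per CDS with the gene's coordinates and, per
#' modification type, the sorted list of 0-based positions of the coding
#' sites it hosts. CDS with no sites carry empty lists. A site inside
#' several overlapping CDS contributes to each host gene's row.
#'
#' @param cds CDS features ([readAnnotation()]).
#' @param classified the [ClassifiedSites] derived from the same `cds`.
#' @param types modification types to report; defaults to the union of
#'   the canonical bacterial types (4mC, 5mC, 6mA) and the types
#'   observed in `classified`.
#' @return a [S4Vectors::DataFrame] with columns `gene_id`, `contig`,
#'   `start0`, `end0`, `strand`, `product` and one
#'   [IRanges::IntegerList] column per type.
#' @export
extendAnnotation <- function(cds, classified, types = NULL) {
  stopifnot(is(cds, "GRanges"))
  if (is.null(types))
    types <- sort(union(.CANONICAL_TYPES, unique(modType(classified))))
  out <- DataFrame(
    gene_id = mcols(cds)$gene_id,
    contig = as.character(seqnames(cds)),
    start0 = start(cds) - 1L,
    end0 = end(cds),
    strand = as.character(strand(cds)),
    product = mcols(cds)$product
  )
  coding <- classified[region(classified) == "coding"]
  hosts <- hostGenes(coding)
  gene_f <- factor(unlist(hosts), levels = out$gene_id)
  pos <- rep(sitePositions(coding), lengths(hosts))
  type <- rep(modType(coding), lengths(hosts))
  for (t in types) {
    sel <- type == t
    lst <- splitAsList(pos[sel], gene_f[sel])
    out[[t]] <- IntegerList(lapply(lst, function(v) sort(unique(v))))
  }
  out
}

#' Count summary of classified sites
#'
#' Tabulates classified sites per modification type and region
#' (coding / non-coding), with per-type totals and an overall total row.
#' Every site counts exactly once, even when hosted by several
#' overlapping CDS.
#'
#' @param classified a [ClassifiedSites] object.
#' @param types types to include (all-zero rows for unobserved ones);
#'   defaults as in [extendAnnotation()].
#' @return a `data.frame` with columns `mod_type`, `coding`,
#'   `non_coding`, `total`; the last row (`mod_type == "total"`) holds
#'   the column sums.
#' @export
summarizeCounts <- function(classified, types = NULL) {
  if (is.null(types))
    types <- sort(union(.CANONICAL_TYPES, unique(modType(classified))))
  tab <- table(factor(modType(classified), levels = types),
               factor(region(classified), levels = c("coding", "non-coding")))
  out <- data.frame(
    mod_type = types,
    coding = as.integer(tab[, "coding"]),
    non_coding = as.integer(tab[, "non-coding"]),
    stringsAsFactors = FALSE
  )
  out$total <- out$coding + out$non_coding
  rbind(out, data.frame(mod_type = "total",
                        coding = sum(out$coding),
                        non_coding = sum(out$non_coding),
                        total = sum(out$total)))
}

#' Write classification outputs
#'
#' Emits the four per-sample CSV files: coding sites (one row per site
#' per host gene), non-coding sites with flanking-gene annotation,
#' the extended annotation (position lists serialized as
#' semicolon-joined integers) and the count statistics. All position
#' columns are 0-based; each file carries a leading comment line saying
#' so. With `splitByReference = TRUE` one file set is written per
#' contig, and their concatenation equals the unsplit outputs modulo
#' row order.
#'
#' @param classified [ClassifiedSites].
#' @param extended output of [extendAnnotation()].
#' @param summary output of [summarizeCounts()].
#' @param outDir output directory (created if needed).
#' @param prefix file-name prefix, typically the sample name.
#' @param splitByReference write one file set per contig.
#' @return character vector of written paths, invisibly.
#' @export
writeClassificationOutputs <- function(classified, extended, summary,
                                       outDir, prefix = "sample",
                                       splitByReference = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(cl, ext, smry, tag) {
    base <- file.path(outDir, paste0(prefix, tag))
    p <- paste0(base, ".coding.csv")
    .writeCommentedCsv(.codingTable(cl, ext), p)
    p2 <- paste0(base, ".noncoding.csv")
    .writeCommentedCsv(.noncodingTable(cl, ext), p2)
    p3 <- paste0(base, ".extended_annotation.csv")
    .writeCommentedCsv(.extendedTable(ext), p3)
    p4 <- paste0(base, ".statistics.csv")
    .writeCommentedCsv(smry, p4)
    c(p, p2, p3, p4)
  }
  if (splitByReference) {
    for (ctg in unique(c(as.character(seqnames(classified)),
                         extended$contig))) {
      cl <- classified[as.character(seqnames(classified)) == ctg]
      ext <- extended[extended$contig == ctg, , drop = FALSE]
      written <- c(written, emit(cl, ext, summarizeCounts(cl),
                                 paste0(".", ctg)))
    }
  } else {
    written <- emit(classified, extended, summary, "")
  }
  invisible(written)
}

.writeCommentedCsv <- function(df, path) {
  writeLines("# coordinates: 0-based; position lists are ;-joined", path)
  data.table::fwrite(as.data.frame(df), path, append = TRUE,
                     col.names = TRUE, quote = "auto")
  path
}

# read back a CSV written by .writeCommentedCsv
.readCommentedCsv <- function(path, ...) {
  data.table::fread(path, skip = 1L, header = TRUE, sep = ",",
                    data.table = TRUE, showProgress = FALSE, ...)
}

.codingTable <- function(classified, extended) {
  coding <- classified[region(classified) == "coding"]
  hosts <- hostGenes(coding)
  k <- lengths(hosts)
  idx <- rep(seq_along(coding), k)
  gene <- unlist(hosts)
  gi <- match(gene, extended$gene_id)
  data.table::data.table(
    contig = as.character(seqnames(coding))[idx],
    position = sitePositions(coding)[idx],
    strand = .dotStrand(coding)[idx],
    mod_type = modType(coding)[idx],
    valid_coverage = validCoverage(coding)[idx],
    percent_modified = percentModified(coding)[idx],
    gene_id = if (length(gene)) gene else character(0),
    gene_start = extended$start0[gi],
    gene_end = extended$end0[gi],
    gene_strand = extended$strand[gi],
    product = extended$product[gi]
  )
}

.noncodingTable <- function(classified, extended) {
  nc <- classified[region(classified) == "non-coding"]
  m <- mcols(nc)
  gi_up <- match(m$upstream_gene, extended$gene_id)
  gi_dn <- match(m$downstream_gene, extended$gene_id)
  blank <- function(x) ifelse(is.na(x), "", x)  # empty at contig ends
  data.table::data.table(
    contig = as.character(seqnames(nc)),
    position = sitePositions(nc),
    strand = .dotStrand(nc),
    mod_type = modType(nc),
    valid_coverage = validCoverage(nc),
    percent_modified = percentModified(nc),
    upstream_gene = blank(m$upstream_gene),
    upstream_gene_end = m$upstream_end0,
    upstream_product = blank(extended$product[gi_up]),
    downstream_gene = blank(m$downstream_gene),
    downstream_gene_start = m$downstream_start0,
    downstream_product = blank(extended$product[gi_dn])
  )
}

.extendedTable <- function(extended) {
  df <- as.data.frame(extended[, c("gene_id", "contig", "start0", "end0",
                                   "strand", "product")])
  typecols <- setdiff(colnames(extended),
                      c("gene_id", "contig", "start0", "end0", "strand",
                        "product"))
  for (t in typecols)
    df[[t]] <- vapply(extended[[t]], pm_join_positions, character(1))
  df
}

.dotStrand <- function(x) {
  s <- as.character(strand(x))
  ifelse(s == "*", ".", s)
}

#' Read an extended annotation CSV back into memory
#'
#' Inverse of the extended-annotation writer: position-list columns are
#' parsed from semicolon-joined strings back to
#' [IRanges::IntegerList]s.
#'
#' @param path an `*.extended_annotation.csv` file.
#' @return a [S4Vectors::DataFrame] as produced by
#'   [extendAnnotation()].
#' @export
readExtendedAnnotation <- function(path) {
  pm_assert(file.exists(path),
            sprintf("extended annotation not found: %s", path))
  dt <- .readCommentedCsv(path)
  fixed <- c("gene_id", "contig", "start0", "end0", "strand", "product")
  pm_assert(all(fixed %in% colnames(dt)),
            sprintf("not an extended annotation file (missing columns): %s", path))
  out <- DataFrame(gene_id = as.character(dt$gene_id),
                   contig = as.character(dt$contig),
                   start0 = as.integer(dt$start0),
                   end0 = as.integer(dt$end0),
                   strand = as.character(dt$strand),
                   product = as.character(dt$product))
  for (t in setdiff(colnames(dt), fixed))
    out[[t]] <- IntegerList(lapply(as.character(dt[[t]]), pm_split_positions))
  out
}
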