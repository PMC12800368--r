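## Genome annotation input: CDS extraction from GFF3 or GenBank.
##
## Only CDS features are used for coding/non-coding classification; other
## feature types (tRNA, rRNA, pseudogenes, ...) are deliberately ignored,
## so sites inside them classify as non-coding.

#' Read CDS features from a genome annotation
#'
#' Parses a GFF3 or GenBank flat file and returns the coding sequences as
#' a [GenomicRanges::GRanges] (1-based, inclusive, the Bioconductor
#' convention; GFF3 coordinates map directly, and exported tables convert
#' to 0-based). Metadata columns: `gene_id` (locus tag, or feature
#' ID/gene name when no locus tag is present) and `product`. Duplicate
#' gene identifiers are disambiguated with a numeric suffix and logged.
#'
#' @param path annotation file.
#' @param format `"gff3"`, `"genbank"`, or `"auto"` (detect from the file
#'   extension, falling back to content sniffing).
#' @return `GRanges` of CDS features, sorted by contig and start.
#' @export
readAnnotation <- function(path, format = c("auto", "gff3", "genbank")) {
  format <- match.arg(format)
  pm_assert(file.exists(path), sprintf("annotation file not found: %s", path))
  if (format == "auto") format <- .detectAnnotationFormat(path)
  cds <- switch(format,
    gff3 = .readGff3Cds(path),
    genbank = .readGenBankCds(path)
  )
  if (length(cds) == 0L) {
    pm_warn(sprintf("annotation contains no CDS features: %s", path))
    return(cds)
  }
  cds <- sort(cds, ignore.strand = TRUE)
  ids <- mcols(cds)$gene_id
  bad <- which(is.na(ids) | !nzchar(ids))
  if (length(bad)) {
    mcols(cds)$gene_id[bad] <- sprintf("CDS_%06d", bad)
    pm_warn(sprintf("%d CDS without identifiers were assigned placeholder ids", length(bad)))
  }
  dup <- duplicated(mcols(cds)$gene_id)
  if (any(dup)) {
    pm_log(sprintf("%d duplicate CDS identifier(s) disambiguated with suffixes",
                   sum(dup)), level = "WARN")
    mcols(cds)$gene_id <- make.unique(mcols(cds)$gene_id, sep = "_dup")
  }
  cds
}

.detectAnnotationFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) return("gff3")
  if (ext %in% c("gb", "gbk", "gbff", "genbank")) return("genbank")
  head <- readLines(path, n = 5L, warn = FALSE)
  head <- head[nzchar(head)]
  if (length(head) && startsWith(head[1L], "LOCUS")) return("genbank")
  if (length(head) && any(startsWith(head, "##gff-version"))) return("gff3")
  stop(sprintf("cannot detect annotation format of %s; pass format explicitly",
               path), call. = FALSE)
}

.readGff3Cds <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop(sprintf("failed to parse GFF3 %s: %s",
                                path, conditionMessage(e)), call. = FALSE))
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "CDS"]
  m <- mcols(gr)
  pick <- function(nm) if (nm %in% colnames(m)) as.character(m[[nm]]) else
    rep(NA_character_, length(gr))
  gene_id <- pick("locus_tag")
  for (alt in c("ID", "Name", "gene"))
    gene_id <- ifelse(is.na(gene_id) | !nzchar(gene_id), pick(alt), gene_id)
  product <- pick("product")
  product[is.na(product)] <- ""
  out <- granges(gr)
  mcols(out) <- DataFrame(gene_id = gene_id, product = product)
  out
}

# Minimal GenBank flat-file CDS parser (no installed R package exposes
# GenBank feature tables). Handles per-record LOCUS names, CDS locations
# incl. complement()/join() (compound locations collapse to the
# outermost span), partial-end markers (< >), and multi-line
# locus_tag/gene/product qualifiers.
.readGenBankCds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pm_assert(length(lines) > 0L && any(startsWith(lines, "LOCUS")),
            sprintf("failed to parse GenBank file %s: no LOCUS line", path))
  contig <- NA_character_
  in_features <- FALSE
  feats <- list()
  cur <- NULL   # open CDS: list(contig, loc, quals=character lines)
  flush <- function() {
    if (!is.null(cur)) feats[[length(feats) + 1L]] <<- cur
    cur <<- NULL
  }
  for (ln in lines) {
    if (startsWith(ln, "LOCUS")) {
      flush()
      contig <- strsplit(trimws(ln), "[[:space:]]+")[[1L]][2L]
      in_features <- FALSE
      next
    }
    if (startsWith(ln, "FEATURES")) { in_features <- TRUE; next }
    if (startsWith(ln, "ORIGIN") || startsWith(ln, "//")) {
      flush(); in_features <- FALSE; next
    }
    if (!in_features) next
    if (grepl("^ {5}[A-Za-z]", ln)) {         # new feature
      flush()
      key <- trimws(substr(ln, 6L, 20L))
      if (key == "CDS")
        cur <- list(contig = contig, loc = trimws(substr(ln, 22L, nchar(ln))),
                    quals = character(0))
      next
    }
    if (!is.null(cur)) {
      body <- trimws(ln)
      if (startsWith(body, "/")) {
        cur$quals <- c(cur$quals, body)
      } else if (length(cur$quals) == 0L) {
        cur$loc <- paste0(cur$loc, body)      # continued location
      } else {
        n <- length(cur$quals)               # continued qualifier value
        cur$quals[n] <- paste(cur$quals[n], body)
      }
    }
  }
  flush()
  if (length(feats) == 0L) {
    out <- GRanges()
    mcols(out) <- DataFrame(gene_id = character(0), product = character(0))
    return(out)
  }
  parse_one <- function(f) {
    strand <- if (grepl("complement", f$loc, fixed = TRUE)) "-" else "+"
    nums <- regmatches(f$loc, gregexpr("[0-9]+", f$loc))[[1L]]
    pm_assert(length(nums) >= 1L,
              sprintf("unparseable GenBank location: %s", f$loc))
    nums <- as.numeric(nums)
    qual <- function(name) {
      hit <- grep(paste0("^/", name, "="), f$quals, value = TRUE)
      if (!length(hit)) return(NA_character_)
      v <- sub(paste0("^/", name, "="), "", hit[1L])
      gsub('^"|"$', "", v)
    }
    gene_id <- qual("locus_tag")
    if (is.na(gene_id)) gene_id <- qual("gene")
    product <- qual("product")
    list(contig = f$contig, start = min(nums), end = max(nums),
         strand = strand, gene_id = gene_id,
         product = if (is.na(product)) "" else product)
  }
  parsed <- lapply(feats, parse_one)
  GRanges(
    seqnames = vapply(parsed, `[[`, character(1), "contig"),
    ranges = IRanges(start = vapply(parsed, `[[`, numeric(1), "start"),
                     end = vapply(parsed, `[[`, numeric(1), "end")),
    strand = vapply(parsed, `[[`, character(1), "strand"),
    gene_id = vapply(parsed, `[[`, character(1), "gene_id"),
    product = vapply(parsed, `[[`, character(1), "product")
  )
}
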