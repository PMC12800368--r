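# Test helpers: tiny in-code fixtures and independent brute-force
# oracles the implementation is checked against.

# a small valid record set with controllable coverage/rate
makeRecords <- function(n = 10, contig = "chr", seed = NULL,
                        cov = NULL, rate = NULL, code = "a",
                        start0 = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cov)) cov <- sample(10:80, n, replace = TRUE)
  if (is.null(rate)) {
    nm <- floor(runif(n) * (cov + 1))
    rate <- round(100 * nm / cov, 2)
  } else {
    nm <- round(rate / 100 * cov)
    rate <- round(100 * nm / cov, 2)
  }
  if (is.null(start0)) start0 <- sort(sample(0:100000, n))
  MethylRecords(contig = contig, start0 = start0, raw_code = code,
                valid_coverage = cov, percent_modified = rate,
                n_mod = nm, n_canonical = cov - nm,
                strand = sample(c("+", "-"), n, replace = TRUE))
}

writeBedMethylLines <- function(path, rows) {
  # rows: list of character vectors (fields); joined with tabs
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
}

bedRow <- function(contig = "chr", pos = 100, code = "a", cov = 50,
                   strand = "+", pct = 95, nmod = NULL) {
  if (is.null(nmod)) nmod <- round(pct / 100 * cov)
  pct <- round(100 * nmod / cov, 2)
  c(contig, pos, pos + 1, code, cov, strand, pos, pos + 1, "255,0,0",
    cov, pct, nmod, cov - nmod, 0, 0, 0, 0, 0)
}

# simple CDS set as GRanges (1-based in memory, like readAnnotation)
makeCds <- function(start0, end0, contig = "chr", gene = NULL,
                    strand = "+") {
  if (is.null(gene)) gene <- sprintf("g%03d", seq_along(start0))
  gr <- GenomicRanges::GRanges(contig,
                               IRanges::IRanges(start = start0 + 1L, end = end0),
                               strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = gene, product = paste0("protein ", gene))
  gr
}

# Oracle 1: exhaustive per-site-per-feature interval scan (0-based
# half-open containment; flanking genes by linear search)
bruteClassify <- function(pos0, contigs, cds) {
  cstart <- GenomicRanges::start(cds) - 1L
  cend <- GenomicRanges::end(cds)
  cctg <- as.character(GenomicRanges::seqnames(cds))
  cgene <- S4Vectors::mcols(cds)$gene_id
  lapply(seq_along(pos0), function(i) {
    p <- pos0[i]
    same <- cctg == contigs[i]
    host <- cgene[same & cstart <= p & p < cend]
    if (length(host))
      return(list(region = "coding", host = sort(host),
                  up = NA_character_, down = NA_character_))
    before <- which(same & cend <= p)
    after <- which(same & cstart > p)
    # ties (several CDS sharing the extreme boundary) are all valid
    up <- if (length(before))
      cgene[before[cend[before] == max(cend[before])]] else NA_character_
    down <- if (length(after))
      cgene[after[cstart[after] == min(cstart[after])]] else NA_character_
    list(region = "non-coding", host = character(0),
         up = up, down = down)
  })
}

# Same exhaustive scan as bruteClassify, but materialized as full
# site-by-feature comparison matrices (every pair is still compared)
bruteClassifyMatrix <- function(pos0, contigs, cds) {
  cstart <- GenomicRanges::start(cds) - 1L
  cend <- GenomicRanges::end(cds)
  cctg <- as.character(GenomicRanges::seqnames(cds))
  n <- length(pos0); m <- length(cds)
  same <- outer(contigs, cctg, "==")
  inside <- same & outer(pos0, cstart, ">=") & outer(pos0, cend, "<")
  upA <- matrix(cend, n, m, byrow = TRUE)
  upA[!(same & outer(pos0, cend, ">="))] <- -Inf
  upend <- upA[cbind(seq_len(n), max.col(upA, "first"))]
  dnA <- matrix(cstart, n, m, byrow = TRUE)
  dnA[!(same & outer(pos0, cstart, "<"))] <- Inf
  downstart <- dnA[cbind(seq_len(n), max.col(-dnA, "first"))]
  list(inside = inside, upend = upend, downstart = downstart)
}

# Oracle 2: Hamming distances by explicit double loop
bruteHamming <- function(mat) {
  mat[is.na(mat)] <- 0L
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(mat[i, ] != mat[j, ]) / ncol(mat)
  d
}

# Oracle 3: naive UPGMA recomputing every cluster distance as the mean
# of cross-cluster pairwise distances over the *original* matrix (no
# Lance-Williams update), with the same lowest-index tie-break.
bruteUpgma <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(clusters)
    best <- NULL; bestd <- Inf
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      cross <- dm[clusters[[i]], clusters[[j]], drop = FALSE]
      dij <- mean(cross)
      if (dij < bestd - 1e-10) { bestd <- dij; best <- c(i, j) }
    }
    heights[step] <- bestd
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# default tiny fixture spec used across tests (scaled-down population)
tinySpec <- function(seed = 11, ...) {
  args <- list(
    nGenomes = 3, contigLengths = c(chr = 50000L, pls = 12000L),
    nCore = 25L, nAccessory = 10L, nUniquePerGenome = 4L,
    trueSitesPerType = c("4mC" = 8L, "5mC" = 30L, "6mA" = 50L),
    decoyRows = 1500L, boundaryRateSites = 3L, paralogGenes = 1L,
    seed = seed)
  do.call(fixtureSpec, utils::modifyList(args, list(...)))
}
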