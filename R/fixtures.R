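## Synthetic fixture generation: internally consistent bedMethyl + GFF3 +
## Roary-style inputs with a ground-truth manifest, so the whole pipeline
## is testable without real sequencing data.
##
## The generator emulates the *data products* of a bacterial methylome
## study — per-genome modified-base pileups over a chromosome and a
## plasmid, DFAST-like CDS annotations, and a Roary presence/absence
## table with core/accessory/unique structure — not raw signal or reads.

#' Fixture specification
#'
#' Defaults describe a desk-scale bacterial population study: 5 genomes,
#' a chromosome plus a plasmid each, a pangenome with core, accessory
#' and unique fractions, three methylation types in realistic
#' proportions (6mA most abundant, 4mC rare), and a large excess of
#' decoy pileup rows below the filtering thresholds — including
#' zero-rate rows, which real pileup callers emit for every assessable
#' base. True sites draw their methylation rate from \[90, 100\] (with
#' a few planted at exactly 90.0 to pin threshold inclusivity) and
#' their coverage strictly above any attainable automatic threshold;
#' decoys fail on rate, or on coverage with passing rate. Decoy
#' coverages straddle the automatic median-of-medians threshold so the
#' auto mode is exercised nontrivially.
#'
#' @param nGenomes number of genomes.
#' @param contigLengths named integer vector of per-genome contig
#'   lengths (nt).
#' @param cdsLengthRange,gapRange CDS length and intergenic gap ranges
#'   (nt) used when laying out genes.
#' @param nCore,nAccessory,nUniquePerGenome pangenome structure; core
#'   genes occur in every genome, accessory in 2..(n-1), unique in one.
#' @param trueSitesPerType named vector: surviving sites planted per
#'   modification type per genome.
#' @param codingFraction fraction of true sites planted inside CDS.
#' @param decoyRows below-threshold rows per genome.
#' @param boundaryRateSites true sites planted at exactly 90.0 percent.
#' @param paralogGenes number of core genes given two locus tags in the
#'   first genome.
#' @param seed RNG seed; regeneration with the same spec is
#'   byte-identical.
#' @return a `FixtureSpec` list.
#' @export
fixtureSpec <- function(nGenomes = 5,
                        contigLengths = c(chromosome = 600000L,
                                          plasmid = 80000L),
                        cdsLengthRange = c(300L, 1500L),
                        gapRange = c(50L, 600L),
                        nCore = 300L, nAccessory = 150L,
                        nUniquePerGenome = 40L,
                        trueSitesPerType = c("4mC" = 40L, "5mC" = 700L,
                                             "6mA" = 1200L),
                        codingFraction = 0.5,
                        decoyRows = 48000L,
                        boundaryRateSites = 5L,
                        paralogGenes = 2L,
                        seed = 1L) {
  pm_assert(nGenomes >= 2L, "at least 2 genomes are required")
  pm_assert(!is.null(names(contigLengths)), "contigLengths must be named")
  pm_assert(all(names(trueSitesPerType) %in% names(.FIXTURE_CODES)),
            paste0("trueSitesPerType names must be among: ",
                   paste(names(.FIXTURE_CODES), collapse = ", ")))
  structure(list(
    nGenomes = as.integer(nGenomes),
    contigLengths = contigLengths,
    cdsLengthRange = as.integer(cdsLengthRange),
    gapRange = as.integer(gapRange),
    nCore = as.integer(nCore), nAccessory = as.integer(nAccessory),
    nUniquePerGenome = as.integer(nUniquePerGenome),
    trueSitesPerType = trueSitesPerType,
    codingFraction = codingFraction,
    decoyRows = as.integer(decoyRows),
    boundaryRateSites = as.integer(boundaryRateSites),
    paralogGenes = as.integer(paralogGenes),
    seed = as.integer(seed)
  ), class = "FixtureSpec")
}

.FIXTURE_CODES <- c("4mC" = "21839", "5mC" = "m", "6mA" = "a")
# decoy rows split across types, 6mA-heavy like real pileups
.FIXTURE_DECOY_MIX <- c("4mC" = 0.10, "5mC" = 0.35, "6mA" = 0.55)

#' Generate a synthetic fixture tree with ground truth
#'
#' Writes, under `dir`: one bedMethyl table and one GFF3 annotation per
#' genome, a Roary-layout `gene_presence_absence.csv`, a per-genome
#' truth table (`<genome>.truth.csv`) labelling every row with its
#' expected fate, and `manifest.json` holding the expected automatic
#' coverage threshold, per-genome filtered counts and coding/non-coding
#' splits per type, per-gene position lists, binary pan-matrix cells
#' (absent encoded as -1) and the >= 95 %-prevalence gene sets. All
#' files parse with the package's own readers.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory (created).
#' @return invisibly, the ground-truth manifest as a list (with an
#'   extra `genomes` element naming the generated genomes).
#' @export
generateFixture <- function(spec, dir) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  genomes <- sprintf("GEN%02d", seq_len(spec$nGenomes))
  pangenes <- .fixtureAssignGenes(spec, genomes)

  cds_by_genome <- list()
  sites_by_genome <- list()
  medians <- numeric(0)
  for (g in genomes) {
    layout <- .fixtureLayoutGenome(spec, g, pangenes$content[[g]])
    cds_by_genome[[g]] <- layout
    sites <- .fixturePlantSites(spec, g, layout)
    sites_by_genome[[g]] <- sites
    medians[g] <- pm_median(sites$cov)
  }
  thr <- pm_median(medians)
  pm_assert(thr > .FIXTURE_LOWCOV_MAX && thr < .FIXTURE_TRUECOV_MIN,
            sprintf("infeasible spec: automatic threshold %.1f does not separate true sites from low-coverage decoys", thr))

  # survival by the definitional rule, on the values as written
  for (g in genomes) {
    s <- sites_by_genome[[g]]
    s$survive <- s$cov >= thr & s$rate >= 90
    sites_by_genome[[g]] <- s
  }

  manifest <- .fixtureManifest(spec, genomes, pangenes, cds_by_genome,
                               sites_by_genome, medians, thr)
  .fixtureWriteFiles(dir, genomes, pangenes, cds_by_genome,
                     sites_by_genome, manifest)
  manifest$genomes <- genomes
  invisible(manifest)
}

.FIXTURE_LOWCOV_MAX <- 12L   # low-coverage decoys: cov in [2, 12]
.FIXTURE_TRUECOV_MIN <- 61L  # true sites: cov in [61, 120]

# pangenome structure: which genes occur in which genomes
.fixtureAssignGenes <- function(spec, genomes) {
  n <- spec$nGenomes
  total <- spec$nCore + spec$nAccessory + n * spec$nUniquePerGenome
  names_all <- sprintf("group_%05d", seq_len(total))
  core <- names_all[seq_len(spec$nCore)]
  acc <- names_all[spec$nCore + seq_len(spec$nAccessory)]
  uniq <- split(names_all[spec$nCore + spec$nAccessory + seq_len(n * spec$nUniquePerGenome)],
                rep(genomes, each = spec$nUniquePerGenome))
  member <- lapply(stats::setNames(genomes, genomes), function(g) core)
  for (a in acc) {
    k <- sample(2:max(2L, n - 1L), 1L)
    for (g in sample(genomes, k)) member[[g]] <- c(member[[g]], a)
  }
  for (g in genomes) member[[g]] <- c(member[[g]], uniq[[g]])
  # paralogs: duplicate a few core genes in the first genome
  paralog <- head(core, spec$paralogGenes)
  if (length(paralog))
    member[[genomes[1L]]] <- c(member[[genomes[1L]]], paralog)
  list(genes = names_all, core = core, accessory = acc, unique = uniq,
       content = member, paralog = paralog)
}

# lay the genome's genes out over its contigs; returns a data.table of
# CDS with locus tags in positional order
.fixtureLayoutGenome <- function(spec, genome, genes) {
  genes <- sample(genes)   # shuffle placement order
  rows <- list()
  gi <- 1L
  tag_i <- 1L
  for (ctg in names(spec$contigLengths)) {
    L <- spec$contigLengths[[ctg]]
    pos <- sample(spec$gapRange[1L]:spec$gapRange[2L], 1L)
    while (gi <= length(genes)) {
      len <- sample(spec$cdsLengthRange[1L]:spec$cdsLengthRange[2L], 1L)
      if (pos + len >= L) break
      rows[[length(rows) + 1L]] <- data.table::data.table(
        contig = paste0(genome, "_", ctg),
        start0 = pos, end0 = pos + len,
        strand = sample(c("+", "-"), 1L),
        gene = genes[gi],
        locus_tag = sprintf("%s_%04d", genome, tag_i),
        product = paste0("hypothetical protein ", genes[gi])
      )
      gi <- gi + 1L
      tag_i <- tag_i + 1L
      pos <- pos + len + sample(spec$gapRange[1L]:spec$gapRange[2L], 1L)
    }
  }
  pm_assert(gi > length(genes),
            sprintf("infeasible spec: %d gene(s) do not fit on the contigs of %s",
                    length(genes) - gi + 1L, genome))
  data.table::rbindlist(rows)
}

# plant true sites and decoys; returns a data.table of all bedMethyl
# rows with ground-truth columns (type, region, host tag, cov, rate)
.fixturePlantSites <- function(spec, genome, cds) {
  contigs <- paste0(genome, "_", names(spec$contigLengths))
  clen <- stats::setNames(as.integer(spec$contigLengths), contigs)
  # coding mask per contig
  mask <- lapply(contigs, function(ctg) logical(clen[[ctg]]))
  names(mask) <- contigs
  for (r in seq_len(nrow(cds)))
    mask[[cds$contig[r]]][(cds$start0[r] + 1L):cds$end0[r]] <- TRUE

  draw_counts <- function(cov, rate_lo, rate_hi) {
    # n_mod consistent with a rate in [rate_lo, rate_hi] percent
    lo <- ceiling(rate_lo / 100 * cov)
    hi <- floor(rate_hi / 100 * cov)
    nm <- lo + floor(stats::runif(length(cov)) * (hi - lo + 1))
    pmin(nm, cov)
  }

  all_rows <- list()
  for (t in names(spec$trueSitesPerType)) {
    ntrue <- spec$trueSitesPerType[[t]]
    ncod <- round(spec$codingFraction * ntrue)
    nnc <- ntrue - ncod
    used <- data.table::data.table(contig = character(0), pos = integer(0))
    take_unique <- function(dt) {
      # drop rows colliding with already-used (contig, pos) of this type
      key <- paste(dt$contig, dt$pos)
      ok <- !duplicated(key) & !(key %in% paste(used$contig, used$pos))
      used <<- rbind(used, dt[ok, c("contig", "pos"), with = FALSE])
      dt[ok]
    }
    # coding true sites: host CDS chosen uniformly, position inside it
    cod <- data.table::data.table(contig = character(0), pos = integer(0),
                                  host = character(0))
    while (nrow(cod) < ncod) {
      need <- ncod - nrow(cod)
      ri <- sample(nrow(cds), need, replace = TRUE)
      cand <- data.table::data.table(
        contig = cds$contig[ri],
        pos = cds$start0[ri] +
          floor(stats::runif(need) * (cds$end0[ri] - cds$start0[ri])),
        host = cds$locus_tag[ri])
      cod <- rbind(cod, take_unique(cand))
    }
    # non-coding true sites: uniform over the intergenic complement
    nc_pool <- lapply(contigs, function(ctg) which(!mask[[ctg]]) - 1L)
    names(nc_pool) <- contigs
    pool_sizes <- lengths(nc_pool)
    nc <- data.table::data.table(contig = character(0), pos = integer(0))
    while (nrow(nc) < nnc) {
      need <- nnc - nrow(nc)
      ctg <- sample(contigs, need, replace = TRUE,
                    prob = pool_sizes / sum(pool_sizes))
      cand <- data.table::data.table(
        contig = ctg,
        pos = vapply(ctg, function(cc) sample(nc_pool[[cc]], 1L), integer(1)))
      nc <- rbind(nc, take_unique(cand))
    }
    # decoys: anywhere on the genome
    ndec <- round(spec$decoyRows * .FIXTURE_DECOY_MIX[[t]])
    dec <- data.table::data.table(contig = character(0), pos = integer(0))
    while (nrow(dec) < ndec) {
      need <- ndec - nrow(dec)
      ctg <- sample(contigs, need, replace = TRUE,
                    prob = clen / sum(clen))
      cand <- data.table::data.table(
        contig = ctg,
        pos = floor(stats::runif(need) * clen[ctg]))
      dec <- rbind(dec, take_unique(cand))
    }

    # coverage and rate: trues high-coverage, rate >= 90
    truedt <- rbind(cod[, c("contig", "pos")], nc[, c("contig", "pos")])
    truedt$host <- c(cod$host, rep(NA_character_, nrow(nc)))
    truedt$region <- rep(c("coding", "non-coding"), c(nrow(cod), nrow(nc)))
    truedt$cov <- sample(.FIXTURE_TRUECOV_MIN:120L, nrow(truedt),
                         replace = TRUE)
    truedt$n_mod <- draw_counts(truedt$cov, 90, 100)
    truedt$truth <- "true"
    # decoys: ~95 % fail on rate (most at rate zero, like raw pileups),
    # the rest pass on rate but fail on coverage
    kind <- sample(c("lowrate", "zerorate", "lowcov"), nrow(dec),
                   replace = TRUE, prob = c(0.25, 0.70, 0.05))
    dec$cov <- ifelse(kind == "lowcov",
                      sample(2:.FIXTURE_LOWCOV_MAX, nrow(dec), replace = TRUE),
                      sample(15:60, nrow(dec), replace = TRUE))
    dec$n_mod <- 0L
    lr <- kind == "lowrate"
    dec$n_mod[lr] <- draw_counts(dec$cov[lr], 5, 89.9)
    lc <- kind == "lowcov"
    dec$n_mod[lc] <- draw_counts(dec$cov[lc], 90, 100)
    dec$host <- NA_character_
    dec$region <- NA_character_
    dec$truth <- "decoy"
    dt <- rbind(truedt, dec[, colnames(truedt), with = FALSE])
    dt$type <- t
    all_rows[[t]] <- dt
  }
  out <- data.table::rbindlist(all_rows)

  # boundary cases: coding 6mA true sites pinned to exactly 90.00 %
  bi <- which(out$truth == "true" & out$type == "6mA" &
                out$region == "coding")
  bi <- head(bi, spec$boundaryRateSites)
  out$cov[bi] <- 10L * sample(7:12, length(bi), replace = TRUE)
  out$n_mod[bi] <- as.integer(0.9 * out$cov[bi])

  out$rate <- round(100 * out$n_mod / out$cov, 2)
  # guards implied by the construction
  pm_assert(all(out$rate[out$truth == "true"] >= 90),
            "internal error: true site below rate threshold")
  out$n_other <- pmin(out$cov - out$n_mod,
                      sample(0:2, nrow(out), replace = TRUE))
  out$n_canonical <- out$cov - out$n_mod - out$n_other
  out$strand <- sample(c("+", "-"), nrow(out), replace = TRUE)
  data.table::setorder(out, contig, pos, type)
  out
}

.fixtureManifest <- function(spec, genomes, pangenes, cds_by_genome,
                             sites_by_genome, medians, thr) {
  types <- names(spec$trueSitesPerType)
  per_genome <- list()
  gene_positions <- list()
  for (g in genomes) {
    s <- sites_by_genome[[g]]
    surv <- s[s$survive == TRUE, ]
    counts <- lapply(stats::setNames(types, types), function(t) {
      st <- surv[surv$type == t, ]
      list(coding = sum(st$region == "coding"),
           non_coding = sum(st$region == "non-coding"),
           total = nrow(st))
    })
    per_genome[[g]] <- list(
      n_rows = nrow(s),
      file_median_coverage = medians[[g]],
      n_filtered = nrow(surv),
      counts = counts
    )
    cds <- cds_by_genome[[g]]
    gp <- lapply(stats::setNames(types, types), function(t) {
      st <- surv[surv$type == t & surv$region == "coding", ]
      sp <- split(st$pos, st$host)
      lapply(sp, function(v) sort(unique(as.integer(v))))
    })
    gene_positions[[g]] <- gp
  }
  # binary matrices: gene x genome, -1 = absent
  matrices <- list()
  for (t in types) {
    m <- matrix(-1L, length(pangenes$genes), length(genomes),
                dimnames = list(pangenes$genes, genomes))
    for (g in genomes) {
      cds <- cds_by_genome[[g]]
      tag2gene <- stats::setNames(cds$gene, cds$locus_tag)
      present <- unique(cds$gene)
      m[present, g] <- 0L
      meth_tags <- names(gene_positions[[g]][[t]])
      meth_genes <- unique(tag2gene[meth_tags])
      if (length(meth_genes)) m[meth_genes, g] <- 1L
    }
    matrices[[t]] <- m
  }
  prevalent <- lapply(matrices, function(m) {
    prev <- rowSums(m == 1L) / ncol(m)
    names(prev)[prev >= 0.95]
  })
  core95 <- lapply(matrices, function(m) {
    pres <- rowSums(m >= 0L) / ncol(m)
    names(pres)[pres >= 0.95]
  })
  list(
    seed = spec$seed,
    expected_auto_threshold = thr,
    per_genome = per_genome,
    gene_positions = gene_positions,
    binary_matrices = lapply(matrices, function(m)
      data.frame(Gene = rownames(m), as.data.frame(m), check.names = FALSE,
                 row.names = NULL, stringsAsFactors = FALSE)),
    prevalent_genes_95 = prevalent,
    core_genes_95 = core95
  )
}

.fixtureWriteFiles <- function(dir, genomes, pangenes, cds_by_genome,
                               sites_by_genome, manifest) {
  for (g in genomes) {
    s <- sites_by_genome[[g]]
    bed <- data.table::data.table(
      contig = s$contig, start = s$pos, end = s$pos + 1L,
      code = unname(.FIXTURE_CODES[s$type]), score = s$cov,
      strand = s$strand, thick_start = s$pos, thick_end = s$pos + 1L,
      color = "255,0,0", n_valid_cov = s$cov,
      percent_modified = s$rate, n_mod = s$n_mod,
      n_canonical = s$n_canonical, n_other_mod = s$n_other,
      n_delete = 0L, n_fail = 0L, n_diff = 0L, n_nocall = 0L)
    data.table::fwrite(bed, file.path(dir, paste0(g, ".bedmethyl")),
                       sep = "\t", col.names = FALSE, quote = FALSE)
    .fixtureWriteGff(cds_by_genome[[g]],
                     stats::setNames(
                       as.integer(manifestContigLengths(cds_by_genome[[g]], s)),
                       unique(s$contig)),
                     file.path(dir, paste0(g, ".gff")))
    data.table::fwrite(s, file.path(dir, paste0(g, ".truth.csv")))
  }
  # Roary-layout gene_presence_absence
  gpa <- data.frame(Gene = pangenes$genes, check.names = FALSE,
                    stringsAsFactors = FALSE)
  gpa[["Non-unique Gene name"]] <- ""
  gpa[["Annotation"]] <- paste0("hypothetical protein ", pangenes$genes)
  npres <- integer(length(pangenes$genes))
  cells <- matrix("", length(pangenes$genes), length(genomes),
                  dimnames = list(pangenes$genes, genomes))
  for (g in genomes) {
    cds <- cds_by_genome[[g]]
    sp <- split(cds$locus_tag, cds$gene)
    cells[names(sp), g] <- vapply(sp, paste, character(1), collapse = " ")
  }
  npres <- rowSums(cells != "")
  gpa[["No. isolates"]] <- npres
  gpa[["No. sequences"]] <- npres
  gpa[["Avg sequences per isolate"]] <- 1
  for (col in c("Genome Fragment", "Order within Fragment",
                "Accessory Fragment", "Accessory Order with Fragment",
                "QC", "Min group size nuc", "Max group size nuc",
                "Avg group size nuc"))
    gpa[[col]] <- ""
  for (g in genomes) gpa[[g]] <- cells[, g]
  data.table::fwrite(gpa, file.path(dir, "gene_presence_absence.csv"),
                     quote = TRUE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

# contig lengths as implied by the planted rows (upper bound is fine for
# the GFF sequence-region pragma)
manifestContigLengths <- function(cds, sites) {
  ctgs <- unique(sites$contig)
  vapply(ctgs, function(cc)
    max(sites$pos[sites$contig == cc] + 1L,
        cds$end0[cds$contig == cc]) + 100L, numeric(1))
}

.fixtureWriteGff <- function(cds, contigLengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ctg in names(contigLengths))
    writeLines(sprintf("##sequence-region %s 1 %d", ctg,
                       contigLengths[[ctg]]), con)
  lines <- sprintf(
    "%s\tfixture\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;locus_tag=%s;product=%s",
    cds$contig, cds$start0 + 1L, cds$end0, cds$strand,
    cds$locus_tag, cds$locus_tag, cds$product)
  writeLines(lines, con)
}

# Toy GenBank serialization of a CDS table (used to test GFF3/GenBank
# parse equivalence); synthetic, CDS features only.
.writeToyGenBank <- function(cds, contigLengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(contigLengths)) {
    writeLines(sprintf("LOCUS       %s %d bp    DNA     circular BCT 01-JAN-2026",
                       ctg, contigLengths[[ctg]]), con)
    writeLines(sprintf("DEFINITION  synthetic fixture contig %s.", ctg), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    sub <- cds[cds$contig == ctg, , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      loc <- sprintf("%d..%d", sub$start0[r] + 1L, sub$end0[r])
      if (sub$strand[r] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"",
                         sub$locus_tag[r]), con)
      writeLines(sprintf("                     /product=\"%s\"",
                         sub$product[r]), con)
    }
    writeLines("ORIGIN", con)
    writeLines("//", con)
  }
  invisible(path)
}
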