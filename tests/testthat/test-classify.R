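test_that("containment and flanking assignment follow half-open intervals", {
  cds <- makeCds(start0 = c(5L, 30L), end0 = c(15L, 40L),
                 gene = c("A", "B"))
  rec <- makeRecords(5, start0 = c(10L, 20L, 5L, 15L, 39L),
                     cov = rep(50L, 5), rate = rep(95, 5))
  cl <- classifySites(rec, cds)
  expect_identical(region(cl), c("coding", "non-coding", "coding",
                                 "non-coding", "coding"))
  expect_identical(unname(unlist(hostGenes(cl)[1])), "A")
  # between A and B: upstream A, downstream B
  expect_identical(upstreamGene(cl)[2], "A")
  expect_identical(downstreamGene(cl)[2], "B")
  expect_identical(mcols(cl)$upstream_end0[2], 15L)
  expect_identical(mcols(cl)$downstream_start0[2], 30L)
  # boundary semantics: start is coding, end is not (half-open)
  expect_identical(region(cl)[3], "coding")   # p = CDS start
  expect_identical(region(cl)[4], "non-coding")  # p = CDS end
  # partition invariant
  expect_identical(sum(region(cl) == "coding") +
                     sum(region(cl) == "non-coding"), length(rec))
})

test_that("overlapping CDS yield several hosts but one classified site", {
  cds <- makeCds(start0 = c(100L, 150L), end0 = c(300L, 400L),
                 gene = c("X", "Y"))
  rec <- makeRecords(1, start0 = 200L, cov = 50L, rate = 95)
  cl <- classifySites(rec, cds)
  expect_length(cl, 1)
  expect_setequal(unname(unlist(hostGenes(cl))), c("X", "Y"))
  sm <- summarizeCounts(cl)
  expect_identical(sm$total[sm$mod_type == "total"], 1L)  # counted once
  ext <- extendAnnotation(cds, normalizeModCodes(cl) |> suppressMessages())
  # listed once per host gene in the extended annotation
  expect_identical(unname(lengths(ext[["6mA"]])), c(1L, 1L))
})

test_that("classification equals the exhaustive interval-scan oracle", {
  set.seed(99)
  for (rep in 1:20) {
    ncds <- 50
    s0 <- sort(sample(0:40000, ncds))
    cds <- makeCds(start0 = s0, end0 = s0 + sample(100:800, ncds, TRUE),
                   contig = sample(c("c1", "c2"), ncds, TRUE))
    pos <- sample(0:42000, 400)
    ctg <- sample(c("c1", "c2", "orphan"), 400, TRUE,
                  prob = c(0.48, 0.48, 0.04))
    rec <- MethylRecords(contig = ctg, start0 = pos, raw_code = "m",
                         valid_coverage = 50L, percent_modified = 95,
                         n_mod = 48L, n_canonical = 2L)
    cl <- suppressMessages(classifySites(rec, cds))
    oracle <- bruteClassify(pos, ctg, cds)
    expect_identical(region(cl),
                     vapply(oracle, `[[`, character(1), "region"))
    expect_identical(lapply(as.list(hostGenes(cl)), function(v)
                       sort(unname(v))),
                     unname(lapply(oracle, `[[`, "host")))
    nc <- which(region(cl) == "non-coding")
    upok <- vapply(nc, function(i) {
        got <- upstreamGene(cl)[i]
          (is.na(got) && all(is.na(oracle[[i]]$up))) ||
          got %in% oracle[[i]]$up
      }, logical(1))
    dnok <- vapply(nc, function(i) {
        got <- downstreamGene(cl)[i]
          (is.na(got) && all(is.na(oracle[[i]]$down))) ||
          got %in% oracle[[i]]$down
      }, logical(1))
    expect_true(all(upok))
    expect_true(all(dnok))
  }
})

test_that("extended annotation collects sorted per-gene position lists", {
  cds <- makeCds(start0 = c(0L, 1000L, 2000L), end0 = c(500L, 1500L, 2500L))
  pos <- c(250L, 100L, 1100L, 600L)   # two in g001, one in g002, one intergenic
  rec <- MethylRecords(contig = "chr", start0 = pos, raw_code = "m",
                       valid_coverage = 40L, percent_modified = 92,
                       n_mod = 37L, n_canonical = 3L)
  rec <- suppressMessages(normalizeModCodes(rec))
  cl <- classifySites(rec, cds)
  ext <- extendAnnotation(cds, cl)
  expect_identical(unname(as.list(ext[["5mC"]])),
                   list(c(100L, 250L), 1100L, integer(0)))
  expect_identical(unname(sum(lengths(ext[["6mA"]]))), 0L)
  # conservation: total listed positions = number of coding sites
  expect_identical(sum(lengths(ext[["5mC"]])),
                   sum(region(cl) == "coding"))
  # degenerate: no classified sites at all
  ext0 <- extendAnnotation(cds, cl[0])
  expect_true(all(lengths(ext0[["5mC"]]) == 0))
})

test_that("count summary totals are consistent", {
  rec <- MethylRecords(contig = "chr", start0 = c(1L, 2L, 3L, 10L, 11L),
                       raw_code = "a", valid_coverage = 50L,
                       percent_modified = 95, n_mod = 48L,
                       n_canonical = 2L)
  rec <- suppressMessages(normalizeModCodes(rec))
  cds <- makeCds(start0 = 0L, end0 = 5L)
  cl <- classifySites(rec, cds)
  sm <- summarizeCounts(cl)
  r6 <- sm[sm$mod_type == "6mA", ]
  expect_identical(c(r6$coding, r6$non_coding, r6$total), c(3L, 2L, 5L))
  tot <- sm[sm$mod_type == "total", ]
  expect_identical(tot$total, 5L)
  expect_identical(tot$total, sum(sm$coding[sm$mod_type != "total"]) +
                     sum(sm$non_coding[sm$mod_type != "total"]))
  empty <- summarizeCounts(cl[0])
  expect_true(all(empty$total == 0L))
})

test_that("split-by-reference outputs concatenate to the unsplit outputs", {
  set.seed(5)
  cds <- suppressWarnings(c(
    makeCds(start0 = c(100L, 900L), end0 = c(600L, 1400L), contig = "c1",
            gene = c("c1a", "c1b")),
    makeCds(start0 = c(200L, 1000L), end0 = c(700L, 1600L), contig = "c2",
            gene = c("c2a", "c2b"))))
  pos <- sample(0:2000, 60)
  rec <- MethylRecords(contig = sample(c("c1", "c2"), 60, TRUE),
                       start0 = pos, raw_code = "a",
                       valid_coverage = 50L, percent_modified = 95,
                       n_mod = 48L, n_canonical = 2L)
  rec <- suppressMessages(normalizeModCodes(rec))
  cl <- classifySites(rec, cds)
  ext <- extendAnnotation(cds, cl)
  sm <- summarizeCounts(cl)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeClassificationOutputs(cl, ext, sm, d1, prefix = "s")
  writeClassificationOutputs(cl, ext, sm, d2, prefix = "s",
                             splitByReference = TRUE)
  for (kind in c("coding", "noncoding")) {
    whole <- panMethylome:::.readCommentedCsv(
      file.path(d1, sprintf("s.%s.csv", kind)), colClasses = "character")
    parts <- data.table::rbindlist(lapply(c("c1", "c2"), function(ctg)
      panMethylome:::.readCommentedCsv(
        file.path(d2, sprintf("s.%s.%s.csv", ctg, kind)),
        colClasses = "character")))
    data.table::setorder(whole, contig, position, mod_type)
    data.table::setorder(parts, contig, position, mod_type)
    expect_equal(as.data.frame(parts), as.data.frame(whole))
  }
  # non-coding rows carry both neighbour columns
  nc <- panMethylome:::.readCommentedCsv(file.path(d1, "s.noncoding.csv"))
  expect_true(all(c("upstream_gene", "downstream_gene",
                    "upstream_gene_end", "downstream_gene_start")
                  %in% names(nc)))
  # headers-only files for empty input
  d3 <- withr::local_tempdir()
  writeClassificationOutputs(cl[0], ext, summarizeCounts(cl[0]), d3,
                             prefix = "e")
  cod <- panMethylome:::.readCommentedCsv(file.path(d3, "e.coding.csv"))
  expect_identical(nrow(cod), 0L)
  expect_true("gene_id" %in% names(cod))
})

test_that("sites on contigs missing from the annotation stay in the partition", {
  cds <- makeCds(start0 = 0L, end0 = 100L, contig = "known")
  rec <- MethylRecords(contig = c("known", "unknown"), start0 = c(50L, 10L),
                       raw_code = "a", valid_coverage = 30L,
                       percent_modified = 96.67, n_mod = 29L,
                       n_canonical = 1L)
  expect_message(cl <- classifySites(rec, cds), "absent from the annotation")
  expect_identical(region(cl), c("coding", "non-coding"))
  expect_true(is.na(upstreamGene(cl)[2]) && is.na(downstreamGene(cl)[2]))
})

test_that("extended annotation CSVs round-trip through the reader", {
  cds <- makeCds(start0 = c(0L, 1000L), end0 = c(500L, 1500L))
  rec <- MethylRecords(contig = "chr", start0 = c(10L, 20L, 1100L),
                       raw_code = "m", valid_coverage = 40L,
                       percent_modified = 95, n_mod = 38L,
                       n_canonical = 2L)
  rec <- suppressMessages(normalizeModCodes(rec))
  cl <- classifySites(rec, cds)
  ext <- extendAnnotation(cds, cl)
  d <- withr::local_tempdir()
  writeClassificationOutputs(cl, ext, summarizeCounts(cl), d, prefix = "g")
  back <- readExtendedAnnotation(file.path(d, "g.extended_annotation.csv"))
  expect_identical(back$gene_id, ext$gene_id)
  expect_identical(unname(as.list(back[["5mC"]])),
                   unname(as.list(ext[["5mC"]])))
  expect_identical(back$start0, ext$start0)
})
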