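# a hand-written 4-genome Roary table with a paralog cell
writeToyGpa <- function(path) {
  hdr <- c("Gene", "Non-unique Gene name", "Annotation", "No. isolates",
           "No. sequences", "Avg sequences per isolate", "Genome Fragment",
           "Order within Fragment", "Accessory Fragment",
           "Accessory Order with Fragment", "QC", "Min group size nuc",
           "Max group size nuc", "Avg group size nuc",
           "g1", "g2", "g3", "g4")
  rows <- list(
    c("geneA", "", "prot A", "3", "3", "1", "", "", "", "", "", "", "", "",
      "g1_001", "g2_001", "g3_001", ""),
    c("geneB", "", "prot B", "4", "5", "1.25", "", "", "", "", "", "", "", "",
      "g1_002 g1_005", "g2_002", "g3_002", "g4_001"),
    c("geneC", "", "prot C", "1", "1", "1", "", "", "", "", "", "", "", "",
      "", "", "", "g4_002"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(shQuote(hdr, "cmd"), collapse = ","), con)
  for (r in rows)
    writeLines(paste(shQuote(r, "cmd"), collapse = ","), con)
}

# minimal extended annotation built in code
makeExtended <- function(genes, positions6mA = rep(list(integer(0)),
                                                   length(genes))) {
  DataFrame(gene_id = genes, contig = "c", start0 = seq_along(genes) * 100L,
            end0 = seq_along(genes) * 100L + 50L, strand = "+",
            product = "", "4mC" = IntegerList(rep(list(integer(0)),
                                                  length(genes))),
            "5mC" = IntegerList(rep(list(integer(0)), length(genes))),
            "6mA" = IntegerList(positions6mA), check.names = FALSE)
}

test_that("Roary tables parse with genome auto-detection and paralog splitting", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeToyGpa(tmp)
  pan <- readGenePresenceAbsence(tmp)
  expect_identical(genomeNames(pan), c("g1", "g2", "g3", "g4"))
  expect_identical(geneNames(pan), c("geneA", "geneB", "geneC"))
  # presence in 3 of 4 genomes
  expect_identical(sum(lengths(pan@tags["geneA", ]) > 0), 3L)
  # paralog cell registers both tags
  expect_identical(locusTags(pan, "geneB", "g1"), c("g1_002", "g1_005"))
  # empty cell is absence
  expect_length(locusTags(pan, "geneA", "g4"), 0)
  # missing header columns are a format error
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("foo,bar\n1,2", bad)
  expect_error(readGenePresenceAbsence(bad), "missing column")
})

test_that("pan matrices encode methylated/unmethylated/absent and merge paralogs", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeToyGpa(tmp)
  pan <- readGenePresenceAbsence(tmp)
  ext <- list(
    g1 = makeExtended(c("g1_001", "g1_002", "g1_005"),
                      list(1234L, integer(0), c(40L, 10L))),
    g2 = makeExtended(c("g2_001", "g2_002")),
    g3 = makeExtended(c("g3_001", "g3_002"), list(7L, integer(0))),
    g4 = makeExtended(c("g4_001", "g4_002"), list(integer(0), 99L)))
  pm <- buildPanMethylome(ext, pan, mode = "binary")
  a <- SummarizedExperiment::assay(pm, "6mA")
  expect_identical(a["geneA", ], c(g1 = 1L, g2 = 0L, g3 = 1L, g4 = NA))
  # paralog union: geneB methylated in g1 through its second copy only
  expect_identical(a["geneB", ], c(g1 = 1L, g2 = 0L, g3 = 0L, g4 = 0L))
  expect_identical(a["geneC", ], c(g1 = NA, g2 = NA, g3 = NA, g4 = 1L))
  # all-zero type stays present/absent structured
  a4 <- SummarizedExperiment::assay(pm, "4mC")
  expect_true(all(a4[!is.na(a4)] == 0L))

  pp <- buildPanMethylome(ext, pan, mode = "positions")
  p <- SummarizedExperiment::assay(pp, "6mA")
  expect_identical(p[["geneB", "g1"]], c(10L, 40L))  # merged + sorted
  expect_identical(p[["geneA", "g2"]], integer(0))
  expect_true(is.na(p[["geneA", "g4"]][1]))
  # mode consistency: binarized positions reproduce the binary matrix
  expect_identical(SummarizedExperiment::assay(binarize(pp), "6mA"), a)

  # genome mismatch is a hard error listing both sets
  expect_error(buildPanMethylome(ext[1:3], pan, mode = "binary"),
               "g4")
  # unknown locus tag logged, treated as no evidence
  ext2 <- ext
  ext2$g1 <- makeExtended("g1_001", list(5L))
  expect_message(pm2 <- buildPanMethylome(ext2, pan), "absent from extended")
  expect_identical(SummarizedExperiment::assay(pm2, "6mA")["geneB", "g1"], 0L)
})

test_that("cross-genome count summaries add up", {
  s1 <- data.frame(mod_type = c("6mA", "total"), coding = c(4L, 4L),
                   non_coding = c(6L, 6L), total = c(10L, 10L))
  s2 <- data.frame(mod_type = c("6mA", "total"), coding = c(9L, 9L),
                   non_coding = c(6L, 6L), total = c(15L, 15L))
  out <- summarizePanCounts(list(a = s1, b = s2))
  allrow <- out[out$genome == "all" & out$mod_type == "6mA", ]
  expect_identical(allrow$total, 25L)
  expect_identical(allrow$coding, 13L)
  # single genome: the summary is its own table plus the totals block
  one <- summarizePanCounts(list(solo = s1))
  expect_identical(one[one$genome == "solo", -1],
                   s1, ignore_attr = TRUE)
  expect_equal(one[one$genome == "all" & one$mod_type == "6mA", ]$total, 10)
})

test_that("gene prevalence respects the threshold boundary and absent cells", {
  m <- matrix(0L, 3, 20, dimnames = list(c("a", "b", "c"),
                                         paste0("s", 1:20)))
  m["a", 1:19] <- 1L                 # 19/20 = 0.95, boundary inclusive
  m["b", 1:18] <- 1L                 # 18/20 = 0.90
  m["c", ] <- 1L                     # everywhere
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list("6mA" = m))
  pm <- new("PanMethylome", se, mode = "binary")
  got <- genePrevalence(pm, "6mA", threshold = 0.95)
  expect_setequal(got$gene, c("a", "c"))
  expect_true(got$in_all_genomes[got$gene == "c"])
  expect_false(got$in_all_genomes[got$gene == "a"])
  # absent cells count in the "all" denominator but not the numerator
  m["a", 20] <- NA
  se2 <- SummarizedExperiment::SummarizedExperiment(assays = list("6mA" = m))
  pm2 <- new("PanMethylome", se2, mode = "binary")
  expect_setequal(genePrevalence(pm2, "6mA", 0.95)$gene, c("a", "c"))
  expect_setequal(genePrevalence(pm2, "6mA", 1, denominator = "carrier")$gene,
                  c("a", "c"))
  # positions-mode input is rejected with advice
  ppos <- new("PanMethylome",
              SummarizedExperiment::SummarizedExperiment(assays = list(
                "6mA" = matrix(list(1L, integer(0)), 1, 2,
                               dimnames = list("g", c("s1", "s2"))))),
              mode = "positions")
  expect_error(genePrevalence(ppos, "6mA"), "binarize")
})

test_that("matrix CSVs keep the absent marker distinct from zero", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeToyGpa(tmp)
  pan <- readGenePresenceAbsence(tmp)
  ext <- list(g1 = makeExtended(c("g1_001", "g1_002", "g1_005")),
              g2 = makeExtended(c("g2_001", "g2_002")),
              g3 = makeExtended(c("g3_001", "g3_002"), list(7L, integer(0))),
              g4 = makeExtended(c("g4_001", "g4_002")))
  pm <- buildPanMethylome(ext, pan, mode = "binary")
  d <- withr::local_tempdir()
  paths <- writePanMatrices(pm, d)
  raw <- data.table::fread(paths[["6mA"]], colClasses = "character",
                           na.strings = NULL)
  expect_identical(raw$g4[raw$Gene == "geneA"], "")   # absent
  expect_identical(raw$g2[raw$Gene == "geneA"], "0")  # present, unmethylated
  expect_identical(raw$g3[raw$Gene == "geneA"], "1")
})
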