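test_that("bedMethyl write/read round-trips and accepts both dialects", {
  rec <- makeRecords(50, seed = 1)
  tmp <- withr::local_tempfile(fileext = ".bedmethyl")
  writeRecords(rec, tmp, format = "bedmethyl")
  back <- readBedMethyl(tmp)
  expect_identical(as.character(seqnames(back)), as.character(seqnames(rec)))
  expect_identical(sitePositions(back), sitePositions(rec))
  expect_identical(validCoverage(back), validCoverage(rec))
  expect_equal(percentModified(back), percentModified(rec))
  expect_identical(mcols(back)$n_mod, mcols(rec)$n_mod)
  expect_identical(as.character(strand(back)), as.character(strand(rec)))

  # same table serialized in the mixed tab/space dialect parses
  # identically
  lines <- readLines(tmp)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  mixed <- vapply(parts, function(f)
    paste(c(paste(f[1:9], collapse = "\t"),
            paste(f[10:18], collapse = " ")), collapse = "\t"),
    character(1))
  tmp2 <- withr::local_tempfile(fileext = ".bedmethyl")
  writeLines(mixed, tmp2)
  back2 <- readBedMethyl(tmp2)
  expect_identical(sitePositions(back2), sitePositions(back))
  expect_equal(percentModified(back2), percentModified(back))
  expect_identical(validCoverage(back2), validCoverage(back))
})

test_that("structurally invalid files are rejected with line numbers", {
  tmp <- withr::local_tempfile()
  writeBedMethylLines(tmp, list(bedRow(pos = 10), bedRow(pos = 20)[1:17]))
  expect_error(readBedMethyl(tmp), "line 2")
  writeBedMethylLines(tmp, list(bedRow(pos = 10)[1:17]))
  expect_error(readBedMethyl(tmp), "line 1")

  bad <- bedRow(pos = 30); bad[5] <- "notanumber"
  writeBedMethylLines(tmp, list(bedRow(pos = 10), bad))
  expect_error(readBedMethyl(tmp), "score.*line 2|line 2.*score")

  file.create(tmp2 <- withr::local_tempfile())
  expect_warning(empty <- readBedMethyl(tmp2), "empty")
  expect_length(empty, 0)
})

test_that("modification codes normalize, pass through and stay idempotent", {
  rec <- MethylRecords(contig = "c", start0 = 1:5,
                       raw_code = c("m", "a", "21839", "5mC", "x"),
                       valid_coverage = 10L, percent_modified = 50,
                       n_mod = 5L, n_canonical = 5L)
  expect_message(out <- normalizeModCodes(rec), "unmapped.*'x'")
  expect_identical(modType(out), c("5mC", "6mA", "4mC", "5mC", "x"))
  expect_identical(rawCode(out), c("m", "a", "21839", "5mC", "x"))
  # idempotent
  again <- suppressMessages(normalizeModCodes(out))
  expect_identical(modType(again), modType(out))
})

test_that("automatic threshold is the median of per-file medians", {
  dir <- withr::local_tempdir()
  # three files with per-file medians 10, 20, 30
  meds <- c(10, 20, 30)
  paths <- character(3)
  for (i in 1:3) {
    rec <- makeRecords(7, cov = meds[i] + c(-2, -1, 0, 0, 0, 1, 2),
                       start0 = 1:7)
    paths[i] <- file.path(dir, sprintf("f%d.bedmethyl", i))
    writeRecords(rec, paths[i])
  }
  expect_equal(suppressMessages(computeCoverageThreshold(paths)), 20)
  # permutation invariance in file order
  expect_equal(suppressMessages(computeCoverageThreshold(rev(paths))), 20)
  # single file, odd count
  single <- file.path(dir, "s.bedmethyl")
  writeRecords(makeRecords(3, cov = c(5, 7, 9), start0 = 1:3), single)
  expect_equal(suppressMessages(computeCoverageThreshold(single)), 7)
  # even count: arithmetic mean of the central pair, kept fractional
  writeRecords(makeRecords(4, cov = c(5, 7, 10, 20), start0 = 1:4), single)
  expect_equal(suppressMessages(computeCoverageThreshold(single)), 8.5)
  # record order within a file does not matter
  writeRecords(makeRecords(4, cov = c(20, 7, 5, 10), start0 = 1:4), single)
  expect_equal(suppressMessages(computeCoverageThreshold(single)), 8.5)
  expect_error(computeCoverageThreshold(character(0)), "at least one")
  expect_error(computeCoverageThreshold(file.path(dir, "nope")),
               "unreadable")
})

test_that("filtering is inclusive at both thresholds and matches a per-record recheck", {
  rec <- makeRecords(1000, seed = 42)
  cfg <- filterConfig(minCoverage = 36, minRate = 90)
  kept <- filterRecords(rec, cfg)
  # independent record-by-record recheck
  manual <- vapply(seq_along(rec), function(i)
    validCoverage(rec)[i] >= 36 && percentModified(rec)[i] >= 90,
    logical(1))
  expect_identical(sitePositions(kept), sitePositions(rec)[manual])

  # inclusive boundaries
  edge <- MethylRecords(contig = "c", start0 = 1:2, raw_code = "a",
                        valid_coverage = c(36L, 35L),
                        percent_modified = c(90, 99.9),
                        n_mod = c(32L, 35L), n_canonical = c(4L, 0L))
  expect_identical(sitePositions(filterRecords(edge, cfg)), 1L)

  # monotone in both thresholds; degenerate corners
  n0 <- length(filterRecords(rec, minCoverage = 0, minRate = 0))
  expect_identical(n0, length(rec))
  for (cov in c(10, 30, 50)) {
    a <- length(filterRecords(rec, minCoverage = cov, minRate = 50))
    b <- length(filterRecords(rec, minCoverage = cov + 5, minRate = 50))
    c2 <- length(filterRecords(rec, minCoverage = cov, minRate = 60))
    expect_lte(b, a)
    expect_lte(c2, a)
  }
  expect_length(
    filterRecords(rec, minCoverage = max(validCoverage(rec)) + 1,
                  minRate = 0), 0)
  # zero-rate records are removable only via the rate threshold
  zr <- MethylRecords(contig = "c", start0 = 1L, raw_code = "a",
                      valid_coverage = 100L, percent_modified = 0,
                      n_mod = 0L, n_canonical = 100L)
  expect_length(filterRecords(zr, minCoverage = 0, minRate = 0), 1)
  expect_length(filterRecords(zr, minCoverage = 0, minRate = 0.1), 0)
})

test_that("tabular and json writers agree and handle empty input", {
  rec <- makeRecords(20, seed = 3)
  csv <- withr::local_tempfile(fileext = ".csv")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  writeRecords(rec, csv, "csv")
  writeRecords(rec, tsv, "tsv")
  writeRecords(rec, js, "json")
  a <- data.table::fread(csv)
  b <- data.table::fread(tsv)
  expect_identical(a, b)   # identical after separator substitution
  expect_true(all(c("contig", "score", "percent_modified") %in% names(a)))
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(j), 20)
  expect_equal(j$start, sitePositions(rec))

  empty <- makeRecords(0, cov = integer(0), start0 = integer(0))
  for (fmt in c("bedmethyl", "csv", "tsv", "json")) {
    p <- withr::local_tempfile()
    writeRecords(empty, p, fmt)
    expect_true(file.exists(p))
  }
  expect_error(writeRecords(rec, csv, "parquet"), "valid choices")
})

test_that("consistency checking warns by default and errors when strict", {
  rec <- MethylRecords(contig = "c", start0 = 1L, raw_code = "a",
                       valid_coverage = 50L, percent_modified = 80,
                       n_mod = 10L, n_canonical = 40L)  # 10/50 != 80 %
  expect_warning(checkConsistency(rec), "consistency")
  expect_error(checkConsistency(rec, strict = TRUE), "consistency")
  ok <- MethylRecords(contig = "c", start0 = 1L, raw_code = "a",
                      valid_coverage = 50L, percent_modified = 20,
                      n_mod = 10L, n_canonical = 40L)
  expect_silent(checkConsistency(ok, strict = TRUE))
})
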