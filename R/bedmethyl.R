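## bedMethyl I/O, validation, normalization and filtering.
##
## bedMethyl is the BED-derived 18-column format emitted by nanopore
## modified-base pileup callers: one row per assessed genomic position per
## modification code, with the total valid coverage in the BED score
## column and the percent of reads supporting the modification in column
## 11.

.BEDMETHYL_COLS <- c(
  "contig", "start", "end", "code", "score", "strand",
  "thick_start", "thick_end", "color", "n_valid_cov", "percent_modified",
  "n_mod", "n_canonical", "n_other_mod", "n_delete", "n_fail",
  "n_diff", "n_nocall"
)
.BEDMETHYL_NUMERIC <- setdiff(.BEDMETHYL_COLS,
                              c("contig", "code", "strand", "color"))

#' Default modification-code renaming table
#'
#' Maps the caller's modification codes to the human-readable methylation
#' type names used throughout the package: the single-letter codes `m`
#' (5mC), `a` (6mA) and `h` (5hmC), plus the ChEBI-style numeric code
#' `21839` for 4mC. Codes not covered by the mapping pass through
#' unchanged.
#'
#' @return named character vector (names = raw codes, values = type
#'   names).
#' @export
defaultModCodeMap <- function() {
  c(m = "5mC", a = "6mA", h = "5hmC", "21839" = "4mC")
}

#' Read a bedMethyl file
#'
#' Parses and validates an 18-column bedMethyl table. Two field-separator
#' dialects are accepted: all-tab rows, and the mixed dialect in which
#' columns 1-9 are tab-separated and columns 10-18 space-separated.
#' Structure is verified before any record is returned: every row must
#' have 18 fields and every numeric column must parse; violations raise
#' an error naming the offending line (and column). With `strict = TRUE`
#' the arithmetic consistency checks of [checkConsistency()] also become
#' errors instead of warnings.
#'
#' @param path path to a bedMethyl file.
#' @param strict logical; escalate consistency warnings to errors.
#' @return a [MethylRecords] object, rows in file order. An empty file
#'   yields an empty object with a warning.
#' @seealso [writeRecords()] for the inverse operation.
#' @export
readBedMethyl <- function(path, strict = FALSE) {
  pm_assert(file.exists(path), sprintf("file not found: %s", path))
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L) {
    pm_warn(sprintf("empty bedMethyl file: %s", path))
    return(.emptyMethylRecords())
  }
  dialect_fields <- nf[1L]
  if (!dialect_fields %in% c(10L, 18L))
    stop(sprintf("bedMethyl format error in %s at line 1: expected 18 columns (or the tab/space dialect), found %d tab-separated fields",
                 path, dialect_fields), call. = FALSE)
  bad <- which(nf != dialect_fields)
  if (length(bad))
    stop(sprintf("bedMethyl format error in %s at line %d: expected %d tab-separated fields, found %d",
                 path, bad[1L], dialect_fields, nf[bad[1L]]), call. = FALSE)

  dt <- data.table::fread(path, sep = "\t", header = FALSE, quote = "",
                          colClasses = "character", data.table = TRUE,
                          showProgress = FALSE)
  if (dialect_fields == 10L) {
    # Modkit dialect: columns 10-18 live space-separated in field 10
    tail9 <- data.table::tstrsplit(dt[[10L]], " ", fixed = TRUE)
    if (length(tail9) != 9L || anyNA(tail9[[9L]])) {
      nspace <- lengths(strsplit(dt[[10L]], " ", fixed = TRUE))
      off <- which(nspace != 9L)[1L]
      stop(sprintf("bedMethyl format error in %s at line %d: expected 9 space-separated fields after column 9, found %d",
                   path, off, nspace[off]), call. = FALSE)
    }
    dt <- cbind(dt[, 1:9], data.table::as.data.table(tail9))
  }
  data.table::setnames(dt, .BEDMETHYL_COLS)

  for (col in .BEDMETHYL_NUMERIC) {
    v <- suppressWarnings(as.numeric(dt[[col]]))
    if (anyNA(v)) {
      line <- which(is.na(v))[1L]
      stop(sprintf("bedMethyl type error in %s: non-numeric value '%s' in column '%s' at line %d",
                   path, dt[[col]][line], col, line), call. = FALSE)
    }
    data.table::set(dt, j = col, value = v)
  }

  notone <- which(dt$end != dt$start + 1)
  if (length(notone)) {
    msg <- sprintf("%d record(s) are not single-base (end != start + 1), first at line %d",
                   length(notone), notone[1L])
    if (strict) stop(msg, call. = FALSE) else pm_warn(msg)
  }

  rec <- MethylRecords(
    contig = dt$contig, start0 = dt$start, raw_code = dt$code,
    valid_coverage = dt$score, strand = dt$strand,
    percent_modified = dt$percent_modified,
    n_mod = dt$n_mod, n_canonical = dt$n_canonical,
    n_other_mod = dt$n_other_mod, n_delete = dt$n_delete,
    n_fail = dt$n_fail, n_diff = dt$n_diff, n_nocall = dt$n_nocall,
    thick_start = dt$thick_start, thick_end = dt$thick_end,
    color = dt$color
  )
  if (any(dt$n_valid_cov != dt$score)) {
    msg <- sprintf("score column and Nvalid_cov disagree on %d line(s); score is used as valid coverage",
                   sum(dt$n_valid_cov != dt$score))
    if (strict) stop(msg, call. = FALSE) else pm_warn(msg)
  }
  checkConsistency(rec, strict = strict)
  rec
}

.emptyMethylRecords <- function() {
  MethylRecords(contig = character(0), start0 = integer(0),
                raw_code = character(0), valid_coverage = integer(0))
}

#' Arithmetic consistency of bedMethyl counts
#'
#' Verifies that `valid_coverage` equals `n_mod + n_canonical +
#' n_other_mod` and that `percent_modified` equals
#' `100 * n_mod / valid_coverage` within `tol` (printing precision).
#' Violations warn by default and error when `strict = TRUE`; structural
#' validation of the file itself is always an error in [readBedMethyl()].
#'
#' @param x a [MethylRecords] object.
#' @param tol tolerance on the percent scale (default 0.1).
#' @param strict escalate to an error.
#' @return invisibly, a logical vector marking consistent records.
#' @export
checkConsistency <- function(x, tol = 0.1, strict = FALSE) {
  m <- mcols(x)
  covok <- m$valid_coverage == m$n_mod + m$n_canonical + m$n_other_mod
  expct <- ifelse(m$valid_coverage > 0L,
                  100 * m$n_mod / m$valid_coverage, m$percent_modified)
  pctok <- abs(m$percent_modified - expct) <= tol
  ok <- covok & pctok
  if (length(ok) && !all(ok)) {
    msg <- sprintf("%d record(s) fail the coverage/percent consistency check (first at row %d)",
                   sum(!ok), which(!ok)[1L])
    if (strict) stop(msg, call. = FALSE) else pm_warn(msg)
  }
  invisible(ok)
}

#' Normalize modification codes to methylation type names
#'
#' Rewrites `mod_type` from `raw_code` using a code-to-name table
#' (default [defaultModCodeMap()]). Codes already equal to a mapped name
#' are left unchanged (idempotent); unknown codes pass through verbatim
#' and are logged once per distinct code. `raw_code` is always retained.
#'
#' @param x a [MethylRecords] object.
#' @param mapping named character vector, raw code -> type name.
#' @return `x` with `mod_type` filled in.
#' @export
normalizeModCodes <- function(x, mapping = defaultModCodeMap()) {
  pm_assert(!anyDuplicated(names(mapping)),
            "mod-code mapping must have unique keys")
  raw <- mcols(x)$raw_code
  mapped <- unname(mapping[raw])
  already <- raw %in% mapping             # code is itself a mapped name
  out <- ifelse(already, raw, ifelse(is.na(mapped), raw, mapped))
  unknown <- unique(raw[!already & is.na(mapped)])
  for (code in unknown)
    pm_log(sprintf("unmapped modification code '%s' passed through", code),
           level = "WARN")
  mcols(x)$mod_type <- out
  x
}

#' Automatic coverage threshold: median of per-file median coverages
#'
#' For each bedMethyl file the median of the `valid_coverage` column is
#' taken; the threshold is the median of those per-file medians. The
#' median of an even-length vector is the arithmetic mean of the two
#' central values, and a fractional result is returned (and later
#' compared) unrounded.
#'
#' @param paths character vector of bedMethyl file paths.
#' @return a single numeric threshold (possibly fractional).
#' @export
computeCoverageThreshold <- function(paths) {
  pm_assert(length(paths) >= 1L, "at least one bedMethyl file is required")
  missing <- paths[!file.exists(paths)]
  pm_assert(length(missing) == 0L,
            paste0("unreadable bedMethyl file(s): ",
                   paste(missing, collapse = ", ")))
  meds <- numeric(0)
  for (p in paths) {
    rec <- suppressWarnings(readBedMethyl(p))
    if (length(rec) == 0L) {
      pm_log(sprintf("file with zero records skipped for the coverage threshold: %s", p))
      next
    }
    meds <- c(meds, pm_median(validCoverage(rec)))
  }
  pm_assert(length(meds) >= 1L,
            "no records in any input; cannot derive a coverage threshold")
  thr <- pm_median(meds)
  pm_log(sprintf("automatic coverage threshold: %.1f (median of %d per-file medians)",
                 thr, length(meds)))
  thr
}

#' Filtering configuration
#'
#' Bundles the two filtering thresholds: the minimum valid coverage
#' (a number, or `"auto"` to derive it with
#' [computeCoverageThreshold()]) and the minimum methylation rate in
#' percent (default 90). Both filters are inclusive.
#'
#' @param minCoverage non-negative number or `"auto"`.
#' @param minRate number in \[0, 100\].
#' @return a `FilterConfig` list.
#' @export
filterConfig <- function(minCoverage = "auto", minRate = 90) {
  if (!(identical(minCoverage, "auto") ||
        (is.numeric(minCoverage) && length(minCoverage) == 1L &&
         minCoverage >= 0)))
    stop("minCoverage must be a non-negative number or \"auto\"",
         call. = FALSE)
  pm_assert(is.numeric(minRate) && length(minRate) == 1L &&
              minRate >= 0 && minRate <= 100,
            "minRate must lie in [0, 100]")
  structure(list(minCoverage = minCoverage, minRate = as.numeric(minRate)),
            class = "FilterConfig")
}

#' Resolve an "auto" coverage threshold against a set of files
#'
#' @param config a [filterConfig()] object.
#' @param autoPaths bedMethyl files used to derive the automatic
#'   threshold; required when `minCoverage` is `"auto"`.
#' @return the config with a concrete numeric `minCoverage`.
#' @export
resolveFilterConfig <- function(config, autoPaths = NULL) {
  stopifnot(inherits(config, "FilterConfig"))
  if (identical(config$minCoverage, "auto")) {
    pm_assert(length(autoPaths) >= 1L,
              "minCoverage = \"auto\" requires bedMethyl paths to derive the threshold from")
    config$minCoverage <- computeCoverageThreshold(autoPaths)
  }
  config
}

#' Filter methylation records on coverage and methylation rate
#'
#' Retains a record iff `valid_coverage >= minCoverage` and
#' `percent_modified >= minRate` (both inclusive: boundary records are
#' kept). Record order is preserved. Sites the caller reported with a
#' methylation rate of zero are only removable via `minRate > 0`.
#'
#' @param x a [MethylRecords] object.
#' @param config a resolved [filterConfig()]; alternatively pass
#'   `minCoverage`/`minRate` directly.
#' @param minCoverage,minRate thresholds used when `config` is missing.
#' @return the retained subset of `x`.
#' @export
filterRecords <- function(x, config = NULL, minCoverage = NULL,
                          minRate = 90) {
  if (!is.null(config)) {
    stopifnot(inherits(config, "FilterConfig"))
    pm_assert(is.numeric(config$minCoverage),
              "config not resolved: minCoverage is still \"auto\"")
    minCoverage <- config$minCoverage
    minRate <- config$minRate
  }
  pm_assert(is.numeric(minCoverage) && length(minCoverage) == 1L,
            "minCoverage must be a single number (resolve \"auto\" first)")
  keep <- validCoverage(x) >= minCoverage & percentModified(x) >= minRate
  x[keep]
}

#' Write methylation records
#'
#' Serializes a [MethylRecords] object as bedMethyl (18 tab-separated
#' columns, no header, positions 0-based half-open — round-trips through
#' [readBedMethyl()] to an identical collection), as CSV/TSV with a
#' header row, or as a JSON array of per-record objects. An empty record
#' set produces a valid empty-bodied file in every format.
#'
#' @param x a [MethylRecords] object.
#' @param path output file path.
#' @param format one of `"bedmethyl"`, `"csv"`, `"tsv"`, `"json"`.
#' @return `path`, invisibly.
#' @export
writeRecords <- function(x, path, format = "bedmethyl") {
  valid <- c("bedmethyl", "csv", "tsv", "json")
  if (!is.character(format) || length(format) != 1L || !format %in% valid)
    stop(sprintf("unknown output format '%s'; valid choices: %s",
                 paste(format, collapse = ","),
                 paste(valid, collapse = ", ")), call. = FALSE)
  dt <- .recordsToTable(x)
  switch(format,
    bedmethyl = data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                                   quote = FALSE),
    tsv = data.table::fwrite(dt, path, sep = "\t", col.names = TRUE,
                             quote = FALSE),
    csv = data.table::fwrite(dt, path, sep = ",", col.names = TRUE,
                             quote = "auto"),
    json = jsonlite::write_json(as.data.frame(dt), path, digits = NA,
                                na = "null")
  )
  invisible(path)
}

# bedMethyl column order, 0-based coordinates
.recordsToTable <- function(x) {
  m <- mcols(x)
  data.table::data.table(
    contig = as.character(seqnames(x)),
    start = start(x) - 1L,
    end = start(x),               # single-base, half-open
    code = m$raw_code,
    score = m$valid_coverage,
    strand = ifelse(as.character(strand(x)) == "*", ".",
                    as.character(strand(x))),
    thick_start = m$thick_start,
    thick_end = m$thick_end,
    color = m$color,
    n_valid_cov = m$valid_coverage,
    percent_modified = m$percent_modified,
    n_mod = m$n_mod,
    n_canonical = m$n_canonical,
    n_other_mod = m$n_other_mod,
    n_delete = m$n_delete,
    n_fail = m$n_fail,
    n_diff = m$n_diff,
    n_nocall = m$n_nocall
  )
}
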