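## The two pipeline entry points: per-genome filtering/classification
## (runMiner) and pangenome-wide integration (runPanMiner). Both echo a
## resolved-configuration manifest for reproducibility and log
## per-stage record counts.

#' Filter a bedMethyl table and classify its sites
#'
#' Runs read -> normalize codes -> (resolve automatic coverage
#' threshold) -> filter -> write; when an annotation is given, also
#' classify -> extend annotation -> summarize -> write the four
#' classification CSVs. Without an annotation only the filtered table
#' is written (filter-only mode). Every threshold actually used is
#' logged, and the resolved configuration is written to
#' `<prefix>.run_manifest.json`. On error, files already written by
#' this run are removed.
#'
#' @param bedmethyl path to the input bedMethyl file.
#' @param outDir output directory.
#' @param annotation optional GFF3/GenBank annotation path.
#' @param minCoverage numeric threshold or `"auto"`.
#' @param autoCoverageDir directory of bedMethyl files from which the
#'   automatic threshold is derived; defaults to the input file alone.
#' @param minRate minimum methylation rate in percent (default 90).
#' @param format output format for the filtered table
#'   (`"bedmethyl"`, `"csv"`, `"tsv"`, `"json"`).
#' @param splitByReference write classification outputs per contig.
#' @param modCodeMap code renaming table ([defaultModCodeMap()]).
#' @param strict escalate consistency warnings to errors.
#' @param prefix output file prefix; defaults to the input file stem.
#' @return invisibly, a list with the records, filtered records,
#'   classified sites, extended annotation, count summary, the resolved
#'   thresholds and the written paths.
#' @export
runMiner <- function(bedmethyl, outDir, annotation = NULL,
                     minCoverage = "auto", autoCoverageDir = NULL,
                     minRate = 90, format = "bedmethyl",
                     splitByReference = FALSE,
                     modCodeMap = defaultModCodeMap(),
                     strict = FALSE, prefix = NULL) {
  pm_assert(file.exists(bedmethyl),
            sprintf("bedMethyl input not found: %s", bedmethyl))
  if (is.null(prefix))
    prefix <- sub("\\.[^.]*$", "", basename(bedmethyl))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok && length(written)) {
    pm_log("run failed; removing partial outputs", level = "WARN")
    unlink(written)
  }, add = TRUE)

  records <- readBedMethyl(bedmethyl, strict = strict)
  pm_log(sprintf("parsed %d records from %s", length(records), bedmethyl))
  records <- normalizeModCodes(records, modCodeMap)

  config <- filterConfig(minCoverage = minCoverage, minRate = minRate)
  autoPaths <- if (identical(minCoverage, "auto")) {
    if (is.null(autoCoverageDir)) bedmethyl else
      listBedMethylFiles(autoCoverageDir)
  }
  config <- resolveFilterConfig(config, autoPaths)
  pm_log(sprintf("filtering with min coverage %.1f, min rate %.1f%%",
                 config$minCoverage, config$minRate))
  filtered <- filterRecords(records, config)
  pm_log(sprintf("%d of %d records pass the filters",
                 length(filtered), length(records)))

  fext <- c(bedmethyl = "bedmethyl", csv = "csv", tsv = "tsv",
            json = "json")[[format]]
  fpath <- file.path(outDir, paste0(prefix, ".filtered.", fext))
  writeRecords(filtered, fpath, format = format)
  written <- c(written, fpath)

  classified <- NULL; extended <- NULL; summary <- NULL
  if (!is.null(annotation)) {
    cds <- readAnnotation(annotation)
    classified <- classifySites(filtered, cds)
    pm_log(sprintf("classified sites: %d coding, %d non-coding",
                   sum(region(classified) == "coding"),
                   sum(region(classified) == "non-coding")))
    extended <- extendAnnotation(cds, classified)
    summary <- summarizeCounts(classified)
    written <- c(written,
                 writeClassificationOutputs(classified, extended, summary,
                                            outDir, prefix = prefix,
                                            splitByReference = splitByReference))
  }
  manifest <- list(
    input = bedmethyl, annotation = annotation,
    min_coverage = config$minCoverage, min_rate = config$minRate,
    auto_coverage = identical(minCoverage, "auto"),
    format = format, split_by_reference = splitByReference,
    n_parsed = length(records), n_filtered = length(filtered),
    n_coding = if (is.null(classified)) NA else
      sum(region(classified) == "coding"),
    n_non_coding = if (is.null(classified)) NA else
      sum(region(classified) == "non-coding")
  )
  mpath <- file.path(outDir, paste0(prefix, ".run_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  written <- c(written, mpath)
  ok <- TRUE
  invisible(list(records = records, filtered = filtered,
                 classified = classified, extended = extended,
                 summary = summary, config = config, paths = written))
}

#' List bedMethyl files in a directory
#'
#' @param dir directory to scan.
#' @param pattern file-name pattern (default `*.bedmethyl`/`*.bed`).
#' @return character vector of paths.
#' @export
listBedMethylFiles <- function(dir, pattern = "\\.(bedmethyl|bed)$") {
  pm_assert(dir.exists(dir), sprintf("directory not found: %s", dir))
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  pm_assert(length(files) >= 1L,
            sprintf("no bedMethyl files matching '%s' in %s", pattern, dir))
  sort(files)
}

#' Pangenome-wide methylation integration
#'
#' Crosses per-genome methylation evidence with a Roary pangenome:
#' builds one gene-by-genome matrix per modification type, a
#' cross-genome count summary, and optionally core-gene clustered
#' heatmaps. Per-genome inputs are either cached extended annotations
#' (`extendedDir`, the fast path: classification is skipped) or
#' bedMethyl + GFF pairs (`bedmethylDir`/`gffDir`), which are processed
#' with [runMiner()] first. Genome identifiers are taken from the
#' Roary column headers and matched to input file stems; a mismatch is
#' a hard error listing both sets.
#'
#' @param gpa path to `gene_presence_absence.csv`.
#' @param outDir output directory.
#' @param extendedDir directory with `<genome>.extended_annotation.csv`
#'   (and, if available, `<genome>.statistics.csv`) files.
#' @param bedmethylDir,gffDir directories with `<genome>.bedmethyl` and
#'   `<genome>.gff` files, used when `extendedDir` is `NULL`.
#' @param mode matrix mode, `"binary"` or `"positions"`.
#' @param minCoverage,minRate filtering thresholds for the
#'   classification step (ignored on the cached path). The default
#'   `minCoverage = "auto"` derives the threshold from all input
#'   bedMethyl files.
#' @param presenceThreshold core-gene presence fraction for the heatmap
#'   (default 0.95).
#' @param prevalenceThreshold fraction for the methylated-in-most-genomes
#'   gene report (default 0.95).
#' @param heatmap render clustered heatmaps per modification type.
#' @param heatmapResolution `"compact"`, `"full"` or `"both"`.
#' @param imageFormat `"png"`, `"svg"` or `"pdf"`.
#' @return invisibly, a list with the [PanMethylome], the summary
#'   table, per-type prevalence tables, clustered matrices (when
#'   heatmaps were rendered) and written paths.
#' @export
runPanMiner <- function(gpa, outDir, extendedDir = NULL,
                        bedmethylDir = NULL, gffDir = NULL,
                        mode = c("binary", "positions"),
                        minCoverage = "auto", minRate = 90,
                        presenceThreshold = 0.95,
                        prevalenceThreshold = 0.95,
                        heatmap = FALSE,
                        heatmapResolution = c("compact", "full", "both"),
                        imageFormat = "png") {
  mode <- match.arg(mode)
  heatmapResolution <- match.arg(heatmapResolution)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  pan <- readGenePresenceAbsence(gpa)
  genomes <- genomeNames(pan)

  summaries <- list()
  if (!is.null(extendedDir)) {
    files <- list.files(extendedDir, pattern = "\\.extended_annotation\\.csv$",
                        full.names = TRUE)
    stems <- sub("\\.extended_annotation\\.csv$", "", basename(files))
    .checkGenomeSets(stems, genomes)
    pm_log(sprintf("reusing %d cached extended annotations; classification skipped",
                   length(files)))
    extended <- stats::setNames(lapply(files, readExtendedAnnotation), stems)
    for (g in stems) {
      sp <- file.path(extendedDir, paste0(g, ".statistics.csv"))
      if (file.exists(sp))
        summaries[[g]] <- as.data.frame(.readCommentedCsv(sp))
    }
    if (length(summaries) < length(stems)) {
      pm_log("statistics files missing for some genomes; cross-genome summary covers coding sites only",
             level = "WARN")
      summaries <- lapply(stats::setNames(stems, stems), function(g)
        .codingOnlySummary(extended[[g]]))
    }
  } else {
    pm_assert(!is.null(bedmethylDir) && !is.null(gffDir),
              "either extendedDir or both bedmethylDir and gffDir are required")
    beds <- listBedMethylFiles(bedmethylDir)
    stems <- sub("\\.[^.]*$", "", basename(beds))
    .checkGenomeSets(stems, genomes)
    if (identical(minCoverage, "auto")) {
      # shared threshold over all inputs, computed once
      minCoverage <- computeCoverageThreshold(beds)
    }
    minerDir <- file.path(outDir, "per_genome")
    extended <- list()
    for (i in seq_along(beds)) {
      g <- stems[i]
      gff <- .findAnnotationFor(gffDir, g)
      res <- runMiner(beds[i], minerDir, annotation = gff,
                      minCoverage = minCoverage,
                      minRate = minRate, prefix = g)
      extended[[g]] <- res$extended
      summaries[[g]] <- res$summary
    }
  }

  pm <- buildPanMethylome(extended, pan, mode = mode)
  paths <- writePanMatrices(pm, outDir)
  panSummary <- summarizePanCounts(summaries)
  spath <- file.path(outDir, "pan_methylome.summary.csv")
  data.table::fwrite(panSummary, spath)
  paths <- c(paths, spath)

  bin <- binarize(pm)
  prevalence <- list()
  for (t in modTypes(bin)) {
    prevalence[[t]] <- genePrevalence(bin, t, threshold = prevalenceThreshold)
    p <- file.path(outDir, sprintf("prevalent_genes.%s.csv", t))
    data.table::fwrite(prevalence[[t]], p)
    paths <- c(paths, p)
  }

  clustered <- list()
  if (heatmap) {
    core <- selectCoreGenes(bin, presenceThreshold)
    pm_log(sprintf("core-gene selection (>= %.0f%% presence): %d of %d genes kept",
                   100 * presenceThreshold, nrow(core), nrow(bin)))
    res <- if (heatmapResolution == "both") c("compact", "full") else
      heatmapResolution
    for (t in modTypes(core)) {
      cl <- clusterPanMatrix(core, t)
      clustered[[t]] <- cl
      for (r in res) {
        p <- file.path(outDir, sprintf("heatmap.%s.%s.%s", t, r, imageFormat))
        renderHeatmap(cl, p, resolution = r, format = imageFormat)
        paths <- c(paths, p)
      }
    }
  }
  manifest <- list(
    gpa = gpa, mode = mode, genomes = genomes,
    cached_extended = !is.null(extendedDir),
    presence_threshold = presenceThreshold,
    prevalence_threshold = prevalenceThreshold,
    heatmap = heatmap,
    n_genes = length(geneNames(pan)), mod_types = modTypes(pm)
  )
  mpath <- file.path(outDir, "pan_run_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(pan = pm, summary = panSummary, prevalence = prevalence,
                 clustered = clustered, paths = c(paths, mpath)))
}

.checkGenomeSets <- function(stems, genomes) {
  if (!setequal(stems, genomes))
    stop(sprintf(
      "genome identifiers of the inputs do not match the Roary columns.\n  Roary columns: %s\n  input stems:   %s",
      paste(sort(genomes), collapse = ", "),
      paste(sort(stems), collapse = ", ")), call. = FALSE)
}

.findAnnotationFor <- function(gffDir, stem) {
  for (ext in c(".gff", ".gff3", ".gb", ".gbk", ".gbff")) {
    p <- file.path(gffDir, paste0(stem, ext))
    if (file.exists(p)) return(p)
  }
  stop(sprintf("no annotation found for genome '%s' in %s", stem, gffDir),
       call. = FALSE)
}

# fallback cross-genome summary when only extended annotations are
# cached: non-coding counts are unknown
.codingOnlySummary <- function(ext) {
  fixed <- c("gene_id", "contig", "start0", "end0", "strand", "product")
  types <- setdiff(colnames(ext), fixed)
  coding <- vapply(types, function(t) sum(lengths(ext[[t]])), integer(1))
  out <- data.frame(mod_type = types, coding = as.integer(coding),
                    non_coding = NA_integer_, total = NA_integer_)
  rbind(out, data.frame(mod_type = "total", coding = sum(out$coding),
                        non_coding = NA_integer_, total = NA_integer_))
}
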