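## Heatmap rendering of clustered methylation matrices.
##
## Three-state colouring: yellow = methylated (1), blue = non-methylated
## (0), grey = gene absent from the genome (NA). Rendering never
## re-clusters: the cell ordering comes from the ClusteredPanMatrix.

.HEATMAP_COLS <- c(absent = "grey80", unmethylated = "#2C7BB6",
                   methylated = "#FFD700")

#' Render a clustered methylation heatmap
#'
#' Draws the gene-by-genome binary matrix in the clustered order. Two
#' resolutions: `"full"` labels every gene on the y-axis and its height
#' grows linearly with the gene count (for detailed study of individual
#' genes); `"compact"` omits gene labels at a fixed size (for overall
#' trends). Genome labels are always drawn. Alongside the image a
#' reproducibility sidecar CSV (`<out>.order.csv`) records the gene and
#' genome leaf orders.
#'
#' @param clustered a [ClusteredPanMatrix].
#' @param outPath output image path.
#' @param resolution `"compact"` or `"full"`.
#' @param format `"png"`, `"svg"` or `"pdf"`; `"auto"` (default) infers
#'   it from the file extension.
#' @param cellInches full-mode per-gene row height, inches (default
#'   0.12).
#' @return `outPath`, invisibly.
#' @export
renderHeatmap <- function(clustered, outPath,
                          resolution = c("compact", "full"),
                          format = "auto", cellInches = 0.12) {
  stopifnot(is(clustered, "ClusteredPanMatrix"))
  resolution <- match.arg(resolution)
  valid <- c("png", "svg", "pdf")
  if (identical(format, "auto")) format <- tolower(tools::file_ext(outPath))
  if (!format %in% valid)
    stop(sprintf("unknown image format '%s'; valid choices: %s",
                 format, paste(valid, collapse = ", ")), call. = FALSE)
  mat <- clustered@matrix[clustered@geneOrder, clustered@genomeOrder,
                          drop = FALSE]
  nr <- nrow(mat); nc <- ncol(mat)
  hin <- if (resolution == "full") max(4, nr * cellInches + 1.5) else 6
  win <- max(4, nc * 0.35 + 2)
  switch(format,
         png = grDevices::png(outPath, width = win, height = hin,
                              units = "in", res = if (resolution == "full") 150 else 72),
         svg = grDevices::svg(outPath, width = win, height = hin),
         pdf = grDevices::pdf(outPath, width = win, height = hin))
  on.exit(grDevices::dev.off(), add = TRUE)
  op <- graphics::par(mar = c(5, if (resolution == "full") 7 else 2, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  # draw with row 1 at the top; NA cells are left transparent by
  # image(), so paint the absent-state background first
  z <- t(mat[rev(seq_len(nr)), , drop = FALSE])
  graphics::plot(NA, xlim = c(0.5, nc + 0.5), ylim = c(0.5, nr + 0.5),
                 xlab = "", ylab = "", axes = FALSE, xaxs = "i", yaxs = "i",
                 main = sprintf("%s methylation, %d core genes x %d genomes",
                                clustered@modType, nr, nc))
  graphics::rect(0.5, 0.5, nc + 0.5, nr + 0.5,
                 col = .HEATMAP_COLS[["absent"]], border = NA)
  graphics::image(x = seq_len(nc), y = seq_len(nr), z = z,
                  zlim = c(0, 1),
                  col = c(.HEATMAP_COLS[["unmethylated"]],
                          .HEATMAP_COLS[["methylated"]]),
                  add = TRUE, useRaster = FALSE)
  graphics::axis(1, at = seq_len(nc), labels = colnames(mat), las = 2,
                 cex.axis = 0.8, tick = FALSE)
  if (resolution == "full")
    graphics::axis(2, at = rev(seq_len(nr)), labels = rownames(mat),
                   las = 2, cex.axis = 0.5, tick = FALSE)
  graphics::legend("topright", inset = c(0, -0.08), xpd = TRUE, horiz = TRUE,
                   legend = c("methylated", "non-methylated", "absent"),
                   fill = .HEATMAP_COLS[c("methylated", "unmethylated",
                                          "absent")],
                   bty = "n", cex = 0.7)
  writeClusterOrders(clustered, paste0(outPath, ".order.csv"))
  invisible(outPath)
}

#' Write the clustering order sidecar
#'
#' Records, for reproducibility, the dendrogram leaf order of both axes:
#' columns `axis` ("gene"/"genome"), `rank` (position in the rendered
#' heatmap) and `name`.
#'
#' @param clustered a [ClusteredPanMatrix].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeClusterOrders <- function(clustered, path) {
  stopifnot(is(clustered, "ClusteredPanMatrix"))
  df <- rbind(
    data.frame(axis = "gene",
               rank = seq_along(clustered@geneOrder),
               name = rownames(clustered@matrix)[clustered@geneOrder]),
    data.frame(axis = "genome",
               rank = seq_along(clustered@genomeOrder),
               name = colnames(clustered@matrix)[clustered@genomeOrder])
  )
  data.table::fwrite(df, path)
  invisible(path)
}
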