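## Core-gene selection, Hamming distances and deterministic UPGMA
## clustering of binary methylation profiles.

#' Restrict a binary pan-methylome to core genes
#'
#' Keeps genes present (non-absent cell) in at least
#' `presenceThreshold` of the genomes; row order is preserved. With the
#' default 0.95 this is the usual soft-core definition.
#'
#' @param x a binary-mode [PanMethylome].
#' @param presenceThreshold fraction in \[0, 1\].
#' @return the row-subsetted [PanMethylome].
#' @export
selectCoreGenes <- function(x, presenceThreshold = 0.95) {
  stopifnot(is(x, "PanMethylome"))
  pm_assert(is.numeric(presenceThreshold) &&
              presenceThreshold >= 0 && presenceThreshold <= 1,
            "presenceThreshold must lie in [0, 1]")
  pm_assert(panMode(x) == "binary",
            "selectCoreGenes needs a binary-mode matrix; run binarize() first")
  a <- SummarizedExperiment::assay(x, 1L)
  presence <- rowSums(!is.na(a)) / ncol(a)
  x[presence >= presenceThreshold, ]
}

#' Pairwise Hamming distances of binary profiles
#'
#' Distance between two binary vectors = (number of differing
#' positions) / (vector length), i.e. in \[0, 1\], symmetric, zero on
#' the diagonal. Absent cells (`NA`) are imputed as 0 — no methylation
#' evidence — for the distance computation only.
#'
#' @param mat binary matrix (possibly with `NA` absent markers).
#' @param axis `"genes"` for row-wise distances (the default),
#'   `"genomes"` for column-wise.
#' @return a [stats::dist] object.
#' @export
hammingDistances <- function(mat, axis = c("genes", "genomes")) {
  axis <- match.arg(axis)
  if (axis == "genomes") mat <- t(mat)
  mat[is.na(mat)] <- 0L
  stats::dist(mat, method = "manhattan") / ncol(mat)
}

# Deterministic UPGMA (average linkage) on a distance matrix.
#
# Agglomerative clustering where the distance between clusters is the
# unweighted mean of all cross-cluster pairwise distances. Ties are
# broken by the lowest-index pair (indices in original item order, the
# merged cluster inheriting the smaller index), so the result is a pure
# function of the distance matrix. Returns a stats::hclust object.
.upgma <- function(d, labels = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  pm_assert(n >= 2L, "need at least 2 items to cluster")
  size <- rep(1L, n)
  id <- -(1:n)            # hclust convention: negatives = singletons
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  diag(dm) <- Inf
  dm[lower.tri(dm)] <- Inf  # keep i < j only
  for (step in seq_len(n - 1L)) {
    m <- min(dm)
    # tolerance absorbs float noise from the incremental distance
    # updates so that genuinely tied pairs break ties by index
    cand <- which(dm <= m + 1e-10)
    # lowest-index pair first: smallest i, then smallest j
    ci <- ((cand - 1L) %% n) + 1L
    cj <- ((cand - 1L) %/% n) + 1L
    o <- order(ci, cj)[1L]
    i <- ci[o]; j <- cj[o]
    height[step] <- dm[i, j]
    # guard monotonicity against float noise in the updates
    if (step > 1L && height[step] < height[step - 1L])
      height[step] <- height[step - 1L]
    merge[step, ] <- sort(c(id[i], id[j]))
    # unweighted average linkage update, merged cluster kept at index i
    k <- setdiff(which(active), c(i, j))
    if (length(k)) {
      dik <- dm[cbind(pmin(i, k), pmax(i, k))]
      djk <- dm[cbind(pmin(j, k), pmax(j, k))]
      dnew <- (size[i] * dik + size[j] * djk) / (size[i] + size[j])
      dm[cbind(pmin(i, k), pmax(i, k))] <- dnew
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    dm[j, ] <- Inf
    dm[, j] <- Inf
    id[i] <- step
  }
  order <- .hclustLeafOrder(merge)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "average",
                 dist.method = "hamming", call = match.call()),
            class = "hclust")
}

# natural left-to-right leaf order of a merge tree
.hclustLeafOrder <- function(merge) {
  leaves <- function(k) {
    if (k < 0L) return(-k)
    c(leaves(merge[k, 1L]), leaves(merge[k, 2L]))
  }
  as.integer(leaves(nrow(merge)))
}

#' Cluster a core-gene methylation matrix
#'
#' Runs average-linkage (UPGMA) hierarchical clustering on the Hamming
#' distance matrices of both the genes (rows) and the genomes (columns)
#' of a binary methylation matrix. Deterministic: ties merge the
#' lowest-index pair first, and leaf orders follow the dendrogram's
#' natural left-to-right traversal (no optimal-leaf-ordering pass).
#' Dimensions with fewer than 2 elements are left unclustered (identity
#' order, `NULL` linkage) with a warning.
#'
#' @param x a binary-mode [PanMethylome] (typically after
#'   [selectCoreGenes()]) or a plain binary matrix.
#' @param type modification type to cluster when `x` is a
#'   [PanMethylome].
#' @return a [ClusteredPanMatrix].
#' @export
clusterPanMatrix <- function(x, type = NULL) {
  if (is(x, "PanMethylome")) {
    pm_assert(panMode(x) == "binary",
              "clustering needs a binary-mode matrix; run binarize() first")
    if (is.null(type)) type <- modTypes(x)[1L]
    mat <- SummarizedExperiment::assay(x, type)
  } else {
    mat <- as.matrix(x)
    if (is.null(type)) type <- "unknown"
  }
  if (is.null(rownames(mat))) rownames(mat) <- paste0("gene", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("genome", seq_len(ncol(mat)))
  geneLink <- NULL; genomeLink <- NULL
  geneOrd <- seq_len(nrow(mat)); genomeOrd <- seq_len(ncol(mat))
  if (nrow(mat) >= 2L) {
    geneLink <- .upgma(hammingDistances(mat, "genes"), labels = rownames(mat))
    geneOrd <- geneLink$order
  } else {
    pm_warn("fewer than 2 genes: gene axis left unclustered")
  }
  if (ncol(mat) >= 2L) {
    genomeLink <- .upgma(hammingDistances(mat, "genomes"),
                         labels = colnames(mat))
    genomeOrd <- genomeLink$order
  } else {
    pm_warn("fewer than 2 genomes: genome axis left unclustered")
  }
  new("ClusteredPanMatrix", matrix = mat, modType = as.character(type),
      geneOrder = as.integer(geneOrd), genomeOrder = as.integer(genomeOrd),
      geneLinkage = geneLink, genomeLinkage = genomeLink)
}
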