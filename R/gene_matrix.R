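#' Sparse cell-by-gene expression container
#'
#' `GeneMatrix` bundles a sparse integer count matrix (cells in rows, genes in
#' columns) with an optional log-normalized layer of identical dimensions.
#' It is the substrate of every pipeline stage.
#'
#' @param counts sparse or dense matrix of nonnegative integer counts with
#'   unique row (cell) and column (gene) names.
#' @param lognorm optional matrix of log-normalized values, same dimensions
#'   and dimnames as `counts`; usually produced by [lognormalize()].
#' @return an object of class `GeneMatrix`.
#' @export
gene_matrix <- function(counts, lognorm = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry cell (row) and gene (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate cell_id: ", rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate gene_id: ", colnames(counts)[duplicated(colnames(counts))][1])
  x <- counts@x
  if (length(x) && (min(x) < 0 || any(x != round(x)))) {
    bad <- which(x < 0 | x != round(x))[1]
    stop("counts must be nonnegative integers; offending value ", x[bad])
  }
  if (!is.null(lognorm)) {
    lognorm <- methods::as(methods::as(methods::as(lognorm, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    if (!identical(dim(lognorm), dim(counts)) ||
        !identical(dimnames(lognorm), dimnames(counts)))
      stop("lognorm layer must match counts dimensions and dimnames")
  }
  structure(list(counts = counts, lognorm = lognorm), class = "GeneMatrix")
}

#' @export
print.GeneMatrix <- function(x, ...) {
  cat(sprintf("GeneMatrix: %d cells x %d genes (%s lognorm layer)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$lognorm)) "no" else "with"))
  invisible(x)
}

#' @rdname gene_matrix
#' @param gm a `GeneMatrix`
#' @export
cell_ids <- function(gm) rownames(gm$counts)

#' @rdname gene_matrix
#' @export
gene_ids <- function(gm) colnames(gm$counts)

#' @rdname gene_matrix
#' @export
n_cells <- function(gm) nrow(gm$counts)

#' @rdname gene_matrix
#' @export
n_genes <- function(gm) ncol(gm$counts)

# Subset a GeneMatrix by cell ids (and optionally gene ids), keeping layers aligned.
subset_cells <- function(gm, cells, genes = NULL) {
  genes <- genes %||% gene_ids(gm)
  gene_matrix(gm$counts[cells, genes, drop = FALSE],
              if (!is.null(gm$lognorm)) gm$lognorm[cells, genes, drop = FALSE])
}

#' Read a sparse count matrix from Matrix Market files
#'
#' Reads the conventional triplet of files used for droplet data: a
#' coordinate MTX with genes in rows and cells in columns, a genes TSV
#' (gene ids in the first column) and a cells TSV (cell barcodes in the
#' first column; extra metadata columns are ignored here).
#'
#' @param mtx_path path to the Matrix Market file
#' @param genes_path path to the gene id TSV (no header)
#' @param cells_path path to the cell id TSV (no header)
#' @return a [gene_matrix()] holding counts only
#' @export
read_counts <- function(mtx_path, genes_path, cells_path) {
  for (f in c(mtx_path, genes_path, cells_path))
    if (!file.exists(f)) stop("file not found: ", f)
  m <- Matrix::readMM(mtx_path)
  genes <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.table(cells_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(genes))
    stop(sprintf("MTX declares %d genes but %s has %d rows",
                 nrow(m), genes_path, length(genes)))
  if (ncol(m) != length(cells))
    stop(sprintf("MTX declares %d cells but %s has %d rows",
                 ncol(m), cells_path, length(cells)))
  dimnames(m) <- list(genes, cells)
  gene_matrix(Matrix::t(m))
}

#' Write a GeneMatrix's counts as Matrix Market files
#'
#' Inverse of [read_counts()]: writes genes x cells coordinate integer MTX
#' plus gene and cell id TSVs. `read_counts(write_counts(gm))` round-trips
#' counts exactly.
#'
#' @inheritParams read_counts
#' @param gm a `GeneMatrix`
#' @return invisibly, `mtx_path`
#' @export
write_counts <- function(gm, mtx_path, genes_path, cells_path) {
  m <- Matrix::t(gm$counts)  # genes x cells on disk
  trip <- Matrix::summary(m)
  trip <- trip[order(trip$j, trip$i), , drop = FALSE]
  con <- file(mtx_path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(sprintf("%d %d %d", nrow(m), ncol(m), nrow(trip)), con)
  if (nrow(trip))
    writeLines(sprintf("%d %d %d", trip$i, trip$j, as.integer(trip$x)), con)
  utils::write.table(data.frame(rownames(m)), genes_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(colnames(m)), cells_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(mtx_path)
}

#' Log-normalize counts
#'
#' Scales each cell to `scale` total counts and applies `log1p`, the standard
#' library-size normalization of droplet toolkits. The sparsity pattern is
#' preserved (zeros stay zero).
#'
#' @param gm a `GeneMatrix` with counts
#' @param scale target library size (default 10,000)
#' @return the `GeneMatrix` with a `lognorm` layer added
#' @export
lognormalize <- function(gm, scale = 10000) {
  totals <- Matrix::rowSums(gm$counts)
  if (any(totals == 0))
    stop("cells with zero total counts present (e.g. ",
         cell_ids(gm)[which(totals == 0)[1]],
         "); run qc_filter before lognormalize")
  ln <- Matrix::Diagonal(x = scale / totals) %*% gm$counts
  ln@x <- log1p(ln@x)
  dimnames(ln) <- dimnames(gm$counts)
  gm$lognorm <- methods::as(ln, "CsparseMatrix")
  gm
}

#' Quality-control filter on UMI count and mitochondrial fraction
#'
#' Retains cells with at least `min_umi` UMIs and at most `max_mito`
#' mitochondrial fraction (both boundaries inclusive), subsetting the matrix
#' and the cell table consistently.
#'
#' @param gm a `GeneMatrix`
#' @param cells cell metadata data.frame with `cell_id`, `umi_count`,
#'   `mito_fraction` columns (one row per cell of `gm`)
#' @param min_umi minimum UMI count (default 1000)
#' @param max_mito maximum mitochondrial fraction (default 0.1)
#' @return list with elements `gm` and `cells`, filtered
#' @export
qc_filter <- function(gm, cells, min_umi = 1000, max_mito = 0.1) {
  stopifnot(all(c("cell_id", "umi_count", "mito_fraction") %in% names(cells)))
  cells <- cells[match(cell_ids(gm), cells$cell_id), , drop = FALSE]
  keep <- cells$umi_count >= min_umi & cells$mito_fraction <= max_mito
  n_removed <- sum(!keep)
  if (all(!keep)) warning("qc_filter removed every cell")
  message(sprintf("qc_filter: removed %d of %d cells", n_removed, length(keep)))
  kept_ids <- cells$cell_id[keep]
  list(gm = subset_cells(gm, kept_ids),
       cells = cells[keep, , drop = FALSE])
}

#' Select highly variable genes by standardized dispersion
#'
#' Ranks genes by the z-score of their log-normalized variance within 20
#' mean-expression bins and returns the top `n`. Deterministic; ties broken
#' by gene id. Genes with zero variance are never selected while `n` is
#' below the gene count.
#'
#' @param gm a `GeneMatrix` with a lognorm layer
#' @param n number of genes to return (default 2000)
#' @param n_bins number of mean bins for dispersion standardization
#' @return character vector of gene ids, ranked
#' @export
select_hvgs <- function(gm, n = 2000, n_bins = 20) {
  if (is.null(gm$lognorm)) stop("lognorm layer required; run lognormalize first")
  if (n > n_genes(gm)) {
    warning("n exceeds the number of genes; returning all genes")
    n <- n_genes(gm)
  }
  ln <- gm$lognorm
  nc <- nrow(ln)
  mu <- Matrix::colMeans(ln)
  ex2 <- Matrix::colSums(ln^2) / nc
  v <- pmax(ex2 - mu^2, 0) * nc / max(nc - 1, 1)
  brk <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(brk) > 2) cut(mu, breaks = brk, include.lowest = TRUE)
         else factor(rep(1L, length(mu)))
  z <- stats::ave(v, bin, FUN = function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  z[v == 0] <- -Inf
  ord <- order(-z, gene_ids(gm))
  gene_ids(gm)[ord][seq_len(n)]
}

#' PCA embedding of log-normalized expression
#'
#' Centers and unit-scales the selected genes, computes principal component
#' scores, and fixes each component's sign so the largest-magnitude loading
#' is positive (bit-reproducible given identical input ordering).
#'
#' @param gm a `GeneMatrix` with a lognorm layer
#' @param hvgs character vector of genes to use
#' @param n_pcs number of components (default 50)
#' @return cells x `n_pcs` score matrix; the rotation, centering and scaling
#'   used are attached as attributes for reuse by [build_reference()]
#' @export
pca_embed <- function(gm, hvgs, n_pcs = 50) {
  if (is.null(gm$lognorm)) stop("lognorm layer required")
  if (n_pcs > length(hvgs)) stop("n_pcs exceeds the number of genes supplied")
  x <- as.matrix(gm$lognorm[, hvgs, drop = FALSE])
  ctr <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  x <- scale(x, center = ctr, scale = sdv)
  sv <- svd(x, nu = n_pcs, nv = n_pcs)
  rot <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs, n_pcs)
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- cell_ids(gm)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  rownames(rot) <- hvgs
  attr(scores, "rotation") <- rot
  attr(scores, "center") <- ctr
  attr(scores, "scale") <- sdv
  attr(scores, "genes") <- hvgs
  scores
}

#' Flag clusters dominated by doublets
#'
#' Returns the clusters whose fraction of doublet-called cells is strictly
#' above `threshold` (the "above 70 percent" rule).
#'
#' @param cells cell metadata with a logical `is_doublet` column
#' @param cluster_labels cluster id per cell, aligned with `cells`
#' @param threshold doublet fraction above which a cluster is flagged
#' @return character vector of flagged cluster ids
#' @export
flag_doublet_clusters <- function(cells, cluster_labels, threshold = 0.7) {
  if (!"is_doublet" %in% names(cells))
    stop("cells must carry an is_doublet column (per-cell doublet calls)")
  if (length(cluster_labels) != nrow(cells))
    stop("cluster_labels must align with cells")
  if (anyNA(cluster_labels)) stop("unknown (NA) cluster label encountered")
  frac <- tapply(cells$is_doublet, cluster_labels, mean)
  sort(names(frac)[frac > threshold])
}

#' Flag clusters scoring high for multiple class signatures
#'
#' Scores each cluster for each cell-class signature as the mean (over the
#' cluster's cells) of the mean log-normalized expression of the signature
#' genes. Clusters exceeding `score_threshold` for two or more classes are
#' returned for manual review; they are not removed automatically.
#'
#' @param gm a `GeneMatrix` with a lognorm layer
#' @param cluster_labels cluster id per cell of `gm`
#' @param sigs named list mapping class name to a character vector of genes
#' @param score_threshold score above which a class is considered "high"
#' @return character vector of flagged cluster ids; the full cluster x class
#'   score matrix is attached as attribute `scores`
#' @export
flag_multisignature_clusters <- function(gm, cluster_labels, sigs, score_threshold) {
  if (length(sigs) == 0 || any(lengths(sigs) == 0))
    stop("signature sets must be non-empty")
  missing <- setdiff(unlist(sigs), gene_ids(gm))
  if (length(missing)) stop("signature genes absent from matrix: ", missing[1])
  if (is.null(gm$lognorm)) stop("lognorm layer required")
  per_cell <- vapply(sigs, function(g)
    Matrix::rowMeans(gm$lognorm[, g, drop = FALSE]), numeric(n_cells(gm)))
  clusters <- sort(unique(cluster_labels))
  scores <- do.call(rbind, lapply(clusters, function(cl)
    colMeans(per_cell[cluster_labels == cl, , drop = FALSE])))
  dimnames(scores) <- list(clusters, names(sigs))
  flagged <- clusters[rowSums(scores > score_threshold) >= 2]
  structure(flagged, scores = scores)
}
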