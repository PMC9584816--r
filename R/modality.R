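#' Per-cluster mean expression (pseudobulk)
#'
#' Mean log-normalized expression per cluster, with cell counts; clusters
#' with fewer than `min_cells` cells are flagged `omitted` and excluded from
#' downstream comparisons.
#'
#' @param gm a `GeneMatrix` with a lognorm layer
#' @param labels cluster label per cell of `gm`
#' @param min_cells omission threshold (default 10)
#' @return a `PseudobulkTable`: list with `mean` (clusters x genes),
#'   `n_cells` and `omitted` (named by cluster)
#' @export
pseudobulk <- function(gm, labels, min_cells = 10) {
  if (is.null(gm$lognorm)) stop("lognorm layer required")
  if (length(labels) != n_cells(gm)) stop("labels must align with cells")
  ids <- sort(unique(as.character(labels)))
  mean_mat <- t(vapply(ids, function(id)
    Matrix::colMeans(gm$lognorm[labels == id, , drop = FALSE]),
    numeric(n_genes(gm))))
  rownames(mean_mat) <- ids
  n <- vapply(ids, function(id) sum(labels == id), numeric(1))
  structure(list(mean = mean_mat, n_cells = n, omitted = n < min_cells),
            class = "PseudobulkTable")
}

#' Per-cluster expressing-cell fractions
#'
#' @inheritParams pseudobulk
#' @return clusters x genes matrix of detection fractions
#' @export
expression_fractions <- function(gm, labels) {
  ids <- sort(unique(as.character(labels)))
  out <- t(vapply(ids, function(id)
    Matrix::colMeans(gm$counts[labels == id, , drop = FALSE] > 0),
    numeric(n_genes(gm))))
  rownames(out) <- ids
  out
}

#' Expression filter for cross-modality comparison
#'
#' Keeps genes detected in more than `pct_min` of the cells of at least one
#' cluster OR with mean log-normalized expression above `mean_min` in at
#' least one cluster.
#'
#' @param pb a `PseudobulkTable`
#' @param pct_table matrix from [expression_fractions()] (same clusters)
#' @param pct_min detection-fraction cutoff (default 0.2)
#' @param mean_min mean-expression cutoff (default 0.2)
#' @return character vector of retained genes
#' @export
gene_filter <- function(pb, pct_table, pct_min = 0.2, mean_min = 0.2) {
  keep <- apply(pct_table, 2, function(x) any(x > pct_min)) |
    apply(pb$mean, 2, function(x) any(x > mean_min))
  colnames(pb$mean)[keep]
}

#' Per-gene cross-modality Pearson correlation
#'
#' Correlates each gene's cluster-mean expression between two modalities
#' over the clusters present (not omitted) in both. Zero-variance genes are
#' reported as missing, never imputed.
#'
#' @param pb_a,pb_b `PseudobulkTable`s of the two modalities
#' @param genes genes to correlate (e.g. from [gene_filter()])
#' @param class_map optional named character vector gene -> class; adds a
#'   per-class mean-correlation summary
#' @return data.frame `gene`, `r` (and `class` when mapped); per-class
#'   summary attached as attribute `class_summary`
#' @export
per_gene_correlation <- function(pb_a, pb_b, genes, class_map = NULL) {
  shared <- intersect(rownames(pb_a$mean)[!pb_a$omitted],
                      rownames(pb_b$mean)[!pb_b$omitted])
  if (length(shared) < 3) stop("fewer than 3 shared clusters")
  a <- pb_a$mean[shared, genes, drop = FALSE]
  b <- pb_b$mean[shared, genes, drop = FALSE]
  r <- vapply(seq_along(genes), function(j) {
    if (stats::sd(a[, j]) == 0 || stats::sd(b[, j]) == 0) NA_real_
    else stats::cor(a[, j], b[, j])
  }, numeric(1))
  out <- data.frame(gene = genes, r = r, stringsAsFactors = FALSE)
  if (!is.null(class_map)) {
    out$class <- unname(class_map[genes])
    cs <- tapply(out$r, out$class, mean, na.rm = TRUE)
    attr(out, "class_summary") <- cs
  }
  out
}

#' Per-cluster cross-modality correlation over marker genes
#'
#' For each cluster, selects its vs-all markers passing `spec_min` and whose
#' per-gene cross-modality correlation exceeds `r_min`, then correlates the
#' two modalities' cluster means across those genes. Clusters omitted in
#' either modality, or with fewer than 3 eligible markers, are reported
#' missing.
#'
#' @inheritParams per_gene_correlation
#' @param markers MarkerResult data.frame (vs-all rows used)
#' @param gene_r result of [per_gene_correlation()]
#' @param spec_min marker specificity cutoff (default 0.25)
#' @param r_min per-gene correlation cutoff (default 0.3)
#' @return data.frame `node_id`, `n_markers`, `r`
#' @export
per_cluster_correlation <- function(pb_a, pb_b, markers, gene_r,
                                    spec_min = 0.25, r_min = 0.3) {
  shared <- intersect(rownames(pb_a$mean)[!pb_a$omitted],
                      rownames(pb_b$mean)[!pb_b$omitted])
  good_genes <- gene_r$gene[!is.na(gene_r$r) & gene_r$r > r_min]
  rows <- lapply(shared, function(nd) {
    mk <- markers$gene[markers$node_id == nd & markers$reference == "all" &
                         markers$specificity > spec_min]
    mk <- intersect(intersect(unique(mk), good_genes), colnames(pb_a$mean))
    if (length(mk) < 3)
      return(data.frame(node_id = nd, n_markers = length(mk), r = NA_real_,
                        stringsAsFactors = FALSE))
    data.frame(node_id = nd, n_markers = length(mk),
               r = stats::cor(pb_a$mean[nd, mk], pb_b$mean[nd, mk]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
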