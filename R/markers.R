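#' Stratified (van Elteren) rank-sum test
#'
#' Combines per-stratum tie-corrected Wilcoxon rank-sum statistics with
#' "locally best" weights `1/(n_h + 1)`. With a single stratum it reduces
#' exactly to the tie-corrected normal-approximation Mann-Whitney test.
#'
#' @param values numeric vector of observations
#' @param group logical (or two-level factor) marking the "in" group
#' @param strata stratum id per observation (e.g. dataset of origin)
#' @return list with elements `z` and `p` (two-sided normal p value);
#'   strata lacking either group are skipped; all-tied data yield
#'   `z = 0, p = 1`
#' @export
van_elteren <- function(values, group, strata = rep(1L, length(values))) {
  if (is.factor(group) || is.character(group)) {
    grp_in <- if ("in" %in% group) "in" else sort(unique(as.character(group)))[1]
    group <- group == grp_in
  }
  stopifnot(length(values) == length(group), length(values) == length(strata))
  num <- 0; den <- 0; used <- 0L
  for (h in unique(strata)) {
    sel <- strata == h
    g <- group[sel]
    if (!any(g) || all(g)) next
    used <- used + 1L
    v <- values[sel]
    n_h <- length(v)
    n_in <- sum(g)
    n_out <- n_h - n_in
    r <- rank(v)
    W <- sum(r[g])
    E <- n_in * (n_h + 1) / 2
    t <- rle(sort(v))$lengths
    tie <- sum(t^3 - t)
    V <- n_in * n_out / 12 * ((n_h + 1) - tie / (n_h * (n_h - 1)))
    w <- 1 / (n_h + 1)
    num <- num + w * (W - E)
    den <- den + w^2 * V
  }
  if (used == 0L) stop("no stratum contains both groups")
  if (den <= 0) return(list(z = 0, p = 1))
  z <- num / sqrt(den)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Vectorized van Elteren over the columns of a dense matrix (cells x genes).
van_elteren_matrix <- function(x, group, strata) {
  num <- rep(0, ncol(x)); den <- rep(0, ncol(x)); used <- 0L
  for (h in unique(strata)) {
    sel <- strata == h
    g <- group[sel]
    if (!any(g) || all(g)) next
    used <- used + 1L
    xh <- x[sel, , drop = FALSE]
    n_h <- nrow(xh)
    n_in <- sum(g)
    n_out <- n_h - n_in
    r <- col_ranks(xh)
    W <- colSums(r[g, , drop = FALSE])
    E <- n_in * (n_h + 1) / 2
    tie <- col_tie_terms(xh)
    V <- n_in * n_out / 12 * ((n_h + 1) - tie / (n_h * (n_h - 1)))
    w <- 1 / (n_h + 1)
    num <- num + w * (W - E)
    den <- den + w^2 * V
  }
  if (used == 0L) stop("no stratum contains both groups")
  z <- ifelse(den > 0, num / sqrt(pmax(den, .Machine$double.xmin)), 0)
  p <- ifelse(den > 0, 2 * stats::pnorm(-abs(z)), 1)
  list(z = z, p = p)
}

#' Fold change and expressing-cell fractions for one gene
#'
#' @param gm a `GeneMatrix` with a lognorm layer
#' @param node_cells,ref_cells disjoint, non-empty cell id vectors
#' @param gene gene id
#' @return list with `avg_log2fc` (fold change of de-logged normalized means
#'   with pseudocount 1), `pct_in`, `pct_out` (fractions of cells with
#'   count > 0)
#' @export
expression_stats <- function(gm, node_cells, ref_cells, gene) {
  if (length(node_cells) == 0 || length(ref_cells) == 0)
    stop("empty cell set")
  if (length(intersect(node_cells, ref_cells)))
    stop("node and reference cells must be disjoint")
  cin <- gm$counts[node_cells, gene]
  cout <- gm$counts[ref_cells, gene]
  lin <- expm1(gm$lognorm[node_cells, gene])
  lout <- expm1(gm$lognorm[ref_cells, gene])
  list(avg_log2fc = log2((mean(lin) + 1) / (mean(lout) + 1)),
       pct_in = mean(cin > 0), pct_out = mean(cout > 0))
}

#' Marker specificity score
#'
#' `S = avg_log2fc * pct_in / max(pct_out, 1/n_ref)`: fold change weighted
#' by how exclusively the gene is detected in the cluster, with the
#' reference fraction floored at one cell to avoid division by zero.
#'
#' @param avg_log2fc average log2 fold change
#' @param pct_in,pct_out expressing-cell fractions (cluster, reference)
#' @param n_ref number of reference cells
#' @return specificity score(s); vectorized
#' @export
specificity <- function(avg_log2fc, pct_in, pct_out, n_ref) {
  stopifnot(all(n_ref > 0))
  avg_log2fc * pct_in / pmax(pct_out, 1 / n_ref)
}

# One marker comparison (in vs ref) over all eligible genes; internal engine
# shared by markers_for_tree and prune_tree.
compare_groups <- function(gm, in_cells, ref_cells, strata = NULL,
                           min_pct = 0.05, genes = NULL) {
  genes <- genes %||% gene_ids(gm)
  all_cells <- c(in_cells, ref_cells)
  grp <- c(rep(TRUE, length(in_cells)), rep(FALSE, length(ref_cells)))
  strata <- strata %||% stats::setNames(rep("all", length(all_cells)), all_cells)
  cts_in <- gm$counts[in_cells, genes, drop = FALSE]
  cts_out <- gm$counts[ref_cells, genes, drop = FALSE]
  pct_in <- Matrix::colMeans(cts_in > 0)
  pct_out <- Matrix::colMeans(cts_out > 0)
  test <- pct_in >= min_pct | pct_out >= min_pct
  genes <- genes[test]
  if (!length(genes)) {
    return(data.frame(gene = character(0), avg_log2fc = numeric(0),
                      pct_in = numeric(0), pct_out = numeric(0),
                      z = numeric(0), p = numeric(0), p_adj = numeric(0),
                      specificity = numeric(0)))
  }
  pct_in <- pct_in[test]; pct_out <- pct_out[test]
  e_in <- expm1(gm$lognorm[in_cells, genes, drop = FALSE])
  e_out <- expm1(gm$lognorm[ref_cells, genes, drop = FALSE])
  fc <- log2((Matrix::colMeans(e_in) + 1) / (Matrix::colMeans(e_out) + 1))
  x <- as.matrix(gm$lognorm[all_cells, genes, drop = FALSE])
  st <- unname(strata[all_cells])
  ve <- van_elteren_matrix(x, grp, st)
  p_adj <- pmin(1, ve$p * length(genes))
  data.frame(gene = genes, avg_log2fc = unname(fc),
             pct_in = unname(pct_in), pct_out = unname(pct_out),
             z = ve$z, p = ve$p, p_adj = p_adj,
             specificity = specificity(unname(fc), unname(pct_in),
                                       unname(pct_out), length(ref_cells)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Marker statistics for every node of a cluster tree
#'
#' For each node two comparisons are run: against all other cells at the
#' same level of the same top-level subtree ("all"), and against the cells
#' of its sibling nodes ("siblings"). p values are van Elteren (stratified
#' by `strata`, e.g. dataset of origin) with Bonferroni correction over the
#' genes tested per comparison. Nodes without siblings omit the siblings
#' comparison.
#'
#' @param gm a `GeneMatrix` with a lognorm layer covering the tree's cells
#' @param tree a `ClusterTree` (see [cluster_tree_from_labels()])
#' @param strata optional named vector cell_id -> stratum
#' @param min_pct minimum expressing fraction (in either group) for a gene
#'   to be tested
#' @param genes optional gene subset
#' @return data.frame of `MarkerResult` rows: gene, node_id, reference,
#'   avg_log2fc, pct_in, pct_out, z, p, p_adj, specificity
#' @export
markers_for_tree <- function(gm, tree, strata = NULL, min_pct = 0.05,
                             genes = NULL) {
  out <- list()
  for (lvl in seq_along(tree$levels)) {
    labels <- tree$levels[[lvl]]
    top <- tree$levels[[1]]
    for (id in sort(unique(labels))) {
      node_cells <- tree$cell_ids[labels == id]
      subtree <- top[match(node_cells[1], tree$cell_ids)]
      ref_all <- tree$cell_ids[labels != id & top == subtree]
      if (lvl == 1) ref_all <- tree$cell_ids[labels != id]
      if (length(ref_all)) {
        res <- compare_groups(gm, node_cells, ref_all, strata, min_pct, genes)
        if (nrow(res)) {
          res$node_id <- id; res$reference <- "all"
          out[[length(out) + 1]] <- res
        }
      }
      parent <- tree$nodes$parent[tree$nodes$id == id]
      sibs <- tree$nodes$id[tree$nodes$parent == parent & tree$nodes$id != id]
      if (length(sibs)) {
        ref_sib <- tree$cell_ids[labels %in% sibs]
        res <- compare_groups(gm, node_cells, ref_sib, strata, min_pct, genes)
        if (nrow(res)) {
          res$node_id <- id; res$reference <- "siblings"
          out[[length(out) + 1]] <- res
        }
      }
    }
  }
  res <- do.call(rbind, out)
  res[, c("gene", "node_id", "reference", "avg_log2fc", "pct_in", "pct_out",
          "z", "p", "p_adj", "specificity")]
}
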