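#' Filter an immediate-early-gene panel by detection frequency
#'
#' Keeps IEGs detected (count > 0) in more than `min_cells` and at most
#' `max_cells` cells, discarding silent and near-ubiquitous genes whose
#' condition response cannot be measured reliably.
#'
#' @param gm a `GeneMatrix`
#' @param ieg_list candidate IEG ids
#' @param min_cells lower detection bound (exclusive); values in (0,1) are
#'   interpreted as fractions of the cell count
#' @param max_cells upper detection bound (inclusive); fractions allowed as
#'   for `min_cells`
#' @return character vector of retained IEGs
#' @export
filter_ieg_panel <- function(gm, ieg_list, min_cells, max_cells) {
  ieg_list <- intersect(ieg_list, gene_ids(gm))
  if (min_cells > 0 && min_cells < 1) min_cells <- min_cells * n_cells(gm)
  if (max_cells > 0 && max_cells <= 1) max_cells <- max_cells * n_cells(gm)
  n_expr <- Matrix::colSums(gm$counts[, ieg_list, drop = FALSE] > 0)
  panel <- ieg_list[n_expr > min_cells & n_expr <= max_cells]
  if (!length(panel)) stop("no IEG passes the detection filter")
  sort(panel)
}

# Rank-sum DE of fasted vs fed within one cell set, over the given genes.
# Returns per-gene p (unadjusted) and log2FC (fasted over fed).
condition_de <- function(gm, node_cells, condition, genes) {
  fasted <- node_cells[condition == "fasted"]
  fed <- node_cells[condition == "fed"]
  x <- as.matrix(gm$lognorm[c(fasted, fed), genes, drop = FALSE])
  grp <- c(rep(TRUE, length(fasted)), rep(FALSE, length(fed)))
  ve <- van_elteren_matrix(x, grp, rep("all", length(grp)))
  e_in <- expm1(gm$lognorm[fasted, genes, drop = FALSE])
  e_out <- expm1(gm$lognorm[fed, genes, drop = FALSE])
  fc <- log2((Matrix::colMeans(e_in) + 1) / (Matrix::colMeans(e_out) + 1))
  data.frame(gene = genes, p = ve$p, log2FC = unname(fc),
             stringsAsFactors = FALSE)
}

# Genes detected in >= min_frac of a node's cells in either condition.
expressed_in_either <- function(gm, node_cells, condition, genes, min_frac = 0.1) {
  keep <- logical(length(genes))
  for (cond in c("fed", "fasted")) {
    cc <- node_cells[condition == cond]
    if (!length(cc)) next
    keep <- keep | Matrix::colMeans(gm$counts[cc, genes, drop = FALSE] > 0) >= min_frac
  }
  genes[keep]
}

#' Condition-dependent activation of one cluster
#'
#' Counts the panel IEGs detected in at least 10 percent of the node's cells
#' in either condition, tests each (two-sided rank-sum, fasted vs fed) and
#' reports how many are significantly up-regulated after Bonferroni
#' correction.
#'
#' @param gm a `GeneMatrix` with lognorm layer
#' @param cells cell metadata with `cell_id` and `condition`
#' @param node_cells cell ids of the cluster
#' @param panel IEG panel from [filter_ieg_panel()]
#' @param alpha significance level (default 0.05)
#' @param n_tests Bonferroni denominator; defaults to the genes tested in
#'   this call, but a run-level wrapper should pass the total across
#'   clusters (the convention used here)
#' @param min_frac detection fraction defining "expressed" (default 0.1)
#' @return one-row data.frame (`ActivationRow`): node sizes and IEG counts,
#'   or `NULL` with a warning if a condition is absent
#' @export
cluster_activation <- function(gm, cells, node_cells, panel, alpha = 0.05,
                               n_tests = NULL, min_frac = 0.1) {
  condition <- cells$condition[match(node_cells, cells$cell_id)]
  if (length(unique(condition)) < 2) {
    warning("node lacks one condition; skipped")
    return(NULL)
  }
  expressed <- expressed_in_either(gm, node_cells, condition, panel, min_frac)
  if (!length(expressed)) {
    return(data.frame(n_iegs_expressed = 0L, n_iegs_up = 0L, pct_up = NA_real_,
                      mean_log2fc = NA_real_, n_cells = length(node_cells)))
  }
  de <- condition_de(gm, node_cells, condition, expressed)
  n_tests <- n_tests %||% nrow(de)
  p_adj <- pmin(1, de$p * n_tests)
  up <- p_adj < alpha & de$log2FC > 0
  data.frame(n_iegs_expressed = length(expressed), n_iegs_up = sum(up),
             pct_up = sum(up) / length(expressed),
             mean_log2fc = mean(de$log2FC), n_cells = length(node_cells))
}

#' Activation table over all clusters of a level
#'
#' Runs [cluster_activation()] for every node, using the total number of
#' tests across the run as the shared Bonferroni denominator.
#'
#' @inheritParams cluster_activation
#' @param labels cluster label per cell of `gm`
#' @return data.frame with one row per scorable node
#' @export
activation_table <- function(gm, cells, labels, panel, alpha = 0.05,
                             min_frac = 0.1) {
  ids <- sort(unique(labels))
  expr_sets <- lapply(ids, function(id) {
    node_cells <- cell_ids(gm)[labels == id]
    condition <- cells$condition[match(node_cells, cells$cell_id)]
    if (length(unique(condition)) < 2) return(character(0))
    expressed_in_either(gm, node_cells, condition, panel, min_frac)
  })
  total_tests <- sum(lengths(expr_sets))
  rows <- lapply(seq_along(ids), function(i) {
    node_cells <- cell_ids(gm)[labels == ids[i]]
    row <- suppressWarnings(
      cluster_activation(gm, cells, node_cells, panel, alpha,
                         n_tests = max(total_tests, 1), min_frac = min_frac))
    if (is.null(row)) return(NULL)
    cbind(data.frame(node_id = ids[i], stringsAsFactors = FALSE), row)
  })
  do.call(rbind, rows)
}

#' Per-cluster differential expression between conditions
#'
#' Rank-sum test of fasted vs fed for every gene detected in at least 10
#' percent of the node's cells in either condition, Bonferroni-corrected.
#'
#' @inheritParams cluster_activation
#' @param min_cells minimum cells per condition (default 3)
#' @return data.frame (`gene`, `p`, `p_adj`, `log2FC`, `significant`) or
#'   `NULL` if the node is too small
#' @export
cluster_deg <- function(gm, cells, node_cells, alpha = 0.05, n_tests = NULL,
                        min_frac = 0.1, min_cells = 3) {
  condition <- cells$condition[match(node_cells, cells$cell_id)]
  if (sum(condition == "fasted") < min_cells || sum(condition == "fed") < min_cells) {
    warning("fewer than ", min_cells, " cells in a condition; skipped")
    return(NULL)
  }
  genes <- expressed_in_either(gm, node_cells, condition, gene_ids(gm), min_frac)
  if (!length(genes)) return(NULL)
  de <- condition_de(gm, node_cells, condition, genes)
  de$p_adj <- pmin(1, de$p * (n_tests %||% nrow(de)))
  de$significant <- de$p_adj < alpha
  de
}

#' Cross-cluster overlap of differentially expressed genes
#'
#' For every gene, the fraction of clusters where it is significant; genes
#' exceeding each threshold fraction are reported (e.g. the globally
#' regulated program shared by at least 20 or 50 percent of clusters).
#'
#' @param deg_tables named list of [cluster_deg()] tables (one per node)
#' @param fractions threshold fractions (default 0.2 and 0.5)
#' @return list with `gene_fraction` (named numeric) and one gene vector per
#'   threshold (named `frac_<x>`)
#' @export
deg_overlap <- function(deg_tables, fractions = c(0.2, 0.5)) {
  deg_tables <- Filter(Negate(is.null), deg_tables)
  if (length(deg_tables) < 2) stop("need DEG tables from at least 2 nodes")
  sig_genes <- lapply(deg_tables, function(d) d$gene[d$significant])
  all_genes <- unique(unlist(sig_genes))
  frac <- vapply(all_genes, function(g)
    mean(vapply(sig_genes, function(s) g %in% s, logical(1))), numeric(1))
  out <- list(gene_fraction = frac)
  for (f in fractions)
    out[[paste0("frac_", f)]] <- sort(names(frac)[frac >= f])
  out
}
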