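#' Shared nearest-neighbour graph
#'
#' Builds the k-NN graph on a low-dimensional embedding and reweights edges
#' by the Jaccard overlap of the two cells' neighbour sets (self included).
#' Edges below the prune cutoff are dropped.
#'
#' @param embedding cells x dims matrix with row names
#' @param k neighbours (default 25)
#' @param prune minimum Jaccard weight to keep an edge (default 1/15)
#' @return an undirected weighted [igraph::graph] whose vertex names are the
#'   cell ids
#' @export
snn_graph <- function(embedding, k = 25, prune = 1 / 15) {
  n <- nrow(embedding)
  if (k >= n) stop("k must be smaller than the number of cells")
  D <- as.matrix(stats::dist(embedding))
  nn <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k), j = as.vector(t(nn)),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  jac <- shared
  jac@x <- jac@x / (2 * k - jac@x)
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac * (jac >= prune))
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
  igraph::V(g)$name <- rownames(embedding)
  g
}

#' Multiresolution community detection
#'
#' Runs a pluggable community partitioner over a ladder of resolutions with
#' fixed seeds. The default partitioner is Leiden (modularity objective) as
#' implemented in igraph.
#'
#' @param graph weighted graph from [snn_graph()]
#' @param resolutions numeric vector of resolution parameters
#' @param community_fn optional function `(graph, resolution, seed)`
#'   returning one cluster label per vertex
#' @param seed RNG seed used for every partitioner call
#' @return list of `ClusterLevel`s (resolution, labels, n_clusters), sorted
#'   by ascending resolution
#' @export
multires_cluster <- function(graph, resolutions, community_fn = NULL, seed = 42) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  community_fn <- community_fn %||% function(g, res, seed) {
    set.seed(seed)
    igraph::cluster_leiden(g, objective_function = "modularity",
                           weights = igraph::E(g)$weight,
                           resolution = res, n_iterations = 5)$membership
  }
  lapply(sort(resolutions), function(res) {
    labels <- as.character(community_fn(graph, res, seed))
    names(labels) <- igraph::V(graph)$name
    list(resolution = res, labels = labels,
         n_clusters = length(unique(labels)))
  })
}

#' Greedy granularity ladder selection
#'
#' Starting from the cluster count of the last base level, repeatedly picks
#' the clustering whose cluster count is nearest to `factor` times the
#' previous selection (among strictly finer clusterings), aiming to roughly
#' multiply granularity by `factor` per level.
#'
#' @param levels list of `ClusterLevel`s from [multires_cluster()]
#' @param base_levels list of per-cell label vectors fixed by the analyst
#'   (e.g. a manual neuron / non-neuron split); only their cluster counts
#'   seed the greedy rule
#' @param factor target granularity multiplier (default 3)
#' @return the selected subset of `levels`, coarse to fine
#' @export
select_levels <- function(levels, base_levels = list(), factor = 3) {
  levels <- levels[order(vapply(levels, `[[`, numeric(1), "n_clusters"))]
  counts <- vapply(levels, `[[`, numeric(1), "n_clusters")
  prev <- if (length(base_levels))
    length(unique(base_levels[[length(base_levels)]])) else 0
  picked <- integer(0)
  repeat {
    cand <- setdiff(which(counts > prev), picked)
    if (!length(cand)) break
    target <- if (prev == 0) min(counts[cand]) else factor * prev
    best <- cand[order(abs(counts[cand] - target), counts[cand])][1]
    picked <- c(picked, best)
    prev <- counts[best]
  }
  levels[picked]
}

# Parent of each fine cluster: the coarse cluster holding the plurality of
# its cells; ties toward the larger coarse cluster, then lexicographic.
plurality_parent <- function(coarse, fine) {
  coarse_sizes <- table(coarse)
  vapply(sort(unique(fine)), function(f) {
    tab <- table(coarse[fine == f])
    cand <- names(tab)[tab == max(tab)]
    if (length(cand) > 1) {
      sz <- coarse_sizes[cand]
      cand <- cand[sz == max(sz)]
      cand <- sort(cand)[1]
    }
    cand
  }, character(1))
}

#' Reconcile a clustering ladder into a strictly nested tree
#'
#' Built-in fallback reconciler with the same contract as published
#' multiresolution tree methods: each finer cluster is attached to the
#' coarser cluster holding the plurality of its cells, then every cell's
#' coarser labels are rewritten from its finest label's ancestor chain so
#' levels are strictly nested. Node ids become `C<levelsize>-<k>` with `k`
#' assigned by descending node size.
#'
#' @param levels list of per-cell label vectors (or `ClusterLevel`s),
#'   coarse to fine, all over the same cells
#' @param cell_ids cell identifiers (taken from label names if absent)
#' @return a `ClusterTree`: list with `cell_ids`, `levels` (per-level node
#'   id per cell) and `nodes` (data.frame id, level, parent)
#' @export
reconcile_tree <- function(levels, cell_ids = NULL) {
  labs <- lapply(levels, function(l) if (is.list(l)) l$labels else l)
  if (length(labs) < 2) stop("need at least 2 levels")
  cell_ids <- cell_ids %||% names(labs[[1]]) %||%
    sprintf("cell%05d", seq_along(labs[[1]]))
  L <- length(labs)
  parent_maps <- vector("list", L)
  for (l in 2:L) parent_maps[[l]] <- plurality_parent(labs[[l - 1]], labs[[l]])
  nested <- vector("list", L)
  nested[[L]] <- as.character(labs[[L]])
  for (l in (L - 1):1)
    nested[[l]] <- unname(parent_maps[[l + 1]][nested[[l + 1]]])
  # rename to C<levelsize>-<k>, parents follow
  new_labels <- vector("list", L)
  rename <- vector("list", L)
  sizes_seen <- integer(0)
  for (l in seq_len(L)) {
    tab <- sort(table(nested[[l]]), decreasing = TRUE)
    ord <- names(tab)[order(-as.vector(tab), names(tab))]
    # "C<levelsize>-<k>"; disambiguated when two levels share a size
    stem <- if (length(ord) %in% sizes_seen)
      sprintf("C%d.%d", length(ord), l) else sprintf("C%d", length(ord))
    sizes_seen <- c(sizes_seen, length(ord))
    rename[[l]] <- stats::setNames(paste0(stem, "-", seq_along(ord)), ord)
    new_labels[[l]] <- unname(rename[[l]][nested[[l]]])
    names(new_labels[[l]]) <- cell_ids
  }
  nodes <- list()
  for (l in seq_len(L)) {
    ids <- unique(new_labels[[l]])
    parent <- if (l == 1) rep("root", length(ids)) else
      vapply(ids, function(id)
        new_labels[[l - 1]][which(new_labels[[l]] == id)[1]], character(1))
    nodes[[l]] <- data.frame(id = ids, level = l, parent = unname(parent),
                             stringsAsFactors = FALSE)
  }
  structure(list(cell_ids = cell_ids, levels = new_labels,
                 nodes = do.call(rbind, nodes)), class = "ClusterTree")
}

#' Build a ClusterTree from already-nested labels
#'
#' Keeps the supplied node labels (useful for planted ground-truth trees);
#' errors if the levels are not strictly nested.
#'
#' @inheritParams reconcile_tree
#' @return a `ClusterTree`
#' @export
cluster_tree_from_labels <- function(levels, cell_ids = NULL) {
  labs <- lapply(levels, function(l) if (is.list(l)) l$labels else as.character(l))
  cell_ids <- cell_ids %||% names(labs[[1]]) %||%
    sprintf("cell%05d", seq_along(labs[[1]]))
  L <- length(labs)
  nodes <- list()
  for (l in seq_len(L)) {
    ids <- sort(unique(labs[[l]]))
    if (l == 1) {
      parent <- rep("root", length(ids))
    } else {
      parent <- vapply(ids, function(id) {
        p <- unique(labs[[l - 1]][labs[[l]] == id])
        if (length(p) != 1) stop("levels are not strictly nested at node ", id)
        p
      }, character(1))
    }
    names(labs[[l]]) <- cell_ids
    nodes[[l]] <- data.frame(id = ids, level = l, parent = unname(parent),
                             stringsAsFactors = FALSE)
  }
  nd <- do.call(rbind, nodes)
  if (anyDuplicated(nd$id)) stop("node ids must be unique across levels")
  structure(list(cell_ids = cell_ids, levels = labs, nodes = nd),
            class = "ClusterTree")
}

#' @export
print.ClusterTree <- function(x, ...) {
  cat(sprintf("ClusterTree: %d cells, %d levels (%s clusters)\n",
              length(x$cell_ids), length(x$levels),
              paste(vapply(x$levels, function(l) length(unique(l)), numeric(1)),
                    collapse = "/")))
  invisible(x)
}

#' Cells belonging to a tree node
#' @param tree a `ClusterTree`
#' @param id node id
#' @return character vector of cell ids
#' @export
tree_node_cells <- function(tree, id) {
  lvl <- tree$nodes$level[tree$nodes$id == id]
  if (!length(lvl)) stop("unknown node: ", id)
  tree$cell_ids[tree$levels[[lvl]] == id]
}

#' Children of a tree node
#' @inheritParams tree_node_cells
#' @return character vector of child node ids
#' @export
tree_children <- function(tree, id) {
  tree$nodes$id[tree$nodes$parent == id]
}

#' Merge sibling clusters lacking discriminative markers
#'
#' Any node with fewer than `min_markers` genes at vs-sibling specificity
#' above `min_spec` (and adjusted p below `p_adj_max`) is merged into its
#' most similar sibling (highest Spearman correlation of mean log-normalized
#' profiles). Markers are recomputed for the affected sibling set and the
#' process iterates to a fixpoint; node ids are then reassigned by final
#' level sizes.
#'
#' @param tree a `ClusterTree`
#' @param gm a `GeneMatrix` (lognorm layer) covering the tree's cells
#' @param strata optional named vector cell_id -> stratum for the tests
#' @param min_markers minimum number of discriminative genes (default 10)
#' @param min_spec specificity cutoff defining "relevant" (default 1)
#' @param p_adj_max adjusted-p cutoff for relevance (default 0.05)
#' @param min_pct minimum expressing fraction for a gene to be tested
#' @param fixpoint iterate until stable (default) or single pass
#' @return the pruned `ClusterTree` (nodes renamed `C<levelsize>-<k>`)
#' @export
prune_tree <- function(tree, gm, strata = NULL, min_markers = 10,
                       min_spec = 1, p_adj_max = 0.05, min_pct = 0.05,
                       fixpoint = TRUE) {
  labs <- lapply(tree$levels, function(l) stats::setNames(as.character(l), tree$cell_ids))
  cell_ids <- tree$cell_ids
  n_disc <- function(in_cells, sib_cells) {
    res <- compare_groups(gm, in_cells, sib_cells, strata, min_pct)
    sum(res$specificity > min_spec & res$p_adj < p_adj_max)
  }
  mean_profile <- function(cells) Matrix::colMeans(gm$lognorm[cells, , drop = FALSE])
  repeat {
    changed <- FALSE
    for (l in seq_along(labs)) {
      parent_of <- if (l == 1) {
        stats::setNames(rep("root", length(unique(labs[[l]]))), sort(unique(labs[[l]])))
      } else {
        ids <- sort(unique(labs[[l]]))
        stats::setNames(vapply(ids, function(id)
          labs[[l - 1]][which(labs[[l]] == id)[1]], character(1)), ids)
      }
      for (p in unique(parent_of)) {
        kids <- names(parent_of)[parent_of == p]
        if (length(kids) < 2) next
        counts <- vapply(kids, function(k) {
          in_cells <- cell_ids[labs[[l]] == k]
          sib_cells <- cell_ids[labs[[l]] %in% setdiff(kids, k)]
          n_disc(in_cells, sib_cells)
        }, numeric(1))
        sizes <- vapply(kids, function(k) sum(labs[[l]] == k), numeric(1))
        weak <- kids[counts < min_markers]
        if (!length(weak)) next
        victim <- weak[order(counts[weak], sizes[weak], weak)][1]
        others <- setdiff(kids, victim)
        vp <- mean_profile(cell_ids[labs[[l]] == victim])
        rho <- vapply(others, function(o)
          stats::cor(vp, mean_profile(cell_ids[labs[[l]] == o]),
                     method = "spearman"), numeric(1))
        rho[!is.finite(rho)] <- -Inf
        target <- others[order(-rho, others)][1]
        labs[[l]][labs[[l]] == victim] <- target
        changed <- TRUE
        break
      }
      if (changed) break
    }
    if (!changed || !fixpoint) break
  }
  if (length(labs) >= 2) reconcile_tree(labs, cell_ids)
  else cluster_tree_from_labels(labs, cell_ids)
}

#' One-call tree construction
#'
#' Convenience wrapper chaining [snn_graph()], [multires_cluster()],
#' [select_levels()] and [reconcile_tree()].
#'
#' @inheritParams snn_graph
#' @inheritParams multires_cluster
#' @inheritParams select_levels
#' @return a `ClusterTree`
#' @export
build_cluster_tree <- function(embedding, resolutions, base_levels = list(),
                               k = 25, factor = 3, community_fn = NULL,
                               seed = 42) {
  g <- snn_graph(embedding, k = k)
  levels <- multires_cluster(g, resolutions, community_fn, seed)
  sel <- select_levels(levels, base_levels, factor)
  base <- lapply(base_levels, function(b) stats::setNames(as.character(b),
                                                          rownames(embedding)))
  reconcile_tree(c(base, lapply(sel, `[[`, "labels")),
                 cell_ids = rownames(embedding))
}
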