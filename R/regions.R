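#' Rank probes within a voxel by ISH energy
#'
#' Rank 1 is the highest energy; ties receive midranks; probes with energy
#' at or below `eps` (not expressed) are excluded.
#'
#' @param energies named numeric vector of probe energies for one voxel
#' @param eps expression threshold (default 0)
#' @return named rank vector over the expressed probes
#' @export
voxel_probe_ranks <- function(energies, eps = 0) {
  expressed <- energies > eps
  if (!any(expressed)) {
    warning("voxel has no expressed probe; skipped")
    return(stats::setNames(numeric(0), character(0)))
  }
  rank(-energies[expressed], ties.method = "average")
}

#' Normalized median marker rank in a voxel
#'
#' Median rank of the expressed marker probes divided by the number of
#' expressed probes in the voxel: values near 0 mean the markers sit at the
#' top of the voxel's expression ranking.
#'
#' @inheritParams voxel_probe_ranks
#' @param marker_probes character vector of marker probe ids
#' @return scalar in \[0, 1\], or `NA` if no marker probe is expressed
#' @export
voxel_enrichment <- function(energies, marker_probes, eps = 0) {
  r <- voxel_probe_ranks(energies, eps)
  mk <- intersect(marker_probes, names(r))
  if (!length(mk)) return(NA_real_)
  stats::median(r[mk]) / length(r)
}

#' Region enrichment score for a marker set
#'
#' Computes the normalized median marker rank for every voxel of the region,
#' keeps the `top_n` most enriched voxels (smallest normalized ranks),
#' averages them and returns 1 minus the average, so 1 means the markers
#' dominate the top of the region's voxels.
#'
#' @param marker_probes marker probe ids (typically specificity > 4 markers)
#' @param grid a `VoxelGrid` from [simulate_voxels()] or equivalent
#' @param region region label
#' @param top_n voxels aggregated (default 4; fewer if the region is small)
#' @param literal_top_rank if `TRUE`, aggregate the voxels with the largest
#'   normalized median ranks instead (the literal reading of "highest
#'   median ranks"); default `FALSE` keeps the enrichment reading under
#'   which scores near 1 mean top-ranked markers
#' @return scalar score in \[0, 1\], or `NA` if no voxel is scorable
#' @export
region_score <- function(marker_probes, grid, region, top_n = 4,
                         literal_top_rank = FALSE) {
  rows <- which(grid$region == region)
  if (!length(rows)) stop("unknown region: ", region)
  enr <- vapply(rows, function(i) voxel_enrichment(grid$energy[i, ], marker_probes),
                numeric(1))
  enr <- enr[!is.na(enr)]
  if (!length(enr)) return(NA_real_)
  enr <- sort(enr, decreasing = literal_top_rank)
  1 - mean(enr[seq_len(min(top_n, length(enr)))])
}

#' Predict spatial regions for tree nodes
#'
#' Scores every (node, region) pair by rank enrichment of the node's
#' high-specificity markers in the region's voxels, optionally down-scales
#' scores by the fraction of the node's cells originating from datasets
#' compatible with the region, and assigns the top region when its adjusted
#' score exceeds `threshold`.
#'
#' @param tree a `ClusterTree`
#' @param markers MarkerResult data.frame (vs-all reference rows are used)
#' @param grid a `VoxelGrid`
#' @param nodes node ids to score (default: all nodes of the finest level)
#' @param spec_min marker specificity cutoff (default 4)
#' @param top_n voxels aggregated per region (default 4)
#' @param threshold assignment threshold on the adjusted score (default 0.8)
#' @param cells optional cell metadata (`cell_id`, `dataset_id`) for
#'   origin down-scaling
#' @param origin_priors optional named list dataset_id -> character vector
#'   of regions the dataset could have sampled
#' @param origin_floor floor of the down-scaling factor (default 0.25)
#' @param top_k regions retained per node in the score table (default 10)
#' @return list with `scores` (node, region, raw_score, adjusted_score,
#'   rank; top `top_k` per node) and `assignment` (named vector node ->
#'   region or `NA`)
#' @export
predict_regions <- function(tree, markers, grid, nodes = NULL, spec_min = 4,
                            top_n = 4, threshold = 0.8, cells = NULL,
                            origin_priors = NULL, origin_floor = 0.25,
                            top_k = 10) {
  finest <- length(tree$levels)
  nodes <- nodes %||% sort(unique(tree$levels[[finest]]))
  regions <- unique(grid$region)
  all_rows <- list()
  assignment <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  for (nd in nodes) {
    mk <- markers$gene[markers$node_id == nd & markers$reference == "all" &
                         markers$specificity > spec_min]
    mk <- intersect(unique(mk), colnames(grid$energy))
    if (!length(mk)) {
      warning("no marker with specificity > ", spec_min, " for node ", nd,
              "; score 0")
      raw <- stats::setNames(rep(0, length(regions)), regions)
    } else {
      raw <- vapply(regions, function(r) {
        s <- region_score(mk, grid, r, top_n)
        if (is.na(s)) 0 else s
      }, numeric(1))
    }
    adj <- raw
    if (!is.null(origin_priors) && !is.null(cells)) {
      node_cells <- tree_node_cells(tree, nd)
      ds <- cells$dataset_id[match(node_cells, cells$cell_id)]
      for (r in regions) {
        compat <- vapply(ds, function(d)
          is.null(origin_priors[[d]]) || r %in% origin_priors[[d]], logical(1))
        adj[r] <- raw[r] * max(mean(compat), origin_floor)
      }
    }
    ord <- order(-adj, regions)
    keep <- ord[seq_len(min(top_k, length(regions)))]
    all_rows[[nd]] <- data.frame(node_id = nd, region = regions[keep],
                                 raw_score = unname(raw[keep]),
                                 adjusted_score = unname(adj[keep]),
                                 rank = seq_along(keep),
                                 n_markers_used = length(mk),
                                 stringsAsFactors = FALSE)
    if (adj[ord[1]] > threshold) assignment[nd] <- regions[ord[1]]
  }
  list(scores = do.call(rbind, c(all_rows, list(make.row.names = FALSE))),
       assignment = assignment)
}
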