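#' Configuration for the synthetic atlas generator
#'
#' Bundles every knob of the seeded generators. The defaults describe a
#' small but realistic droplet-style experiment: a balanced 3-level cell-type
#' hierarchy (27 leaf types), ~100 cells per leaf, 1,000 genes with a
#' heavy-tailed baseline so most genes are sparsely detected, 10 markers per
#' tree node at 8-fold (log2FC 3) enrichment, and negative-binomial counts
#' with moderate overdispersion.
#'
#' @param seed integer seed; mandatory, drives every generator deterministically
#' @param n_genes number of genes
#' @param tree_depth depth of the balanced cell-type tree (levels below root)
#' @param branching children per node
#' @param cells_per_leaf singlet cells per leaf type
#' @param markers_per_node unique marker genes planted per node (all levels)
#' @param marker_log2fc log2 fold boost of a marker within its node's cells
#' @param nb_dispersion negative-binomial size parameter (variance
#'   `mu + mu^2/size`)
#' @param library_size_meanlog,library_size_sdlog lognormal library-size model
#' @param n_batches number of batches; batch effects are per-gene
#'   multiplicative factors `2^N(0, batch_sd)`
#' @param samples_per_batch samples (replicates) per batch; samples within a
#'   batch share the batch effect and differ only by sampling noise
#' @param batch_sd standard deviation of per-gene log2 batch effects
#' @param doublet_rate fraction of extra doublet cells appended
#' @param condition_effect named numeric vector: tree node id -> log2FC
#'   applied to immediate-early genes in that node's fasted cells
#' @param n_iegs number of genes designated as immediate-early genes
#' @param modality_distortion named numeric vector: gene class ->
#'   multiplicative mean distortion for [simulate_second_modality()]
#' @param n_regions number of brain regions for the voxel grid (default: one
#'   per leaf, one-to-one)
#' @param voxels_per_region voxels simulated per region
#' @param voxel_noise_sd lognormal noise sd of voxel probe energies
#' @param marker_energy_boost multiplicative energy boost of a region's
#'   home-leaf markers
#' @return a validated list of class `SimConfig`
#' @export
sim_config <- function(seed,
                       n_genes = 1000,
                       tree_depth = 3,
                       branching = 3,
                       cells_per_leaf = 100,
                       markers_per_node = 10,
                       marker_log2fc = 3,
                       nb_dispersion = 5,
                       library_size_meanlog = log(2500),
                       library_size_sdlog = 0.3,
                       n_batches = 1,
                       samples_per_batch = 2,
                       batch_sd = 0,
                       doublet_rate = 0,
                       condition_effect = numeric(0),
                       n_iegs = 20,
                       modality_distortion = NULL,
                       n_regions = NULL,
                       voxels_per_region = 10,
                       voxel_noise_sd = 0.5,
                       marker_energy_boost = 20) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$doublet_rate < 0 || cfg$doublet_rate > 1)
    stop("doublet_rate must be in [0,1]")
  if (cfg$branching^cfg$tree_depth < 2)
    stop("tree must have at least 2 leaves")
  n_leaves <- cfg$branching^cfg$tree_depth
  if (is.null(cfg$n_regions)) cfg$n_regions <- n_leaves
  if (cfg$n_regions > n_leaves) stop("n_regions exceeds the leaf count")
  structure(cfg, class = "SimConfig")
}

#' Simulate a balanced cell-type hierarchy with planted markers
#'
#' Builds a balanced tree (`branching^tree_depth` leaves), assigns each node
#' below the root a disjoint set of `markers_per_node` genes, designates a
#' pool of immediate-early genes from the non-marker genes, and draws a
#' heavy-tailed baseline expression level per gene. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()]
#' @return list with `nodes` (data.frame: id, parent, level, is_leaf),
#'   `markers` (named list node -> genes), `ieg_genes`, `gene_ids`,
#'   `leaves`, `base_expr`
#' @export
simulate_hierarchy <- function(cfg) {
  with_seed(cfg$seed, {
    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    nodes <- data.frame(id = character(0), parent = character(0),
                        level = integer(0), stringsAsFactors = FALSE)
    prev <- "root"
    for (lvl in seq_len(cfg$tree_depth)) {
      ids <- unlist(lapply(prev, function(p) {
        if (p == "root") paste0("n", seq_len(cfg$branching))
        else paste0(p, ".", seq_len(cfg$branching))
      }))
      parents <- rep(prev, each = cfg$branching)
      nodes <- rbind(nodes, data.frame(id = ids, parent = parents,
                                       level = lvl, stringsAsFactors = FALSE))
      prev <- ids
    }
    nodes$is_leaf <- nodes$level == cfg$tree_depth
    needed <- nrow(nodes) * cfg$markers_per_node + cfg$n_iegs
    if (needed > cfg$n_genes)
      stop(sprintf("need %d marker/IEG genes but only %d genes configured",
                   needed, cfg$n_genes))
    pool <- sample(genes)
    markers <- list()
    k <- 0
    for (id in nodes$id) {
      markers[[id]] <- sort(pool[(k + 1):(k + cfg$markers_per_node)])
      k <- k + cfg$markers_per_node
    }
    ieg_genes <- sort(pool[(k + 1):(k + cfg$n_iegs)])
    base_expr <- stats::setNames(stats::rlnorm(cfg$n_genes, 0, 2), genes)
    # marker genes are drawn as low-baseline genes: cell-type markers are not
    # broadly expressed housekeeping genes, and this keeps detection fractions
    # informative (high in the node, low outside)
    mk_genes <- unlist(markers)
    base_expr[mk_genes] <- stats::rlnorm(length(mk_genes), -0.5, 0.75)
    list(nodes = nodes, markers = markers, ieg_genes = ieg_genes,
         gene_ids = genes, leaves = nodes$id[nodes$is_leaf],
         base_expr = base_expr)
  })
}

# Ancestor path of a tree node (self first, then up to level 1).
sim_ancestors <- function(tree, id) {
  path <- id
  nd <- tree$nodes
  while (TRUE) {
    p <- nd$parent[nd$id == path[length(path)]]
    if (length(p) == 0 || p == "root") break
    path <- c(path, p)
  }
  path
}

# Leaves under a node (the node itself if it is a leaf).
sim_leaves_under <- function(tree, id) {
  tree$leaves[vapply(tree$leaves, function(l) id %in% sim_ancestors(tree, l),
                     logical(1))]
}

#' Simulate negative-binomial counts over the planted hierarchy
#'
#' Each cell's expected expression is the per-gene baseline times `2^log2FC`
#' marker boosts along its leaf's ancestor path, times a per-batch
#' multiplicative effect `2^N(0, batch_sd)`, rescaled to a lognormal library
#' size; counts are drawn NB(mu, size = `nb_dispersion`). Doublets are
#' appended by summing two random singlets' counts and halving (rounded).
#' A fasting-like condition multiplies immediate-early-gene means by
#' `2^condition_effect[node]` in fasted cells of the designated nodes.
#'
#' @param cfg a [sim_config()]
#' @param tree result of [simulate_hierarchy()]
#' @return list with `gm` (a [gene_matrix()]), `cells` (cell metadata
#'   data.frame) and `truth` (ground truth: per-cell labels, markers, IEGs)
#' @export
simulate_counts <- function(cfg, tree) {
  with_seed(cfg$seed + 1L, {
    genes <- tree$gene_ids
    leaves <- tree$leaves
    n <- cfg$cells_per_leaf * length(leaves)
    leaf <- rep(leaves, each = cfg$cells_per_leaf)
    batches <- paste0("batch", seq_len(cfg$n_batches))
    samples <- paste0("s", sprintf("%02d", seq_len(cfg$n_batches * cfg$samples_per_batch)))
    sample_batch <- stats::setNames(rep(batches, each = cfg$samples_per_batch), samples)
    smp <- sample(samples, n, replace = TRUE)
    batch <- unname(sample_batch[smp])
    condition <- sample(c("fed", "fasted"), n, replace = TRUE)

    # per-leaf marker factors
    leaf_factor <- matrix(1, cfg$n_genes, length(leaves),
                          dimnames = list(genes, leaves))
    for (id in tree$nodes$id) {
      under <- sim_leaves_under(tree, id)
      leaf_factor[tree$markers[[id]], under] <-
        leaf_factor[tree$markers[[id]], under] * 2^cfg$marker_log2fc
    }
    batch_factor <- matrix(2^stats::rnorm(cfg$n_genes * cfg$n_batches, 0, cfg$batch_sd),
                           cfg$n_genes, cfg$n_batches,
                           dimnames = list(genes, batches))
    activated_leaves <- lapply(names(cfg$condition_effect), function(id)
      sim_leaves_under(tree, id))
    names(activated_leaves) <- names(cfg$condition_effect)

    libsize <- stats::rlnorm(n, cfg$library_size_meanlog, cfg$library_size_sdlog)
    counts <- matrix(0L, n, cfg$n_genes, dimnames = list(NULL, genes))
    combo <- interaction(leaf, batch, condition, drop = TRUE)
    for (cb in levels(combo)) {
      idx <- which(combo == cb)
      lf <- leaf[idx[1]]
      rel <- tree$base_expr * leaf_factor[, lf] * batch_factor[, batch[idx[1]]]
      if (condition[idx[1]] == "fasted") {
        for (nid in names(activated_leaves)) {
          if (lf %in% activated_leaves[[nid]])
            rel[tree$ieg_genes] <- rel[tree$ieg_genes] * 2^cfg$condition_effect[[nid]]
        }
      }
      p <- rel / sum(rel)
      mu <- outer(libsize[idx], p)
      counts[idx, ] <- stats::rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion)
    }
    cell_id <- sprintf("cell%05d", seq_len(n))
    is_doublet <- rep(FALSE, n)

    n_dbl <- round(cfg$doublet_rate * n)
    if (n_dbl > 0) {
      a <- sample(n, n_dbl, replace = TRUE)
      b <- sample(n, n_dbl, replace = TRUE)
      dbl <- matrix(as.integer(round((counts[a, , drop = FALSE] +
                                      counts[b, , drop = FALSE]) / 2)),
                    n_dbl, cfg$n_genes, dimnames = list(NULL, genes))
      counts <- rbind(counts, dbl)
      cell_id <- c(cell_id, sprintf("dbl%05d", seq_len(n_dbl)))
      leaf <- c(leaf, leaf[a])
      smp <- c(smp, smp[a])
      batch <- c(batch, batch[a])
      condition <- c(condition, condition[a])
      is_doublet <- c(is_doublet, rep(TRUE, n_dbl))
    }
    rownames(counts) <- cell_id

    anc <- do.call(rbind, lapply(leaf, function(l) rev(sim_ancestors(tree, l))))
    colnames(anc) <- paste0("level", seq_len(cfg$tree_depth))
    gm <- gene_matrix(Matrix::Matrix(counts, sparse = TRUE))
    cells <- data.frame(cell_id = cell_id, sample_id = smp,
                        dataset_id = "ds1", batch_id = batch,
                        condition = condition, class_label = anc[, 1],
                        umi_count = as.integer(rowSums(counts)),
                        mito_fraction = stats::runif(length(cell_id), 0, 0.05),
                        doublet_score = NA_real_, stringsAsFactors = FALSE)
    truth <- list(
      cell_info = cbind(data.frame(cell_id = cell_id, leaf = leaf,
                                   stringsAsFactors = FALSE),
                        as.data.frame(anc, stringsAsFactors = FALSE),
                        data.frame(sample_id = smp, batch_id = batch,
                                   condition = condition, is_doublet = is_doublet,
                                   stringsAsFactors = FALSE)),
      markers = tree$markers, ieg_genes = tree$ieg_genes,
      sample_batch = sample_batch)
    rownames(truth$cell_info) <- NULL
    list(gm = gm, cells = cells, truth = truth)
  })
}

#' Simulate an ISH voxel grid with region-specific marker energies
#'
#' Maps each region one-to-one onto a leaf of the planted tree and simulates
#' `voxels_per_region` voxels per region. Probe energies are lognormal noise
#' around 1; in a region's voxels, its home leaf's marker probes are boosted
#' (strictly descending within the marker set) so that with zero noise they
#' occupy exactly ranks 1..m.
#'
#' @param cfg a [sim_config()]
#' @param tree result of [simulate_hierarchy()]
#' @return a `VoxelGrid`: list with `energy` (voxels x probes matrix),
#'   `voxel_id`, `region` (per voxel) and `region_leaf` (named map)
#' @export
simulate_voxels <- function(cfg, tree) {
  with_seed(cfg$seed + 2L, {
    regions <- sprintf("R%02d", seq_len(cfg$n_regions))
    region_leaf <- stats::setNames(tree$leaves[seq_len(cfg$n_regions)], regions)
    n_vox <- cfg$n_regions * cfg$voxels_per_region
    region <- rep(regions, each = cfg$voxels_per_region)
    voxel_id <- sprintf("vox%04d", seq_len(n_vox))
    m <- cfg$markers_per_node
    energy <- matrix(exp(stats::rnorm(n_vox * cfg$n_genes, 0, cfg$voxel_noise_sd)),
                     n_vox, cfg$n_genes,
                     dimnames = list(voxel_id, tree$gene_ids))
    for (r in regions) {
      mk <- tree$markers[[region_leaf[[r]]]]
      rows <- which(region == r)
      boost <- cfg$marker_energy_boost * (1 + (m:1) / m)
      energy[rows, mk] <- energy[rows, mk] *
        matrix(boost, length(rows), m, byrow = TRUE)
    }
    structure(list(energy = energy, voxel_id = voxel_id, region = region,
                   region_leaf = region_leaf), class = "VoxelGrid")
  })
}

#' Simulate a bulk IP-vs-input differential-expression table
#'
#' Emulates a ribosome-capture (bacTRAP-style) contrast: the IP profile is a
#' weighted mixture of target-node expected expression, the input is the
#' global leaf mean. Log2 fold changes carry replicate noise and adjusted
#' p values come from a 3-vs-3 Welch t-test on simulated log-expression
#' (Benjamini-Hochberg corrected).
#'
#' @param cfg a [sim_config()]
#' @param tree result of [simulate_hierarchy()]
#' @param target_nodes character vector of tree node ids
#' @param weights mixture weights over `target_nodes`, summing to 1
#'   (default uniform)
#' @param noise_sd replicate log2-expression noise sd; at 0 the table is the
#'   exact expectation with p_adj 0 for any non-zero fold change
#' @return data.frame with columns `gene`, `log2FC`, `p_adj`
#' @export
simulate_bulk_signature <- function(cfg, tree, target_nodes, weights = NULL,
                                    noise_sd = 0.15) {
  weights <- weights %||% rep(1 / length(target_nodes), length(target_nodes))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  with_seed(cfg$seed + 3L, {
    leaf_profile <- vapply(tree$leaves, function(l) {
      f <- rep(1, cfg$n_genes)
      names(f) <- tree$gene_ids
      for (id in sim_ancestors(tree, l))
        f[tree$markers[[id]]] <- f[tree$markers[[id]]] * 2^cfg$marker_log2fc
      prof <- tree$base_expr * f
      prof / sum(prof) * 1e4
    }, numeric(cfg$n_genes))
    node_profile <- function(id) {
      under <- sim_leaves_under(tree, id)
      rowMeans(leaf_profile[, under, drop = FALSE])
    }
    target <- Reduce(`+`, Map(function(id, w) w * node_profile(id),
                              target_nodes, weights))
    global <- rowMeans(leaf_profile)
    eps <- 0.1
    true_lfc <- log2((target + eps) / (global + eps))
    if (noise_sd == 0) {
      out <- data.frame(gene = tree$gene_ids, log2FC = unname(true_lfc),
                        p_adj = ifelse(abs(true_lfc) > 1e-12, 0, 1),
                        stringsAsFactors = FALSE)
      return(out)
    }
    n_rep <- 3
    ip <- matrix(log2(target + eps), cfg$n_genes, n_rep) +
      stats::rnorm(cfg$n_genes * n_rep, 0, noise_sd)
    inp <- matrix(log2(global + eps), cfg$n_genes, n_rep) +
      stats::rnorm(cfg$n_genes * n_rep, 0, noise_sd)
    m1 <- rowMeans(ip); m2 <- rowMeans(inp)
    v1 <- apply(ip, 1, stats::var); v2 <- apply(inp, 1, stats::var)
    se2 <- v1 / n_rep + v2 / n_rep
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n_rep)^2 / (n_rep - 1) + (v2 / n_rep)^2 / (n_rep - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    p[!is.finite(p)] <- 1
    data.frame(gene = tree$gene_ids, log2FC = unname(m1 - m2),
               p_adj = stats::p.adjust(p, "BH"), stringsAsFactors = FALSE)
  })
}

#' Simulate a second modality with class-specific mean distortion
#'
#' Resamples the count matrix with per-gene-class multiplicative mean
#' distortion (`cfg$modality_distortion`), emulating single-nucleus versus
#' single-cell divergence: distortion-free classes correlate near 1 across
#' modalities, distorted classes less. Only the nonzero support is
#' resampled; structural zeros stay zero.
#'
#' @param cfg a [sim_config()]
#' @param gm the first-modality [gene_matrix()]
#' @param gene_class_map named character vector gene -> class covering all genes
#' @param resample draw NB noise around the distorted means (default TRUE);
#'   `FALSE` returns the rounded distorted means (noise-free limit)
#' @return a [gene_matrix()] of the second modality (counts only)
#' @export
simulate_second_modality <- function(cfg, gm, gene_class_map, resample = TRUE) {
  if (!all(gene_ids(gm) %in% names(gene_class_map)))
    stop("gene_class_map must cover all genes")
  fac <- rep(1, n_genes(gm))
  names(fac) <- gene_ids(gm)
  if (!is.null(cfg$modality_distortion)) {
    cls <- gene_class_map[gene_ids(gm)]
    hit <- cls %in% names(cfg$modality_distortion)
    fac[hit] <- unlist(cfg$modality_distortion)[cls[hit]]
  }
  with_seed(cfg$seed + 4L, {
    counts <- gm$counts
    j <- rep(seq_len(ncol(counts)), diff(counts@p))
    mu <- counts@x * fac[j]
    newx <- if (resample)
      stats::rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion)
    else round(mu)
    out <- counts
    out@x <- as.double(newx)
    gene_matrix(Matrix::drop0(out))
  })
}

#' Write a full synthetic scenario to disk
#'
#' Convenience wrapper: simulates the hierarchy, counts, voxel grid and one
#' single-leaf bulk signature, and writes MTX/TSV/CSV files plus a
#' `ground_truth.json` into `dir`.
#'
#' @param cfg a [sim_config()]
#' @param dir output directory (created if needed)
#' @return invisibly, the list of generated objects
#' @export
write_simulation <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_hierarchy(cfg)
  sim <- simulate_counts(cfg, tree)
  grid <- simulate_voxels(cfg, tree)
  sig <- simulate_bulk_signature(cfg, tree, target_nodes = tree$leaves[1])
  write_counts(sim$gm, file.path(dir, "counts.mtx"),
               file.path(dir, "genes.tsv"), file.path(dir, "cells.tsv"))
  utils::write.table(sim$cells, file.path(dir, "cell_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  vox <- data.frame(voxel_id = grid$voxel_id, region = grid$region,
                    grid$energy, check.names = FALSE)
  utils::write.csv(vox, file.path(dir, "voxels.csv"), row.names = FALSE)
  utils::write.csv(sig, file.path(dir, "bulk_signature.csv"), row.names = FALSE)
  jsonlite::write_json(list(markers = tree$markers,
                            ieg_genes = tree$ieg_genes,
                            cell_info = sim$truth$cell_info),
                       file.path(dir, "ground_truth.json"))
  invisible(list(tree = tree, sim = sim, grid = grid, signature = sig))
}
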