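test_that("simulate_hierarchy builds the balanced tree deterministically", {
  cfg <- sim_config(seed = 5)
  tree <- simulate_hierarchy(cfg)
  expect_equal(nrow(tree$nodes), 3 + 9 + 27)
  expect_length(tree$leaves, 27)
  all_markers <- unlist(tree$markers)
  expect_false(anyDuplicated(all_markers) > 0)  # pairwise disjoint
  tree2 <- simulate_hierarchy(sim_config(seed = 5))
  expect_identical(tree, tree2)
  expect_error(simulate_hierarchy(sim_config(seed = 1, n_genes = 50)),
               "marker/IEG genes")
})

test_that("simulate_counts honours doublet_rate and batch_sd = 0", {
  cfg <- sim_config(seed = 9, tree_depth = 2, cells_per_leaf = 40,
                    n_genes = 300, n_batches = 2)
  tree <- simulate_hierarchy(cfg)
  sim <- simulate_counts(cfg, tree)
  expect_false(any(sim$truth$cell_info$is_doublet))
  # determinism: identical rerun
  sim2 <- simulate_counts(cfg, tree)
  expect_identical(as.matrix(sim$gm$counts), as.matrix(sim2$gm$counts))
  # batch_sd = 0: per-gene means near-identical across batches (sampling only)
  b <- sim$truth$cell_info$batch_id
  m1 <- Matrix::colMeans(sim$gm$counts[b == "batch1", ])
  m2 <- Matrix::colMeans(sim$gm$counts[b == "batch2", ])
  expect_gt(stats::cor(m1, m2), 0.99)

  cfg_d <- sim_config(seed = 9, tree_depth = 2, cells_per_leaf = 40,
                      n_genes = 300, doublet_rate = 0.1)
  sim_d <- simulate_counts(cfg_d, simulate_hierarchy(cfg_d))
  expect_equal(sum(sim_d$truth$cell_info$is_doublet), round(0.1 * 9 * 40))
})

test_that("planted markers separate detection fractions in their nodes", {
  fx <- default_fixture()
  gaps <- unlist(lapply(fx$tree$leaves, function(lf) {
    inc <- fx$ci$leaf == lf
    vapply(fx$tree$markers[[lf]], function(g) {
      mean(fx$gm$counts[inc, g] > 0) - mean(fx$gm$counts[!inc, g] > 0)
    }, numeric(1))
  }))
  expect_gt(mean(gaps), 0.4)
})

test_that("ground truth labels are self-consistent (strictly nested)", {
  fx <- default_fixture()
  expect_s3_class(fx$ptree, "ClusterTree")  # construction enforces nesting
  expect_identical(fx$ptree$levels[[3]], stats::setNames(fx$ci$level3, fx$ci$cell_id))
})

test_that("simulate_voxels plants top-ranked markers in home regions", {
  cfg0 <- sim_config(seed = 2, tree_depth = 1, branching = 3, n_genes = 100,
                     voxel_noise_sd = 0)
  tree0 <- simulate_hierarchy(cfg0)
  grid0 <- simulate_voxels(cfg0, tree0)
  home <- grid0$region_leaf[["R01"]]
  r <- voxel_probe_ranks(grid0$energy[1, ])
  expect_setequal(names(sort(r)[1:10]), tree0$markers[[home]])
  expect_equal(unname(sort(r[tree0$markers[[home]]])), 1:10)
  expect_identical(grid0, simulate_voxels(cfg0, tree0))
})

test_that("non-marker probe ranks are uniform across regions", {
  cfg <- sim_config(seed = 21, tree_depth = 1, branching = 2, n_genes = 100,
                    n_regions = 2, voxels_per_region = 250)
  tree <- simulate_hierarchy(cfg)
  grid <- simulate_voxels(cfg, tree)
  nonmarker <- setdiff(tree$gene_ids, unlist(tree$markers))[1]
  rk <- vapply(seq_along(grid$voxel_id), function(i)
    voxel_probe_ranks(grid$energy[i, ])[[nonmarker]], numeric(1))
  ks <- suppressWarnings(stats::ks.test(rk[grid$region == "R01"],
                                        rk[grid$region == "R02"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("bulk signatures recover planted mixtures", {
  cfg <- sim_config(seed = 4)
  tree <- simulate_hierarchy(cfg)
  m <- cfg$markers_per_node
  # noise-free single leaf: its own markers head the list
  de0 <- simulate_bulk_signature(cfg, tree, tree$leaves[5], noise_sd = 0)
  top <- de0$gene[order(-de0$log2FC)][1:m]
  expect_setequal(top, tree$markers[[tree$leaves[5]]])
  # 50/50 mixture: both leaves' markers in the top 2m of the signature
  de2 <- simulate_bulk_signature(cfg, tree, tree$leaves[c(1, 14)],
                                 weights = c(0.5, 0.5))
  sig <- build_signature(de2)
  top <- sig[1:(2 * m + 5)]
  expect_gte(mean(tree$markers[[tree$leaves[1]]] %in% top), 0.7)
  expect_gte(mean(tree$markers[[tree$leaves[14]]] %in% top), 0.7)
  # uniform weights over all leaves: significance at type-I level only
  de_null <- simulate_bulk_signature(cfg, tree, tree$leaves,
                                     weights = rep(1 / 27, 27))
  expect_lt(mean(de_null$p_adj < 0.05), 0.07)
})

test_that("second modality reproduces counts exactly in the noise-free limit", {
  fx <- default_fixture()
  cfg <- fx$cfg
  gm2 <- simulate_second_modality(cfg, fx$gm,
                                  stats::setNames(rep("x", n_genes(fx$gm)),
                                                  gene_ids(fx$gm)),
                                  resample = FALSE)
  expect_identical(as.matrix(gm2$counts), as.matrix(fx$gm$counts))
})

test_that("write_simulation produces a loadable on-disk bundle", {
  d <- withr::local_tempdir()
  cfg <- sim_config(seed = 3, tree_depth = 1, branching = 2, n_genes = 60,
                    cells_per_leaf = 15, n_iegs = 5)
  write_simulation(cfg, d)
  gm <- read_counts(file.path(d, "counts.mtx"), file.path(d, "genes.tsv"),
                    file.path(d, "cells.tsv"))
  expect_equal(n_cells(gm), 30)
  gt <- jsonlite::read_json(file.path(d, "ground_truth.json"))
  expect_length(gt$markers, 2)
})
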