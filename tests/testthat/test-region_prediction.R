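test_that("voxel_probe_ranks ranks high energy first with midrank ties", {
  expect_equal(unname(voxel_probe_ranks(c(a = 5, b = 3, c = 1))), c(1, 2, 3))
  expect_equal(unname(voxel_probe_ranks(c(a = 5, b = 5, c = 1))), c(1.5, 1.5, 3))
  expect_equal(unname(voxel_probe_ranks(c(a = 0, b = 2))), 1)
  expect_warning(r <- voxel_probe_ranks(c(a = 0, b = 0)), "no expressed")
  expect_length(r, 0)
})

test_that("voxel_enrichment normalizes the median marker rank", {
  # 10 markers at ranks 1..10 of 100 expressed probes -> 0.055
  e <- c(seq(200, 191), stats::runif(90, 1, 100))
  names(e) <- sprintf("p%03d", 1:100)
  expect_equal(voxel_enrichment(e, sprintf("p%03d", 1:10)), 5.5 / 100)
  # single marker at the very bottom -> 1.0
  e2 <- c(bottom = 0.001, stats::setNames(stats::runif(9, 1, 2), paste0("q", 1:9)))
  expect_equal(voxel_enrichment(e2, "bottom"), 1)
  # 1 marker at rank 1 of 2 probes -> 0.5
  expect_equal(voxel_enrichment(c(m = 5, o = 1), "m"), 0.5)
  expect_true(is.na(voxel_enrichment(c(m = 0, o = 1), "m")))
})

test_that("region_score is rank-based and antitone in marker ranks", {
  set.seed(5)
  energy <- matrix(stats::runif(8 * 50, 1, 2), 8, 50,
                   dimnames = list(paste0("v", 1:8), sprintf("p%02d", 1:50)))
  energy[1:4, 1:5] <- matrix(rep(c(10, 9.8, 9.6, 9.4, 9.2), each = 4), 4, 5)
  grid <- structure(list(energy = energy, voxel_id = paste0("v", 1:8),
                         region = rep(c("A", "B"), each = 4)),
                    class = "VoxelGrid")
  mk <- sprintf("p%02d", 1:5)
  sA <- region_score(mk, grid, "A")
  expect_gt(sA, region_score(mk, grid, "B"))
  # monotone transform invariance (rank-based)
  grid2 <- grid; grid2$energy <- grid$energy^3
  expect_equal(region_score(mk, grid2, "A"), sA, tolerance = 1e-12)
  # pushing a marker to the bottom never raises the score
  grid3 <- grid; grid3$energy[1:4, 1] <- 0.5
  expect_lte(region_score(mk, grid3, "A"), sA)
  # markers always bottom-ranked: score tends to 0
  grid4 <- grid; grid4$energy[1:4, 1:5] <- 1e-6
  expect_lt(region_score(mk, grid4, "A"), 0.2)
  expect_error(region_score(mk, grid, "Z"), "unknown region")
})

test_that("predict_regions assigns planted regions and applies origin down-scaling", {
  cfg <- sim_config(seed = 71, tree_depth = 1, branching = 3, n_genes = 300,
                    voxel_noise_sd = 0.4)
  tree <- simulate_hierarchy(cfg)
  grid <- simulate_voxels(cfg, tree)
  sim <- simulate_counts(cfg, tree)
  gm <- lognormalize(sim$gm)
  ci <- sim$truth$cell_info
  ptree <- cluster_tree_from_labels(list(rep("all", nrow(ci)), ci$leaf),
                                    ci$cell_id)
  mk <- markers_for_tree(gm, ptree)
  pred <- predict_regions(ptree, mk, grid, nodes = tree$leaves, spec_min = 4)
  truth <- stats::setNames(names(grid$region_leaf), grid$region_leaf)
  expect_identical(unname(pred$assignment[tree$leaves]),
                   unname(truth[tree$leaves]))
  expect_true(all(pred$scores$adjusted_score >= 0 &
                    pred$scores$adjusted_score <= 1))
  # impossible threshold: nothing assigned
  pred_none <- predict_regions(ptree, mk, grid, nodes = tree$leaves,
                               spec_min = 4, threshold = 1.01)
  expect_true(all(is.na(pred_none$assignment)))
  # node whose cells all come from a dataset restricted to another region:
  # its home-region score is down-scaled below threshold
  cells <- sim$cells
  n1_cells <- ci$cell_id[ci$leaf == tree$leaves[1]]
  cells$dataset_id[cells$cell_id %in% n1_cells] <- "dsB"
  priors <- list(dsB = "R02", ds1 = c("R01", "R02", "R03"))
  pred_ds <- predict_regions(ptree, mk, grid, nodes = tree$leaves[1],
                             spec_min = 4, cells = cells,
                             origin_priors = priors, origin_floor = 0.25)
  sc <- pred_ds$scores
  expect_lt(sc$adjusted_score[sc$region == "R01"],
            sc$raw_score[sc$region == "R01"])
  expect_true(is.na(pred_ds$assignment[1]) ||
                pred_ds$assignment[1] == "R02")
})

test_that("no qualifying marker yields score 0 with a warning", {
  cfg <- sim_config(seed = 72, tree_depth = 1, branching = 3, n_genes = 100,
                    voxel_noise_sd = 0)
  tree <- simulate_hierarchy(cfg)
  grid <- simulate_voxels(cfg, tree)
  mk_empty <- data.frame(gene = character(0), node_id = character(0),
                         reference = character(0), specificity = numeric(0))
  ptree <- cluster_tree_from_labels(
    list(rep("all", 4), rep(c("x", "y"), 2)), paste0("c", 1:4))
  expect_warning(pred <- predict_regions(ptree, mk_empty, grid, nodes = "x"),
                 "score 0")
  expect_true(all(pred$scores$raw_score == 0))
})
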