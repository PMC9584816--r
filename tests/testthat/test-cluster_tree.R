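test_that("snn_graph computes Jaccard weights on shared neighbourhoods", {
  # 6 points: two tight pairs far apart plus satellites
  emb <- rbind(c(0, 0), c(0, 0.001), c(0, 0.002), c(10, 0), c(10, 0.001),
               c(10, 0.002))
  rownames(emb) <- paste0("c", 1:6)
  g <- snn_graph(emb, k = 3, prune = 0)
  w <- igraph::E(g)$weight
  ends <- igraph::ends(g, igraph::E(g))
  # cells 1 and 2 share all 3 neighbours -> weight 1
  e12 <- which((ends[, 1] == "c1" & ends[, 2] == "c2") |
               (ends[, 1] == "c2" & ends[, 2] == "c1"))
  expect_equal(w[e12], 1)
  # disjoint neighbour sets -> no edge across the two blobs
  cross <- (ends[, 1] %in% paste0("c", 1:3)) != (ends[, 2] %in% paste0("c", 1:3))
  expect_false(any(cross))
  expect_equal(igraph::count_components(g), 2)
  expect_error(snn_graph(emb, k = 6), "smaller")
})

test_that("multires_cluster recovers a planted partition and is deterministic", {
  set.seed(1)
  g <- igraph::sample_sbm(300, pref.matrix = diag(0.25, 3) + 0.01,
                          block.sizes = rep(100, 3))
  igraph::V(g)$name <- paste0("v", 1:300)
  igraph::E(g)$weight <- 1
  lv <- multires_cluster(g, c(1e-4, 0.5))
  expect_equal(lv[[1]]$n_clusters, 1)
  expect_gte(ari(lv[[2]]$labels, rep(1:3, each = 100)), 0.9)
  lv2 <- multires_cluster(g, c(1e-4, 0.5))
  expect_identical(lv, lv2)
})

test_that("select_levels follows the greedy tripling rule", {
  mk_lv <- function(n) list(resolution = n, labels = NULL, n_clusters = n)
  lv <- lapply(c(2, 7, 20, 63, 190, 600), mk_lv)
  base <- list(rep(letters[1:7], 10))
  sel <- vapply(select_levels(lv, base, factor = 3), `[[`, numeric(1), "n_clusters")
  expect_equal(sel, c(20, 63, 190, 600))
  expect_equal(vapply(select_levels(lv[3], base), `[[`, numeric(1), "n_clusters"), 20)
  sel1 <- vapply(select_levels(lv, factor = 1), `[[`, numeric(1), "n_clusters")
  expect_equal(sel1, c(2, 7, 20, 63, 190, 600))
})

test_that("reconcile_tree preserves nested input and handles noise", {
  coarse <- rep(c("A", "B"), each = 30)
  fine <- rep(c("a1", "a2", "b1", "b2"), c(15, 15, 20, 10))
  tr <- reconcile_tree(list(coarse, fine))
  # refinement predicate: each fine node maps into exactly one coarse node
  for (id in unique(tr$levels[[2]]))
    expect_length(unique(tr$levels[[1]][tr$levels[[2]] == id]), 1)
  expect_equal(ari(tr$levels[[1]], coarse), 1)
  expect_equal(ari(tr$levels[[2]], fine), 1)
  # identical levels: every node gets exactly one child
  tr2 <- reconcile_tree(list(coarse, coarse))
  expect_true(all(table(tr2$nodes$parent[tr2$nodes$level == 2]) == 1))
  # 5% noise at the coarse level: plurality still recovers every parent
  set.seed(8)
  noisy <- coarse
  flip <- sample(60, 3)
  noisy[flip] <- ifelse(coarse[flip] == "A", "B", "A")
  tr3 <- reconcile_tree(list(noisy, fine))
  expect_equal(ari(tr3$levels[[1]], coarse), 1)
})

test_that("prune_tree merges marker-free sibling splits and is idempotent", {
  cfg <- sim_config(seed = 31, tree_depth = 1, branching = 2, n_genes = 200,
                    cells_per_leaf = 60, n_iegs = 5)
  tree <- simulate_hierarchy(cfg)
  sim <- simulate_counts(cfg, tree)
  gm <- lognormalize(sim$gm)
  ci <- sim$truth$cell_info
  set.seed(2)
  # level 2 splits leaf n2 into two random halves (no discriminative genes)
  split <- ifelse(ci$leaf == "n1", "n1f",
                  sample(c("n2a", "n2b"), nrow(ci), replace = TRUE))
  tr <- cluster_tree_from_labels(list(ci$leaf, split), ci$cell_id)
  pruned <- prune_tree(tr, gm)
  expect_equal(length(unique(pruned$levels[[2]])), 2)
  expect_equal(ari(pruned$levels[[2]], ci$leaf), 1)
  # real siblings with >= 10 planted markers each stay untouched
  expect_equal(ari(pruned$levels[[1]], ci$leaf), 1)
  # idempotence
  again <- prune_tree(pruned, gm)
  expect_identical(again$levels, pruned$levels)
})

test_that("prune_tree chain-merges a redundant three-way sibling split", {
  cfg <- sim_config(seed = 33, tree_depth = 1, branching = 2, n_genes = 200,
                    cells_per_leaf = 60, n_iegs = 5)
  tree <- simulate_hierarchy(cfg)
  sim <- simulate_counts(cfg, tree)
  gm <- lognormalize(sim$gm)
  ci <- sim$truth$cell_info
  set.seed(3)
  lab <- ifelse(ci$leaf == "n1", "X", sample(c("Y", "Z"), nrow(ci), replace = TRUE))
  base <- rep("all", nrow(ci))
  tr <- cluster_tree_from_labels(list(base, lab), ci$cell_id)
  pruned <- prune_tree(tr, gm)
  expect_equal(length(unique(pruned$levels[[2]])), 2)
})
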