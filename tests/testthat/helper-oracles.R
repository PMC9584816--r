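# Independent oracles and tiny fixture builders shared across tests.

# Naive extrapolated-RBO oracle: literal translation of the closed form with
# explicit prefix intersections (O(l^2)); independent of the package's
# incremental implementation.
naive_rbo <- function(S, L, p) {
  if (length(S) > length(L)) { tmp <- S; S <- L; L <- tmp }
  s <- length(S); l <- length(L)
  X <- vapply(seq_len(l), function(d)
    length(intersect(S[seq_len(min(d, s))], L[seq_len(d)])), numeric(1))
  sum1 <- sum(X / seq_len(l) * p^seq_len(l))
  sum2 <- 0
  if (l > s) for (d in (s + 1):l) sum2 <- sum2 + X[s] * (d - s) / (s * d) * p^d
  (1 - p) / p * (sum1 + sum2) + ((X[l] - X[s]) / l + X[s] / s) * p^l
}

# All duplicate-free ordered lists over an alphabet, lengths 1..max_len.
all_ranked_lists <- function(alphabet, max_len) {
  out <- list()
  grow <- function(prefix) {
    if (length(prefix) > 0) out[[length(out) + 1]] <<- prefix
    if (length(prefix) == max_len) return()
    for (a in setdiff(alphabet, prefix)) grow(c(prefix, a))
  }
  grow(character(0))
  out
}

# Small dense GeneMatrix fixture with hand-set counts.
toy_gm <- function(counts, normalize = TRUE) {
  gm <- gene_matrix(Matrix::Matrix(counts, sparse = TRUE))
  if (normalize) lognormalize(gm) else gm
}

ari <- atlasforge:::adjusted_rand_index
subset_cells_helper <- atlasforge:::subset_cells

# Shared mid-sized simulation used by several test files (lazily built once).
.fixture_env <- new.env()
default_fixture <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  cfg <- sim_config(seed = 101)
  tree <- simulate_hierarchy(cfg)
  sim <- simulate_counts(cfg, tree)
  qc <- qc_filter(sim$gm, sim$cells)
  gm <- lognormalize(qc$gm)
  ci <- sim$truth$cell_info[match(cell_ids(gm), sim$truth$cell_info$cell_id), ]
  ptree <- cluster_tree_from_labels(
    list(ci$level1, ci$level2, ci$level3), cell_ids(gm))
  .fixture_env$fx <- list(cfg = cfg, tree = tree, sim = sim, gm = gm,
                          cells = qc$cells, ci = ci, ptree = ptree)
  .fixture_env$fx
}

# Marker table on the planted tree of the default fixture (computed once).
default_markers <- function() {
  if (!is.null(.fixture_env$mk)) return(.fixture_env$mk)
  fx <- default_fixture()
  .fixture_env$mk <- markers_for_tree(fx$gm, fx$ptree)
  .fixture_env$mk
}
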