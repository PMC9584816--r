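test_that("MTX round-trip is lossless and validates dimensions", {
  counts <- matrix(c(0, 2, 0, 5, 1, 0), nrow = 3,
                   dimnames = list(paste0("c", 1:3), paste0("g", 1:2)))
  gm <- toy_gm(counts, normalize = FALSE)
  d <- withr::local_tempdir()
  f <- file.path(d, c("m.mtx", "genes.tsv", "cells.tsv"))
  write_counts(gm, f[1], f[2], f[3])
  gm2 <- read_counts(f[1], f[2], f[3])
  expect_identical(as.matrix(gm2$counts), as.matrix(gm$counts))
  # writing the re-read object reproduces the file byte-for-byte
  f2 <- file.path(d, c("m2.mtx", "g2.tsv", "c2.tsv"))
  write_counts(gm2, f2[1], f2[2], f2[3])
  expect_identical(readLines(f[1]), readLines(f2[1]))
  # dimension mismatch: cells TSV with too few rows
  writeLines(c("c1", "c2"), f[3])
  expect_error(read_counts(f[1], f[2], f[3]), "2 rows")
})

test_that("gene_matrix rejects duplicates and non-integer counts", {
  m <- matrix(1, 2, 2, dimnames = list(c("a", "a"), c("g1", "g2")))
  expect_error(gene_matrix(m), "duplicate cell_id")
  m2 <- matrix(c(1, 0.5, 2, 3), 2, 2,
               dimnames = list(c("a", "b"), c("g1", "g2")))
  expect_error(gene_matrix(m2), "nonnegative integers")
})

test_that("lognormalize follows the log1p(count/total * scale) formula", {
  counts <- matrix(c(7, 0, 1, 1), nrow = 2, byrow = TRUE,
                   dimnames = list(c("c1", "c2"), c("g1", "g2")))
  gm <- lognormalize(gene_matrix(counts))
  expect_equal(gm$lognorm["c1", "g1"], log1p(10000), tolerance = 1e-12)
  expect_equal(unname(as.vector(gm$lognorm["c2", ])), rep(log1p(5000), 2),
               tolerance = 1e-12)
  # zero-total cell is an error pointing at QC
  bad <- gene_matrix(matrix(c(1, 0), 2, 1,
                            dimnames = list(c("c1", "c2"), "g1")))
  expect_error(lognormalize(bad), "qc_filter")
})

test_that("lognormalize preserves sparsity support with finite values", {
  fx <- default_fixture()
  gm <- fx$gm
  expect_identical(gm$lognorm@i, gm$counts@i)
  expect_identical(gm$lognorm@p, gm$counts@p)
  expect_true(all(is.finite(gm$lognorm@x)) && all(gm$lognorm@x >= 0))
})

test_that("qc_filter keeps inclusive boundaries and is monotone", {
  counts <- matrix(1L, 4, 2, dimnames = list(paste0("c", 1:4), c("g1", "g2")))
  cells <- data.frame(cell_id = paste0("c", 1:4),
                      umi_count = c(999L, 1000L, 5000L, 5000L),
                      mito_fraction = c(0, 0.10, 0.11, 0.05))
  res <- suppressMessages(qc_filter(gene_matrix(counts), cells))
  expect_setequal(res$cells$cell_id, c("c2", "c4"))
  # identity when everything passes
  res2 <- suppressMessages(qc_filter(gene_matrix(counts), cells,
                                     min_umi = 0, max_mito = 1))
  expect_identical(cell_ids(res2$gm), paste0("c", 1:4))
  # monotonicity in both thresholds
  n_kept <- function(mu, mm) nrow(suppressMessages(
    qc_filter(gene_matrix(counts), cells, mu, mm))$cells)
  for (mu in c(0, 500, 1000, 2000))
    expect_gte(n_kept(mu, 0.1), n_kept(mu + 1000, 0.1))
  for (mm in c(0, 0.05, 0.1))
    expect_lte(n_kept(0, mm), n_kept(0, mm + 0.05))
})

test_that("select_hvgs ranks cluster-restricted genes above flat ones", {
  set.seed(7)
  n <- 200
  counts <- matrix(rpois(n * 30, 2), n, 30,
                   dimnames = list(sprintf("c%03d", 1:n), sprintf("g%02d", 1:30)))
  # marker: same overall mean, concentrated in cells 1..20
  counts[, 1] <- 0
  counts[1:20, 1] <- rpois(20, 20)
  counts[, 2] <- rpois(n, mean(counts[, 1]))  # flat gene, equal mean
  counts[, 3] <- 0                            # constant-zero gene
  gm <- lognormalize(gene_matrix(counts))
  hv <- select_hvgs(gm, 10)
  expect_true("g01" %in% hv)
  expect_lt(match("g01", hv), match("g02", c(hv, "g02")))
  expect_false("g03" %in% select_hvgs(gm, 29))
  expect_warning(all_g <- select_hvgs(gm, 40), "all genes")
  expect_setequal(all_g, gene_ids(gm))
})

test_that("pca_embed is deterministic and captures planted structure", {
  set.seed(11)
  n <- 120
  counts <- matrix(rpois(n * 40, 3), n, 40,
                   dimnames = list(sprintf("c%03d", 1:n), sprintf("g%02d", 1:40)))
  counts[1:60, 1:5] <- counts[1:60, 1:5] + matrix(rpois(60 * 5, 40), 60, 5)
  gm <- lognormalize(gene_matrix(counts))
  emb <- pca_embed(gm, gene_ids(gm), 10)
  emb2 <- pca_embed(gm, gene_ids(gm), 10)
  expect_identical(emb, emb2)
  # PC1 separates the two planted groups
  grp <- rep(c(TRUE, FALSE), each = 60)
  gap <- abs(mean(emb[grp, 1]) - mean(emb[!grp, 1]))
  spread <- max(stats::sd(emb[grp, 1]), stats::sd(emb[!grp, 1]))
  expect_gt(gap, 3 * spread)
  expect_error(pca_embed(gm, gene_ids(gm)[1:5], 10), "n_pcs")
})

test_that("pca_embed on low-rank data leaves trailing PCs empty", {
  base <- matrix(rpois(50 * 2, 10), 50, 2)
  counts <- base[, c(1, 2, 1, 2, 1, 2)] + 0L
  dimnames(counts) <- list(sprintf("c%02d", 1:50), sprintf("g%d", 1:6))
  gm <- lognormalize(gene_matrix(counts))
  emb <- pca_embed(gm, gene_ids(gm), 6)
  v <- apply(emb, 2, stats::var)
  expect_lt(sum(v[3:6]), 1e-20 + 0.001 * sum(v))
})

test_that("flag_doublet_clusters applies the strict above-threshold rule", {
  cells <- data.frame(cell_id = sprintf("c%02d", 1:30),
                      is_doublet = c(rep(c(TRUE, FALSE), c(8, 2)),
                                     rep(c(TRUE, FALSE), c(7, 3)),
                                     rep(FALSE, 10)))
  labels <- rep(c("A", "B", "C"), each = 10)
  expect_identical(as.character(flag_doublet_clusters(cells, labels)), "A")
  expect_length(flag_doublet_clusters(cells[21:30, ], labels[21:30]), 0)
  expect_error(flag_doublet_clusters(cells, c(labels[-1], NA)), "NA")
})

test_that("flag_multisignature_clusters finds planted hybrid clusters", {
  set.seed(3)
  n <- 90
  counts <- matrix(rpois(n * 20, 1), n, 20,
                   dimnames = list(sprintf("c%03d", 1:n), sprintf("g%02d", 1:20)))
  neu <- paste0("g0", 1:3); ast <- paste0("g0", 4:6)
  counts[1:30, neu] <- counts[1:30, neu] + 20L        # pure neurons
  counts[31:60, ast] <- counts[31:60, ast] + 20L      # pure astrocytes
  counts[61:90, c(neu, ast)] <- counts[61:90, c(neu, ast)] + 10L  # hybrids
  gm <- lognormalize(gene_matrix(counts))
  labels <- rep(c("neu", "ast", "dbl"), each = 30)
  sigs <- list(neuron = neu, astro = ast)
  flagged <- flag_multisignature_clusters(gm, labels, sigs, score_threshold = 5)
  expect_identical(as.character(flagged), "dbl")
  expect_length(flag_multisignature_clusters(gm, labels, sigs["neuron"], 5), 0)
  expect_error(flag_multisignature_clusters(gm, labels, list(), 2), "non-empty")
})
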