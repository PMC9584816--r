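#' Build a desk-scale reference embedding model
#'
#' Packages a PCA embedding of the reference (loadings, centering, scaling,
#' feature list, latent coordinates and labels) so query data can be placed
#' in the same latent space. Any embedder honouring the same contract
#' (reference and query in one space) can replace it.
#'
#' @param gm reference `GeneMatrix` (lognorm layer required)
#' @param hvgs feature genes (default: [select_hvgs()] result)
#' @param n_pcs latent dimensions (default 50)
#' @return a `ReferenceModel` list: `rotation`, `center`, `scale`, `genes`,
#'   `latent` (reference cells x n_pcs)
#' @export
build_reference <- function(gm, hvgs = NULL, n_pcs = 50) {
  hvgs <- hvgs %||% select_hvgs(gm, min(2000, n_genes(gm)))
  emb <- pca_embed(gm, hvgs, n_pcs)
  structure(list(rotation = attr(emb, "rotation"),
                 center = attr(emb, "center"),
                 scale = attr(emb, "scale"),
                 genes = attr(emb, "genes"),
                 latent = emb[, , drop = FALSE]),
            class = "ReferenceModel")
}

#' Embed query cells into the reference latent space
#'
#' Matches the query's genes to the reference feature set (zero-filling
#' missing features, with a warning reporting the missing fraction), applies
#' the reference centering/scaling and projects onto the reference loadings.
#'
#' @param reference_model a `ReferenceModel` from [build_reference()]
#' @param query_gm query `GeneMatrix` with a lognorm layer
#' @return query cells x n_pcs latent matrix
#' @export
embed_query <- function(reference_model, query_gm) {
  feats <- reference_model$genes
  common <- intersect(feats, gene_ids(query_gm))
  if (!length(common)) stop("query shares no genes with the reference features")
  if (length(common) < length(feats))
    warning(sprintf("query is missing %.1f%% of reference features; zero-filling",
                    100 * (1 - length(common) / length(feats))))
  x <- matrix(0, n_cells(query_gm), length(feats),
              dimnames = list(cell_ids(query_gm), feats))
  x[, common] <- as.matrix(query_gm$lognorm[, common, drop = FALSE])
  x <- sweep(sweep(x, 2, reference_model$center), 2, reference_model$scale, "/")
  x %*% reference_model$rotation
}

#' Cosine similarity from cosine distance
#'
#' With `d` the Euclidean distance between L2-normalized vectors
#' (`d` in \[0, 2\]), `1 - d^2/2` is exactly the cosine of the angle; the
#' result is clipped at 0 so it can serve as a non-negative voting weight.
#'
#' @param d non-negative distance(s)
#' @return similarity in \[0, 1\]
#' @export
cosine_sim_from_dist <- function(d) {
  if (any(d < 0)) stop("distances must be non-negative")
  pmax(1 - d^2 / 2, 0)
}

#' Propagate reference labels to query cells by weighted k-NN voting
#'
#' For each query cell the `k` nearest reference cells (Euclidean on
#' L2-normalized latent rows) vote with their cosine similarity; the
#' per-label probability is the label's share of the total similarity.
#' Ties in the argmax go to the label of the single nearest neighbour; if
#' all similarities are zero the vote is uniform over the neighbour labels
#' (with a warning).
#'
#' @param query query latent matrix (cells x d)
#' @param reference reference latent matrix in the same space
#' @param ref_labels label per reference cell
#' @param k neighbours (default 25)
#' @return data.frame with `cell_id`, `predicted_label`, `probability`, and
#'   the full probability matrix as attribute `probs`
#' @export
propagate_labels <- function(query, reference, ref_labels, k = 25) {
  if (k > nrow(reference)) stop("k exceeds the reference size")
  qn <- l2_normalize_rows(as.matrix(query))
  rn <- l2_normalize_rows(as.matrix(reference))
  labels <- as.character(ref_labels)
  lev <- sort(unique(labels))
  cosm <- tcrossprod(qn, rn)               # cosine similarities
  probs <- matrix(0, nrow(qn), length(lev),
                  dimnames = list(rownames(qn), lev))
  pred <- character(nrow(qn))
  warned <- FALSE
  for (i in seq_len(nrow(qn))) {
    d2 <- pmax(2 - 2 * cosm[i, ], 0)
    ord <- order(d2)
    nb <- ord[seq_len(k)]
    sims <- cosine_sim_from_dist(sqrt(d2[nb]))
    if (sum(sims) == 0) {
      if (!warned) { warning("all-zero similarities; uniform vote used"); warned <- TRUE }
      sims <- rep(1, k)
    }
    w <- tapply(sims, factor(labels[nb], levels = lev), sum, default = 0)
    p <- w / sum(w)
    probs[i, ] <- p
    top <- lev[p == max(p)]
    pred[i] <- if (length(top) > 1) labels[nb[1]] else top
  }
  out <- data.frame(cell_id = rownames(qn) %||% seq_len(nrow(qn)),
                    predicted_label = pred,
                    probability = apply(probs, 1, max),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "probs") <- probs
  out
}
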