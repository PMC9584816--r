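#' Normalized classifier entropy
#'
#' Mean over cells of the Shannon entropy of the held-out class-probability
#' rows, normalized by `log` of the number of classes, so 1 means the
#' classifier is at chance (samples indistinguishable) and 0 means perfect
#' separation.
#'
#' @param oob numeric matrix, cells x classes, rows summing to 1
#' @return scalar in \[0, 1\]; a single-column matrix returns 1 (a fully
#'   merged state is indistinguishable by construction)
#' @export
normalized_entropy <- function(oob) {
  oob <- as.matrix(oob)
  if (ncol(oob) < 2) return(1.0)
  p <- pmin(pmax(oob, 0), 1)
  h <- -rowSums(ifelse(p > 0, p * log(p), 0))
  mean(h) / log(ncol(oob))
}

#' Sample dissimilarity from held-out class probabilities
#'
#' Averages the probability rows per sample and converts pairwise Spearman
#' correlations of the mean profiles into distances `1 - rho`.
#'
#' @param oob numeric matrix, cells x classes
#' @param sample_ids sample id per row of `oob`
#' @return symmetric distance matrix over samples, zero diagonal; a constant
#'   profile yields distance 1 with a warning
#' @export
sample_dissimilarity <- function(oob, sample_ids) {
  oob <- as.matrix(oob)
  ids <- sort(unique(sample_ids))
  prof <- t(vapply(ids, function(s)
    colMeans(oob[sample_ids == s, , drop = FALSE]), numeric(ncol(oob))))
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  const <- apply(prof, 1, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)))
  if (any(const)) warning("constant oob profile; distances set to 1 for: ",
                          paste(ids[const], collapse = ", "))
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i < j) {
      if (const[i] || const[j]) d[i, j] <- d[j, i] <- 1
      else {
        rho <- stats::cor(prof[i, ], prof[j, ], method = "spearman")
        d[i, j] <- d[j, i] <- 1 - rho
      }
    }
  }
  d
}

# Leave-one-out k-NN class-probability classifier on a precomputed distance
# matrix: for each cell, class frequencies among its k nearest other cells.
oof_knn_probs <- function(D, labels, k) {
  labels <- factor(labels)
  n <- nrow(D)
  k <- min(k, n - 1)
  probs <- matrix(0, n, nlevels(labels),
                  dimnames = list(rownames(D), levels(labels)))
  for (i in seq_len(n)) {
    ord <- order(D[i, ])
    nb <- setdiff(ord, i)[seq_len(k)]
    tab <- tabulate(labels[nb], nbins = nlevels(labels))
    probs[i, ] <- tab / sum(tab)
  }
  probs
}

#' Detect batches by iterative entropy-gated sample merging
#'
#' Starts with every sample as its own group and repeatedly proposes merging
#' the two groups whose held-out class-probability profiles are most similar
#' (Spearman distance). A classifier retrained on the two candidate groups
#' alone decides the merge: if their pairwise normalized entropy is at least
#' `threshold` the classifier cannot tell them apart and they merge;
#' otherwise the pair is marked unmergeable. Terminates when no mergeable
#' pair remains; the surviving groups are the batches.
#'
#' @param embedding cells x dims numeric matrix (e.g. 50 PCs from
#'   [pca_embed()])
#' @param sample_ids sample id per row of `embedding`
#' @param classifier optional function `(embedding, labels)` returning a
#'   cells x groups matrix of held-out class probabilities; the default is a
#'   leave-one-out k-NN estimator
#' @param threshold entropy above which two groups are considered the same
#'   batch (default 0.9)
#' @param k neighbours for the default classifier
#' @param gate `"pair"` (default) gates each candidate merge on the entropy
#'   of the retrained pairwise classifier; `"global"` gates on the averaged
#'   entropy over all groups after the tentative merge
#' @return list with `batches` (named character vector sample -> batch id)
#'   and `trace` (one row per proposed merge: groups, distance, entropy,
#'   accepted)
#' @export
detect_batches <- function(embedding, sample_ids, classifier = NULL,
                           threshold = 0.9, k = 25,
                           gate = c("pair", "global")) {
  gate <- match.arg(gate)
  samples <- sort(unique(sample_ids))
  if (length(samples) < 2) {
    return(list(batches = stats::setNames(rep("B1", length(samples)), samples),
                trace = data.frame()))
  }
  D <- NULL
  if (is.null(classifier)) {
    D <- as.matrix(stats::dist(embedding))
    classifier <- function(idx, labels) oof_knn_probs(D[idx, idx, drop = FALSE],
                                                      labels, k)
    cls <- function(idx, labels) classifier(idx, labels)
  } else {
    cls <- function(idx, labels) classifier(embedding[idx, , drop = FALSE], labels)
  }
  groups <- stats::setNames(as.list(samples), samples)
  unmergeable <- character(0)
  trace <- list()
  all_idx <- seq_along(sample_ids)

  group_labels <- function() {
    map <- stats::setNames(rep(names(groups), lengths(groups)), unlist(groups))
    unname(map[sample_ids])
  }
  pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

  repeat {
    if (length(groups) < 2) break
    gl <- group_labels()
    oob <- cls(all_idx, gl)
    gd <- sample_dissimilarity(oob, gl)
    cand <- NULL
    ids <- rownames(gd)
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i < j && !(pair_key(ids[i], ids[j]) %in% unmergeable)) {
        cand <- rbind(cand, data.frame(a = ids[i], b = ids[j],
                                       d = gd[i, j], stringsAsFactors = FALSE))
      }
    }
    if (is.null(cand)) break
    keys <- vapply(seq_len(nrow(cand)), function(i)
      pair_key(cand$a[i], cand$b[i]), character(1))
    cand <- cand[order(cand$d, keys), , drop = FALSE]
    a <- cand$a[1]; b <- cand$b[1]
    sub <- which(gl %in% c(a, b))
    oob_pair <- cls(sub, gl[sub])
    h <- if (gate == "pair") {
      normalized_entropy(oob_pair)
    } else {
      gl2 <- gl
      gl2[gl2 %in% c(a, b)] <- pair_key(a, b)
      normalized_entropy(cls(all_idx, gl2))
    }
    accept <- h >= threshold
    trace[[length(trace) + 1]] <- data.frame(
      group_a = a, group_b = b, distance = cand$d[1], entropy = h,
      accepted = accept, n_groups = length(groups), stringsAsFactors = FALSE)
    if (accept) {
      merged <- sort(c(groups[[a]], groups[[b]]))
      groups[[a]] <- NULL; groups[[b]] <- NULL
      groups[[paste(merged, collapse = "+")]] <- merged
      groups <- groups[order(names(groups))]
    } else {
      unmergeable <- c(unmergeable, pair_key(a, b))
    }
  }
  batch_ids <- paste0("B", seq_along(groups))
  batches <- stats::setNames(rep(batch_ids, lengths(groups)), unlist(groups))
  batches <- batches[samples]
  list(batches = batches,
       trace = if (length(trace)) do.call(rbind, trace) else data.frame())
}
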