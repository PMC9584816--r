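#' Build a ranked signature from a bulk DE table
#'
#' Keeps genes significantly enriched in the IP (adjusted p below
#' `p_adj_max`, positive log2 fold change) and orders them by descending
#' log2 fold change (ties broken lexicographically).
#'
#' @param de_table data.frame with `gene`, `log2FC`, `p_adj`
#' @param p_adj_max significance cutoff (default 0.05)
#' @param contrast label used in error messages
#' @return character vector of genes, head = most enriched
#' @export
build_signature <- function(de_table, p_adj_max = 0.05, contrast = "signature") {
  stopifnot(all(c("gene", "log2FC", "p_adj") %in% names(de_table)))
  keep <- de_table$p_adj < p_adj_max & de_table$log2FC > 0
  if (!any(keep)) stop("no significantly IP-enriched genes in ", contrast)
  d <- de_table[keep, , drop = FALSE]
  if (anyDuplicated(d$gene)) stop("duplicate genes in ", contrast)
  d$gene[order(-d$log2FC, d$gene)]
}

#' Extrapolated rank-biased overlap for uneven lists
#'
#' Top-weighted similarity of two duplicate-free ranked lists under
#' persistence `p`. With `s <= l` the lengths of the shorter and longer list
#' and `X_d` the overlap of the depth-`d` prefixes (the shorter list capped
#' at `s`):
#' `RBO = (1-p)/p * [ sum_{d=1}^{l} (X_d/d) p^d +
#'  sum_{d=s+1}^{l} X_s (d-s)/(s d) p^d ] + [ (X_l - X_s)/l + X_s/s ] p^l`.
#' Identical lists give 1, disjoint equal-length lists give 0.
#'
#' @param S,L character vectors (ranked, duplicate-free); order of the two
#'   arguments is irrelevant (they are swapped so `|S| <= |L|`)
#' @param p persistence in (0,1): the probability of looking one rank deeper
#' @return RBO in \[0, 1\]
#' @export
rbo_ext <- function(S, L, p = 0.98) {
  if (p <= 0 || p >= 1) stop("p must be in (0,1)")
  if (anyDuplicated(S) || anyDuplicated(L)) stop("lists must be duplicate-free")
  if (length(S) > length(L)) { tmp <- S; S <- L; L <- tmp }
  s <- length(S); l <- length(L)
  if (s == 0) return(0)
  # incremental prefix overlaps X_d = |S[1:min(d,s)] intersect L[1:d]|
  in_S_prefix <- new.env(hash = TRUE, parent = emptyenv())
  in_L_prefix <- new.env(hash = TRUE, parent = emptyenv())
  X <- numeric(l)
  x <- 0
  for (d in seq_len(l)) {
    if (d <= s) {
      g <- S[d]
      if (!is.null(in_L_prefix[[g]])) x <- x + 1
      in_S_prefix[[g]] <- TRUE
    }
    g <- L[d]
    if (!is.null(in_S_prefix[[g]])) x <- x + 1
    in_L_prefix[[g]] <- TRUE
    X[d] <- x
  }
  d <- seq_len(l)
  sum1 <- sum(X / d * p^d)
  sum2 <- if (l > s) {
    dd <- (s + 1):l
    sum(X[s] * (dd - s) / (s * dd) * p^dd)
  } else 0
  (1 - p) / p * (sum1 + sum2) + ((X[l] - X[s]) / l + X[s] / s) * p^l
}

#' Map a bulk signature onto tree nodes by RBO
#'
#' Ranks each node's vs-all markers by `rank_key` and computes the
#' extrapolated RBO against the signature; scores are also reported relative
#' to the best node, mirroring how per-cluster signature enrichment is
#' usually displayed.
#'
#' @param signature ranked gene vector from [build_signature()]
#' @param markers MarkerResult data.frame
#' @param nodes node ids to score (e.g. all nodes of one tree level)
#' @param rank_key `"log2fc"` (default) or `"specificity"`
#' @param p RBO persistence (default 0.98)
#' @param p_adj_max marker significance filter (default 0.05)
#' @return data.frame with `node_id`, `rbo`, `relative_rbo`, `n_markers`
#' @export
enrich_tree <- function(signature, markers, nodes, rank_key = c("log2fc", "specificity"),
                        p = 0.98, p_adj_max = 0.05) {
  rank_key <- match.arg(rank_key)
  key_col <- if (rank_key == "log2fc") "avg_log2fc" else "specificity"
  res <- lapply(nodes, function(nd) {
    m <- markers[markers$node_id == nd & markers$reference == "all" &
                   markers$p_adj < p_adj_max & markers$avg_log2fc > 0, , drop = FALSE]
    if (!nrow(m)) {
      warning("node ", nd, " has no markers; rbo 0")
      return(data.frame(node_id = nd, rbo = 0, n_markers = 0L,
                        stringsAsFactors = FALSE))
    }
    ranked <- m$gene[order(-m[[key_col]], m$gene)]
    data.frame(node_id = nd, rbo = rbo_ext(signature, ranked, p),
               n_markers = nrow(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  mx <- max(out$rbo)
  out$relative_rbo <- if (mx > 0) out$rbo / mx else 0
  out[order(-out$rbo, out$node_id), c("node_id", "rbo", "relative_rbo", "n_markers")]
}
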