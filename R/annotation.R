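# Look up a specificity value from the marker table; `default` when untested.
lookup_spec <- function(markers, gene, node, reference, default = 0) {
  hit <- markers$gene == gene & markers$node_id == node &
    markers$reference == reference
  if (any(hit)) markers$specificity[which(hit)[1]] else default
}

#' Naming score of a gene for a tree node
#'
#' `T = S_all * S_siblings / max(1, max_i S_siblings(i))` where `i` runs
#' over the node's children: a good name gene is specific for the whole node
#' (vs all, vs siblings) but not for any single sub-branch. Leaves (or a
#' gene untested in every child) use denominator 1; a gene untested in a
#' child contributes 0 to the child maximum.
#'
#' @param gene gene id
#' @param node node id
#' @param markers MarkerResult data.frame from [markers_for_tree()]
#' @param tree the `ClusterTree`
#' @return the naming score T
#' @export
naming_score <- function(gene, node, markers, tree) {
  s_all <- lookup_spec(markers, gene, node, "all")
  s_sib <- lookup_spec(markers, gene, node, "siblings")
  kids <- tree_children(tree, node)
  denom <- if (length(kids)) {
    max(1, vapply(kids, function(k)
      lookup_spec(markers, gene, k, "siblings", default = 0), numeric(1)))
  } else 1
  s_all * s_sib / denom
}

#' Assign marker-gene names to every tree node
#'
#' Visits the tree top-down. Per node the candidates are its vs-sibling
#' markers passing the adjusted-p filter, minus excluded gene patterns and
#' any gene already used in an ancestor's name; the gene with the highest
#' naming score T is chosen (ties by vs-all specificity, then
#' lexicographic) and prepended to the parent's concatenated name.
#' Siblingless nodes inherit the parent name unchanged; manually named
#' nodes (top levels) take their configured name.
#'
#' @param tree a pruned `ClusterTree`
#' @param markers MarkerResult data.frame from [markers_for_tree()]
#' @param exclusions character vector of regular expressions for genes never
#'   used as names (default mitochondrial and ribosomal prefixes)
#' @param manual_names named character vector node_id -> name for manually
#'   labelled top levels
#' @param p_adj_max candidate filter on the vs-sibling adjusted p value
#' @return data.frame with `node_id`, `chosen_gene`, `full_name`
#' @export
assign_names <- function(tree, markers, exclusions = c("^mt-", "^Rp[ls]"),
                         manual_names = NULL, p_adj_max = 0.05) {
  sib <- markers[markers$reference == "siblings", , drop = FALSE]
  nodes <- tree$nodes[order(tree$nodes$level, tree$nodes$id), , drop = FALSE]
  full_name <- c(root = "")
  used <- list(root = character(0))
  chosen <- stats::setNames(rep(NA_character_, nrow(nodes)), nodes$id)
  out_name <- chosen
  excluded <- function(g) {
    any(vapply(exclusions, function(rx) grepl(rx, g), logical(1)))
  }
  for (r in seq_len(nrow(nodes))) {
    id <- nodes$id[r]
    parent <- nodes$parent[r]
    pn <- full_name[[parent]]
    pu <- used[[parent]]
    sibs <- tree$nodes$id[tree$nodes$parent == parent & tree$nodes$id != id]
    if (!is.null(manual_names) && id %in% names(manual_names)) {
      nm <- manual_names[[id]]
      full_name[[id]] <- if (nzchar(pn)) paste(nm, pn, sep = ".") else nm
      used[[id]] <- c(pu, nm)
    } else if (!length(sibs)) {
      full_name[[id]] <- pn
      used[[id]] <- pu
    } else {
      cand <- sib[sib$node_id == id & sib$p_adj < p_adj_max &
                    sib$avg_log2fc > 0, , drop = FALSE]
      if (nrow(cand)) {
        keep <- !vapply(cand$gene, excluded, logical(1)) & !(cand$gene %in% pu)
        cand <- cand[keep, , drop = FALSE]
      }
      if (!nrow(cand)) {
        warning("no eligible name gene for node ", id, "; using its id")
        full_name[[id]] <- if (nzchar(pn)) paste(id, pn, sep = ".") else id
        used[[id]] <- pu
      } else {
        tt <- vapply(cand$gene, naming_score, numeric(1),
                     node = id, markers = markers, tree = tree)
        s_all <- vapply(cand$gene, lookup_spec, numeric(1),
                        markers = markers, node = id, reference = "all")
        pick <- order(-tt, -s_all, cand$gene)[1]
        g <- cand$gene[pick]
        chosen[[id]] <- g
        full_name[[id]] <- if (nzchar(pn)) paste(g, pn, sep = ".") else g
        used[[id]] <- c(pu, g)
      }
    }
    out_name[[id]] <- full_name[[id]]
  }
  data.frame(node_id = nodes$id, chosen_gene = unname(chosen[nodes$id]),
             full_name = unname(out_name[nodes$id]), stringsAsFactors = FALSE)
}
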