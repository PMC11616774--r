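#' Descending competition ranking
#'
#' The largest value gets rank 1; ties share the minimum applicable rank; the
#' next distinct value's rank is one plus the count of strictly larger values.
#' This is the ranking function applied to each score column before the
#' threshold selection, so boundary ties at the cutoff are all-in.
#'
#' @param values Finite numeric vector, one value per node.
#' @return Integer ranks in `[1, length(values)]`, names preserved.
#' @examples
#' rank_nodes(c(a = 3, b = 1, c = 2))
#' @export
rank_nodes <- function(values) {
  if (any(!is.finite(values))) {
    bn_stop("rank_nodes requires finite values", "bn_domain_error")
  }
  r <- as.integer(rank(-values, ties.method = "min"))
  names(r) <- names(values)
  r
}

#' Per-node scores of a Boolean network
#'
#' Computes, for every node, vertex betweenness (VB), determinative power
#' (DP), total degree, z-transformed connectivity `C_i`, the descending
#' competition ranks on VB, DP and `C_i`, and the rank mismatch
#' `rank_C - (rank_VB + rank_DP) / 2`.
#'
#' @param net A `boolean_network`.
#' @param graph Optionally, its precomputed interaction graph.
#' @return A data frame with columns `node`, `VB`, `DP`, `degree`, `C`,
#'   `rank_VB`, `rank_DP`, `rank_C`, `mismatch`, one row per node in network
#'   order.
#' @seealso [classify()], [select_nodes()]
#' @export
score_nodes <- function(net, graph = build_interaction_graph(net)) {
  vb <- vertex_betweenness(graph)
  dp <- determinative_power(net)
  stats <- connectivity_zscores(graph)
  scores <- data.frame(
    node = net$nodes,
    VB = unname(vb[net$nodes]),
    DP = unname(dp[net$nodes]),
    degree = unname(stats$degree[net$nodes]),
    C = unname(stats$z[net$nodes]),
    stringsAsFactors = FALSE
  )
  scores$rank_VB <- rank_nodes(scores$VB)
  scores$rank_DP <- rank_nodes(scores$DP)
  scores$rank_C <- rank_nodes(scores$C)
  scores$mismatch <- compute_mismatch(scores)
  scores
}

#' Threshold selection of candidate nodes
#'
#' A node is selected when it ranks in the top `ceiling(T * n)` on both
#' vertex betweenness and determinative power — the intersection of the two
#' top-rank sets. `T` is a fraction in `(0, 1]`; the default in the analysis
#' front-ends is 0.73, the threshold found to balance sensitivity and
#' specificity for the high/low dynamic-impact classification.
#'
#' @param scores Score table from [score_nodes()] (needs `rank_VB`,
#'   `rank_DP`).
#' @param T Selection threshold, a fraction in `(0, 1]`.
#' @return Character vector of selected node names, in table order.
#' @export
select_nodes <- function(scores, T) {
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T <= 0 || T > 1) {
    bn_stop("selection threshold T must lie in (0, 1]", "bn_domain_error")
  }
  cutoff <- ceiling(T * nrow(scores))
  scores$node[scores$rank_VB <= cutoff & scores$rank_DP <= cutoff]
}

#' Rank mismatch between static measures and connectivity
#'
#' `mismatch(g) = rank_C(g) - (rank_VB(g) + rank_DP(g)) / 2`. Positive values
#' mean the node ranks higher (numerically smaller rank) on the static
#' impact measures VB and DP than on connectivity: high predicted dynamic
#' impact despite sparse wiring.
#'
#' @param scores Table with columns `rank_VB`, `rank_DP`, `rank_C`.
#' @return Numeric vector of signed mismatch values.
#' @export
compute_mismatch <- function(scores) {
  scores$rank_C - (scores$rank_VB + scores$rank_DP) / 2
}

#' Classify nodes into gatekeepers, selected, and non-selected
#'
#' Applies the threshold selection and the mismatch criterion: a
#' *gatekeeper* is a selected node with strictly positive mismatch — a
#' sparsely connected node whose high VB/DP ranks predict a large dynamic
#' impact, and hence a preferential intervention candidate compared to hubs
#' (which are hard to target and risk lethal side effects). Selected nodes
#' with mismatch `<= 0` are *selected non-gatekeepers*; the rest are
#' *non-selected*. Hubs (`C_i >=` `hub_threshold`) are flagged independently
#' and may coincide with gatekeepers; they are annotations, not exclusions.
#'
#' @param scores Score table from [score_nodes()].
#' @param T Selection threshold fraction in `(0, 1]`; default 0.73.
#' @param hub_threshold Connectivity z-score defining hubs; default 2.5.
#' @return An object of class `bn_classification`: a list with `table` (the
#'   score table plus `class` and `is_hub` columns), `recommendations`
#'   (gatekeepers by descending mismatch, ties broken by node name), and the
#'   parameters used.
#' @examples
#' net <- fixture("bottleneck12")
#' classify(score_nodes(net))$recommendations[1]
#' @export
classify <- function(scores, T = 0.73, hub_threshold = 2.5) {
  selected <- scores$node %in% select_nodes(scores, T)
  cls <- ifelse(!selected, "non_selected",
                ifelse(scores$mismatch > 0, "gatekeeper",
                       "selected_non_gatekeeper"))
  table <- scores
  table$class <- factor(cls, levels = c("gatekeeper",
                                        "selected_non_gatekeeper",
                                        "non_selected"))
  table$is_hub <- scores$C >= hub_threshold

  gk <- table[table$class == "gatekeeper", , drop = FALSE]
  ord <- order(-gk$mismatch, gk$node)
  structure(
    list(
      table = table,
      recommendations = gk$node[ord],
      T = T,
      hub_threshold = hub_threshold
    ),
    class = "bn_classification"
  )
}

#' @export
print.bn_classification <- function(x, ...) {
  counts <- table(x$table$class)
  cat(sprintf(
    "Node classification (T = %d%%, hub C >= %.2f)\n", round(100 * x$T),
    x$hub_threshold
  ))
  cat(sprintf("  gatekeepers: %d, selected non-gatekeepers: %d, non-selected: %d, hubs: %d\n",
              counts[["gatekeeper"]], counts[["selected_non_gatekeeper"]],
              counts[["non_selected"]], sum(x$table$is_hub)))
  if (length(x$recommendations) > 0L) {
    cat("  suggested intervention targets, sorted by mismatch:\n")
    for (node in x$recommendations) {
      m <- x$table$mismatch[x$table$node == node]
      cat(sprintf("    %s (mismatch %+.1f)\n", node, m))
    }
  } else {
    cat("  no recommended targets at this threshold\n")
  }
  invisible(x)
}
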