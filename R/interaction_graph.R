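#' Derive the interaction graph of a Boolean network
#'
#' Builds the directed regulator-to-target graph: an edge `g -> h` exists
#' exactly when `g` appears in the input list of `h`'s rule. Self-loops are
#' kept; duplicate edges cannot arise because rule inputs are distinct. The
#' interaction graph has `n` vertices, orders of magnitude smaller than the
#' `2^n`-state dynamic state graph, which is what makes static screening
#' feasible for large models.
#'
#' @param net A `boolean_network`.
#' @return An [igraph::igraph] directed graph whose vertices are the network
#'   nodes in network order.
#' @examples
#' net <- parse_boolnet("targets, factors\nA, B\nB, A")
#' igraph::ecount(build_interaction_graph(net))
#' @export
build_interaction_graph <- function(net) {
  validate_boolean_network(net)
  edges <- do.call(rbind, lapply(net$nodes, function(h) {
    inputs <- net$rules[[h]]$inputs
    if (length(inputs) == 0L) return(NULL)
    cbind(inputs, rep(h, length(inputs)))
  }))
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = net$nodes)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, t(edges))
  }
  g
}

#' Vertex betweenness on the interaction graph
#'
#' Freeman/Brandes betweenness on the directed, unweighted graph: for each
#' node `v`, the sum over ordered pairs `(s, t)` with `s != t != v` of the
#' fraction of shortest `s -> t` paths passing through `v`. Pairs with no
#' connecting path contribute zero; scores are unnormalized. Self-loops are
#' ignored (no shortest path uses one). Nodes scoring high act as structural
#' bottlenecks.
#'
#' @param graph A directed igraph as returned by [build_interaction_graph()].
#' @return Named numeric vector of non-negative scores, in vertex order.
#' @export
vertex_betweenness <- function(graph) {
  g <- igraph::simplify(graph, remove.multiple = FALSE, remove.loops = TRUE)
  scores <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
  scores[igraph::V(graph)$name]
}

#' Degree statistics and z-transformed connectivity
#'
#' For each node, the total degree `delta_i` (in-degree plus out-degree; a
#' self-loop adds 1 to each) and its z-transform
#' `C_i = (delta_i - mean(delta)) / sigma`, with `sigma` the population
#' (divide-by-n) standard deviation of the degree distribution. On a regular
#' graph (`sigma = 0`) all `C_i` are defined as 0, so no node is a hub.
#'
#' @param graph A directed igraph with at least one vertex.
#' @return A list of class `degree_stats` with elements `degree` (named
#'   integer), `mean`, `sd`, and `z` (named numeric `C_i`).
#' @export
connectivity_zscores <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0L) {
    bn_stop("connectivity z-scores are undefined for an empty graph",
            "bn_domain_error")
  }
  degree <- igraph::degree(graph, mode = "all", loops = TRUE)
  mean_deg <- mean(degree)
  sigma <- sqrt(mean((degree - mean_deg)^2))
  z <- if (sigma > 0) (degree - mean_deg) / sigma else rep(0, n)
  names(z) <- names(degree)
  structure(
    list(degree = degree, mean = mean_deg, sd = sigma, z = z),
    class = "degree_stats"
  )
}

#' Hub detection by connectivity z-score
#'
#' Hubs are highly connected central regulators, defined by z-transformed
#' connectivity `C_i >= hub_threshold`; the boundary value is included.
#'
#' @param stats A `degree_stats` object from [connectivity_zscores()].
#' @param hub_threshold Z-score cutoff; default 2.5, the standard hub
#'   definition over the degree distribution of the interaction graph.
#' @return Character vector of hub node names.
#' @export
detect_hubs <- function(stats, hub_threshold = 2.5) {
  stopifnot(inherits(stats, "degree_stats"))
  names(stats$z)[stats$z >= hub_threshold]
}
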