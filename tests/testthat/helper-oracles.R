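# Independent brute-force oracles. These deliberately avoid the code paths
# they check: betweenness is recomputed by per-source BFS path counting
# (not igraph), mutual information by tabulating the joint distribution,
# and attractors by explicit state-graph cycle detection via strong
# components, with successors evaluated from the rule expressions rather
# than the compiled truth tables.

# --- shortest-path betweenness ------------------------------------------

# dist and shortest-path counts from source s over an out-adjacency list
bfs_path_counts <- function(adj, s, n) {
  dist <- rep(Inf, n)
  sigma <- numeric(n)
  dist[s] <- 0
  sigma[s] <- 1
  frontier <- s
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (is.infinite(dist[v])) {
          dist[v] <- dist[u] + 1
          nxt <- c(nxt, v)
        }
        if (dist[v] == dist[u] + 1) sigma[v] <- sigma[v] + sigma[u]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

oracle_betweenness <- function(graph) {
  n <- igraph::vcount(graph)
  adj <- lapply(seq_len(n), function(u) {
    nb <- as.integer(igraph::neighbors(graph, u, mode = "out"))
    setdiff(nb, u)  # self-loops never lie on a shortest path
  })
  per_source <- lapply(seq_len(n), function(s) bfs_path_counts(adj, s, n))
  vb <- numeric(n)
  for (s in seq_len(n)) {
    ds <- per_source[[s]]
    for (t in seq_len(n)) {
      if (t == s || is.infinite(ds$dist[t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        dv <- per_source[[v]]
        if (ds$dist[v] + dv$dist[t] == ds$dist[t]) {
          vb[v] <- vb[v] + ds$sigma[v] * dv$sigma[t] / ds$sigma[t]
        }
      }
    }
  }
  names(vb) <- igraph::V(graph)$name
  vb
}

# --- mutual information from the joint distribution ---------------------

oracle_mutual_information <- function(net, g, h) {
  rule <- net$rules[[h]]
  k <- length(rule$inputs)
  j <- match(g, rule$inputs)
  joint <- matrix(0, nrow = 2, ncol = 2)  # rows x_g, cols f_h
  for (b in 0:(2^k - 1)) {
    bits <- as.integer(bitwAnd(bitwShiftR(b, seq_len(k) - 1L), 1L))
    names(bits) <- rule$inputs
    f <- eval_rule_expr(rule$expr, bits)
    joint[bits[[j]] + 1L, f + 1L] <- joint[bits[[j]] + 1L, f + 1L] + 1
  }
  p <- joint / sum(joint)
  px <- rowSums(p)
  py <- colSums(p)
  mi <- 0
  for (x in 1:2) {
    for (y in 1:2) {
      if (p[x, y] > 0) {
        mi <- mi + p[x, y] * log2(p[x, y] / (px[x] * py[y]))
      }
    }
  }
  mi
}

# expression-tree evaluation, bypassing compiled truth tables
eval_rule_expr <- function(expr, bits) {
  switch(expr$type,
    const = expr$value,
    var = unname(bits[[expr$name]]),
    not = 1L - eval_rule_expr(expr$arg, bits),
    and = as.integer(all(vapply(expr$args, eval_rule_expr, 0L, bits = bits) == 1L)),
    or = as.integer(any(vapply(expr$args, eval_rule_expr, 0L, bits = bits) == 1L))
  )
}

# --- attractors via the explicit state-transition graph -----------------

# Successor of every state computed from rule expressions; returns 1-based
# codes like the package's internal map, but by an independent route.
oracle_successors <- function(net) {
  n <- length(net$nodes)
  vapply(0:(2^n - 1L), function(code) {
    bits <- as.integer(bitwAnd(bitwShiftR(code, seq_len(n) - 1L), 1L))
    names(bits) <- net$nodes
    nxt <- vapply(net$nodes, function(h) {
      eval_rule_expr(net$rules[[h]]$expr, bits)
    }, integer(1))
    as.integer(sum(nxt * 2^(seq_len(n) - 1L)) + 1L)
  }, integer(1))
}

# Attractors as a set of sorted 0-based state-code vectors: strong
# components of the state graph that are closed cycles.
oracle_attractors <- function(net) {
  succ <- oracle_successors(net)
  g <- igraph::graph_from_edgelist(
    cbind(seq_along(succ), succ), directed = TRUE)
  comp <- igraph::components(g, mode = "strong")
  keys <- character(0)
  for (id in seq_len(comp$no)) {
    members <- which(comp$membership == id)
    if (length(members) > 1L || succ[members] == members) {
      keys <- c(keys, paste(sort(members - 1L), collapse = ","))
    }
  }
  sort(keys)
}

attractor_keys <- function(aset) {
  sort(vapply(aset$attractors, function(a) {
    paste(sort(a$codes), collapse = ",")
  }, ""))
}

# random directed test graphs: interaction graphs of random Boolean networks
random_digraph <- function(n, k, seed) {
  build_interaction_graph(random_boolean_network(n, k, seed = seed))
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
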