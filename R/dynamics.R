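#' Synchronous update step
#'
#' Computes `x(t+1) = f(x(t))`: every node's next value is read from its
#' truth table using the *current* values of its inputs, all nodes updating
#' simultaneously.
#'
#' @param net A `boolean_network`.
#' @param state Integer 0/1 vector of length `n`, position `i` the activity
#'   of node `i`.
#' @return The successor state, same shape, named by node.
#' @examples
#' net <- fixture("toggle")
#' synchronous_step(net, c(0, 1))
#' @export
synchronous_step <- function(net, state) {
  validate_boolean_network(net)
  n <- length(net$nodes)
  if (length(state) != n || !all(state %in% c(0L, 1L))) {
    bn_stop(sprintf("state must be a 0/1 vector of length %d", n),
            "bn_domain_error")
  }
  state <- as.integer(state)
  names(state) <- net$nodes
  nxt <- vapply(net$nodes, function(h) {
    rule <- net$rules[[h]]
    idx <- sum(state[rule$inputs] * bitwShiftL(1L, seq_along(rule$inputs) - 1L))
    rule$table[[idx + 1L]]
  }, integer(1))
  nxt
}

# Successor of every state, as a 1-based index vector over the 2^n state
# codes (node i = bit i-1). Fully vectorized; the workhorse of the oracle.
transition_map <- function(net) {
  n <- length(net$nodes)
  states <- 0:(2^n - 1L)
  succ <- integer(2^n)
  for (i in seq_len(n)) {
    rule <- net$rules[[net$nodes[[i]]]]
    idx <- rep(0L, 2^n)
    for (j in seq_along(rule$inputs)) {
      pos <- match(rule$inputs[[j]], net$nodes)
      bit <- bitwAnd(bitwShiftR(states, pos - 1L), 1L)
      idx <- idx + bitwShiftL(bit, j - 1L)
    }
    succ <- succ + bitwShiftL(rule$table[idx + 1L], i - 1L)
  }
  succ + 1L
}

decode_states <- function(codes, n) {
  m <- vapply(seq_len(n), function(i) bitwAnd(bitwShiftR(codes, i - 1L), 1L),
              integer(length(codes)))
  matrix(m, nrow = length(codes), ncol = n)
}

# Rotate a cycle of state codes so the lexicographically smallest state
# (compared coordinate-wise in node order) comes first.
canonical_rotation <- function(codes, n) {
  if (length(codes) == 1L) return(codes)
  m <- decode_states(codes, n)
  start <- do.call(order, c(lapply(seq_len(n), function(j) m[, j]),
                            list(decreasing = FALSE)))[1L]
  codes[c(start:length(codes), seq_len(start - 1L))[seq_along(codes)]]
}

#' Exhaustive synchronous attractor search
#'
#' Enumerates all `2^n` states, computes the synchronous successor map, and
#' finds every attractor (fixed point or cycle) by pointer doubling: the
#' successor map is composed with itself `n` times, after which every state
#' has been projected onto its attractor cycle. Each attractor is returned in
#' canonical rotation (lexicographically smallest state first) together with
#' its basin size; basin sizes sum to `2^n`. The cost grows exponentially in
#' `n`, which is precisely why the static screening exists — this engine is
#' a validation device for small networks, not a production path, and
#' refuses networks above `max_nodes`.
#'
#' @param net A `boolean_network`.
#' @param max_nodes Hard cap on network size (default 20, about 10^6 states).
#' @return An object of class `bn_attractor_set`: list with `nodes`,
#'   `attractors` (each a list with `codes`, `states` matrix — rows are
#'   cycle states in temporal order — and `basin_size`).
#' @examples
#' aset <- find_attractors(fixture("toggle"))
#' length(aset$attractors)  # two fixed points and one 2-cycle
#' @export
find_attractors <- function(net, max_nodes = 20L) {
  validate_boolean_network(net)
  n <- length(net$nodes)
  if (n > max_nodes) {
    bn_stop(sprintf(
      "network has %d nodes; exhaustive attractor search is capped at %d (2^%d states). Raise max_nodes only if you can afford ~2^%d state evaluations, or screen statically with score_nodes()/classify().",
      n, max_nodes, max_nodes, n
    ), "bn_capacity_error")
  }
  succ <- transition_map(net)

  # After n doublings the composed map covers >= 2^n steps, past any
  # transient tail, so every state lands on its attractor cycle.
  final <- succ
  for (i in seq_len(n)) final <- final[final]

  cycle_states <- sort(unique(final))
  attr_id <- integer(length(succ))
  attractors <- list()
  for (code1 in cycle_states) {
    if (attr_id[[code1]] != 0L) next
    cyc <- code1
    cur <- succ[[code1]]
    while (cur != code1) {
      cyc <- c(cyc, cur)
      cur <- succ[[cur]]
    }
    id <- length(attractors) + 1L
    attr_id[cyc] <- id
    attractors[[id]] <- canonical_rotation(cyc - 1L, n)
  }

  basin <- tabulate(attr_id[final], nbins = length(attractors))
  structure(
    list(
      nodes = net$nodes,
      attractors = lapply(seq_along(attractors), function(i) {
        codes <- attractors[[i]]
        states <- decode_states(codes, n)
        colnames(states) <- net$nodes
        list(codes = codes, states = states, basin_size = basin[[i]])
      })
    ),
    class = "bn_attractor_set"
  )
}

#' @export
print.bn_attractor_set <- function(x, ...) {
  cat(sprintf("%d attractor(s) over %d nodes (%s)\n",
              length(x$attractors), length(x$nodes),
              paste(x$nodes, collapse = ", ")))
  for (i in seq_along(x$attractors)) {
    a <- x$attractors[[i]]
    kind <- if (nrow(a$states) == 1L) "fixed point" else
      sprintf("cycle of length %d", nrow(a$states))
    cat(sprintf("  [%d] %s, basin %d: %s\n", i, kind, a$basin_size,
                paste(apply(a$states, 1L, paste, collapse = ""),
                      collapse = " -> ")))
  }
  invisible(x)
}

#' Fix a node by knockout or overexpression
#'
#' Returns a copy of the network in which the perturbed node's rule is the
#' constant 0 (knockout) or 1 (overexpression), with its inputs removed; all
#' other rules are untouched. Applying the same perturbation twice is
#' idempotent.
#'
#' @param net A `boolean_network`.
#' @param node Name of the node to fix.
#' @param value 0 for knockout, 1 for overexpression.
#' @return The perturbed `boolean_network`.
#' @export
apply_perturbation <- function(net, node, value) {
  validate_boolean_network(net)
  if (!node %in% net$nodes) {
    bn_stop(sprintf("unknown node '%s'", node), "bn_domain_error")
  }
  if (!value %in% c(0L, 1L)) {
    bn_stop("perturbation value must be 0 (knockout) or 1 (overexpression)",
            "bn_domain_error")
  }
  expr <- bn_const(value)
  net$rules[[node]] <- list(inputs = character(0), expr = expr,
                            table = as.integer(value))
  net
}

#' Attractor-landscape impact of a perturbation
#'
#' Compares the attractor sets before and after a perturbation. Attractor
#' identity is equality of full-state sets (all `n` coordinates, the
#' perturbed node's fixed coordinate included). Reports the fraction of
#' original attractors lost, the number of new attractors, and for each new
#' attractor the minimal Hamming distance from any of its states to any
#' state of any original attractor. A perturbation with high dynamic impact
#' loses many original attractors while creating new ones far (in Hamming
#' distance) from everything seen before, i.e. it reshapes the phenotype
#' landscape.
#'
#' @param original,perturbed `bn_attractor_set` objects over the same nodes.
#' @return A list of class `bn_impact` with `fraction_lost` in `[0, 1]`,
#'   `n_new`, and `min_hamming` (integer vector, one entry per new attractor).
#' @examples
#' net <- fixture("toggle")
#' impact_metrics(find_attractors(net),
#'                find_attractors(apply_perturbation(net, "A", 0)))
#' @export
impact_metrics <- function(original, perturbed) {
  stopifnot(inherits(original, "bn_attractor_set"),
            inherits(perturbed, "bn_attractor_set"))
  if (!identical(original$nodes, perturbed$nodes)) {
    bn_stop("attractor sets are over different node universes",
            "bn_domain_error")
  }
  key <- function(a) paste(sort(a$codes), collapse = ",")
  orig_keys <- vapply(original$attractors, key, "")
  pert_keys <- vapply(perturbed$attractors, key, "")

  lost <- !(orig_keys %in% pert_keys)
  new <- !(pert_keys %in% orig_keys)
  orig_codes <- unlist(lapply(original$attractors, `[[`, "codes"))

  min_hamming <- vapply(which(new), function(i) {
    codes <- perturbed$attractors[[i]]$codes
    min(vapply(codes, function(c1) {
      min(popcount(bitwXor(c1, orig_codes)))
    }, integer(1)))
  }, integer(1))

  structure(
    list(
      fraction_lost = sum(lost) / length(orig_keys),
      n_new = sum(new),
      min_hamming = min_hamming
    ),
    class = "bn_impact"
  )
}

#' @export
print.bn_impact <- function(x, ...) {
  cat(sprintf(
    "Perturbation impact: %.1f%% of original attractors lost, %d new attractor(s)%s\n",
    100 * x$fraction_lost, x$n_new,
    if (x$n_new > 0L) {
      sprintf(" (min Hamming distances: %s)",
              paste(x$min_hamming, collapse = ", "))
    } else ""
  ))
  invisible(x)
}

popcount <- function(x) {
  count <- integer(length(x))
  while (any(x > 0L)) {
    count <- count + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  count
}

#' Export attractors as JSON
#'
#' Serializes an attractor set as a JSON array of attractors, each a list of
#' bit-strings in node order (first character = first node).
#'
#' @param aset A `bn_attractor_set`.
#' @param file Optional path to write to.
#' @return The JSON string, invisibly when `file` is given.
#' @export
attractors_to_json <- function(aset, file = NULL) {
  stopifnot(inherits(aset, "bn_attractor_set"))
  payload <- list(
    nodes = aset$nodes,
    attractors = lapply(aset$attractors, function(a) {
      list(
        states = apply(a$states, 1L, paste, collapse = ""),
        basin_size = a$basin_size
      )
    })
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(json, file)
    return(invisible(json))
  }
  json
}
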