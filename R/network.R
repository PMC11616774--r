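#' Boolean network objects
#'
#' A `boolean_network` holds an ordered set of node names and, for each node,
#' an update rule: an ordered list of distinct input nodes, a Boolean
#' expression over exactly those inputs, and the compiled truth table. The
#' system evolves as `x(t+1) = f(x(t))` under synchronous update.
#'
#' The truth-table bit order is fixed: the first listed input is the
#' least-significant bit, so `table[b + 1]` is the rule value when input `j`
#' carries bit `j` of `b`. Constant (input-less) rules have a length-1 table.
#'
#' @param nodes Character vector of unique, non-empty node names.
#' @param rules Named list (one entry per node, same order) of lists with
#'   elements `inputs` (character), `expr` (expression tree), `table`
#'   (integer vector of length `2^length(inputs)`).
#' @return An object of class `boolean_network`.
#' @keywords internal
new_boolean_network <- function(nodes, rules) {
  net <- structure(list(nodes = nodes, rules = rules),
                   class = "boolean_network")
  validate_boolean_network(net)
  net
}

validate_boolean_network <- function(net) {
  nodes <- net$nodes
  if (length(nodes) == 0L || anyDuplicated(nodes) || any(!nzchar(nodes))) {
    bn_stop("node names must be unique and non-empty", "bn_invalid_network")
  }
  if (!identical(names(net$rules), nodes)) {
    bn_stop("rules must be named by, and ordered as, the node names",
            "bn_invalid_network")
  }
  for (name in nodes) {
    rule <- net$rules[[name]]
    k <- length(rule$inputs)
    if (anyDuplicated(rule$inputs) ||
        !all(rule$inputs %in% nodes)) {
      bn_stop(sprintf("rule for '%s' has invalid inputs", name),
              "bn_invalid_network")
    }
    if (length(rule$table) != 2^k ||
        !all(rule$table %in% c(0L, 1L))) {
      bn_stop(sprintf("rule for '%s' has a malformed truth table", name),
              "bn_invalid_network")
    }
    vars <- expr_variables(rule$expr)
    if (!all(vars %in% rule$inputs)) {
      bn_stop(sprintf("rule expression for '%s' references a non-input", name),
              "bn_symbol_error")
    }
  }
  invisible(net)
}

#' Compile a Boolean expression to a truth table
#'
#' Evaluates `expr` on every assignment of the ordered `inputs`. Entry
#' `b + 1` of the result corresponds to assignment `b` in `0:(2^k - 1)`,
#' with the first listed input as the least-significant bit.
#'
#' @param expr A Boolean expression tree as produced by the model parsers.
#' @param inputs Character vector of input node names, in bit order.
#' @return Integer vector of 0/1 values of length `2^length(inputs)`.
#' @examples
#' net <- parse_boolnet("targets, factors\nA, B\nB, A")
#' compile_truth_table(net$rules$A$expr, "B")
#' @export
compile_truth_table <- function(expr, inputs) {
  extra <- setdiff(expr_variables(expr), inputs)
  if (length(extra) > 0L) {
    bn_stop(sprintf("unresolved symbol '%s' in rule expression", extra[[1L]]),
            "bn_symbol_error")
  }
  k <- length(inputs)
  vapply(0:(2^k - 1), function(b) {
    values <- as.integer(bitwAnd(bitwShiftR(b, seq_len(k) - 1L), 1L))
    names(values) <- inputs
    eval_expr(expr, as.list(values))
  }, integer(1))
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Boolean network: %d nodes\n", length(x$nodes)))
  for (name in x$nodes) {
    cat(sprintf("  %s, %s\n", name, deparse_expr(x$rules[[name]]$expr)))
  }
  invisible(x)
}

# Internal constructor from (name, expression) pairs; compiles tables and
# checks that every referenced node has a rule.
network_from_expressions <- function(nodes, exprs) {
  rules <- vector("list", length(nodes))
  names(rules) <- nodes
  for (i in seq_along(nodes)) {
    expr <- exprs[[i]]
    inputs <- expr_variables(expr)
    undefined <- setdiff(inputs, nodes)
    if (length(undefined) > 0L) {
      bn_stop(
        sprintf("rule for '%s' references undefined node '%s'",
                nodes[[i]], undefined[[1L]]),
        "bn_symbol_error"
      )
    }
    rules[[i]] <- list(
      inputs = inputs,
      expr = expr,
      table = compile_truth_table(expr, inputs)
    )
  }
  new_boolean_network(nodes, rules)
}
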