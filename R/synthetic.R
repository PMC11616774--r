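#' Generate a random N-K Boolean network
#'
#' Classic random Boolean network construction for testing and calibration:
#' each of the `n` nodes draws `k` distinct inputs uniformly without
#' replacement (self-inputs allowed, as real regulatory models routinely
#' contain self-loops) and an i.i.d. Bernoulli(`bias`) truth table over its
#' `2^k` input assignments. The rule expression is synthesized from the table
#' as minterm DNF, so generated networks satisfy every `boolean_network`
#' invariant and round-trip through [write_boolnet()]/[parse_boolnet()].
#' With `bias` 0 or 1 all rules are constant and the dynamics have a single
#' fixed point.
#'
#' Randomness is seed-threaded: a supplied `seed` is used inside a local RNG
#' scope and the caller's `.Random.seed` is restored, so identical seeds give
#' identical networks and no global state leaks.
#'
#' @param n Number of nodes.
#' @param k Inputs per node, `1 <= k <= n`.
#' @param bias Probability that a truth-table entry is 1 (default 0.5).
#' @param seed Optional integer seed.
#' @return A `boolean_network` with nodes `N1 ... Nn`.
#' @examples
#' net <- random_boolean_network(5, 2, seed = 1)
#' identical(net, random_boolean_network(5, 2, seed = 1))
#' @export
random_boolean_network <- function(n, k, bias = 0.5, seed = NULL) {
  if (!is.numeric(n) || n < 1L || !is.numeric(k) || k < 1L || k > n) {
    bn_stop("need 1 <= k <= n", "bn_domain_error")
  }
  if (!is.numeric(bias) || bias < 0 || bias > 1) {
    bn_stop("bias must lie in [0, 1]", "bn_domain_error")
  }
  n <- as.integer(n)
  k <- as.integer(k)
  with_preserved_seed(seed, {
    nodes <- sprintf("N%d", seq_len(n))
    rules <- lapply(seq_len(n), function(i) {
      inputs <- nodes[sample.int(n, k)]
      table <- as.integer(stats::rbinom(2^k, 1L, bias))
      if (all(table == table[[1L]])) {
        # a constant table has no real regulators; normalize to an
        # input-less rule so text round-trips are exact
        inputs <- character(0)
        table <- table[[1L]]
      }
      expr <- expr_from_table(table, inputs)
      list(inputs = inputs, expr = expr, table = table)
    })
    names(rules) <- nodes
    new_boolean_network(nodes, rules)
  })
}

with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Curated example networks
#'
#' Small hand-written networks shipped as BoolNet text files:
#' \describe{
#'   \item{toggle}{two nodes copying each other (`A = B`, `B = A`).}
#'   \item{negator}{one self-inhibiting node, a period-2 oscillator.}
#'   \item{chain3}{linear chain `a -> b -> c`.}
#'   \item{diamond}{two equal-length paths `a -> d` through `b` and `c`.}
#'   \item{star8}{a hub feeding eight leaves; the classic high-degree node.}
#'   \item{bottleneck12}{two dense clusters joined only through one sparse
#'     bridge node, engineered so the bridge tops both vertex betweenness
#'     and determinative power while ranking low on connectivity — the
#'     archetypal gatekeeper.}
#' }
#'
#' @param name One of the catalogue names above.
#' @return A `boolean_network`.
#' @examples
#' fixture("toggle")
#' @export
fixture <- function(name) {
  catalogue <- c("toggle", "negator", "chain3", "diamond", "star8",
                 "bottleneck12")
  if (!is.character(name) || length(name) != 1L || !name %in% catalogue) {
    bn_stop(sprintf("unknown fixture '%s'; available: %s",
                    paste(name, collapse = ","),
                    paste(catalogue, collapse = ", ")),
            "bn_lookup_error")
  }
  path <- system.file("extdata", paste0(name, ".bn"), package = "bnscreen",
                      mustWork = TRUE)
  parse_boolnet(path)
}
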