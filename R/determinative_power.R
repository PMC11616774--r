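#' Binary Shannon entropy
#'
#' `H(p) = -p log2(p) - (1 - p) log2(1 - p)` in bits, with `0 log2(0) := 0`.
#'
#' @param p Probability (vectorized), each in `[0, 1]`.
#' @return Entropy in bits, in `[0, 1]`.
#' @examples
#' binary_entropy(c(0, 0.25, 0.5, 1))
#' @export
binary_entropy <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    bn_stop("binary_entropy requires probabilities in [0, 1]",
            "bn_domain_error")
  }
  term <- function(q) ifelse(q == 0, 0, -q * log2(q))
  term(p) + term(1 - p)
}

#' Mutual information between a regulator and a target's update function
#'
#' Quantifies, in bits, how much knowing the state of regulator `g` reduces
#' uncertainty about the next state of `h`:
#' `MI(x_g; f_h) = H(f_h) - H(f_h | x_g)` with
#' `H(f_h | x_g) = (H(f_h | x_g = 0) + H(f_h | x_g = 1)) / 2`. All
#' probabilities are computed by exhaustive enumeration of `h`'s truth table
#' under independent uniform Bernoulli(1/2) inputs, so no dynamics are
#' evaluated. The value lies in `[0, 1]`; it is 1 when `f_h` copies (or
#' negates) `x_g` alone, and 0 when `f_h` is independent of `x_g` — e.g. an
#' XOR input, or a syntactic input the function does not actually depend on.
#'
#' @param net A `boolean_network`.
#' @param g Name of a regulator; must be an input of `h`'s rule.
#' @param h Name of the target node.
#' @return Mutual information in bits.
#' @examples
#' net <- parse_boolnet("targets, factors\nA, A\nB, A & C\nC, C")
#' mutual_information(net, "A", "B")  # H(1/4) - 1/2
#' @export
mutual_information <- function(net, g, h) {
  validate_boolean_network(net)
  if (!h %in% net$nodes || !g %in% net$nodes) {
    bn_stop("unknown node name", "bn_domain_error")
  }
  rule <- net$rules[[h]]
  j <- match(g, rule$inputs)
  if (is.na(j)) {
    bn_stop(sprintf("'%s' is not an input of the rule for '%s'", g, h),
            "bn_domain_error")
  }
  table <- rule$table
  b <- 0:(length(table) - 1L)
  g_bit <- bitwAnd(bitwShiftR(b, j - 1L), 1L)

  p1 <- mean(table)
  p1_g0 <- mean(table[g_bit == 0L])
  p1_g1 <- mean(table[g_bit == 1L])
  mi <- binary_entropy(p1) -
    0.5 * (binary_entropy(p1_g0) + binary_entropy(p1_g1))
  max(mi, 0)  # clip the negative epsilon of floating-point cancellation
}

#' Determinative power of a node
#'
#' The sum, over every node `h` whose rule lists `g` as an input (self-loops
#' included), of `MI(x_g; f_h)`: the total information, in bits, that the
#' state of `g` carries about the update functions of its targets. Nodes that
#' regulate nothing have DP 0. Because a non-essential syntactic input
#' contributes MI = 0, no essentiality pruning is needed, and DP does not
#' depend on the order in which a rule lists its inputs.
#'
#' @param net A `boolean_network`.
#' @param g Node name, or a character vector of names.
#' @return Named numeric vector of DP values in bits.
#' @examples
#' net <- parse_boolnet("targets, factors\nA, B\nB, A")
#' determinative_power(net, "A")  # one identity target: 1 bit
#' @export
determinative_power <- function(net, g = net$nodes) {
  validate_boolean_network(net)
  unknown <- setdiff(g, net$nodes)
  if (length(unknown) > 0L) {
    bn_stop(sprintf("unknown node '%s'", unknown[[1L]]), "bn_domain_error")
  }
  dp <- vapply(g, function(gi) {
    total <- 0
    for (h in net$nodes) {
      if (gi %in% net$rules[[h]]$inputs) {
        total <- total + mutual_information(net, gi, h)
      }
    }
    total
  }, numeric(1))
  names(dp) <- g
  dp
}
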