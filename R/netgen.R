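#' Generate a random Boolean network
#'
#' Draws the wiring of an N-K-style random Boolean network as used for gene
#' regulatory network modelling: each node receives 1 or 2 incoming edges
#' (arity drawn uniformly), input nodes are sampled uniformly without
#' replacement from all `n` nodes (self-inputs allowed), and the logic
#' operator is drawn uniformly among the regime's operators of that arity.
#' Discrete-regime binary operators are AND, OR, XOR; continuous-regime
#' binary operators are OR and AND NOT (`A AND (NOT B)`). Unary rules are
#' COPY or NOT in both regimes. Outgoing edges are left emergent and
#' unconstrained, so some nodes may regulate nothing (out-degree 0) while
#' others become highly regulated hubs.
#'
#' @param n number of nodes (genes); must be >= 1. With `n = 1` only the
#'   self-loop is available as an input.
#' @param regime `"discrete"` or `"continuous"`; selects the operator menu.
#' @param seed optional integer; when given, generation is a pure function
#'   of `(n, regime, seed)` and the caller's RNG stream is untouched.
#' @return a [boolean_network()] in which every node has in-degree 1 or 2.
#' @examples
#' net <- generate_ruleset(10, "discrete", seed = 1)
#' table(in_degrees(net))
#' @export
generate_ruleset <- function(n, regime = c("discrete", "continuous"),
                             seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != floor(n)) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  regime <- match.arg(regime)
  n <- as.integer(n)
  with_seed_(seed, {
    rules <- lapply(seq_len(n), function(i) random_rule_(i, n, regime))
    boolean_network(rules, regime = regime)
  })
}

random_rule_ <- function(target, n, regime) {
  arity <- if (n < 2L) 1L else sample(2L, 1L)
  inputs <- sample.int(n, arity)  # without replacement, random order
  if (arity == 1L) {
    op <- sample(OPS_UNARY, 1L)
    logic_rule(target, "LINK", inputs, neg = (op == "NOT"))
  } else {
    op <- sample(OPS_BINARY[[regime]], 1L)
    if (op == "ANDNOT") {
      logic_rule(target, "AND", inputs, neg = c(FALSE, TRUE))
    } else {
      logic_rule(target, op, inputs, neg = c(FALSE, FALSE))
    }
  }
}
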