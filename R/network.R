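# Flat rule representation. Every rule is one of
#   CONST            -- no inputs; the node holds its current value
#   LINK  (1 input)  -- COPY when neg = FALSE, NOT when neg = TRUE
#   AND/OR/XOR (2)   -- per-leaf negation flags; AND with neg = c(FALSE, TRUE)
#                       is the "A AND NOT B" template of the continuous menu
OPS_UNARY <- c("COPY", "NOT")
OPS_BINARY <- list(
  discrete   = c("AND", "OR", "XOR"),
  continuous = c("OR", "ANDNOT")
)

#' Construct a logic rule
#'
#' A rule drives one node of a Boolean network. Rules are stored in a flat
#' form: an operator (`CONST`, `LINK`, `AND`, `OR`, `XOR`), 0-2 input node
#' indices, and one negation flag per input (a negated leaf means `NOT Gj`).
#' A `LINK` rule with `neg = FALSE` is a plain copy of its input; with
#' `neg = TRUE` it is a negation. An `AND` rule with one negated leaf
#' realizes the `A AND NOT B` template used by continuous-regime networks.
#' A `CONST` rule has no inputs and holds the node at its current value; it
#' arises from lesioning, never from generation.
#'
#' @param target node index (1-based) that the rule drives.
#' @param op one of `"CONST"`, `"LINK"`, `"AND"`, `"OR"`, `"XOR"`.
#' @param inputs integer vector of input node indices; length must match the
#'   operator arity (0 for `CONST`, 1 for `LINK`, 2 otherwise).
#' @param neg logical vector, one flag per input; `TRUE` negates that leaf.
#' @return an object of class `logic_rule`.
#' @export
logic_rule <- function(target, op, inputs = integer(0),
                       neg = rep(FALSE, length(inputs))) {
  op <- match.arg(op, c("CONST", "LINK", "AND", "OR", "XOR"))
  inputs <- as.integer(inputs)
  neg <- as.logical(neg)
  arity <- switch(op, CONST = 0L, LINK = 1L, 2L)
  if (length(inputs) != arity) {
    stop(sprintf("operator %s takes %d input(s), got %d", op, arity,
                 length(inputs)), call. = FALSE)
  }
  if (length(neg) != length(inputs) || anyNA(neg)) {
    stop("`neg` must be one non-NA flag per input", call. = FALSE)
  }
  if (anyNA(inputs) || any(inputs < 1L)) {
    stop("input indices must be positive integers", call. = FALSE)
  }
  structure(list(target = as.integer(target)[1], op = op,
                 inputs = inputs, neg = neg),
            class = "logic_rule")
}

#' Construct a Boolean network
#'
#' @param rules list of [logic_rule()] objects; rule `i` must drive node `i`.
#' @param regime `"discrete"` (operators AND/OR/XOR/NOT/COPY) or
#'   `"continuous"` (AND NOT/OR/NOT/COPY, convertible to an SDE model).
#' @return an object of class `boolean_network` with fields `n`, `rules`,
#'   `regime`.
#' @export
boolean_network <- function(rules, regime = c("discrete", "continuous")) {
  regime <- match.arg(regime)
  n <- length(rules)
  if (n < 1) stop("a network needs at least one rule", call. = FALSE)
  for (i in seq_len(n)) {
    r <- rules[[i]]
    if (!inherits(r, "logic_rule")) {
      stop(sprintf("rules[[%d]] is not a logic_rule", i), call. = FALSE)
    }
    if (r$target != i) {
      stop(sprintf("rule %d has target %d; rule i must drive node i",
                   i, r$target), call. = FALSE)
    }
    if (any(r$inputs > n)) {
      stop(sprintf("rule %d references node outside [1, %d]", i, n),
           call. = FALSE)
    }
  }
  structure(list(n = n, rules = rules, regime = regime),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Boolean network: %d nodes, %s regime\n", x$n, x$regime))
  cat(serialize_ruleset(x), sep = "\n")
  invisible(x)
}

#' Network degree statistics
#'
#' `in_degrees()` counts the inputs of each node's rule (0 after lesioning,
#' otherwise 1-2); `out_degrees()` counts, for each node, in how many rules
#' it appears as an input (unconstrained, may be 0); `edge_count()` is the
#' total number of edges, i.e. the sum of in-degrees.
#'
#' @param net a [boolean_network()].
#' @return integer vector of length `net$n` (or a single count).
#' @export
in_degrees <- function(net) {
  vapply(net$rules, function(r) length(r$inputs), integer(1))
}

#' @rdname in_degrees
#' @export
out_degrees <- function(net) {
  tabulate(unlist(lapply(net$rules, `[[`, "inputs")), nbins = net$n)
}

#' @rdname in_degrees
#' @export
edge_count <- function(net) sum(in_degrees(net))
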