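#' Specify a lesion condition
#'
#' A lesion removes all incoming edges (type 1) or all incoming and
#' outgoing edges (type 2) of a set of nodes. Cut conditions run in
#' 10%-of-nodes increments: at 30% on a 10-node network exactly 3 nodes
#' are lesioned; 0% leaves the network as generated; 100% isolates every
#' node.
#'
#' @param lesion_type `"type1"` (incoming edges only, outgoing preserved)
#'   or `"type2"` (incoming and outgoing edges cut).
#' @param cut_percent integer in `{0, 10, ..., 100}`.
#' @param lesioned_nodes distinct node indices; must number
#'   `cut_percent/100 * n` (see [select_lesion_nodes()]).
#' @return an object of class `lesion_spec`.
#' @export
lesion_spec <- function(lesion_type = c("type1", "type2"), cut_percent,
                        lesioned_nodes) {
  lesion_type <- match.arg(lesion_type)
  check_cut_percent_(cut_percent)
  lesioned_nodes <- sort(unique(as.integer(lesioned_nodes)))
  structure(list(lesion_type = lesion_type,
                 cut_percent = as.integer(cut_percent),
                 lesioned_nodes = lesioned_nodes),
            class = "lesion_spec")
}

check_cut_percent_ <- function(cut_percent) {
  ok <- is.numeric(cut_percent) && length(cut_percent) == 1 &&
    !is.na(cut_percent) && cut_percent >= 0 && cut_percent <= 100 &&
    cut_percent %% 10 == 0
  if (!ok) {
    stop("`cut_percent` must be one of 0, 10, ..., 100", call. = FALSE)
  }
  invisible(TRUE)
}

#' Draw the nodes to lesion for a cut condition
#'
#' Uniformly random subset, without replacement, of size
#' `cut_percent/100 * n`.
#'
#' @param n node count.
#' @param cut_percent integer in `{0, 10, ..., 100}`.
#' @param seed optional integer for a self-contained draw.
#' @return sorted integer vector of node indices (empty at 0%, all nodes
#'   at 100%).
#' @export
select_lesion_nodes <- function(n, cut_percent, seed = NULL) {
  check_cut_percent_(cut_percent)
  size <- as.integer(round(cut_percent / 100 * n))
  with_seed_(seed, sort(sample.int(n, size)))
}

#' Apply a lesion to a Boolean network
#'
#' Returns a new network; the input is unchanged. For both types, each
#' lesioned node's rule becomes the zero-input `CONST` rule, so the node
#' holds its (randomly drawn) initial state for the whole run. Type-2
#' lesioning additionally deletes every occurrence of a lesioned node as
#' an input of surviving rules: a binary rule losing one operand collapses
#' to the single-input rule on the remaining operand, preserving that
#' leaf's negation (so `A AND NOT B` losing `B` becomes `COPY A`, and
#' losing `A` becomes `NOT B`); a rule losing all inputs becomes `CONST`.
#' The operation is idempotent and never increases the edge count.
#'
#' @param net a [boolean_network()].
#' @param spec a [lesion_spec()]; `lesioned_nodes` must lie in `[1, n]`.
#' @return the lesioned [boolean_network()].
#' @examples
#' net <- parse_ruleset(c("G1 = (G2 OR G3)", "G2 = G1", "G3 = (NOT G2)"))
#' spec <- lesion_spec("type2", 30, lesioned_nodes = 2)
#' serialize_ruleset(apply_lesion(net, spec))
#' @export
apply_lesion <- function(net, spec) {
  stopifnot(inherits(net, "boolean_network"), inherits(spec, "lesion_spec"))
  cut <- spec$lesioned_nodes
  if (length(cut) > 0 && (min(cut) < 1 || max(cut) > net$n)) {
    stop(sprintf("lesioned nodes must lie in [1, %d]", net$n), call. = FALSE)
  }
  rules <- net$rules
  for (i in cut) rules[[i]] <- logic_rule(i, "CONST")
  if (spec$lesion_type == "type2" && length(cut) > 0) {
    for (i in seq_len(net$n)) {
      r <- rules[[i]]
      if (r$op == "CONST") next
      keep <- !(r$inputs %in% cut)
      if (all(keep)) next
      rules[[i]] <- if (!any(keep)) {
        logic_rule(i, "CONST")
      } else {
        logic_rule(i, "LINK", r$inputs[keep], r$neg[keep])
      }
    }
  }
  boolean_network(rules, regime = net$regime)
}
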