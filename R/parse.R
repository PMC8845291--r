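#' Parse a plain-text Boolean ruleset
#'
#' Reads the equation dialect used throughout the package: one line per
#' node, `Gi = expr` with `expr := atom | (expr OP expr) | (NOT expr)`,
#' `OP` in AND, OR, XOR (also written `AND NOT`), atoms being gene names
#' `G1..Gn` or the token `CONST` for a rule without inputs. `#` comments
#' and blank lines are ignored. Each gene must be defined exactly once and
#' an expression may reference at most two inputs (nested binary
#' expressions are rejected). Negations are normalized onto the leaves
#' (double negation cancels; a negated AND/OR is rewritten by De Morgan's
#' laws; a negated XOR is not representable and raises a parse error).
#'
#' @param text a character vector of lines, or a single string with
#'   embedded newlines.
#' @param regime regime tag for the resulting network; `"discrete"` unless
#'   stated. Parsing itself is regime-agnostic.
#' @return a [boolean_network()] whose rules evaluate identically to the
#'   written equations.
#' @examples
#' net <- parse_ruleset(c("G1 = (G2 OR G3)", "G2 = (NOT G1)", "G3 = G3"))
#' serialize_ruleset(net)
#' @seealso [serialize_ruleset()], [read_ruleset()]
#' @export
parse_ruleset <- function(text, regime = c("discrete", "continuous")) {
  regime <- match.arg(regime)
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  eqs <- list()
  for (ln in seq_along(text)) {
    line <- sub("#.*$", "", text[[ln]])
    if (!nzchar(trimws(line))) next
    eq_pos <- regexpr("=", line, fixed = TRUE)
    if (eq_pos < 0) {
      stop(sprintf("line %d: expected 'Gi = expression'", ln), call. = FALSE)
    }
    eqs[[length(eqs) + 1L]] <- list(
      lhs = trimws(substr(line, 1L, eq_pos - 1L)),
      rhs = trimws(substr(line, eq_pos + 1L, nchar(line))),
      line = ln
    )
  }
  n <- length(eqs)
  if (n == 0) stop("no equations found", call. = FALSE)
  rules <- vector("list", n)
  for (eq in eqs) {
    i <- gene_index_(eq$lhs, n, eq$line)
    if (!is.null(rules[[i]])) {
      stop(sprintf("line %d: %s defined more than once", eq$line, eq$lhs),
           call. = FALSE)
    }
    rules[[i]] <- parse_expression_(eq$rhs, target = i, n = n, line = eq$line)
  }
  boolean_network(rules, regime = regime)
}

gene_index_ <- function(name, n, line) {
  m <- regmatches(name, regexec("^G([0-9]+)$", name))[[1]]
  idx <- if (length(m) == 2) as.integer(m[2]) else NA_integer_
  if (is.na(idx) || idx < 1L || idx > n) {
    stop(sprintf("line %d: unknown gene name '%s' (expected G1..G%d)",
                 line, name, n), call. = FALSE)
  }
  idx
}

parse_expression_ <- function(rhs, target, n, line) {
  toks <- tokenize_(rhs, line)
  cur <- new.env(parent = emptyenv())
  cur$toks <- toks
  cur$pos <- 1L
  tree <- parse_expr_(cur, n, line)
  if (cur$pos <= length(cur$toks)) {
    stop(sprintf("line %d: malformed expression, unexpected '%s'",
                 line, cur$toks[cur$pos]), call. = FALSE)
  }
  tree_to_rule_(tree, target, line)
}

tokenize_ <- function(rhs, line) {
  spaced <- gsub("\\)", " ) ", gsub("\\(", " ( ", rhs))
  toks <- strsplit(trimws(spaced), "[[:space:]]+")[[1]]
  if (length(toks) == 0) {
    stop(sprintf("line %d: empty expression", line), call. = FALSE)
  }
  toks
}

peek_ <- function(cur) {
  if (cur$pos > length(cur$toks)) NA_character_ else cur$toks[cur$pos]
}
advance_ <- function(cur) {
  tok <- peek_(cur)
  cur$pos <- cur$pos + 1L
  tok
}

parse_expr_ <- function(cur, n, line) {
  left <- parse_term_(cur, n, line)
  nxt <- peek_(cur)
  if (!is.na(nxt) && nxt %in% c("AND", "OR", "XOR")) {
    advance_(cur)
    right <- parse_term_(cur, n, line)
    return(list(kind = "bin", op = nxt, l = left, r = right))
  }
  left
}

parse_term_ <- function(cur, n, line) {
  tok <- advance_(cur)
  if (is.na(tok)) {
    stop(sprintf("line %d: malformed expression, unexpected end", line),
         call. = FALSE)
  }
  if (tok == "(") {
    e <- parse_expr_(cur, n, line)
    if (!identical(advance_(cur), ")")) {
      stop(sprintf("line %d: malformed expression, missing ')'", line),
           call. = FALSE)
    }
    return(e)
  }
  if (tok == "NOT") {
    return(list(kind = "not", x = parse_term_(cur, n, line)))
  }
  if (tok == "CONST") return(list(kind = "const"))
  if (tok %in% c(")", "AND", "OR", "XOR")) {
    stop(sprintf("line %d: malformed expression near '%s'", line, tok),
         call. = FALSE)
  }
  list(kind = "leaf", idx = gene_index_(tok, n, line))
}

# Normalize a parse tree into the flat rule form, pushing negations to the
# leaves (De Morgan for AND/OR; a negated XOR has no flat equivalent).
norm_tree_ <- function(node, negated, line) {
  switch(node$kind,
    leaf = list(kind = "leaf", idx = node$idx, neg = negated),
    const = {
      if (negated) {
        stop(sprintf("line %d: CONST cannot be negated", line), call. = FALSE)
      }
      list(kind = "const")
    },
    not = norm_tree_(node$x, !negated, line),
    bin = {
      op <- node$op
      if (negated) {
        if (op == "XOR") {
          stop(sprintf("line %d: negated XOR is not representable", line),
               call. = FALSE)
        }
        op <- if (op == "AND") "OR" else "AND"
      }
      l <- norm_tree_(node$l, negated, line)
      r <- norm_tree_(node$r, negated, line)
      if (l$kind != "leaf" || r$kind != "leaf") {
        stop(sprintf(paste0("line %d: expression uses more than two inputs ",
                            "or nested binary operators"), line),
             call. = FALSE)
      }
      list(kind = "bin", op = op, l = l, r = r)
    }
  )
}

tree_to_rule_ <- function(tree, target, line) {
  flat <- norm_tree_(tree, FALSE, line)
  switch(flat$kind,
    const = logic_rule(target, "CONST"),
    leaf = logic_rule(target, "LINK", flat$idx, flat$neg),
    bin = logic_rule(target, flat$op, c(flat$l$idx, flat$r$idx),
                     c(flat$l$neg, flat$r$neg))
  )
}

#' Serialize a Boolean network to the equation dialect
#'
#' Emits one canonical equation per node: `Gi = CONST` for zero-input
#' rules, `Gi = Gj` / `Gi = (NOT Gj)` for single-input rules, and
#' `Gi = (A OP B)` with `(NOT Gj)` leaves for binary rules. The output
#' round-trips through [parse_ruleset()] to an identically evaluating
#' network.
#'
#' @param net a [boolean_network()].
#' @return character vector, one equation per node.
#' @export
serialize_ruleset <- function(net) {
  vapply(net$rules, function(r) {
    lhs <- sprintf("G%d = ", r$target)
    leaf <- function(j) {
      if (r$neg[j]) sprintf("(NOT G%d)", r$inputs[j])
      else sprintf("G%d", r$inputs[j])
    }
    rhs <- switch(r$op,
      CONST = "CONST",
      LINK = leaf(1),
      sprintf("(%s %s %s)", leaf(1), sub("ANDNOT", "AND", r$op), leaf(2))
    )
    paste0(lhs, rhs)
  }, character(1))
}

#' Read or write a ruleset file
#'
#' Plain-text UTF-8 persistence of generated networks, one equation per
#' line in the dialect of [parse_ruleset()].
#'
#' @param path file path.
#' @param regime passed to [parse_ruleset()].
#' @param net a [boolean_network()].
#' @return `read_ruleset()` returns a [boolean_network()];
#'   `write_ruleset()` returns `path` invisibly.
#' @export
read_ruleset <- function(path, regime = c("discrete", "continuous")) {
  parse_ruleset(readLines(path, warn = FALSE), regime = regime)
}

#' @rdname read_ruleset
#' @export
write_ruleset <- function(net, path) {
  writeLines(serialize_ruleset(net), path)
  invisible(path)
}
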