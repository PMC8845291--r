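# Independent oracles used across tests; deliberately implemented through
# different code paths than the package (string tabulation, hand-rolled
# update maps, closed-form roots).

# Joint entropy by pasting rows into strings and tabulating.
oracle_entropy <- function(mat, cols) {
  keys <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
  p <- as.numeric(table(keys)) / length(keys)
  -sum(p * log2(p))
}

oracle_mi <- function(mat, a, b) {
  oracle_entropy(mat, a) + oracle_entropy(mat, b) -
    oracle_entropy(mat, union(a, b))
}

# Hand-written synchronous update for the fixed 3-node test network
#   G1 = (G2 OR G3); G2 = (NOT G1); G3 = (G1 XOR G2)
oracle_step3 <- function(s) {
  c(as.integer(s[2] | s[3]),
    1L - s[1],
    as.integer(xor(s[1] == 1, s[2] == 1)))
}

net3 <- function() {
  parse_ruleset(c("G1 = (G2 OR G3)", "G2 = (NOT G1)", "G3 = (G1 XOR G2)"))
}

# A small results table with prescribed condition means, shaped like a
# run_grid() output (one replicate per row).
fake_results <- function(df) {
  df$regime <- "discrete-varying"
  if (is.null(df$replicate)) {
    df$replicate <- stats::ave(seq_len(nrow(df)), df$lesion_type,
                               df$cut_percent, df$k, FUN = seq_along)
  }
  df$mi_subset <- ifelse(is.na(df$partial_degeneracy), NA_real_, 1)
  df$mi_full <- 1
  df$seed <- seq_len(nrow(df))
  df$error <- NA_character_
  class(df) <- c("degeneracy_results", class(df))
  df
}
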