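#' Plug-in joint entropy of a node subset
#'
#' Shannon entropy (log base 2) of the empirical distribution of joint
#' states of the subset's columns across the kept time steps:
#' `H = -sum_s P(s) log2 P(s)` with the convention `0 * log 0 = 0`. This
#' is the maximum-likelihood ("plug-in") estimator with no bias
#' correction; all degeneracy comparisons in the package are made within
#' this estimator.
#'
#' @param series a `binary_series` (or a 0/1 matrix), rows = time steps.
#' @param subset column (node) indices; the empty subset has entropy 0 by
#'   convention (a message is emitted).
#' @return entropy in bits, between 0 and `length(subset)`.
#' @examples
#' m <- cbind(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))
#' empirical_joint_entropy(m, 1:2)
#' @export
empirical_joint_entropy <- function(series, subset) {
  m <- as_series_matrix_(series)
  if (nrow(m) == 0) stop("empty series", call. = FALSE)
  if (length(subset) == 0) {
    message("empty subset: entropy defined as 0 bits by convention")
    return(0)
  }
  subset <- as.integer(subset)
  if (anyNA(subset) || min(subset) < 1 || max(subset) > ncol(m)) {
    stop("subset indices outside the series columns", call. = FALSE)
  }
  if (length(subset) > 25) {
    stop("subset too large for exact joint-state tabulation", call. = FALSE)
  }
  codes <- as.vector(m[, subset, drop = FALSE] %*% 2^(seq_along(subset) - 1))
  counts <- tabulate(codes + 1L, nbins = 2L^length(subset))
  p <- counts[counts > 0] / nrow(m)
  -sum(p * log2(p))
}

#' Plug-in mutual information between two node subsets
#'
#' `MI(A; B) = H(A) + H(B) - H(A, B)`, where the joint term is the
#' entropy over the union of the two column sets. Subsets may overlap
#' (when `B` is contained in `A`, `MI = H(B)` identically). The plug-in
#' MI is symmetric, non-negative, and bounded by `min(H(A), H(B))`.
#'
#' @param series a `binary_series` (or a 0/1 matrix).
#' @param subset_a,subset_b column (node) indices.
#' @return mutual information in bits.
#' @export
mutual_information <- function(series, subset_a, subset_b) {
  joint <- union(subset_a, subset_b)
  empirical_joint_entropy(series, subset_a) +
    empirical_joint_entropy(series, subset_b) -
    empirical_joint_entropy(series, joint)
}

#' Partial degeneracy of one perturbed subset
#'
#' The single-subset degeneracy term
#' `MI^P(X_j^k; O) - (k/n) * MI^P(X; O)`: the mutual information between
#' the perturbed subset and the output sheet, measured on a run in which
#' only that subset was perturbed, minus the linear share of the overall
#' MI, measured on a companion run of the same network in which all `n`
#' nodes were perturbed. Individual values may be negative; condition
#' averages are expected to be non-negative.
#'
#' @param series_k run with exactly `subset` perturbed.
#' @param series_full run with all `n` nodes perturbed (same network and
#'   output sheet, independent dynamics noise).
#' @param subset the perturbed subset of size `k`, `1 <= k <= n`.
#' @param output the output sheet (node indices, typically `n/2` of them).
#' @param n node count of the network.
#' @return partial degeneracy in bits (may be negative).
#' @export
partial_degeneracy <- function(series_k, series_full, subset, output, n) {
  k <- length(subset)
  if (k < 1 || k > n) {
    stop("subset size k must lie in [1, n]", call. = FALSE)
  }
  mi_k <- mutual_information(series_k, subset, output)
  mi_full <- mutual_information(series_full, seq_len(n), output)
  mi_k - (k / n) * mi_full
}

#' Total degeneracy from a per-k MI profile
#'
#' Sums the per-subset-size degeneracy terms
#' `D_N(X; O) = sum_k [ <MI^P(X_j^k; O)> - (k/n) * MI^P(X; O) ]` for
#' `k = 1..n`. When the k = n average MI comes from the same runs as the
#' overall MI the last term is identically 0, and a per-k MI profile that
#' increases exactly linearly (`per_k_mi[k] = (k/n) * overall_mi`) gives
#' total degeneracy 0 — the zero-degeneracy null of a fully disconnected
#' system.
#'
#' @param per_k_mi numeric vector of length `n`: average perturbed-subset
#'   MI for each subset size `k = 1..n` (bits).
#' @param overall_mi MI between the whole (all-perturbed) system and the
#'   output sheet (bits).
#' @param n node count.
#' @return an object of class `degeneracy_result` with fields `per_k_mi`,
#'   `overall_mi`, `per_k_term`, `total`, `n`.
#' @export
degeneracy_total <- function(per_k_mi, overall_mi, n) {
  if (length(per_k_mi) != n) {
    stop(sprintf("`per_k_mi` must have n = %d entries (k = 1..n)", n),
         call. = FALSE)
  }
  k <- seq_len(n)
  per_k_term <- per_k_mi - (k / n) * overall_mi
  structure(list(per_k_mi = per_k_mi, overall_mi = overall_mi,
                 per_k_term = per_k_term, total = sum(per_k_term),
                 n = as.integer(n)),
            class = "degeneracy_result")
}

#' @export
print.degeneracy_result <- function(x, ...) {
  cat(sprintf("Degeneracy D_N(X;O) = %.4f bits (n = %d, overall MI = %.4f bits)\n",
              x$total, x$n, x$overall_mi))
  print(data.frame(k = seq_len(x$n), mean_mi = x$per_k_mi,
                   term = x$per_k_term, row.names = NULL))
  invisible(x)
}
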