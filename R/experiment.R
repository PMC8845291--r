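#' Configure the lesion x perturbation factorial study
#'
#' Describes one full grid: lesion types crossed with cut conditions and
#' perturbed-subset sizes, replicated over freshly generated random
#' networks. Defaults mirror the study conditions: 10-node networks, cut
#' conditions 0-100% in steps of 10, subset sizes `k = 1..n`, 1000 time
#' steps with a 10-step burn-in, subset flip probability 0.25, baseline
#' flip probability 0.05 for the varying-activity regime (0 for classical
#' RBNs), Gaussian perturbation sd 0.01 for the continuous regime.
#' Replicates default to 200 (desk scale); set `replicates = 1000` for
#' full-scale runs.
#'
#' @param regime `"discrete-varying"` (baseline bit-flip noise on all
#'   nodes), `"discrete-classical"` (no baseline noise), or
#'   `"continuous"` (SDE dynamics with median discretization).
#' @param lesion_types subset of `c("type1", "type2")`.
#' @param cut_percents cut conditions, multiples of 10 in `[0, 100]`.
#' @param n node count.
#' @param k_values perturbed-subset sizes.
#' @param replicates random networks per condition cell.
#' @param steps,burn_in simulation length and burn-in.
#' @param flip_p subset bit-flip probability (discrete regimes).
#' @param baseline_flip_p baseline bit-flip probability; default `NULL`
#'   resolves to 0.05 for `"discrete-varying"` and 0 otherwise.
#' @param pert_sd Gaussian perturbation sd (continuous regime).
#' @param kinetics a [kinetic_params()] (continuous regime).
#' @param master_seed integer root of the deterministic seed tree; every
#'   replicate's seeds are pure functions of the master seed and its
#'   condition coordinates, so any single row can be reproduced without
#'   re-running the grid.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(regime = c("discrete-varying",
                                         "discrete-classical",
                                         "continuous"),
                              lesion_types = c("type1", "type2"),
                              cut_percents = seq(0, 100, by = 10),
                              n = 10, k_values = seq_len(n),
                              replicates = 200, steps = 1000, burn_in = 10,
                              flip_p = 0.25, baseline_flip_p = NULL,
                              pert_sd = 0.01,
                              kinetics = kinetic_params(),
                              master_seed = 1) {
  regime <- match.arg(regime)
  lesion_types <- match.arg(lesion_types, c("type1", "type2"),
                            several.ok = TRUE)
  if (is.null(baseline_flip_p)) {
    baseline_flip_p <- if (regime == "discrete-varying") 0.05 else 0
  }
  for (cp in cut_percents) check_cut_percent_(cp)
  if (length(k_values) == 0 || any(k_values < 1) || any(k_values > n)) {
    stop("`k_values` must be a non-empty subset of 1..n", call. = FALSE)
  }
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  if (steps <= burn_in || burn_in < 0) {
    stop("need steps > burn_in >= 0", call. = FALSE)
  }
  structure(list(regime = regime, lesion_types = lesion_types,
                 cut_percents = as.integer(cut_percents), n = as.integer(n),
                 k_values = as.integer(k_values),
                 replicates = as.integer(replicates),
                 steps = as.integer(steps), burn_in = as.integer(burn_in),
                 flip_p = flip_p, baseline_flip_p = baseline_flip_p,
                 pert_sd = pert_sd, kinetics = kinetics,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

# Deterministic seed tree: a Lehmer-style integer hash of the master seed
# and the row coordinates, kept below 2^31.
derive_seed_ <- function(master, ...) {
  h <- as.double(master) %% 2147483647
  for (v in c(...)) {
    h <- (h * 48271 + as.double(v) + 1) %% 2147483647
  }
  as.integer(h)
}

#' Run one replicate of the factorial study
#'
#' Generates a fresh random network, applies the lesion, draws a random
#' output sheet of `n/2` nodes and a random perturbed subset of size `k`
#' (both redrawn every replicate, both drawn from all `n` nodes so subset
#' and output sheet may overlap), runs the regime's simulator twice —
#' once with the subset perturbed, once with all `n` nodes perturbed,
#' with independent dynamics seeds — and returns the partial-degeneracy
#' row. All randomness descends deterministically from the configuration's
#' master seed and the row coordinates.
#'
#' @param config an [experiment_config()].
#' @param lesion_type `"type1"` or `"type2"`.
#' @param cut_percent cut condition.
#' @param k perturbed-subset size.
#' @param replicate_index replicate number within the condition.
#' @return a list with the condition coordinates, `mi_subset`, `mi_full`,
#'   `partial_degeneracy` (bits) and the replicate's root seed.
#' @export
run_replicate <- function(config, lesion_type, cut_percent, k,
                          replicate_index) {
  stopifnot(inherits(config, "experiment_config"))
  lt_idx <- match(lesion_type, c("type1", "type2"))
  if (is.na(lt_idx)) stop("unknown lesion type", call. = FALSE)
  check_cut_percent_(cut_percent)
  n <- config$n
  if (k < 1 || k > n) stop("k must lie in [1, n]", call. = FALSE)

  seed_setup <- derive_seed_(config$master_seed, lt_idx, cut_percent, k,
                             replicate_index, 1L)
  seed_dyn_k <- derive_seed_(config$master_seed, lt_idx, cut_percent, k,
                             replicate_index, 2L)
  seed_dyn_full <- derive_seed_(config$master_seed, lt_idx, cut_percent, k,
                                replicate_index, 3L)

  net_regime <- if (config$regime == "continuous") "continuous" else "discrete"
  setup <- with_seed_(seed_setup, {
    net <- generate_ruleset(n, net_regime)
    nodes <- select_lesion_nodes(n, cut_percent)
    list(net = net,
         nodes = nodes,
         output = sort(sample.int(n, n %/% 2)),
         subset = sort(sample.int(n, k)))
  })
  lesioned <- apply_lesion(setup$net,
                           lesion_spec(lesion_type, cut_percent,
                                       setup$nodes))

  if (config$regime == "continuous") {
    model <- compile_sde(lesioned, config$kinetics)
    ser_k <- discretize_median(
      simulate_sde(model, config$steps, config$burn_in, setup$subset,
                   config$pert_sd, seed = seed_dyn_k))
    ser_full <- discretize_median(
      simulate_sde(model, config$steps, config$burn_in, seq_len(n),
                   config$pert_sd, seed = seed_dyn_full))
  } else {
    ser_k <- simulate_discrete(
      lesioned, config$steps, config$burn_in,
      perturbation_spec(setup$subset, config$flip_p, config$baseline_flip_p),
      seed = seed_dyn_k)
    ser_full <- simulate_discrete(
      lesioned, config$steps, config$burn_in,
      perturbation_spec(seq_len(n), config$flip_p, config$baseline_flip_p),
      seed = seed_dyn_full)
  }

  mi_k <- mutual_information(ser_k, setup$subset, setup$output)
  mi_full <- mutual_information(ser_full, seq_len(n), setup$output)
  list(regime = config$regime, lesion_type = lesion_type,
       cut_percent = as.integer(cut_percent), k = as.integer(k),
       replicate = as.integer(replicate_index),
       mi_subset = mi_k, mi_full = mi_full,
       partial_degeneracy = mi_k - (k / n) * mi_full,
       seed = seed_setup)
}

#' Run the full factorial grid
#'
#' Iterates lesion types x cut conditions x subset sizes x replicates
#' with the deterministic seed tree of [run_replicate()]. Failures of
#' individual replicates are recorded in the `error` column and the run
#' continues.
#'
#' @param config an [experiment_config()].
#' @param progress emit a progress message per condition to standard
#'   error.
#' @return a `data.frame` of class `degeneracy_results` with one row per
#'   replicate: condition coordinates, `mi_subset`, `mi_full`,
#'   `partial_degeneracy`, `seed`, `error`. The configuration is attached
#'   as attribute `config`.
#' @export
run_grid <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  conds <- expand.grid(k = config$k_values, cut_percent = config$cut_percents,
                       lesion_type = config$lesion_types,
                       stringsAsFactors = FALSE)
  total <- nrow(conds) * config$replicates
  lesion_type <- character(total)
  cut_percent <- integer(total)
  k_col <- integer(total)
  replicate <- integer(total)
  mi_subset <- rep(NA_real_, total)
  mi_full <- rep(NA_real_, total)
  pd <- rep(NA_real_, total)
  seed <- rep(NA_integer_, total)
  err <- rep(NA_character_, total)

  row <- 0L
  for (ci in seq_len(nrow(conds))) {
    if (progress) {
      message(sprintf("[%d/%d] %s cut=%d%% k=%d", ci, nrow(conds),
                      conds$lesion_type[ci], conds$cut_percent[ci],
                      conds$k[ci]))
    }
    for (rep_i in seq_len(config$replicates)) {
      row <- row + 1L
      lesion_type[row] <- conds$lesion_type[ci]
      cut_percent[row] <- conds$cut_percent[ci]
      k_col[row] <- conds$k[ci]
      replicate[row] <- rep_i
      res <- tryCatch(
        run_replicate(config, conds$lesion_type[ci], conds$cut_percent[ci],
                      conds$k[ci], rep_i),
        error = function(e) conditionMessage(e))
      if (is.character(res)) {
        err[row] <- res
      } else {
        mi_subset[row] <- res$mi_subset
        mi_full[row] <- res$mi_full
        pd[row] <- res$partial_degeneracy
        seed[row] <- res$seed
      }
    }
  }
  out <- data.frame(regime = config$regime, lesion_type = lesion_type,
                    cut_percent = cut_percent, k = k_col,
                    replicate = replicate, mi_subset = mi_subset,
                    mi_full = mi_full, partial_degeneracy = pd,
                    seed = seed, error = err, stringsAsFactors = FALSE)
  attr(out, "config") <- config
  class(out) <- c("degeneracy_results", class(out))
  out
}

#' Aggregate replicate rows by condition
#'
#' Means and standard errors of partial degeneracy and the MI terms per
#' (lesion type, cut condition, subset size) cell; recomputable from the
#' raw rows at any time.
#'
#' @param results a [run_grid()] table.
#' @return a `data.frame` with one row per condition cell.
#' @export
aggregate_results <- function(results) {
  results <- as.data.frame(results)
  ok <- is.na(results$error)
  results <- results[ok, , drop = FALSE]
  if (nrow(results) == 0) stop("no successful replicates", call. = FALSE)
  key <- list(lesion_type = results$lesion_type,
              cut_percent = results$cut_percent, k = results$k)
  agg <- aggregate(results$partial_degeneracy, by = key, FUN = mean)
  names(agg)[4] <- "mean_pd"
  agg$se_pd <- aggregate(results$partial_degeneracy, by = key,
                         FUN = function(x) stats::sd(x) / sqrt(length(x)))$x
  agg$mean_mi_subset <- aggregate(results$mi_subset, by = key, FUN = mean)$x
  agg$mean_mi_full <- aggregate(results$mi_full, by = key, FUN = mean)$x
  agg$n_rep <- aggregate(results$partial_degeneracy, by = key,
                         FUN = length)$x
  agg[order(agg$lesion_type, agg$cut_percent, agg$k), , drop = FALSE]
}

#' Condition-level total degeneracy
#'
#' For each (lesion type, cut condition), the total degeneracy
#' `D_N(X; O)` obtained by summing the condition-mean partial-degeneracy
#' terms over all subset sizes `k`. By linearity this equals applying the
#' per-k summation to the condition-mean MI values.
#'
#' @param results a [run_grid()] table.
#' @return a `data.frame` with columns `lesion_type`, `cut_percent`,
#'   `degeneracy`.
#' @export
condition_degeneracy <- function(results) {
  agg <- aggregate_results(results)
  out <- aggregate(agg$mean_pd,
                   by = list(lesion_type = agg$lesion_type,
                             cut_percent = agg$cut_percent),
                   FUN = sum)
  names(out)[3] <- "degeneracy"
  out[order(out$lesion_type, out$cut_percent), , drop = FALSE]
}

#' Locate degeneracy peaks
#'
#' Reports, per lesion type, the subset size `k` maximizing mean partial
#' degeneracy (overall and within each cut condition) and the cut
#' condition maximizing mean partial degeneracy at each `k`. Ties resolve
#' to the smallest coordinate.
#'
#' @param results a [run_grid()] table.
#' @return an object of class `peak_report`: a list with elements
#'   `overall_k` (data frame lesion_type, k_peak), `k_by_cut` and
#'   `cut_by_k`.
#' @export
summarize_peaks <- function(results) {
  agg <- aggregate_results(results)
  if (nrow(agg) == 0) stop("empty results table", call. = FALSE)
  argmax_ <- function(df, coord) df[[coord]][which.max(df$mean)]

  raw <- as.data.frame(results)
  raw <- raw[is.na(raw$error), , drop = FALSE]
  pooled <- aggregate(raw$partial_degeneracy,
                      by = list(lesion_type = raw$lesion_type,
                                k = raw$k), FUN = mean)
  names(pooled)[3] <- "mean"
  pooled <- pooled[order(pooled$lesion_type, pooled$k), ]
  overall_k <- do.call(rbind, lapply(split(pooled, pooled$lesion_type),
    function(df) data.frame(lesion_type = df$lesion_type[1],
                            k_peak = argmax_(df, "k"))))

  agg <- agg[order(agg$lesion_type, agg$cut_percent, agg$k), ]
  k_by_cut <- do.call(rbind, lapply(
    split(agg, list(agg$lesion_type, agg$cut_percent), drop = TRUE),
    function(df) data.frame(lesion_type = df$lesion_type[1],
                            cut_percent = df$cut_percent[1],
                            k_peak = df$k[which.max(df$mean_pd)])))
  agg2 <- agg[order(agg$lesion_type, agg$k, agg$cut_percent), ]
  cut_by_k <- do.call(rbind, lapply(
    split(agg2, list(agg2$lesion_type, agg2$k), drop = TRUE),
    function(df) data.frame(lesion_type = df$lesion_type[1], k = df$k[1],
                            cut_peak = df$cut_percent[which.max(df$mean_pd)])))
  structure(list(overall_k = reset_rows_(overall_k),
                 k_by_cut = reset_rows_(k_by_cut[order(k_by_cut$lesion_type,
                                                       k_by_cut$cut_percent), ]),
                 cut_by_k = reset_rows_(cut_by_k[order(cut_by_k$lesion_type,
                                                       cut_by_k$k), ])),
            class = "peak_report")
}

reset_rows_ <- function(df) {
  rownames(df) <- NULL
  df
}

#' @export
print.peak_report <- function(x, ...) {
  cat("Peak subset size per lesion type (pooled over cut conditions):\n")
  print(x$overall_k)
  cat("\nPeak cut condition per subset size:\n")
  print(x$cut_by_k)
  invisible(x)
}

#' Compare lesion types with a two-factor ANOVA without replication
#'
#' Builds the lesion-type x cut-condition matrix of condition-mean total
#' degeneracy (2 x 11 under the default grid) and fits a two-factor
#' analysis of variance without replication, so the interaction mean
#' square serves as the error term: with 2 types and 11 cut conditions
#' the lesion-type factor is tested on df = (1, 10).
#'
#' @param results a [run_grid()] table containing both lesion types at
#'   every cut condition.
#' @return an object of class `lesion_anova`: list with `F_value`,
#'   `p_value`, `df` (length-2), and the condition-mean `table`.
#' @export
anova_lesion_types <- function(results) {
  cd <- condition_degeneracy(results)
  types <- unique(cd$lesion_type)
  cuts <- unique(cd$cut_percent)
  if (length(types) < 2 || nrow(cd) != length(types) * length(cuts)) {
    stop("need both lesion types at every cut condition", call. = FALSE)
  }
  cd$lesion_type <- factor(cd$lesion_type)
  cd$cut <- factor(cd$cut_percent)
  fit <- aov(degeneracy ~ lesion_type + cut, data = cd)
  sm <- summary(fit)[[1]]
  i <- grep("^lesion_type", rownames(sm))
  res <- grep("^Residuals", rownames(sm))
  structure(list(F_value = sm[i, "F value"], p_value = sm[i, "Pr(>F)"],
                 df = c(sm[i, "Df"], sm[res, "Df"]), table = cd),
            class = "lesion_anova")
}

#' @export
print.lesion_anova <- function(x, ...) {
  cat(sprintf("Lesion-type effect: F(%d, %d) = %.3f, p = %.4f\n",
              x$df[1], x$df[2], x$F_value, x$p_value))
  invisible(x)
}
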