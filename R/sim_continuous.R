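#' Kinetic parameters of the continuous gene-expression model
#'
#' Single-species (mRNA-only) kinetics used when a continuous-regime
#' Boolean network is compiled to stochastic differential equations. Each
#' gene follows `dx_i = (m * R_i(x) - lambda * x_i) dt + sigma_sys dW`,
#' where `R_i` is the soft-logic evaluation of the gene's rule over Hill
#' activations `a_j = x_j^h / (theta^h + x_j^h)`. Defaults give an ON
#' level of `m/lambda = 2` expression units, a half-maximal threshold at
#' `theta = m/(2*lambda) = 1`, and a steep (switch-like) Hill coefficient.
#'
#' @param production maximal production rate `m` (expression units per
#'   unit time).
#' @param degradation first-order degradation rate `lambda` (per unit
#'   time).
#' @param hill_threshold Hill half-activation threshold `theta`
#'   (expression units).
#' @param hill_coef Hill coefficient `h` (dimensionless, >= 1).
#' @param sigma_sys intrinsic noise amplitude (expression units per
#'   square-root time unit); always on, giving the model its baseline
#'   variance.
#' @param dt Euler-Maruyama integration step (time units).
#' @return an object of class `kinetic_params`.
#' @export
kinetic_params <- function(production = 20, degradation = 10,
                           hill_threshold = 1, hill_coef = 10,
                           sigma_sys = 0.05, dt = 0.01) {
  vals <- c(production = production, degradation = degradation,
            hill_threshold = hill_threshold, dt = dt)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("rates, threshold and dt must be positive", call. = FALSE)
  }
  if (!is.finite(hill_coef) || hill_coef < 1) {
    stop("`hill_coef` must be >= 1", call. = FALSE)
  }
  if (!is.finite(sigma_sys) || sigma_sys < 0) {
    stop("`sigma_sys` must be >= 0", call. = FALSE)
  }
  structure(list(production = production, degradation = degradation,
                 hill_threshold = hill_threshold, hill_coef = hill_coef,
                 sigma_sys = sigma_sys, dt = dt),
            class = "kinetic_params")
}

#' Compile a Boolean network into a continuous (SDE) model
#'
#' Converts each rule to a soft-logic production term `R_i` in `[0, 1]`:
#' leaves map to Hill activations, `NOT a` to `1 - a`, `A OR B` to the
#' probabilistic sum `a + b - a*b`, `A AND NOT B` to `a * (1 - b)`, and a
#' copy to `a`. A `CONST` (lesion-isolated) gene keeps `R_i` frozen at the
#' Hill activation of its own initial expression level. The drift of gene
#' `i` is `m * R_i(x) - lambda * x_i`, bounded between `-lambda * x_i` and
#' `m - lambda * x_i`.
#'
#' @param net a [boolean_network()] with `regime = "continuous"`; a
#'   discrete-regime network (whose menu includes XOR) is rejected, as XOR
#'   has no monotone soft-logic form.
#' @param params a [kinetic_params()].
#' @return an object of class `continuous_model`.
#' @export
compile_sde <- function(net, params = kinetic_params()) {
  stopifnot(inherits(net, "boolean_network"),
            inherits(params, "kinetic_params"))
  if (net$regime != "continuous" ||
      any(vapply(net$rules, `[[`, "", "op") == "XOR")) {
    stop("invalid regime: SDE conversion needs a continuous-regime network (no XOR)",
         call. = FALSE)
  }
  n <- net$n
  op <- integer(n)          # 0 CONST, 1 LINK, 2 AND, 3 OR
  ins <- matrix(1L, n, 2L)
  neg <- matrix(FALSE, n, 2L)
  for (i in seq_len(n)) {
    r <- net$rules[[i]]
    op[i] <- switch(r$op, CONST = 0L, LINK = 1L, AND = 2L, OR = 3L)
    m <- length(r$inputs)
    if (m > 0) {
      ins[i, seq_len(m)] <- r$inputs
      neg[i, seq_len(m)] <- r$neg
    }
  }
  structure(list(n = n, op = op, inputs = ins, neg = neg,
                 params = params, net = net),
            class = "continuous_model")
}

#' @export
print.continuous_model <- function(x, ...) {
  cat(sprintf("Continuous (SDE) model: %d genes, m=%g, lambda=%g, theta=%g, h=%g\n",
              x$n, x$params$production, x$params$degradation,
              x$params$hill_threshold, x$params$hill_coef))
  invisible(x)
}

#' Simulate the SDE model with Gaussian perturbation
#'
#' Euler-Maruyama integration with step `dt`; every gene receives
#' intrinsic noise `sigma_sys * sqrt(dt) * N(0,1)` per step, and each gene
#' of the perturbed subset additionally receives `N(0, pert_sd)` per
#' recorded step, injected additively into the state. Expression is
#' clamped at 0 from below. One sample is recorded per integration step
#' and the first `burn_in` samples are discarded (1000 steps, 10 burn-in
#' gives 990 kept rows). Initial expression levels are drawn uniformly on
#' `[0, m/lambda]` unless `init` is supplied.
#'
#' @param model a [compile_sde()] result.
#' @param steps total integration steps (default 1000).
#' @param burn_in leading samples to discard (default 10).
#' @param pert_subset gene indices receiving the perturbation noise.
#' @param pert_sd standard deviation of the perturbation (default 0.01
#'   expression units).
#' @param seed optional integer for a reproducible run.
#' @param init optional non-negative initial state of length `n`.
#' @return an `expression_matrix`: kept samples as a
#'   `(steps - burn_in) x n` non-negative matrix, plus run metadata.
#' @export
simulate_sde <- function(model, steps = 1000, burn_in = 10,
                         pert_subset = integer(0), pert_sd = 0.01,
                         seed = NULL, init = NULL) {
  stopifnot(inherits(model, "continuous_model"))
  if (burn_in < 0 || steps <= burn_in) {
    stop("need steps > burn_in >= 0", call. = FALSE)
  }
  pert_subset <- as.integer(pert_subset)
  if (length(pert_subset) > 0 &&
      (min(pert_subset) < 1 || max(pert_subset) > model$n)) {
    stop("perturbed subset references gene outside the model", call. = FALSE)
  }
  p <- model$params
  perturbed <- rep(FALSE, model$n)
  perturbed[pert_subset] <- TRUE
  with_seed_(seed, {
    if (is.null(init)) {
      init <- stats::runif(model$n, 0, p$production / p$degradation)
    }
    if (length(init) != model$n || any(init < 0)) {
      stop("`init` must be a non-negative state of length n", call. = FALSE)
    }
    mat <- sim_sde_core(model$op, model$inputs - 1L, model$neg,
                        as.numeric(init), p$production, p$degradation,
                        p$hill_threshold, p$hill_coef, p$sigma_sys, p$dt,
                        as.integer(steps), as.integer(burn_in),
                        perturbed, pert_sd)
    colnames(mat) <- node_names_(model$n)
    structure(list(values = mat, steps = as.integer(steps),
                   burn_in = as.integer(burn_in),
                   meta = list(pert_subset = pert_subset, pert_sd = pert_sd,
                               params = p, seed = seed, init = init)),
              class = "expression_matrix")
  })
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d kept samples x %d genes (%d steps, %d burn-in)\n",
              nrow(x$values), ncol(x$values), x$steps, x$burn_in))
  invisible(x)
}

#' Discretize expression by the per-gene median
#'
#' For every gene, values strictly above the gene's median over the kept
#' samples become 1, all others (including ties and constant genes)
#' become 0. The result is invariant under any positive rescaling of the
#' expression values.
#'
#' @param expr an `expression_matrix` (or a plain numeric matrix).
#' @return a `binary_series` of the same shape.
#' @export
discretize_median <- function(expr) {
  v <- as_series_matrix_(expr)
  if (nrow(v) == 0) stop("empty expression matrix", call. = FALSE)
  meds <- apply(v, 2, stats::median)
  bits <- t(t(v) > meds)
  storage.mode(bits) <- "integer"
  colnames(bits) <- colnames(v)
  steps <- if (inherits(expr, "expression_matrix")) expr$steps else nrow(v)
  burn_in <- if (inherits(expr, "expression_matrix")) expr$burn_in else 0L
  meta <- if (inherits(expr, "expression_matrix")) expr$meta else list()
  new_binary_series(bits, steps, burn_in, meta = meta)
}
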