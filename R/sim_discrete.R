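#' Specify a perturbation of the discrete dynamics
#'
#' Perturbation is uncorrelated bit-flip noise: after each synchronous
#' update, every node of the perturbed subset flips with probability
#' `flip_p`, and every node of the network flips with probability
#' `baseline_flip_p` (the "varying unit activity" noise; 0 for classical
#' deterministic RBNs, 0.05 for varying-activity RBNs). A node in the
#' subset can therefore flip twice in one step, composing to no net flip.
#'
#' @param subset node indices of the perturbed subset `X_j^k` (may be
#'   empty, may overlap the output sheet).
#' @param flip_p per-node, per-step flip probability for the subset.
#' @param baseline_flip_p per-node, per-step flip probability for all
#'   nodes.
#' @return an object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(subset = integer(0), flip_p = 0.25,
                              baseline_flip_p = 0) {
  subset <- as.integer(subset)
  if (anyNA(subset) || any(duplicated(subset))) {
    stop("`subset` must be distinct node indices", call. = FALSE)
  }
  for (p in c(flip_p, baseline_flip_p)) {
    if (!is.numeric(p) || is.na(p) || p < 0 || p > 1) {
      stop("flip probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(subset = subset, flip_p = flip_p,
                 baseline_flip_p = baseline_flip_p),
            class = "perturbation_spec")
}

new_binary_series <- function(samples, steps, burn_in, meta = list()) {
  structure(list(samples = samples, steps = as.integer(steps),
                 burn_in = as.integer(burn_in), meta = meta),
            class = "binary_series")
}

#' @export
print.binary_series <- function(x, ...) {
  cat(sprintf("Binary time series: %d kept steps x %d nodes (%d steps, %d burn-in)\n",
              nrow(x$samples), ncol(x$samples), x$steps, x$burn_in))
  invisible(x)
}

as_series_matrix_ <- function(x) {
  if (inherits(x, "binary_series")) return(x$samples)
  if (inherits(x, "expression_matrix")) return(x$values)
  as.matrix(x)
}

#' Evaluate one logic rule on a network state
#'
#' Truth-table evaluation of a rule at the given state bits; a `CONST`
#' rule returns the node's current value.
#'
#' @param rule a [logic_rule()].
#' @param state integer vector of bits (0/1), one per node.
#' @return a single bit (integer 0 or 1).
#' @export
evaluate_rule <- function(rule, state) {
  state <- as.integer(state)
  if (rule$op == "CONST") return(state[rule$target])
  v <- state[rule$inputs]
  v[rule$neg] <- 1L - v[rule$neg]
  switch(rule$op,
    LINK = v[1],
    AND = v[1] * v[2],
    OR = max(v[1], v[2]),
    XOR = (v[1] + v[2]) %% 2L
  )
}

#' Advance a network one synchronous step
#'
#' Every node's next value is computed from the same previous state;
#' `CONST` nodes carry their value forward.
#'
#' @param net a [boolean_network()].
#' @param state integer vector of bits, length `net$n`.
#' @return the next state (integer vector of bits).
#' @export
step_synchronous <- function(net, state) {
  if (length(state) != net$n) {
    stop(sprintf("state has length %d, network has %d nodes",
                 length(state), net$n), call. = FALSE)
  }
  vapply(net$rules, evaluate_rule, integer(1), state = state)
}

# Compile rules to per-node truth tables for the C++ core. Column index is
# 1 + b1 + 2*b2 over the bits of the rule's inputs; single-input rules use
# the first two columns only; zero-input rules are flagged by nin = 0.
compile_tables_ <- function(net) {
  n <- net$n
  tt <- matrix(0L, n, 4L)
  nin <- integer(n)
  ins <- matrix(1L, n, 2L)
  for (i in seq_len(n)) {
    r <- net$rules[[i]]
    m <- length(r$inputs)
    nin[i] <- m
    if (m == 0L) next
    ins[i, seq_len(m)] <- r$inputs
    if (m == 1L) {
      for (b in 0:1) {
        probe <- integer(n)
        probe[r$inputs[1]] <- b
        tt[i, b + 1L] <- evaluate_rule(r, probe)
      }
    } else {
      for (b2 in 0:1) for (b1 in 0:1) {
        probe <- integer(n)
        probe[r$inputs[1]] <- b1
        probe[r$inputs[2]] <- b2
        tt[i, 1L + b1 + 2L * b2] <- evaluate_rule(r, probe)
      }
    }
  }
  list(tt = tt, nin = nin, inputs = ins - 1L)
}

#' Simulate synchronous Boolean dynamics with bit-flip perturbation
#'
#' Starts from a uniformly random initial state; at each step the whole
#' network is updated synchronously, then subset flips (probability
#' `pert$flip_p`) and baseline flips (`pert$baseline_flip_p`) are applied
#' independently per node, and the post-flip state is recorded. The first
#' `burn_in` recorded states are discarded, so the default 1000 steps with
#' a 10-step burn-in yield 990 kept samples. A `CONST` (lesion-isolated)
#' node restores its randomly drawn initial state at every update, keeping
#' its activity constant over the run; a flip on such a node therefore
#' shows in exactly one recorded sample.
#'
#' @param net a [boolean_network()].
#' @param steps total number of time steps (default 1000).
#' @param burn_in leading steps to discard (default 10); `steps` must
#'   exceed `burn_in`.
#' @param pert a [perturbation_spec()].
#' @param seed optional integer; identical arguments and seed give a
#'   bit-identical series.
#' @return a `binary_series`: kept samples as a `(steps - burn_in) x n`
#'   0/1 matrix with columns `G1..Gn`, plus run metadata.
#' @examples
#' net <- generate_ruleset(10, seed = 1)
#' ser <- simulate_discrete(net, pert = perturbation_spec(1:3), seed = 2)
#' nrow(ser$samples)
#' @export
simulate_discrete <- function(net, steps = 1000, burn_in = 10,
                              pert = perturbation_spec(), seed = NULL) {
  stopifnot(inherits(net, "boolean_network"),
            inherits(pert, "perturbation_spec"))
  if (burn_in < 0 || steps <= burn_in) {
    stop("need steps > burn_in >= 0", call. = FALSE)
  }
  if (length(pert$subset) > 0 && max(pert$subset) > net$n) {
    stop("perturbed subset references node outside the network",
         call. = FALSE)
  }
  comp <- compile_tables_(net)
  perturbed <- rep(FALSE, net$n)
  perturbed[pert$subset] <- TRUE
  with_seed_(seed, {
    init <- sample(0:1, net$n, replace = TRUE)
    mat <- sim_discrete_core(comp$tt, comp$nin, comp$inputs, init,
                             as.integer(steps), as.integer(burn_in),
                             perturbed, pert$flip_p, pert$baseline_flip_p)
    colnames(mat) <- node_names_(net$n)
    new_binary_series(mat, steps, burn_in,
                      meta = list(pert = pert, seed = seed, init = init))
  })
}
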