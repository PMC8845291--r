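test_that("SDE compilation rejects non-continuous networks", {
  disc <- parse_ruleset(c("G1 = (G2 XOR G3)", "G2 = G1", "G3 = G1"))
  expect_error(compile_sde(disc), "regime")
  cont <- parse_ruleset(c("G1 = (G2 AND (NOT G3))", "G2 = G1", "G3 = G1"),
                        regime = "continuous")
  expect_s3_class(compile_sde(cont), "continuous_model")
})

test_that("kinetic parameter validation", {
  expect_error(kinetic_params(production = -1), "positive")
  expect_error(kinetic_params(hill_coef = 0.5), "hill_coef")
  expect_error(kinetic_params(dt = 0), "positive")
})

test_that("self-copy converges to the stable high fixed point (ODE limit)", {
  net <- parse_ruleset("G1 = G1", regime = "continuous")
  model <- compile_sde(net, kinetic_params(sigma_sys = 0))
  p <- model$params
  drift <- function(x) {
    p$production * x^p$hill_coef /
      (p$hill_threshold^p$hill_coef + x^p$hill_coef) - p$degradation * x
  }
  root <- uniroot(drift, c(1.5, 2.5), tol = 1e-12)$root
  x0 <- 0.99 * p$production / p$degradation
  em <- simulate_sde(model, 1000, 10, init = x0)
  expect_lt(abs(em$values[990, 1] - root), 1e-3)
})

test_that("self-negation converges to the interior equilibrium (bisection)", {
  net <- parse_ruleset("G1 = (NOT G1)", regime = "continuous")
  model <- compile_sde(net, kinetic_params(sigma_sys = 0))
  p <- model$params
  drift <- function(x) {
    a <- x^p$hill_coef / (p$hill_threshold^p$hill_coef + x^p$hill_coef)
    p$production * (1 - a) - p$degradation * x
  }
  root <- uniroot(drift, c(1e-9, p$production / p$degradation),
                  tol = 1e-12)$root
  for (x0 in c(0.05, 1.9)) {
    em <- simulate_sde(model, 2000, 10, init = x0)
    expect_lt(abs(em$values[1990, 1] - root), 1e-2)
  }
})

test_that("zero-noise integration is deterministic and non-negative", {
  net <- generate_ruleset(10, "continuous", seed = 31)
  model <- compile_sde(net, kinetic_params(sigma_sys = 0))
  a <- simulate_sde(model, 500, 0, seed = 32)
  b <- simulate_sde(model, 500, 0, seed = 32)
  expect_identical(a$values, b$values)
  expect_true(all(a$values >= 0))
  noisy <- simulate_sde(compile_sde(net), 1000, 10, seed = 33)
  expect_identical(dim(noisy$values), c(990L, 10L))
  expect_true(all(noisy$values >= 0))
})

test_that("a frozen noiseless model started at rest stays constant", {
  net <- generate_ruleset(10, "continuous", seed = 41)
  frozen <- apply_lesion(net, lesion_spec("type2", 100, 1:10))
  model <- compile_sde(frozen, kinetic_params(sigma_sys = 0))
  em <- simulate_sde(model, 100, 0, init = rep(0, 10))
  expect_true(all(em$values == 0))
  # Gaussian perturbation touches only the subset genes
  em2 <- simulate_sde(model, 100, 0, pert_subset = 1, pert_sd = 0.01,
                      init = rep(0, 10), seed = 42)
  expect_true(all(em2$values[, 2:10] == 0))
  expect_gt(sd(em2$values[, 1]), 0)
})

test_that("median discretization follows the strict-above rule", {
  col <- c(0.1, 0.9, 0.5, 0.7)  # median 0.6
  out <- discretize_median(matrix(col, ncol = 1))
  expect_identical(as.vector(out$samples), c(0L, 1L, 0L, 1L))
  const <- discretize_median(matrix(rep(2.5, 8), ncol = 1))
  expect_true(all(const$samples == 0L))
  # invariance under positive rescaling
  m <- matrix(runif(200), 50, 4)
  expect_identical(discretize_median(m)$samples,
                   discretize_median(3.7 * m)$samples)
  # an even-length column of distinct values splits exactly in half
  m2 <- matrix(sample(seq_len(100)), 100, 1)
  expect_identical(mean(discretize_median(m2)$samples), 0.5)
})

test_that("continuous pipeline yields 990 kept rows and binary output", {
  net <- generate_ruleset(10, "continuous", seed = 51)
  model <- compile_sde(net)
  em <- simulate_sde(model, 1000, 10, pert_subset = 1:5, seed = 52)
  bs <- discretize_median(em)
  expect_identical(dim(bs$samples), c(990L, 10L))
  expect_true(all(bs$samples %in% 0:1))
})
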