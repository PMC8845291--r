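test_that("entropy matches direct evaluation on small tables", {
  const <- matrix(0L, 100, 1)
  expect_equal(empirical_joint_entropy(const, 1), 0)
  alt <- matrix(rep(c(0L, 1L), 495), ncol = 1)
  expect_equal(empirical_joint_entropy(alt, 1), 1)
  # joint states {00:2, 01:1, 10:1} -> p = (1/2, 1/4, 1/4) -> 1.5 bits
  pair <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 1L), c(1L, 0L))
  expect_equal(empirical_joint_entropy(pair, 1:2), 1.5)
})

test_that("entropy and MI agree with the string-tabulation oracle", {
  set.seed(61)
  for (i in 1:25) {
    m <- matrix(sample(0:1, 36, replace = TRUE), 12, 3)
    for (sub in list(1, 2, 1:2, c(1, 3), 1:3)) {
      expect_equal(empirical_joint_entropy(m, sub), oracle_entropy(m, sub))
    }
    expect_equal(mutual_information(m, 1, 2:3), oracle_mi(m, 1, 2:3))
    expect_equal(mutual_information(m, 1:2, 2:3), oracle_mi(m, 1:2, 2:3))
  }
})

test_that("MI identities: symmetry, containment, independence, bounds", {
  set.seed(62)
  m <- matrix(sample(0:1, 990 * 6, replace = TRUE), 990, 6)
  expect_equal(mutual_information(m, 1:2, 3:5),
               mutual_information(m, 3:5, 1:2))
  # B contained in A -> MI = H(B) exactly
  expect_equal(mutual_information(m, 1:4, 2:3),
               empirical_joint_entropy(m, 2:3))
  # all four joint states equally often -> zero MI
  balanced <- cbind(rep(0:1, each = 2, times = 25),
                    rep(0:1, times = 50))
  expect_equal(mutual_information(balanced, 1, 2), 0)
  for (i in 1:10) {
    a <- sample(6, 2)
    b <- sample(6, 3)
    mi <- mutual_information(m, a, b)
    expect_gte(mi, 0)
    expect_lte(mi, min(empirical_joint_entropy(m, a),
                       empirical_joint_entropy(m, b)) + 1e-12)
  }
})

test_that("entropy is monotone under adding columns and bounded by |S|", {
  set.seed(63)
  m <- matrix(sample(0:1, 500 * 5, replace = TRUE), 500, 5)
  for (i in 1:10) {
    s <- sample(5, sample(3, 1))
    t <- union(s, sample(5, 1))
    hs <- empirical_joint_entropy(m, s)
    expect_lte(hs, length(s))
    expect_gte(empirical_joint_entropy(m, t), hs - 1e-12)
  }
})

test_that("edge cases: empty subset, empty series, bad indices", {
  m <- matrix(0L, 5, 2)
  expect_message(h0 <- empirical_joint_entropy(m, integer(0)), "convention")
  expect_equal(h0, 0)
  expect_error(empirical_joint_entropy(m[0, , drop = FALSE], 1), "empty")
  expect_error(empirical_joint_entropy(m, 3), "columns")
})

test_that("degeneracy summation follows the per-k decomposition", {
  # linear per-k MI profile is the zero-degeneracy null
  n <- 10
  overall <- 3.2
  linear <- (seq_len(n) / n) * overall
  res <- degeneracy_total(linear, overall, n)
  expect_equal(res$total, 0)
  expect_equal(res$per_k_term, rep(0, n))
  # all-zero profile
  expect_equal(degeneracy_total(rep(0, n), 0, n)$total, 0)
  # arbitrary profile equals the brute-force sum
  set.seed(64)
  per_k <- runif(n, 0, 5)
  overall <- runif(1, 0, 5)
  res <- degeneracy_total(per_k, overall, n)
  brute <- 0
  for (k in seq_len(n)) brute <- brute + per_k[k] - (k / n) * overall
  expect_equal(res$total, brute)
  # k = n term vanishes when overall MI comes from the same runs
  res2 <- degeneracy_total(per_k, per_k[n], n)
  expect_equal(res2$per_k_term[n], 0)
  expect_error(degeneracy_total(per_k[1:5], overall, n), "entries")
})

test_that("partial degeneracy cancels at k = n and freezes at zero", {
  set.seed(65)
  m <- matrix(sample(0:1, 990 * 10, replace = TRUE), 990, 10)
  out <- c(1, 4, 6, 8, 9)
  expect_equal(partial_degeneracy(m, m, 1:10, out, 10), 0)
  # frozen network: every term is zero
  frozen <- matrix(1L, 990, 10)
  expect_equal(partial_degeneracy(frozen, frozen, 1:3, out, 10), 0)
  expect_equal(empirical_joint_entropy(frozen, 1:10), 0)
  expect_equal(mutual_information(frozen, 1:3, out), 0)
  expect_error(partial_degeneracy(m, m, integer(0), out, 10), "k")
})

test_that("partial degeneracy can be negative for single replicates", {
  set.seed(66)
  found_negative <- FALSE
  for (i in 1:20) {
    net <- generate_ruleset(10)
    out <- sort(sample.int(10, 5))
    sub <- sort(sample.int(10, 2))
    sk <- simulate_discrete(net, 300, 10, perturbation_spec(sub, 0.25, 0.05))
    sf <- simulate_discrete(net, 300, 10, perturbation_spec(1:10, 0.25, 0.05))
    if (partial_degeneracy(sk, sf, sub, out, 10) < 0) found_negative <- TRUE
  }
  expect_true(found_negative)
})
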