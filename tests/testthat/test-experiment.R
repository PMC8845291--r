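test_that("configuration defaults and validation", {
  cfg <- experiment_config()
  expect_identical(cfg$regime, "discrete-varying")
  expect_identical(cfg$baseline_flip_p, 0.05)
  expect_identical(cfg$cut_percents, as.integer(seq(0, 100, 10)))
  expect_identical(cfg$k_values, 1:10)
  expect_identical(cfg$flip_p, 0.25)
  expect_identical(cfg$steps, 1000L)
  expect_identical(cfg$burn_in, 10L)
  classical <- experiment_config(regime = "discrete-classical")
  expect_identical(classical$baseline_flip_p, 0)
  expect_error(experiment_config(cut_percents = c(0, 15)), "cut_percent")
  expect_error(experiment_config(k_values = 0:3), "k_values")
  expect_error(experiment_config(replicates = 0), "replicates")
})

test_that("replicates are pure functions of the seed tree", {
  cfg <- experiment_config(master_seed = 99, replicates = 2)
  a <- run_replicate(cfg, "type2", 30, 4, 1)
  b <- run_replicate(cfg, "type2", 30, 4, 1)
  expect_identical(a, b)
  c <- run_replicate(cfg, "type2", 30, 4, 2)
  expect_false(identical(a$seed, c$seed))
  d <- run_replicate(cfg, "type1", 30, 4, 1)
  expect_false(identical(a$seed, d$seed))
})

test_that("the grid has one row per condition and replicate", {
  cfg <- experiment_config(lesion_types = "type1", cut_percents = c(0, 100),
                           k_values = c(2, 5), replicates = 2,
                           steps = 200, burn_in = 10, master_seed = 5)
  tab <- run_grid(cfg)
  expect_identical(nrow(tab), 2L * 2L * 2L)
  expect_true(all(is.na(tab$error)))
  expect_identical(sort(unique(tab$cut_percent)), c(0L, 100L))
  # a single row recomputed in isolation matches its grid row
  solo <- run_replicate(cfg, "type1", 100, 5, 2)
  row <- tab[tab$cut_percent == 100 & tab$k == 5 & tab$replicate == 2, ]
  expect_equal(row$partial_degeneracy, solo$partial_degeneracy)
  expect_identical(row$seed, solo$seed)
})

test_that("aggregation is recomputable from the raw rows", {
  cfg <- experiment_config(lesion_types = "type1", cut_percents = 0,
                           k_values = c(3, 7), replicates = 4,
                           steps = 200, burn_in = 10, master_seed = 6)
  tab <- run_grid(cfg)
  agg <- aggregate_results(tab)
  for (k in c(3, 7)) {
    manual <- mean(tab$partial_degeneracy[tab$k == k])
    expect_equal(agg$mean_pd[agg$k == k], manual)
  }
  cd <- condition_degeneracy(tab)
  expect_equal(cd$degeneracy, sum(agg$mean_pd))
  # linearity: summing mean per-k terms equals the per-k decomposition of
  # the condition-mean MI values
  mi_k <- sapply(c(3, 7), function(k) mean(tab$mi_subset[tab$k == k]))
  mi_full <- sapply(c(3, 7), function(k) mean(tab$mi_full[tab$k == k]))
  expect_equal(cd$degeneracy,
               sum(mi_k - (c(3, 7) / 10) * mi_full))
})

test_that("peak location reports argmax with smallest-coordinate ties", {
  grid <- expand.grid(lesion_type = "type1", cut_percent = c(0L, 10L),
                      k = 1:4, stringsAsFactors = FALSE)
  grid$partial_degeneracy <- c(1, 1, 2, 2, 3, 3, 2, 2)[order(order(
    grid$cut_percent, grid$k))]
  # build explicitly: pd rises to k = 3 then falls, identical at both cuts
  grid$partial_degeneracy <- rep(c(1, 2, 3, 2), each = 2)
  tab <- fake_results(grid)
  pk <- summarize_peaks(tab)
  expect_identical(pk$overall_k$k_peak, 3L)
  expect_identical(unique(pk$cut_by_k$cut_peak), 0L)  # tie -> smaller cut
  # strictly increasing curve peaks at the largest k
  grid$partial_degeneracy <- rep(1:4, each = 2)
  expect_identical(summarize_peaks(fake_results(grid))$overall_k$k_peak, 4L)
})

test_that("the two-factor ANOVA matches hand-computed sums of squares", {
  d1 <- c(1, 2, 3)
  d2 <- c(2, 3, 5)
  grid <- expand.grid(lesion_type = c("type1", "type2"),
                      cut_percent = c(0L, 50L, 100L), k = 1L,
                      stringsAsFactors = FALSE)
  grid$partial_degeneracy <- ifelse(grid$lesion_type == "type1",
                                    d1[match(grid$cut_percent, c(0, 50, 100))],
                                    d2[match(grid$cut_percent, c(0, 50, 100))])
  tab <- fake_results(grid)
  an <- anova_lesion_types(tab)
  # hand computation: row effect SS with 1 df, interaction as error (2 df)
  y <- rbind(d1, d2)
  grand <- mean(y)
  ss_type <- 3 * sum((rowMeans(y) - grand)^2)
  ss_cut <- 2 * sum((colMeans(y) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_type - ss_cut
  f_hand <- (ss_type / 1) / (ss_err / 2)
  expect_equal(an$F_value, f_hand)
  expect_identical(an$df, c(1, 2))
  expect_equal(an$p_value, pf(f_hand, 1, 2, lower.tail = FALSE))
  # equal lesion-type means (with non-zero interaction) give F = 0
  grid$partial_degeneracy <- ifelse(grid$lesion_type == "type1",
                                    c(1, 2, 3)[match(grid$cut_percent, c(0, 50, 100))],
                                    c(2, 1, 3)[match(grid$cut_percent, c(0, 50, 100))])
  an0 <- anova_lesion_types(fake_results(grid))
  expect_equal(an0$F_value, 0)
})

test_that("the ANOVA on the full 2 x 11 design reports df = (1, 10)", {
  set.seed(71)
  grid <- expand.grid(lesion_type = c("type1", "type2"),
                      cut_percent = seq(0L, 100L, 10L), k = 1L,
                      stringsAsFactors = FALSE)
  grid$partial_degeneracy <- rnorm(nrow(grid))
  an <- anova_lesion_types(fake_results(grid))
  expect_identical(an$df, c(1, 10))
  expect_error(anova_lesion_types(fake_results(
    grid[grid$lesion_type == "type1", ])), "both lesion types")
})

test_that("experiment configs round-trip through JSON", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(regime = "continuous", replicates = 7,
                            master_seed = 3,
                            kinetics = list(production = 15)),
                       path, auto_unbox = TRUE)
  cfg <- experiment_config_from_json(path)
  expect_identical(cfg$regime, "continuous")
  expect_identical(cfg$replicates, 7L)
  expect_equal(cfg$kinetics$production, 15)
  jsonlite::write_json(list(bogus = 1), path, auto_unbox = TRUE)
  expect_error(experiment_config_from_json(path), "unknown")
})
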