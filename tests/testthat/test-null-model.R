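test_that("uniform assignment conserves predators and honors forced cases", {
  set.seed(11)
  for (i in 1:50) {
    m <- sample(1:12, 1)
    n <- sample(1:10, 1)
    occ <- assign_uniform(m, n)
    expect_length(occ, n)
    expect_equal(sum(occ), m)
    expect_true(all(occ >= 0))
  }
  expect_equal(assign_uniform(5, 1), 5L)
  expect_error(assign_uniform(0, 4), "m")
  expect_error(assign_uniform(4, 0), "n")
})

test_that("group statistics follow the occupied-prey definition", {
  expect_equal(group_statistics(c(3, 2, 1, 1, 1, 0, 0, 0)),
               list(mean_group = 1.6, max_group = 3))
  expect_equal(group_statistics(c(8, 0, 0, 0, 0, 0, 0, 0)),
               list(mean_group = 8, max_group = 8))
  expect_equal(group_statistics(rep(1, 8)),
               list(mean_group = 1, max_group = 1))
  expect_error(group_statistics(c(0, 0)), "no feeding groups")
  expect_error(group_statistics(c(-1, 2)), "non-negative")
})

test_that("exact null distribution matches closed forms and sums to one", {
  d22 <- exact_null_distribution(2, 2)
  expect_equal(sum(d22$prob), 1)
  expect_equal(sum(d22$mean_group * d22$prob), 1.5)
  expect_equal(sum(d22$max_group * d22$prob), 1.5)
  # P(both predators share one prey item) = 1/2 by 4-outcome enumeration
  expect_equal(d22$prob[d22$max_group == 2], 0.5)
  d32 <- exact_null_distribution(3, 2)
  expect_equal(sum(d32$max_group * d32$prob), 2.25)
  d1 <- exact_null_distribution(1, 5)
  expect_equal(d1$mean_group, 1)
  expect_equal(d1$prob, 1)
  expect_error(exact_null_distribution(60, 60), "Monte-Carlo")
})

test_that("exact null distribution equals direct n^m enumeration", {
  for (cfg in list(c(2, 3), c(3, 3), c(4, 4), c(4, 2))) {
    mine <- exact_null_distribution(cfg[1], cfg[2])
    brute <- oracle_uniform_enum(cfg[1], cfg[2])
    expect_equal(mine$mean_group, brute$mean_group, tolerance = 1e-12)
    expect_equal(mine$max_group, brute$max_group, tolerance = 1e-12)
    expect_equal(mine$prob, brute$prob, tolerance = 1e-12)
  }
})

test_that("simulated uniform trials match the exact distribution (chi-square)", {
  set.seed(101)
  for (cfg in list(c(2, 2), c(3, 3), c(4, 3), c(4, 4))) {
    m <- cfg[1]; n <- cfg[2]
    exact <- exact_null_distribution(m, n)
    s <- socialdining:::sim_uniform_trials(200000, m, n)
    key <- paste(signif(s$mean, 10), s$max)
    exact_key <- paste(signif(exact$mean_group, 10), exact$max_group)
    counts <- as.numeric(table(factor(key, levels = exact_key)))
    expect_gt(gof_pvalue(counts, exact$prob), 0.001)
  }
})

test_that("dataset statistics agree with exact expectations", {
  set.seed(5)
  one <- simulate_dataset_stats(1, 4, trials_per_dataset = 1)
  expect_equal(unname(one), c(1, 1))
  # m=2, n=2: E[mean per trial] = 1.5
  reps <- replicate(400, simulate_dataset_stats(2, 2, 10)["mean_of_means"])
  expect_lt(abs(mean(reps) - 1.5), 4 * sd(reps) / sqrt(length(reps)))
  # m=8, n=8 against the enumeration oracle's expectation
  exact <- exact_null_distribution(8, 8)
  e_mean <- sum(exact$mean_group * exact$prob)
  s <- socialdining:::sim_uniform_trials(50000, 8, 8)
  se <- sd(s$mean) / sqrt(length(s$mean))
  expect_lt(abs(mean(s$mean) - e_mean), 4 * se)
})

test_that("null p-values use the >= tail with no pseudo-count", {
  r <- null_pvalue(0, "mean", m = 4, n = 4, trials_per_dataset = 3,
                   n_datasets = 500, seed = 1)
  expect_equal(r$p_value, 1)
  r2 <- null_pvalue(100, "max", m = 4, n = 4, trials_per_dataset = 3,
                    n_datasets = 500, seed = 1)
  expect_identical(r2$p_value, 0)   # exactly zero, not 1/(N+1)
  expect_equal(r2$p_value, mean(r2$null_sample >= 100))
  expect_error(null_pvalue(1, "mean", m = 4, n = 4, trials_per_dataset = 3,
                           n_datasets = 0), "n_datasets")
  expect_error(null_pvalue(1, "median", m = 4, n = 4,
                           trials_per_dataset = 3, n_datasets = 10))
})

test_that("identical seeds reproduce the null sample bit for bit", {
  a <- null_pvalue(1.8, "mean", m = 8, n = 8, trials_per_dataset = 5,
                   n_datasets = 300, seed = 99)
  b <- null_pvalue(1.8, "mean", m = 8, n = 8, trials_per_dataset = 5,
                   n_datasets = 300, seed = 99)
  expect_identical(a$null_sample, b$null_sample)
  c <- null_pvalue(1.8, "mean", m = 8, n = 8, trials_per_dataset = 5,
                   n_datasets = 300, seed = 100)
  expect_false(identical(a$null_sample, c$null_sample))
})

test_that("an all-predators-on-one-prey draw is as rare as the closed form", {
  # P(all 8 on one prey of 8) = 8 * (1/8)^8 ~ 4.8e-7: essentially never
  # among 1e5 draws
  set.seed(17)
  s <- socialdining:::sim_uniform_trials(100000, 8, 8)
  expect_lte(sum(s$max == 8), 2)
})

test_that("null p-values are approximately uniform under the null", {
  # heterogeneous feeder counts make the dataset mean effectively
  # continuous, so ties between observed and simulated values are negligible
  set.seed(23)
  n_rep <- 5000; n_ds <- 200; tpd <- 15
  feeders <- c(5, 6, 7, 8, 9, 10, 11, 9, 8, 7, 6, 5, 8, 9, 10)
  s <- socialdining:::sim_uniform_trials(n_rep * (n_ds + 1) * tpd,
                                         feeders, 12)
  dm <- socialdining:::dataset_means(s$mean, tpd)
  by_rep <- matrix(dm, nrow = n_ds + 1)
  p <- colMeans(by_rep[-1, , drop = FALSE] >=
                  rep(by_rep[1, ], each = n_ds))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("per-trial feeder counts condition the null simulation", {
  feeders <- c(2, 5, 8)
  r <- null_pvalue(2, "mean", n = 8, m_feeding = feeders,
                   n_datasets = 400, seed = 3)
  expect_equal(r$config$trials_per_dataset, 3L)
  # every simulated dataset mean is bounded by the feeder counts
  expect_true(all(r$null_sample >= 1 & r$null_sample <= mean(feeders)))
  expect_error(null_pvalue(2, "mean", n = 8, m_feeding = feeders,
                           trials_per_dataset = 4, n_datasets = 10),
               "one entry per trial")
})
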