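test_that("exact seating enumeration matches the Ewens sampling formula", {
  for (m in 2:4) {
    for (alpha in c(0.5, 1, 4)) {
      d <- exact_sdm_partition(m, alpha)
      expect_equal(sum(d$prob), 1)
      for (i in seq_len(nrow(d))) {
        sizes <- as.integer(strsplit(d$partition[i], ",")[[1]])
        expect_equal(d$prob[i], oracle_ewens_prob(sizes, alpha),
                     tolerance = 1e-12,
                     label = sprintf("m=%d alpha=%g partition %s", m, alpha,
                                     d$partition[i]))
      }
    }
  }
})

test_that("three-predator seating probabilities match direct arithmetic", {
  d <- exact_sdm_partition(3, 1)
  probs <- setNames(d$prob, d$partition)
  expect_equal(unname(probs["3"]), 1 / 3)
  expect_equal(unname(probs["2,1"]), 1 / 2)
  expect_equal(unname(probs["1,1,1"]), 1 / 6)
})

test_that("pair-joining probability is 1/(1+alpha)", {
  for (alpha in c(0.5, 1, 4)) {
    d <- exact_sdm_partition(2, alpha)
    expect_equal(d$prob[d$partition == "2"], 1 / (1 + alpha))
  }
  # and empirically through the occupancy sampler
  set.seed(31)
  same <- replicate(4000, max(sdm_assign(2, 5, alpha = 1)) == 2)
  expect_lt(abs(mean(same) - 0.5), 0.03)
})

test_that("occupancy sampler respects model constraints", {
  set.seed(7)
  occ <- sdm_assign(8, 10, alpha = 2)
  expect_length(occ, 10L)
  expect_equal(sum(occ), 8L)
  expect_error(sdm_assign(8, 4, alpha = 2), "n >= m")
  expect_error(sdm_assign(8, 8, alpha = 0), "alpha")
  expect_error(sdm_assign(8, 8, alpha = -1), "alpha")
  # enormous alpha forces singleton seating
  set.seed(8)
  for (i in 1:20) expect_equal(max(sdm_assign(8, 8, alpha = 1e6)), 1L)
})

test_that("single-trial sampler matches the enumeration oracle (chi-square)", {
  set.seed(41)
  for (cfg in list(list(m = 3, n = 4, alpha = 1),
                   list(m = 4, n = 4, alpha = 4))) {
    exact <- exact_sdm_partition(cfg$m, cfg$alpha)
    draws <- replicate(30000, {
      occ <- sdm_assign(cfg$m, cfg$n, cfg$alpha)
      paste(sort(occ[occ > 0], decreasing = TRUE), collapse = ",")
    })
    counts <- as.numeric(table(factor(draws, levels = exact$partition)))
    expect_gt(gof_pvalue(counts, exact$prob), 0.001)
  }
})

test_that("vectorized seating matches the enumeration oracle over a grid", {
  set.seed(43)
  grid <- expand.grid(m = 2:4, alpha = c(0.5, 1, 4))
  for (i in seq_len(nrow(grid))) {
    m <- grid$m[i]; alpha <- grid$alpha[i]
    exact <- exact_sdm_partition(m, alpha)
    s <- socialdining:::sim_crp_trials(200000, m, alpha)
    key <- paste(signif(s$mean, 10), s$max)
    exact_key <- paste(signif(exact$mean_group, 10), exact$max_group)
    # for m <= 4 the (mean, max) pair identifies the partition
    expect_equal(anyDuplicated(exact_key), 0L)
    counts <- as.numeric(table(factor(key, levels = exact_key)))
    expect_gt(gof_pvalue(counts, exact$prob), 0.001,
              label = sprintf("m=%d alpha=%g", m, alpha))
  }
})

test_that("expected mean group size decreases strictly with alpha", {
  set.seed(47)
  grid <- c(0.25, 1, 4, 16, 64)
  est <- sapply(grid, function(a) {
    s <- socialdining:::sim_crp_trials(40000, 8, a)
    c(mean(s$mean), sd(s$mean) / sqrt(length(s$mean)))
  })
  for (i in seq_len(length(grid) - 1)) {
    gap <- est[1, i] - est[1, i + 1]
    expect_gt(gap, 2 * sqrt(est[2, i]^2 + est[2, i + 1]^2))
  }
})

test_that("dataset statistics approach both alpha limits", {
  set.seed(53)
  hi <- sdm_dataset_stats(1e8, m = 8, n = 8, trials_per_dataset = 200)
  expect_equal(unname(hi["mean_of_means"]), 1, tolerance = 1e-3)
  lo <- sdm_dataset_stats(1e-8, m = 8, n = 8, trials_per_dataset = 200)
  expect_equal(unname(lo["mean_of_means"]), 8, tolerance = 1e-3)
  expect_equal(unname(lo["mean_of_max"]), 8, tolerance = 1e-3)
})

test_that("sdm p-values share the >= tail convention and extremes", {
  r <- sdm_pvalue(1, "mean", alpha = 4, m = 8, n = 8,
                  trials_per_dataset = 5, n_datasets = 400, seed = 2)
  expect_equal(r$p_value, 1)   # every dataset mean is >= 1
  r2 <- sdm_pvalue(8, "mean", alpha = 4, m = 8, n = 8,
                   trials_per_dataset = 5, n_datasets = 400, seed = 2)
  expect_lt(r2$p_value, 0.01)  # the single-group extreme is out of reach
  expect_error(sdm_pvalue(2, "mean", alpha = 4, m = 9, n = 8,
                          trials_per_dataset = 5, n_datasets = 10),
               "n >= m")
})

test_that("bisection recovers known concentration parameters within 0.5", {
  for (cfg in list(list(alpha = 1, seed = 61), list(alpha = 4, seed = 62))) {
    target <- withr::with_seed(cfg$seed, {
      s <- socialdining:::sim_crp_trials(10000 * 13, 8, cfg$alpha)
      mean(s$mean)
    })
    fit <- estimate_alpha(target, m = 8, n = 8, trials_per_dataset = 13,
                          n_datasets_per_eval = 10000,
                          seed = cfg$seed + 1000)
    expect_true(fit$converged)
    expect_lt(abs(fit$alpha_hat - cfg$alpha), 0.5)
    expect_lte(abs(fit$achieved_stat - fit$target_stat), fit$tolerance)
    expect_true(fit$bracket_lo < fit$alpha_hat || !fit$converged)
  }
})

test_that("bisection rejects unattainable targets and pins at the bracket", {
  expect_error(estimate_alpha(0.9, m = 8, n = 8, trials_per_dataset = 5,
                              n_datasets_per_eval = 100),
               "attainable range")
  expect_error(estimate_alpha(8.5, m = 8, n = 8, trials_per_dataset = 5,
                              n_datasets_per_eval = 100),
               "attainable range")
  # a target just above the singleton limit pins at the upper bracket
  expect_warning(
    fit <- estimate_alpha(1.0005, m = 8, n = 8, trials_per_dataset = 5,
                          n_datasets_per_eval = 200, seed = 5,
                          bracket = c(1e-6, 50)),
    "pinned")
  expect_false(fit$converged)
  expect_equal(fit$alpha_hat, 50)
})
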