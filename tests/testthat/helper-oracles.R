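# Independent brute-force oracles and shared fixtures for the test suite.
# Everything here is written from first principles, separate from the package
# implementation it checks.

fixture_trials <- function() {
  suppressWarnings(load_trials(socialdining_example("feeding_trials.csv")))
}

fixture_choices <- function() {
  load_choices(socialdining_example("choice_assays.csv"))
}

# Exhaustive enumeration of all n^m equiprobable uniform assignments,
# returning the distribution of (mean_group, max_group).
oracle_uniform_enum <- function(m, n) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), m)))
  stats <- t(apply(grid, 1L, function(row) {
    counts <- tabulate(row, nbins = n)
    c(mean = m / sum(counts > 0), max = max(counts))
  }))
  agg <- aggregate(list(prob = rep(1 / nrow(grid), nrow(grid))),
                   by = list(mean_group = stats[, "mean"],
                             max_group = stats[, "max"]), FUN = sum)
  agg[order(agg$mean_group, agg$max_group), ]
}

# Ewens sampling formula: probability of an unordered partition with part
# multiplicities a_k (a_k parts of size k) under a CRP with concentration a.
oracle_ewens_prob <- function(sizes, alpha) {
  m <- sum(sizes)
  a_k <- tabulate(sizes, nbins = m)
  rising <- prod(alpha + seq_len(m) - 1)
  factorial(m) / rising *
    prod((alpha / seq_len(m))^a_k / factorial(a_k))
}

# Chi-square goodness of fit of observed category counts against exact
# probabilities, pooling categories with tiny expectation.
gof_pvalue <- function(counts, probs, min_expected = 5) {
  n <- sum(counts)
  keep <- probs * n >= min_expected
  if (!all(keep)) {
    counts <- c(counts[keep], sum(counts[!keep]))
    probs <- c(probs[keep], sum(probs[!keep]))
  }
  suppressWarnings(chisq.test(counts, p = probs)$p.value)
}

# Observed per-trial values from the packaged table, split by condition.
table1_values <- function() {
  tr <- fixture_trials()
  d7 <- tr[tr$deprivation_days == 7, ]
  d3 <- tr[tr$deprivation_days == 3, ]
  list(d7 = d7, d3 = d3)
}
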