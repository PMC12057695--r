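# Uniform-choice null model: m predators each select one of n prey items
# independently and with equal probability 1/n.

#' Assign predators to prey uniformly at random
#'
#' Draws one trial of the independent-choice null model: each of `m`
#' predators selects each of `n` prey items with probability `1/n`. Uses the
#' current RNG stream; call `set.seed()` for reproducibility.
#'
#' @param m Number of predators (feeding slugs).
#' @param n Number of prey items (anemones).
#' @return An occupancy vector: `n` non-negative integer counts summing to
#'   `m`.
#' @examples
#' set.seed(1)
#' assign_uniform(8, 8)
#' @export
assign_uniform <- function(m, n) {
  m <- check_count(m, "m")
  n <- check_count(n, "n")
  tabulate(sample.int(n, m, replace = TRUE), nbins = n)
}

#' Group-size statistics of one occupancy vector
#'
#' The mean group size is the number of feeding predators divided by the
#' number of occupied prey items; the maximum group size is the largest
#' single occupancy.
#'
#' @param occ An occupancy vector of non-negative integer counts.
#' @return A list with elements `mean_group` and `max_group`.
#' @examples
#' group_statistics(c(3, 2, 1, 1, 1, 0, 0, 0))  # mean 1.6, max 3
#' @export
group_statistics <- function(occ) {
  if (!is.numeric(occ) || any(occ < 0) || any(occ != round(occ))) {
    stop("`occ` must be a vector of non-negative integer counts",
         call. = FALSE)
  }
  occupied <- sum(occ > 0)
  if (occupied == 0L) stop("no feeding groups: all counts are zero",
                           call. = FALSE)
  list(mean_group = sum(occ) / occupied, max_group = max(occ))
}

# Vectorized core: per-trial (mean, max) group size for `n_trials` uniform
# trials. `m` may be a scalar or one feeder count per trial within a dataset
# (recycled across datasets).
sim_uniform_trials <- function(n_trials, m, n) {
  m_all <- rep_len(as.integer(m), n_trials)
  choice <- sample.int(n, sum(m_all), replace = TRUE)
  idx <- rep.int(seq_len(n_trials), m_all)
  counts <- matrix(tabulate((idx - 1L) * n + choice, nbins = n_trials * n),
                   nrow = n)
  occupied <- colSums(counts > 0L)
  tc <- t(counts)
  list(mean = m_all / occupied,
       max = tc[cbind(seq_len(n_trials), max.col(tc))])
}

dataset_means <- function(per_trial, trials_per_dataset) {
  colMeans(matrix(per_trial, nrow = trials_per_dataset))
}

#' Simulate one dataset of uniform-choice trials
#'
#' Simulates `trials_per_dataset` independent null-model trials and returns
#' the dataset-level means of the per-trial mean and maximum group sizes —
#' the two statistics the Monte-Carlo tests compare. Uses the current RNG
#' stream.
#'
#' @inheritParams assign_uniform
#' @param trials_per_dataset Number of trials per simulated dataset.
#' @param m_feeding Optional vector of per-trial feeder counts overriding
#'   `m` (one entry per trial); use it to condition the null model on the
#'   observed number of feeding animals in each trial.
#' @return A named numeric vector `c(mean_of_means, mean_of_max)`.
#' @examples
#' set.seed(1)
#' simulate_dataset_stats(8, 8, trials_per_dataset = 15)
#' @export
simulate_dataset_stats <- function(m, n, trials_per_dataset,
                                   m_feeding = NULL) {
  n <- check_count(n, "n")
  trials_per_dataset <- check_count(trials_per_dataset, "trials_per_dataset")
  m_vec <- resolve_m(m, m_feeding, trials_per_dataset)
  s <- sim_uniform_trials(trials_per_dataset, m_vec, n)
  c(mean_of_means = mean(s$mean), mean_of_max = mean(s$max))
}

resolve_m <- function(m, m_feeding, trials_per_dataset) {
  if (!is.null(m_feeding)) {
    m_feeding <- vapply(seq_along(m_feeding), function(i)
      check_count(m_feeding[i], "m_feeding"), integer(1L))
    if (length(m_feeding) != trials_per_dataset) {
      stop("`m_feeding` must have one entry per trial", call. = FALSE)
    }
    return(m_feeding)
  }
  rep.int(check_count(m, "m"), trials_per_dataset)
}

new_mc_result <- function(observed, statistic, sample, config) {
  structure(list(
    observed_stat = observed,
    statistic_name = sprintf("dataset mean of per-trial %s group size",
                             statistic),
    null_sample = sample,
    p_value = mean(sample >= observed),
    config = config
  ), class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat("Monte-Carlo comparison:", x$statistic_name, "\n")
  cat(sprintf("  model: %s, %d datasets of %d trials\n",
              x$config$model, length(x$null_sample),
              x$config$trials_per_dataset))
  cat(sprintf("  observed %.4f vs simulated %.4f (sd %.4f)\n",
              x$observed_stat, mean(x$null_sample), sd(x$null_sample)))
  cat(sprintf("  upper-tail P = %.5g\n", x$p_value))
  invisible(x)
}

#' Monte-Carlo p-value under the uniform-choice null model
#'
#' Simulates `n_datasets` datasets of `trials_per_dataset` trials each, takes
#' the dataset mean of the chosen per-trial statistic, and reports the
#' fraction of simulated datasets whose statistic is at least as large
#' (`>=`, no pseudo-count) as the observed value. The p-value can therefore
#' be exactly zero.
#'
#' @param observed Observed dataset-level statistic.
#' @param statistic `"mean"` (dataset mean of per-trial mean group size) or
#'   `"max"` (dataset mean of per-trial maximum group size).
#' @inheritParams simulate_dataset_stats
#' @param n_datasets Number of simulated datasets.
#' @param seed Optional integer seed; the caller's RNG stream is untouched.
#' @return An `mc_result` with the observed statistic, the simulated sample,
#'   and the upper-tail `p_value`.
#' @examples
#' null_pvalue(1.82, "mean", m = 8, n = 8, trials_per_dataset = 15,
#'             n_datasets = 1000, seed = 1)
#' @export
null_pvalue <- function(observed, statistic = c("mean", "max"), m = NULL,
                        n = 8, trials_per_dataset = NULL, n_datasets = 1e5,
                        m_feeding = NULL, seed = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(is.numeric(observed), length(observed) == 1L)
  n <- check_count(n, "n")
  n_datasets <- check_count(n_datasets, "n_datasets")
  if (is.null(trials_per_dataset) && !is.null(m_feeding)) {
    trials_per_dataset <- length(m_feeding)
  }
  trials_per_dataset <- check_count(trials_per_dataset, "trials_per_dataset")
  m_vec <- resolve_m(m, m_feeding, trials_per_dataset)
  sample <- with_seed(seed, {
    s <- sim_uniform_trials(n_datasets * trials_per_dataset, m_vec, n)
    dataset_means(s[[statistic]], trials_per_dataset)
  })
  new_mc_result(observed, statistic, sample, list(
    model = "uniform null", m = unique(m_vec), n = n,
    trials_per_dataset = trials_per_dataset, n_datasets = n_datasets,
    m_feeding = m_feeding, seed = seed))
}

#' Exact null distribution of group-size statistics
#'
#' Enumerates the occupancy partitions of `m` predators over `n` prey items
#' under uniform independent choice, with exact multinomial probabilities,
#' and returns the induced distribution of the per-trial (mean, max)
#' group-size pair. Serves as the brute-force oracle for the Monte-Carlo
#' simulator.
#'
#' @inheritParams assign_uniform
#' @return A data frame with columns `mean_group`, `max_group`, `prob`
#'   (summing to one), one row per distinct statistic pair.
#' @examples
#' d <- exact_null_distribution(2, 2)
#' sum(d$mean_group * d$prob)  # 1.5
#' @export
exact_null_distribution <- function(m, n) {
  m <- check_count(m, "m")
  n <- check_count(n, "n")
  if (choose(m + n - 1, n - 1) > 2e6) {
    stop("too many occupancy patterns to enumerate; ",
         "use the Monte-Carlo simulator instead", call. = FALSE)
  }
  parts <- integer_partitions(m, max_parts = n)
  rows <- lapply(parts, function(p) {
    k <- length(p)
    mult <- table(p)
    # labeled prey arrangements of this partition x multinomial probability
    arrangements <- exp(lfactorial(n) - lfactorial(n - k) -
                          sum(lfactorial(mult)))
    prob_one <- exp(lfactorial(m) - sum(lfactorial(p)) - m * log(n))
    data.frame(mean_group = m / k, max_group = max(p),
               prob = arrangements * prob_one)
  })
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(prob ~ mean_group + max_group, data = out, sum)
  agg[order(agg$mean_group, agg$max_group), ]
}

# All partitions of m into at most `max_parts` positive parts
# (non-increasing order).
integer_partitions <- function(m, max_parts = m) {
  rec <- function(remaining, largest, parts) {
    if (remaining == 0L) return(list(parts))
    if (length(parts) >= max_parts) return(list())
    out <- list()
    for (p in seq_len(min(remaining, largest))) {
      out <- c(out, rec(remaining - p, p, c(parts, p)))
    }
    out
  }
  rec(m, m, integer(0))
}
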