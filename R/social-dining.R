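# Social dining model: sequential Chinese-restaurant-process seating of m
# predators over n prey items (n >= m). With k predators already seated, the
# next one joins an occupied prey item holding m_i predators with probability
# m_i / (k + alpha) and opens a new feeding group with probability
# alpha / (k + alpha), the new prey item drawn uniformly from those still
# unoccupied. The denominator is the number already seated plus alpha — the
# standard CRP normalization, without which the seating probabilities do not
# sum to one.

#' Seat predators by the social dining model
#'
#' Draws one trial of the social dining model over `n` labeled prey items.
#' The first predator seats uniformly at random; each later one joins an
#' occupied prey item with probability proportional to its occupancy and
#' starts a new group with probability proportional to `alpha` (the new prey
#' item uniform among the unoccupied ones, which always exist because
#' `n >= m`). Uses the current RNG stream.
#'
#' @param m Number of predators.
#' @param n Number of prey items; must satisfy `n >= m`.
#' @param alpha Concentration parameter (> 0). Small values give strong
#'   clustering; large values approach independent singleton seating.
#' @return An occupancy vector of `n` non-negative integer counts summing to
#'   `m`.
#' @examples
#' set.seed(1)
#' sdm_assign(8, 8, alpha = 4)
#' @export
sdm_assign <- function(m, n, alpha) {
  m <- check_count(m, "m")
  n <- check_count(n, "n")
  check_alpha(alpha)
  if (m > n) {
    stop("the social dining model assumes n >= m (at least as many prey ",
         "items as predators)", call. = FALSE)
  }
  occ <- integer(n)
  occ[sample.int(n, 1L)] <- 1L
  for (k in seq_len(m - 1L)) {
    u <- runif(1L) * (k + alpha)
    if (u < k) {
      # join: pick the occupied prey item containing the floor(u)+1-th seat
      occupied <- which(occ > 0L)
      j <- occupied[findInterval(u, cumsum(occ[occupied])) + 1L]
    } else {
      empty <- which(occ == 0L)
      j <- empty[sample.int(length(empty), 1L)]
    }
    occ[j] <- occ[j] + 1L
  }
  occ
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("`alpha` must be a single positive number", call. = FALSE)
  }
  invisible(alpha)
}

# Vectorized core: per-trial (mean, max) group size for n_trials CRP trials.
# Only the partition of predators into groups matters for the group-size
# statistics, so prey-item labels are not tracked here. `m` may be a scalar
# or a per-trial feeder count (recycled across datasets). The number of RNG
# draws is (max(m) - 1) * n_trials regardless of alpha, so a fixed seed
# yields common random numbers across alpha values.
sim_crp_trials <- function(n_trials, m, alpha) {
  m_all <- rep_len(as.integer(m), n_trials)
  m_max <- max(m_all)
  sizes <- matrix(0L, n_trials, m_max)
  sizes[, 1L] <- 1L
  n_groups <- rep.int(1L, n_trials)
  if (m_max > 1L) {
    for (k in seq_len(m_max - 1L)) {
      u <- runif(n_trials) * (k + alpha)
      active <- m_all > k
      cum <- sizes
      if (m_max > 1L) {
        for (j in 2:m_max) cum[, j] <- cum[, j] + cum[, j - 1L]
      }
      pick <- rowSums(cum < u) + 1L
      new_group <- pick > n_groups
      pick[new_group] <- n_groups[new_group] + 1L
      sel <- which(active)
      n_groups[sel] <- n_groups[sel] +
        (new_group[sel])
      idx <- cbind(sel, pick[sel])
      sizes[idx] <- sizes[idx] + 1L
    }
  }
  list(mean = m_all / n_groups,
       max = sizes[cbind(seq_len(n_trials), max.col(sizes))])
}

#' Simulate one dataset of social-dining trials
#'
#' As [simulate_dataset_stats()], but seating each trial by the social dining
#' model at concentration `alpha`.
#'
#' @inheritParams sdm_assign
#' @inheritParams simulate_dataset_stats
#' @return A named numeric vector `c(mean_of_means, mean_of_max)`.
#' @examples
#' set.seed(1)
#' sdm_dataset_stats(4, m = 8, n = 8, trials_per_dataset = 13)
#' @export
sdm_dataset_stats <- function(alpha, m, n, trials_per_dataset,
                              m_feeding = NULL) {
  check_alpha(alpha)
  n <- check_count(n, "n")
  trials_per_dataset <- check_count(trials_per_dataset, "trials_per_dataset")
  m_vec <- resolve_m(m, m_feeding, trials_per_dataset)
  if (any(m_vec > n)) {
    stop("the social dining model assumes n >= m", call. = FALSE)
  }
  s <- sim_crp_trials(trials_per_dataset, m_vec, alpha)
  c(mean_of_means = mean(s$mean), mean_of_max = mean(s$max))
}

#' Monte-Carlo p-value under the social dining model
#'
#' As [null_pvalue()], with trials seated by the social dining model at
#' concentration `alpha` instead of uniform choice. The same upper-tail
#' (`>=`) convention is used.
#'
#' @inheritParams null_pvalue
#' @inheritParams sdm_assign
#' @return An `mc_result`.
#' @examples
#' sdm_pvalue(1.85, "mean", alpha = 4, m = 8, n = 8,
#'            trials_per_dataset = 13, n_datasets = 1000, seed = 1)
#' @export
sdm_pvalue <- function(observed, statistic = c("mean", "max"), alpha,
                       m = NULL, n = 8, trials_per_dataset = NULL,
                       n_datasets = 1e5, m_feeding = NULL, seed = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(is.numeric(observed), length(observed) == 1L)
  check_alpha(alpha)
  n <- check_count(n, "n")
  n_datasets <- check_count(n_datasets, "n_datasets")
  if (is.null(trials_per_dataset) && !is.null(m_feeding)) {
    trials_per_dataset <- length(m_feeding)
  }
  trials_per_dataset <- check_count(trials_per_dataset, "trials_per_dataset")
  m_vec <- resolve_m(m, m_feeding, trials_per_dataset)
  if (any(m_vec > n)) {
    stop("the social dining model assumes n >= m", call. = FALSE)
  }
  sample <- with_seed(seed, {
    s <- sim_crp_trials(n_datasets * trials_per_dataset, m_vec, alpha)
    dataset_means(s[[statistic]], trials_per_dataset)
  })
  new_mc_result(observed, statistic, sample, list(
    model = sprintf("social dining (alpha = %.4g)", alpha),
    alpha = alpha, m = unique(m_vec), n = n,
    trials_per_dataset = trials_per_dataset, n_datasets = n_datasets,
    m_feeding = m_feeding, seed = seed))
}

#' Estimate the concentration parameter by bisection
#'
#' Finds the concentration parameter `alpha` at which the Monte-Carlo
#' expectation of a dataset-level group-size statistic matches an observed
#' value. The expectation is strictly decreasing in `alpha` (stronger
#' clustering at small `alpha`), so plain bisection applies. Every
#' evaluation reuses the same RNG seed (common random numbers), which makes
#' the simulated objective a deterministic, near-monotone function of
#' `alpha` and lets the bisection converge to the stated tolerance even
#' though each evaluation is stochastic.
#'
#' @param target_stat Observed dataset statistic to match. Must lie strictly
#'   between 1 (the `alpha -> Inf` limit of the mean statistic) and `m` (the
#'   `alpha -> 0` single-group limit).
#' @inheritParams sdm_dataset_stats
#' @param n_datasets_per_eval Simulated datasets per bisection evaluation.
#' @param tolerance Convergence tolerance on the statistic scale.
#' @param bracket Length-2 numeric bracket for `alpha`.
#' @param seed Optional integer seed (also the common-random-numbers seed).
#' @param max_iter Maximum bisection iterations.
#' @param statistic Which dataset statistic to match: `"mean"` (default, the
#'   dataset mean of per-trial mean group sizes) or `"max"`.
#' @return An `alpha_fit` list: `alpha_hat`, `target_stat`, `achieved_stat`,
#'   `iterations`, `bracket_lo`, `bracket_hi` (final bracket), `tolerance`,
#'   `n_datasets_per_eval`, `seed`, `statistic`, `converged`.
#' @examples
#' estimate_alpha(1.85, m = 8, n = 8, trials_per_dataset = 13,
#'                n_datasets_per_eval = 500, seed = 1)
#' @export
estimate_alpha <- function(target_stat, m, n, trials_per_dataset,
                           n_datasets_per_eval = 1e4, tolerance = 1e-3,
                           bracket = c(1e-6, 1e3), seed = NULL,
                           max_iter = 100L, statistic = c("mean", "max"),
                           m_feeding = NULL) {
  statistic <- match.arg(statistic)
  n <- check_count(n, "n")
  trials_per_dataset <- check_count(trials_per_dataset, "trials_per_dataset")
  n_datasets_per_eval <- check_count(n_datasets_per_eval,
                                     "n_datasets_per_eval")
  max_iter <- check_count(max_iter, "max_iter")
  m_vec <- resolve_m(m, m_feeding, trials_per_dataset)
  if (any(m_vec > n)) {
    stop("the social dining model assumes n >= m", call. = FALSE)
  }
  stopifnot(is.numeric(target_stat), length(target_stat) == 1L,
            is.numeric(bracket), length(bracket) == 2L, bracket[1] > 0,
            bracket[1] < bracket[2], tolerance > 0)
  # alpha -> 0 puts every trial in a single group (statistic -> mean(m));
  # alpha -> Inf gives all singletons (statistic -> 1)
  if (target_stat <= 1 || target_stat >= mean(m_vec)) {
    stop(sprintf(
      "target statistic %.4g is outside the attainable range (1, %.4g)",
      target_stat, mean(m_vec)), call. = FALSE)
  }
  eval_seed <- derive_seed(seed, 1L) %||% sample.int(2^31 - 2, 1L)
  objective <- function(alpha) {
    with_seed(eval_seed, {
      s <- sim_crp_trials(n_datasets_per_eval * trials_per_dataset, m_vec,
                          alpha)
      mean(s[[statistic]])
    }) - target_stat
  }
  lo <- bracket[1]; hi <- bracket[2]
  g_lo <- objective(lo); g_hi <- objective(hi)
  make_fit <- function(alpha_hat, achieved, iter, converged) {
    structure(list(
      alpha_hat = alpha_hat, target_stat = target_stat,
      achieved_stat = achieved, iterations = iter,
      bracket_lo = lo, bracket_hi = hi, tolerance = tolerance,
      n_datasets_per_eval = n_datasets_per_eval, seed = seed,
      statistic = statistic, converged = converged
    ), class = "alpha_fit")
  }
  if (g_lo < 0) {
    stop(sprintf(
      "target %.4g exceeds the simulated statistic %.4g at bracket_lo = %g",
      target_stat, g_lo + target_stat, lo), call. = FALSE)
  }
  if (g_hi > 0) {
    warning("target below the simulated statistic at bracket_hi; ",
            "alpha_hat pinned at the upper bracket", call. = FALSE)
    return(make_fit(hi, g_hi + target_stat, 0L, FALSE))
  }
  for (iter in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    g_mid <- objective(mid)
    if (abs(g_mid) <= tolerance) {
      return(make_fit(mid, g_mid + target_stat, iter, TRUE))
    }
    if (g_mid > 0) lo <- mid else hi <- mid
  }
  stop(sprintf(
    paste0("bisection did not reach tolerance %.3g within %d iterations ",
           "(bracket [%.6g, %.6g]); increase n_datasets_per_eval or the ",
           "tolerance"),
    tolerance, max_iter, lo, hi), call. = FALSE)
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat("Concentration-parameter fit (bisection, common random numbers)\n")
  cat(sprintf("  alpha_hat = %.4f  (%sconverged, %d iterations)\n",
              x$alpha_hat, if (x$converged) "" else "NOT ", x$iterations))
  cat(sprintf("  matched dataset %s statistic: target %.4f, achieved %.4f\n",
              x$statistic, x$target_stat, x$achieved_stat))
  cat(sprintf("  %d datasets per evaluation, tolerance %.3g\n",
              x$n_datasets_per_eval, x$tolerance))
  invisible(x)
}

#' Exact partition distribution of the social dining model
#'
#' Enumerates every sequential seating path of `m` predators under the
#' social dining model and accumulates the probability of each unordered
#' partition of predators into feeding groups. Because the model is
#' exchangeable, this equals the Ewens sampling distribution; the function
#' serves as the brute-force oracle for [sdm_assign()] and
#' [sim_crp_trials()].
#'
#' @param m Number of predators (kept small; the recursion enumerates all
#'   seating paths and is guarded at `m <= 12`).
#' @param alpha Concentration parameter.
#' @return A data frame with one row per partition: `partition` (sizes in
#'   decreasing order, comma-separated), `n_groups`, `mean_group`,
#'   `max_group`, `prob` (summing to one).
#' @examples
#' exact_sdm_partition(3, alpha = 1)  # {3}: 1/6, {2,1}: 1/2, {1,1,1}: 1/3
#' @export
exact_sdm_partition <- function(m, alpha) {
  m <- check_count(m, "m")
  check_alpha(alpha)
  if (m > 12L) stop("exact enumeration is guarded at m <= 12", call. = FALSE)
  acc <- new.env(parent = emptyenv())
  rec <- function(sizes, k, prob) {
    if (k == m) {
      key <- paste(sort(sizes, decreasing = TRUE), collapse = ",")
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + prob
      return(invisible())
    }
    denom <- k + alpha
    for (j in seq_along(sizes)) {
      grown <- sizes
      grown[j] <- grown[j] + 1L
      rec(grown, k + 1L, prob * sizes[j] / denom)
    }
    rec(c(sizes, 1L), k + 1L, prob * alpha / denom)
  }
  rec(1L, 1L, 1)
  keys <- ls(acc)
  out <- data.frame(
    partition = keys,
    prob = vapply(keys, function(k) acc[[k]], numeric(1L)),
    stringsAsFactors = FALSE
  )
  sizes <- lapply(strsplit(out$partition, ","), as.integer)
  out$n_groups <- vapply(sizes, length, integer(1L))
  out$mean_group <- m / out$n_groups
  out$max_group <- vapply(sizes, max, integer(1L))
  out <- out[order(-out$n_groups, out$partition),
             c("partition", "n_groups", "mean_group", "max_group", "prob")]
  rownames(out) <- NULL
  out
}
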