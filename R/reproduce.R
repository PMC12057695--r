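# One-shot reproduction of every computational result derivable from the
# packaged tables.

#' Recompute the study's group-formation results
#'
#' Runs the full pipeline on a feeding-trial table and a choice-assay table
#' (the packaged tables by default): per-condition dataset summaries;
#' uniform-null Monte-Carlo p-values for the dataset mean of per-trial mean
#' and maximum group sizes (conditioning each simulated trial on the
#' observed number of feeding animals, plus an all-`m`-feed sensitivity
#' run); the bisection fit of the social-dining concentration parameter to
#' the 3-day dataset; social-dining Monte-Carlo p-values at the fitted
#' concentration; every exact binomial choice test; and Welch comparisons of
#' the two group-size statistics between deprivation conditions.
#'
#' Observed statistics for the model comparisons use
#' [refine_group_means()] so they equal the unrounded per-trial values (set
#' `refine_means = FALSE` to compare the printed two-decimal values
#' instead); dataset summaries always aggregate the table as loaded.
#'
#' @param trials Path to a feeding-trial CSV, or a [trial_dataset()].
#' @param choices Path to a choice-assay CSV, or a `choice_records` frame.
#' @param n_datasets Simulated datasets per Monte-Carlo p-value.
#' @param fit_n_datasets Simulated datasets per bisection evaluation.
#' @param seed Integer seed governing every stochastic stage.
#' @param refine_means Reconstruct exact rational per-trial means before
#'   computing observed statistics (default `TRUE`).
#' @return A `reproduction_report` list; see [write_report()].
#' @examples
#' rep <- run_reproduction(n_datasets = 500, fit_n_datasets = 200, seed = 1)
#' rep$alpha_fit$alpha_hat
#' @export
run_reproduction <- function(trials = socialdining_example("feeding_trials.csv"),
                             choices = socialdining_example("choice_assays.csv"),
                             n_datasets = 1e5, fit_n_datasets = 1e4,
                             seed = 1, refine_means = TRUE) {
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("reproduction stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  trials <- stage("load_trials", {
    if (inherits(trials, "trial_dataset")) trials else load_trials(trials)
  })
  records <- stage("load_choices", {
    if (inherits(choices, "choice_records")) choices
    else load_choices(choices)
  })

  split_days <- sort(unique(trials$deprivation_days), decreasing = TRUE)
  groups <- lapply(split_days, function(d) {
    ds <- trials[trials$deprivation_days == d, ]
    # inconsistent printed rows already warned about at load time
    suppressWarnings(
      trial_dataset(ds, label = sprintf("%d-day deprivation", d)))
  })
  names(groups) <- paste0("d", split_days)

  summaries <- stage("summarize", lapply(groups, summarize_trials))

  observed <- lapply(groups, function(g) {
    go <- if (refine_means) suppressWarnings(refine_group_means(g)) else g
    list(mean = mean(go$mean_group_size, na.rm = TRUE),
         max = mean(go$max_group_size, na.rm = TRUE),
         feeders = g$n_slugs - g$n_not_feeding,
         m = g$n_slugs[1L], n = g$n_anemones[1L], n_trials = nrow(g))
  })

  null_results <- stage("null_pvalue", {
    out <- list()
    for (gname in names(groups)) {
      ob <- observed[[gname]]
      for (st in c("mean", "max")) {
        out[[paste0(gname, "_", st)]] <- null_pvalue(
          ob[[st]], st, n = ob$n, m_feeding = ob$feeders,
          n_datasets = n_datasets,
          seed = derive_seed(seed, 10 + match(gname, names(groups))))
        out[[paste0(gname, "_", st, "_all_feed")]] <- null_pvalue(
          ob[[st]], st, m = ob$m, n = ob$n,
          trials_per_dataset = ob$n_trials, n_datasets = n_datasets,
          seed = derive_seed(seed, 20 + match(gname, names(groups))))
      }
    }
    out
  })

  fit_group <- if ("d3" %in% names(groups)) "d3" else names(groups)[1L]
  ob_fit <- observed[[fit_group]]
  alpha_fit <- stage("estimate_alpha", estimate_alpha(
    ob_fit$mean, m = ob_fit$m, n = ob_fit$n,
    trials_per_dataset = ob_fit$n_trials,
    n_datasets_per_eval = fit_n_datasets,
    seed = derive_seed(seed, 30)))

  sdm_results <- stage("sdm_pvalue", {
    out <- list()
    for (gname in names(groups)) {
      ob <- observed[[gname]]
      for (st in c("mean", "max")) {
        out[[paste0(gname, "_", st)]] <- sdm_pvalue(
          ob[[st]], st, alpha = alpha_fit$alpha_hat, m = ob_fit$m,
          n = ob_fit$n, trials_per_dataset = ob_fit$n_trials,
          n_datasets = n_datasets,
          seed = derive_seed(seed, 40 + match(gname, names(groups))))
      }
    }
    out
  })

  tallies <- stage("tally_choices", tally_choices(records))
  binomial <- stage("exact_binomial_test", lapply(
    seq_len(nrow(tallies)), function(i) {
      with(tallies[i, ], {
        r <- exact_binomial_test(k_social, n)
        c(as.list(tallies[i, ]),
          list(p_value = r$p_value, ci_low = r$ci_low, ci_high = r$ci_high))
      })
    }))

  welch <- stage("welch_t_test", {
    if (length(groups) == 2L) {
      g_lo <- suppressWarnings(
        if (refine_means) refine_group_means(groups[[2L]]) else groups[[2L]])
      g_hi <- suppressWarnings(
        if (refine_means) refine_group_means(groups[[1L]]) else groups[[1L]])
      list(
        mean = welch_t_test(g_lo$mean_group_size, g_hi$mean_group_size),
        max = welch_t_test(g_lo$max_group_size, g_hi$max_group_size))
    }
  })

  structure(list(
    summaries = summaries,
    observed = lapply(observed, function(o) o[c("mean", "max")]),
    null = null_results,
    alpha_fit = alpha_fit,
    sdm = sdm_results,
    binomial = binomial,
    welch = welch,
    provenance = list(
      package = "socialdining",
      version = as.character(utils::packageVersion("socialdining")),
      seed = seed, n_datasets = n_datasets,
      fit_n_datasets = fit_n_datasets, refine_means = refine_means,
      report_schema = "1")
  ), class = "reproduction_report")
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat("== Group-formation reproduction report ==\n\n")
  for (s in x$summaries) print(s)
  cat("\nUniform-null Monte-Carlo p-values (feeder-count convention):\n")
  for (nm in names(x$null)) {
    if (grepl("all_feed", nm)) next
    cat(sprintf("  %-10s P = %.5g\n", nm, x$null[[nm]]$p_value))
  }
  cat("Sensitivity (all animals feeding):\n")
  for (nm in grep("all_feed", names(x$null), value = TRUE)) {
    cat(sprintf("  %-18s P = %.5g\n", nm, x$null[[nm]]$p_value))
  }
  cat("\n")
  print(x$alpha_fit)
  cat("\nSocial-dining Monte-Carlo p-values at the fitted alpha:\n")
  for (nm in names(x$sdm)) {
    cat(sprintf("  %-10s P = %.5g\n", nm, x$sdm[[nm]]$p_value))
  }
  cat("\nExact binomial choice tests:\n")
  for (b in x$binomial) {
    cat(sprintf("  %-6s %dd %-4s %2d/%2d  P = %.3g\n", b$assay,
                b$deprivation_days, b$acclimation, b$k_social, b$n,
                b$p_value))
  }
  if (!is.null(x$welch)) {
    cat("\nWelch comparisons between deprivation conditions:\n")
    cat(sprintf("  mean group size: t = %.5g, df = %.5g, P = %.4g\n",
                x$welch$mean$t_stat, x$welch$mean$df, x$welch$mean$p_value))
    cat(sprintf("  max group size:  t = %.5g, df = %.5g, P = %.4g\n",
                x$welch$max$t_stat, x$welch$max$df, x$welch$max$p_value))
  }
  cat(sprintf("\nseed %s; %s datasets per test; %s per fit evaluation\n",
              x$provenance$seed, x$provenance$n_datasets,
              x$provenance$fit_n_datasets))
  invisible(x)
}

#' Write a reproduction report to disk
#'
#' Writes `report.json` (machine-readable; Monte-Carlo samples are reduced
#' to their p-values and moments so the file stays small and deterministic)
#' and `report.txt` (the printed report).
#'
#' @param report A `reproduction_report` from [run_reproduction()].
#' @param dir Output directory (created if missing).
#' @return The two file paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "reproduction_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  strip_mc <- function(r) list(
    observed_stat = r$observed_stat, statistic_name = r$statistic_name,
    p_value = r$p_value, null_mean = mean(r$null_sample),
    null_sd = sd(r$null_sample), config = r$config)
  payload <- list(
    summaries = lapply(report$summaries, unclass),
    observed = report$observed,
    null = lapply(report$null, strip_mc),
    alpha_fit = unclass(report$alpha_fit),
    sdm = lapply(report$sdm, strip_mc),
    binomial = report$binomial,
    welch = lapply(report$welch, unclass),
    provenance = report$provenance)
  json_path <- file.path(dir, "report.json")
  txt_path <- file.path(dir, "report.txt")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  writeLines(utils::capture.output(print(report)), txt_path)
  invisible(c(json = json_path, txt = txt_path))
}
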