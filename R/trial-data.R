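#' Path to a packaged example table
#'
#' The package ships the two study tables it analyses as plain CSV:
#' `feeding_trials.csv` (one row per group-feeding trial: arena counts,
#' maximum and mean feeding-group size, number of non-feeders) and
#' `choice_assays.csv` (one row per two-alternative choice trial).
#'
#' @param file File name, or `NULL` to list the available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' socialdining_example()
#' socialdining_example("feeding_trials.csv")
#' @export
socialdining_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "socialdining")))
  }
  path <- system.file("extdata", file, package = "socialdining")
  if (!nzchar(path)) {
    stop("no packaged file '", file, "'; see socialdining_example()",
         call. = FALSE)
  }
  path
}

trial_columns <- c(
  "trial_id", "deprivation_days", "n_slugs", "n_anemones",
  "max_group_size", "mean_group_size", "n_not_feeding"
)

#' Construct a validated trial dataset
#'
#' @param trials A data frame with the columns listed in [load_trials()].
#' @param label Optional dataset label (e.g. a deprivation condition).
#' @return A `trial_dataset`: a data frame with the seven trial columns and a
#'   `label` attribute.
#' @export
trial_dataset <- function(trials, label = NULL) {
  trials <- as.data.frame(trials)
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  trials <- trials[trial_columns]
  if (nrow(trials) == 0L) stop("trial dataset is empty", call. = FALSE)
  for (col in trial_columns) {
    v <- trials[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1L]
      stop(sprintf("non-numeric value in column '%s', row %d", col,
                   if (is.na(bad)) 1L else bad), call. = FALSE)
    }
    allow_na <- col %in% c("max_group_size", "mean_group_size")
    if (!allow_na && anyNA(v)) {
      stop(sprintf("missing value in column '%s', row %d", col,
                   which(is.na(v))[1L]), call. = FALSE)
    }
  }
  if (anyDuplicated(trials$trial_id)) {
    stop("trial_id values must be unique within a dataset", call. = FALSE)
  }
  with(trials, {
    if (any(n_not_feeding > n_slugs)) {
      stop("n_not_feeding exceeds n_slugs in row ",
           which(n_not_feeding > n_slugs)[1L], call. = FALSE)
    }
    if (any(max_group_size > n_slugs, na.rm = TRUE)) {
      stop("max_group_size exceeds n_slugs in row ",
           which(max_group_size > n_slugs)[1L], call. = FALSE)
    }
    feeding <- n_not_feeding < n_slugs
    if (any(feeding & !is.na(mean_group_size) & mean_group_size < 1)) {
      stop("mean_group_size below 1 despite feeding slugs in row ",
           which(feeding & mean_group_size < 1)[1L], call. = FALSE)
    }
  })
  # Source tables are preserved verbatim: a printed max below the printed
  # mean (a known inconsistency in one trial) warns but never rejects.
  bad <- which(trials$max_group_size < trials$mean_group_size)
  if (length(bad)) {
    warning("max_group_size < mean_group_size in trial(s) ",
            paste(trials$trial_id[bad], collapse = ", "),
            "; kept as recorded", call. = FALSE)
  }
  rownames(trials) <- NULL
  structure(trials, label = label,
            class = c("trial_dataset", "data.frame"))
}

#' Read a feeding-trial table
#'
#' Reads a CSV with one row per group-feeding trial and columns `trial_id`,
#' `deprivation_days`, `n_slugs`, `n_anemones`, `max_group_size`,
#' `mean_group_size` and `n_not_feeding`. Row order is preserved. Rows whose
#' printed maximum group size falls below the printed mean are loaded with a
#' warning rather than rejected, so published tables reproduce verbatim.
#'
#' @param path Path to a CSV file.
#' @param label Optional dataset label.
#' @return A [trial_dataset()].
#' @examples
#' trials <- load_trials(socialdining_example("feeding_trials.csv"))
#' nrow(trials)
#' @export
load_trials <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty trial file: ", path, call. = FALSE)
  trial_dataset(raw, label = label)
}

#' Write a feeding-trial table
#'
#' Inverse of [load_trials()]: `load_trials(write_trials(x, f))` returns `x`
#' field for field.
#'
#' @param dataset A [trial_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  write.csv(as.data.frame(dataset), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize a trial dataset
#'
#' Column-wise aggregates of the two per-trial group-size statistics: the
#' mean, median and sample (n-1) standard deviation of the per-trial mean
#' group size, and the same three aggregates of the per-trial maximum group
#' size. Trials without group statistics (no feeding slugs) are excluded from
#' the aggregates but counted in `n_trials`.
#'
#' @param dataset A [trial_dataset()].
#' @return A `trial_summary` list with elements `label`, `n_trials`,
#'   `mean_of_means`, `median_of_means`, `sd_of_means`, `mean_of_max`,
#'   `median_of_max`, `sd_of_max`.
#' @examples
#' trials <- load_trials(socialdining_example("feeding_trials.csv"))
#' summarize_trials(trials[trials$deprivation_days == 7, ])
#' @export
summarize_trials <- function(dataset) {
  if (!inherits(dataset, "trial_dataset")) dataset <- trial_dataset(dataset)
  if (nrow(dataset) == 0L) stop("empty trial dataset", call. = FALSE)
  mg <- dataset$mean_group_size
  xg <- dataset$max_group_size
  agg <- function(v) {
    v <- v[!is.na(v)]
    c(mean = mean(v), median = median(v),
      sd = if (length(v) > 1L) sd(v) else NA_real_)
  }
  a <- agg(mg); b <- agg(xg)
  structure(list(
    label = attr(dataset, "label"),
    n_trials = nrow(dataset),
    mean_of_means = a[["mean"]], median_of_means = a[["median"]],
    sd_of_means = a[["sd"]],
    mean_of_max = b[["mean"]], median_of_max = b[["median"]],
    sd_of_max = b[["sd"]]
  ), class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, digits = 4, ...) {
  cat("Trial dataset summary",
      if (!is.null(x$label)) paste0(" (", x$label, ")"), "\n", sep = "")
  cat("  trials:          ", x$n_trials, "\n", sep = "")
  cat(sprintf("  mean group size: mean %.*g, median %.*g, sd %.*g\n",
              digits, x$mean_of_means, digits, x$median_of_means,
              digits, x$sd_of_means))
  cat(sprintf("  max group size:  mean %.*g, median %.*g, sd %.*g\n",
              digits, x$mean_of_max, digits, x$median_of_max,
              digits, x$sd_of_max))
  invisible(x)
}

#' Export a trial summary as JSON
#'
#' @param summary A `trial_summary` from [summarize_trials()].
#' @param path Output path for a JSON file.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "trial_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Reconstruct exact per-trial mean group sizes
#'
#' A per-trial mean feeding-group size is a ratio of two small integers
#' (feeding slugs over feeding groups), but published tables print it rounded
#' to two decimals (e.g. 7/3 as 2.33). For each trial this replaces the
#' printed value with the closest ratio `a/b` with `1 <= b <= a <= n_slugs`,
#' preferring the smaller denominator on ties. Values that are already exact
#' ratios (1.75, 1.4, 2.5, ...) are unchanged. Location tests on the refined
#' values reproduce statistics computed from unrounded data.
#'
#' @param dataset A [trial_dataset()].
#' @return The dataset with `mean_group_size` refined.
#' @examples
#' trials <- load_trials(socialdining_example("feeding_trials.csv"))
#' refine_group_means(trials)$mean_group_size[9]  # 2.33 -> 7/3
#' @export
refine_group_means <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  refine_one <- function(v, m) {
    if (is.na(v)) return(v)
    best <- v; err <- Inf
    for (b in seq_len(m)) {
      a <- round(v * b)
      if (a < b || a > m) next
      e <- abs(v - a / b)
      if (e < err - 1e-12) { err <- e; best <- a / b }
    }
    best
  }
  dataset$mean_group_size <- mapply(
    refine_one, dataset$mean_group_size, dataset$n_slugs
  )
  dataset
}

assay_codes <- c("ST", "FC", "ST+FC", "BA", "MA")

#' Read a choice-assay record table
#'
#' Reads a CSV with one row per two-alternative choice trial and columns
#' `assay` (one of `ST`, `FC`, `ST+FC`, `BA`, `MA`), `deprivation_days`,
#' `acclimation` (`ASW` or `ATW`) and `choice` (`social`, `control`, or
#' `none` for omitted no-choice trials). Optional columns `latency_s`,
#' `chosen_diameter_cm` and `other_diameter_cm` are carried through and
#' filled with `NA` when absent.
#'
#' @param path Path to a CSV file.
#' @return A `choice_records` data frame with an added logical column
#'   `chose_social` (`NA` for omitted trials).
#' @examples
#' rec <- load_choices(socialdining_example("choice_assays.csv"))
#' tally_choices(rec, assay = "FC", deprivation_days = 7, acclimation = "ASW")
#' @export
load_choices <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("assay", "deprivation_days", "acclimation", "choice")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(raw$assay), assay_codes)
  if (length(bad)) {
    stop("unknown assay code(s): ", paste(bad, collapse = ", "),
         "; valid codes are ", paste(assay_codes, collapse = ", "),
         call. = FALSE)
  }
  if (!all(raw$acclimation %in% c("ASW", "ATW"))) {
    stop("acclimation must be 'ASW' or 'ATW'", call. = FALSE)
  }
  if (!all(raw$choice %in% c("social", "control", "none"))) {
    stop("choice must be 'social', 'control' or 'none'", call. = FALSE)
  }
  for (col in c("latency_s", "chosen_diameter_cm", "other_diameter_cm")) {
    if (is.null(raw[[col]])) raw[[col]] <- NA_real_
    raw[[col]] <- as.numeric(raw[[col]])
    lower <- if (col == "latency_s") 0 else .Machine$double.xmin
    if (any(raw[[col]] < lower, na.rm = TRUE)) {
      stop("column '", col, "' must be ",
           if (col == "latency_s") "non-negative" else "positive",
           " where present", call. = FALSE)
    }
  }
  raw$chose_social <- ifelse(raw$choice == "none", NA, raw$choice == "social")
  rownames(raw) <- NULL
  structure(raw, class = c("choice_records", "data.frame"))
}

#' Write a choice-assay record table
#'
#' @param records A `choice_records` data frame from [load_choices()] or
#'   [gen_choice_records()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_choices <- function(records, path) {
  stopifnot(inherits(records, "choice_records"))
  out <- as.data.frame(records)
  out$chose_social <- NULL
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tally choice records per assay condition
#'
#' Counts, for each assay condition, the trials with a choice (`n`), the
#' social selections (`k_social`) and the omitted no-choice trials
#' (`n_omitted`). With any of the filter arguments supplied, only matching
#' records are tallied and a single row is always returned (all zero when no
#' record matches).
#'
#' @param records A `choice_records` data frame.
#' @param assay,deprivation_days,acclimation Optional filters.
#' @return A data frame with columns `assay`, `deprivation_days`,
#'   `acclimation`, `n`, `k_social`, `n_omitted`.
#' @export
tally_choices <- function(records, assay = NULL, deprivation_days = NULL,
                          acclimation = NULL) {
  stopifnot(inherits(records, "choice_records"))
  filtered <- !is.null(assay) || !is.null(deprivation_days) ||
    !is.null(acclimation)
  keep <- rep(TRUE, nrow(records))
  if (!is.null(assay)) keep <- keep & records$assay == assay
  if (!is.null(deprivation_days)) {
    keep <- keep & records$deprivation_days == deprivation_days
  }
  if (!is.null(acclimation)) keep <- keep & records$acclimation == acclimation
  records <- records[keep, , drop = FALSE]
  if (filtered && nrow(records) == 0L) {
    return(data.frame(assay = assay %||% NA_character_,
                      deprivation_days = deprivation_days %||% NA_real_,
                      acclimation = acclimation %||% NA_character_,
                      n = 0L, k_social = 0L, n_omitted = 0L))
  }
  key <- interaction(records$assay, records$deprivation_days,
                     records$acclimation, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    data.frame(assay = g$assay[1L],
               deprivation_days = g$deprivation_days[1L],
               acclimation = g$acclimation[1L],
               n = sum(!is.na(g$chose_social)),
               k_social = sum(g$chose_social, na.rm = TRUE),
               n_omitted = sum(is.na(g$chose_social)))
  }))
  out <- out[order(out$assay, out$deprivation_days, out$acclimation), ]
  rownames(out) <- NULL
  out
}
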