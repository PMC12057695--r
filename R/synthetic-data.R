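# Generators producing study-shaped data with known ground truth, so every
# inference stage can be exercised without any external data.

#' Generate synthetic group-feeding trials
#'
#' Emulates the arena assay: each trial starts with `m` predators and `n`
#' prey items; each predator independently feeds with probability
#' `feeding_prob` (non-feeding is modeled as independent per-animal thinning
#' before seating — a modeling convenience, not a mechanistic claim), and the
#' feeders are seated by either the uniform-choice null model or the social
#' dining model. Each trial records the endpoint mean group size over
#' occupied prey items, the endpoint maximum occupancy, and the number of
#' non-feeders. Trials in which no animal feeds are recorded with
#' `n_not_feeding = m` and missing group statistics.
#'
#' @param n_trials Number of trials to generate.
#' @param model `"null"` (uniform choice) or `"sdm"` (social dining model).
#' @param m Predators per trial.
#' @param n Prey items per trial (must be `>= m` for the social dining
#'   model).
#' @param alpha Concentration parameter; required iff `model = "sdm"`.
#' @param feeding_prob Per-animal probability of feeding, in (0, 1].
#' @param deprivation_days Deprivation label written into the dataset.
#' @param seed Optional integer seed; output is byte-for-byte reproducible.
#' @param label Dataset label.
#' @return A [trial_dataset()].
#' @examples
#' gen_group_trials(5, model = "sdm", alpha = 4, seed = 1)
#' @export
gen_group_trials <- function(n_trials, model = c("null", "sdm"), m = 8,
                             n = 8, alpha = NULL, feeding_prob = 1,
                             deprivation_days = 7, seed = NULL,
                             label = NULL) {
  model <- match.arg(model)
  n_trials <- check_count(n_trials, "n_trials")
  m <- check_count(m, "m")
  n <- check_count(n, "n")
  stopifnot(is.numeric(feeding_prob), length(feeding_prob) == 1L,
            feeding_prob > 0, feeding_prob <= 1)
  if (model == "sdm") {
    if (is.null(alpha)) stop("`alpha` is required when model = 'sdm'",
                             call. = FALSE)
    check_alpha(alpha)
    if (m > n) stop("the social dining model assumes n >= m", call. = FALSE)
  } else if (!is.null(alpha)) {
    stop("`alpha` applies only to model = 'sdm'", call. = FALSE)
  }
  with_seed(seed, {
    feeders <- rbinom(n_trials, m, feeding_prob)
    mean_g <- rep(NA_real_, n_trials)
    max_g <- rep(NA_real_, n_trials)
    active <- feeders > 0L
    if (any(active)) {
      fa <- feeders[active]
      s <- if (model == "null") {
        sim_uniform_trials(sum(active), fa, n)
      } else {
        sim_crp_trials(sum(active), fa, alpha)
      }
      mean_g[active] <- s$mean
      max_g[active] <- s$max
    }
    trials <- data.frame(
      trial_id = seq_len(n_trials),
      deprivation_days = deprivation_days,
      n_slugs = m, n_anemones = n,
      max_group_size = max_g, mean_group_size = mean_g,
      n_not_feeding = m - feeders
    )
    trial_dataset(trials, label = label %||%
                    sprintf("synthetic %s model", model))
  })
}

#' Generate synthetic choice-assay records
#'
#' Independent Bernoulli(`p_social`) two-alternative choice outcomes.
#'
#' @param n_records Number of records.
#' @param p_social Probability of selecting the social option.
#' @param assay Assay code label.
#' @param deprivation_days,acclimation Condition labels.
#' @param seed Optional integer seed.
#' @return A `choice_records` data frame (see [load_choices()]).
#' @examples
#' tally_choices(gen_choice_records(24, 0.25, seed = 1))
#' @export
gen_choice_records <- function(n_records, p_social = 0.5, assay = "FC",
                               deprivation_days = 7, acclimation = "ASW",
                               seed = NULL) {
  n_records <- check_count(n_records, "n_records")
  stopifnot(is.numeric(p_social), length(p_social) == 1L,
            p_social >= 0, p_social <= 1)
  if (!assay %in% assay_codes) {
    stop("unknown assay code '", assay, "'; valid codes are ",
         paste(assay_codes, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    social <- runif(n_records) < p_social
    out <- data.frame(
      assay = assay, deprivation_days = deprivation_days,
      acclimation = acclimation,
      choice = ifelse(social, "social", "control"),
      latency_s = NA_real_, chosen_diameter_cm = NA_real_,
      other_diameter_cm = NA_real_,
      chose_social = social
    )
    structure(out, class = c("choice_records", "data.frame"))
  })
}

#' Generate per-individual social-choice scores
#'
#' Emulates a repeated-choice consistency assay: each individual is tested
#' `n_tests` times and its score is the number of times it chose the social
#' option. With `heterogeneity = 0` every individual shares p = 0.5 and the
#' scores are Binomial(`n_tests`, 0.5). With `heterogeneity = h > 0` each
#' individual first draws its own probability from a symmetric
#' Beta(1/h, 1/h); large `h` piles mass on 0 and 1 and drives a bimodal
#' score distribution (consistent individual preferences).
#'
#' @param n_individuals Number of individuals.
#' @param n_tests Repeated tests per individual (0 allowed).
#' @param heterogeneity Non-negative preference-heterogeneity parameter.
#' @param seed Optional integer seed.
#' @return A data frame with columns `individual`, `p_social` (the latent
#'   per-individual probability) and `score` (0..`n_tests`).
#' @examples
#' table(gen_individual_scores(100, 4, heterogeneity = 0, seed = 1)$score)
#' @export
gen_individual_scores <- function(n_individuals, n_tests = 4,
                                  heterogeneity = 0, seed = NULL) {
  n_individuals <- check_count(n_individuals, "n_individuals")
  n_tests <- check_count(n_tests, "n_tests", min = 0L)
  stopifnot(is.numeric(heterogeneity), length(heterogeneity) == 1L,
            heterogeneity >= 0)
  with_seed(seed, {
    p <- if (heterogeneity == 0) {
      rep(0.5, n_individuals)
    } else {
      rbeta(n_individuals, 1 / heterogeneity, 1 / heterogeneity)
    }
    data.frame(individual = seq_len(n_individuals), p_social = p,
               score = rbinom(n_individuals, n_tests, p))
  })
}
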