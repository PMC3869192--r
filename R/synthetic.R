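#' Planted age effects
#'
#' Describes one feature whose occurrence pattern is tied to host age.
#' `prevalence_shift` features differ in presence probability between young
#' and old (the pattern of the vitamin-B12 CbiN family: present in ~55% of
#' the young versus ~11% of the old at cutoff 43). `accessory_burst`
#' features occur in a small random fraction of one class only, at strongly
#' elevated abundance — the regime a TF-iDF ranking targets.
#'
#' @param feature_id Identifier for the planted feature.
#' @param kind `"prevalence_shift"` or `"accessory_burst"`.
#' @param cutoff Age cutoff (years) at which the effect switches.
#' @param presence_young,presence_old Presence probabilities at or below /
#'   above the cutoff.
#' @param burst_abundance_multiplier Abundance multiplier for bursts.
#' @return A `planted_effect` list.
#' @export
planted_effect <- function(feature_id, kind = c("prevalence_shift", "accessory_burst"),
                           cutoff = 40, presence_young = 0.55, presence_old = 0.11,
                           burst_abundance_multiplier = 50) {
  kind <- rlang::arg_match(kind)
  stopifnot(presence_young >= 0, presence_young <= 1,
            presence_old >= 0, presence_old <= 1)
  structure(list(feature_id = feature_id, kind = kind, cutoff = as.integer(cutoff),
                 presence_young = presence_young, presence_old = presence_old,
                 burst_abundance_multiplier = burst_abundance_multiplier),
            class = "planted_effect")
}

#' Standard planted-effect mix
#'
#' The default study condition: `n_prevalence` prevalence-shift features
#' (presence 0.55 young / 0.11 old) plus `n_burst` accessory bursts
#' (present in a random 30% of the young only, at 50x abundance), all
#' switching at the same cutoff. With five bursts at 30% coverage, ~83% of
#' young samples carry at least one burst, so the planted partition is
#' strongly (not marginally) recoverable.
#'
#' @param cutoff Planted age cutoff (years).
#' @param n_prevalence,n_burst How many features of each kind.
#' @param presence_young,presence_old Prevalence-shift presence rates.
#' @param burst_fraction Fraction of the young class carrying each burst.
#' @param burst_multiplier Abundance multiplier for bursts.
#' @return List of [planted_effect()] objects.
#' @export
planted_age_effects <- function(cutoff = 40, n_prevalence = 5, n_burst = 5,
                                presence_young = 0.55, presence_old = 0.11,
                                burst_fraction = 0.3, burst_multiplier = 50) {
  c(
    lapply(seq_len(n_prevalence), function(i) {
      planted_effect(sprintf("PLT_prev_%02d", i), "prevalence_shift", cutoff,
                     presence_young, presence_old)
    }),
    lapply(seq_len(n_burst), function(i) {
      planted_effect(sprintf("PLT_burst_%02d", i), "accessory_burst", cutoff,
                     presence_young = burst_fraction, presence_old = 0,
                     burst_abundance_multiplier = burst_multiplier)
    })
  )
}

#' Synthetic-cohort configuration
#'
#' Defines the statistical structure of a simulated functional-profile
#' cohort: roughly half the features present in a given sample (background
#' presence 0.5), 15% of features unique to a single sample, over-dispersed
#' (negative-binomial) counts, country-level multiplicative batch effects on
#' a random tenth of background features, and an age distribution that is
#' either approximately uniform over 22-87 years (the age-balanced design)
#' or skewed with ~85% of hosts over 40 (the large single-study design).
#'
#' @param n_samples,n_features Cohort dimensions.
#' @param age_distribution `"uniform"` or `"qin_like"`.
#' @param age_range Inclusive age bounds for the uniform distribution.
#' @param countries Named numeric vector of country mixture weights.
#' @param planted List of [planted_effect()]s (counted inside `n_features`).
#' @param frac_sample_unique Fraction of features occurring in exactly one
#'   sample.
#' @param background_presence Per-feature presence probability.
#' @param count_scale Mean count for present features.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   over-dispersed).
#' @param batch_feature_frac Fraction of background features per country
#'   subject to the batch effect.
#' @param batch_multiplier Multiplicative batch-effect size.
#' @param seed Integer seed; the cohort is a pure function of the config.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 120, n_features = 500,
                             age_distribution = c("uniform", "qin_like"),
                             age_range = c(22L, 87L),
                             countries = c(Spain = 0.5, Denmark = 0.5),
                             planted = list(),
                             frac_sample_unique = 0.15,
                             background_presence = 0.5,
                             count_scale = 10, dispersion = 1,
                             batch_feature_frac = 0.1, batch_multiplier = 2,
                             seed = 1) {
  age_distribution <- rlang::arg_match(age_distribution)
  if (n_samples < 4) stop_parameter("need at least 4 samples")
  stopifnot(frac_sample_unique >= 0, frac_sample_unique <= 1,
            background_presence >= 0, background_presence <= 1)
  n_unique <- round(frac_sample_unique * n_features)
  if (length(planted) + n_unique >= n_features) {
    stop_parameter("planted + sample-unique features exceed n_features")
  }
  structure(list(n_samples = as.integer(n_samples), n_features = as.integer(n_features),
                 age_distribution = age_distribution, age_range = as.integer(age_range),
                 countries = countries, planted = planted,
                 frac_sample_unique = frac_sample_unique,
                 background_presence = background_presence,
                 count_scale = count_scale, dispersion = dispersion,
                 batch_feature_frac = batch_feature_frac,
                 batch_multiplier = batch_multiplier, seed = as.integer(seed)),
            class = "synthetic_config")
}

draw_ages <- function(config) {
  n <- config$n_samples
  if (config$age_distribution == "uniform") {
    sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)
  } else {
    # decade mixture skewed towards 40-69 (~85% of hosts over 40)
    decades <- sample(c(20L, 30L, 40L, 50L, 60L), n, replace = TRUE,
                      prob = c(6, 8, 39, 43, 28) / 124)
    decades + sample.int(10L, n, replace = TRUE) - 1L
  }
}

present_counts <- function(n, prob, config) {
  present <- stats::runif(n) < prob
  counts <- numeric(n)
  counts[present] <- stats::rnbinom(sum(present), size = config$dispersion,
                                    mu = config$count_scale) + 1
  counts
}

#' Generate a synthetic age-annotated cohort
#'
#' Simulates a samples x features abundance table, per-sample metadata, and
#' the ground truth needed for recovery testing: ages and countries are
#' drawn from the configured mixtures; background features are present
#' i.i.d. with over-dispersed counts; a fixed number of features are each
#' assigned to exactly one sample; each country multiplies a private random
#' tenth of the background features (never the planted ones, so batch and
#' age effects stay orthogonal); planted features follow their
#' [planted_effect()]. Identical configurations (including seed) give
#' identical cohorts.
#'
#' @param config A [synthetic_config()].
#' @return List with `profile` ([fp_profile]), `records` (metadata tibble)
#'   and `truth` (list: `planted` feature ids, `cutoff`, `seed`, `config`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    n <- config$n_samples
    sample_ids <- sprintf("S%03d", seq_len(n))
    ages <- draw_ages(config)
    for (eff in config$planted) {
      if (eff$cutoff < min(ages) || eff$cutoff >= max(ages)) {
        abort_agemark(sprintf("planted cutoff %d outside the generated age range [%d, %d)",
                              eff$cutoff, min(ages), max(ages)),
                      "agemark_config_error")
      }
    }
    countries <- sample(names(config$countries), n, replace = TRUE,
                        prob = config$countries)
    n_planted <- length(config$planted)
    n_unique <- round(config$frac_sample_unique * config$n_features)
    n_background <- config$n_features - n_planted - n_unique
    bg_ids <- sprintf("F%04d", seq_len(n_background))
    uq_ids <- sprintf("U%04d", seq_len(n_unique))

    bg <- matrix(present_counts(n * n_background, config$background_presence, config),
                 nrow = n, dimnames = list(sample_ids, bg_ids))
    # country batch effect: private random background subset per country
    n_batch <- round(config$batch_feature_frac * n_background)
    for (co in names(config$countries)) {
      cols <- sample.int(n_background, n_batch)
      rows <- countries == co
      bg[rows, cols] <- bg[rows, cols] * config$batch_multiplier
    }
    uq <- matrix(0, n, n_unique, dimnames = list(sample_ids, uq_ids))
    if (n_unique > 0) {
      hosts <- sample.int(n, n_unique, replace = TRUE)
      uq[cbind(hosts, seq_len(n_unique))] <-
        stats::rnbinom(n_unique, size = config$dispersion, mu = config$count_scale) + 1
    }
    pl <- matrix(0, n, n_planted,
                 dimnames = list(sample_ids,
                                 vapply(config$planted, `[[`, character(1), "feature_id")))
    for (j in seq_len(n_planted)) {
      eff <- config$planted[[j]]
      young <- ages <= eff$cutoff
      prob <- ifelse(young, eff$presence_young, eff$presence_old)
      v <- present_counts(n, prob, config)
      if (eff$kind == "accessory_burst") v <- v * eff$burst_abundance_multiplier
      pl[, j] <- v
    }
    profile <- fp_profile(cbind(pl, bg, uq), namespace = "pfam")
    records <- tibble::tibble(sample_id = sample_ids, age = as.integer(ages),
                              country = countries, ibd = NA, obese = NA)
    truth <- list(planted = colnames(pl),
                  cutoff = if (n_planted) config$planted[[1]]$cutoff else NA_integer_,
                  seed = config$seed, config = config)
    list(profile = profile, records = records, truth = truth)
  })
}

#' Fraction of planted features recovered by a ranking
#'
#' @param ranking A `fp_ranking`.
#' @param truth The `truth` element from [generate_cohort()].
#' @return Fraction in \[0, 1\] of planted features present in the ranking;
#'   `NA` when nothing was planted.
#' @export
recovery_score <- function(ranking, truth) {
  if (!length(truth$planted)) return(NA_real_)
  mean(truth$planted %in% ranking$feature)
}

#' Permute ages across samples
#'
#' Breaks any age-feature association while preserving the marginal age
#' distribution — the null condition for calibration checks.
#'
#' @param records Metadata tibble.
#' @param seed Integer seed.
#' @return The records with the `age` column permuted.
#' @export
permute_ages <- function(records, seed = 1) {
  records$age <- withr::with_seed(seed, sample(records$age))
  records
}
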