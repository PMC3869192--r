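test_that("AUC equals the O(n^2) pairwise oracle on random instances", {
  expect_equal(roc_auc(c(1, 2, 9, 10), c("young", "young", "old", "old")), 1.0)
  expect_equal(roc_auc(rep(5, 6), rep(c("young", "old"), 3)), 0.5)
  withr::with_seed(71, {
    for (i in 1:30) {
      n <- sample(6:30, 1)
      scores <- sample(seq(-2, 2, by = 0.5), n, replace = TRUE)  # force ties
      labels <- sample(c("young", "old"), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      expect_identical(roc_auc(scores, labels), oracle_auc(scores, labels))
    }
  })
  expect_error(roc_auc(1:4, rep("old", 4)), class = "agemark_parameter_error")
})

test_that("AUC of negated tie-free scores is the complement", {
  withr::with_seed(72, {
    scores <- rnorm(25)
    labels <- sample(c("young", "old"), 25, replace = TRUE, prob = c(0.5, 0.5))
  })
  expect_equal(roc_auc(scores, labels) + roc_auc(-scores, labels), 1.0)
})

test_that("leave-one-out with a perfectly separating, always-selected feature is perfect", {
  # one feature with huge TF-iDF signal in the old class, everything else flat
  n <- 10
  m <- matrix(1, n, 5, dimnames = list(paste0("S", 1:n), paste0("F", 1:5)))
  m[6:10, "F5"] <- 50
  m[1:5, "F5"] <- 0
  rec <- tibble::tibble(sample_id = paste0("S", 1:n),
                        age = c(rep(30L, 5), rep(60L, 5)), country = "X")
  run <- loo_run(m, label_by_cutoff(rec, 40), selector = "tfidf", n_features = 1)
  expect_equal(run$auc, 1.0)
  expect_equal(run$accuracy, 1.0)
  expect_true(all(vapply(run$selected$features, function(f) "F5" %in% f, logical(1))))
  # bookkeeping: one selection log entry per evaluated fold
  expect_equal(nrow(run$selected), nrow(run$per_sample))
})

test_that("permuted labels give near-chance AUC", {
  cohort <- tiny_cohort(seed = 23, n_samples = 40, n_features = 80)
  null_rec <- permute_ages(cohort$records, seed = 99)
  run <- loo_run(cohort$profile, label_by_cutoff(null_rec, 40), selector = "tfidf")
  expect_gte(run$auc, 0.3)
  expect_lte(run$auc, 0.7)
})

test_that("subset experiments are reproducible and carry selection rates", {
  cohort <- tiny_cohort(seed = 29, n_samples = 36, n_features = 80)
  row1 <- subset_experiment(cohort$profile, cohort$records, 40, selector = "tfidf",
                            n_features = 5, n_runs = 4, subset_size = 20, seed = 7)
  row2 <- subset_experiment(cohort$profile, cohort$records, 40, selector = "tfidf",
                            n_features = 5, n_runs = 4, subset_size = 20, seed = 7)
  expect_identical(row1, row2)
  expect_lte(row1$ci_low, row1$mean_auc)
  expect_gte(row1$ci_high, row1$mean_auc)
  rates <- attr(row1, "selection_rate")
  expect_true(all(rates$rate > 0 & rates$rate <= 1))
  expect_error(subset_experiment(cohort$profile, cohort$records, 40,
                                 subset_size = 500, n_runs = 2),
               class = "agemark_parameter_error")
})

test_that("the confidence interval is the t-based interval across runs", {
  cohort <- tiny_cohort(seed = 31, n_samples = 30, n_features = 60)
  row <- subset_experiment(cohort$profile, cohort$records, 40, selector = "tfidf",
                           n_features = 5, n_runs = 5, subset_size = 20, seed = 3)
  aucs <- attr(row, "per_run_auc")
  half <- qt(0.975, df = length(aucs) - 1) * sd(aucs) / sqrt(length(aucs))
  expect_equal(row$mean_auc, mean(aucs), tolerance = 1e-12)
  expect_equal(row$ci_high - row$mean_auc, half, tolerance = 1e-12)
})

test_that("a cutoff sweep emits one row per valid cutoff, skipping degenerate ones", {
  cohort <- tiny_cohort(seed = 37, n_samples = 30, n_features = 60)
  sweep <- cutoff_sweep(cohort$profile, cohort$records, 38:43, selector = "tfidf",
                        n_features = 5, n_runs = 3, subset_size = 20, seed = 5)
  expect_equal(nrow(sweep), 6L)
  expect_identical(sweep$cutoff, 38:43)

  empty <- cutoff_sweep(cohort$profile, cohort$records, integer(0),
                        selector = "tfidf", n_features = 5, n_runs = 3,
                        subset_size = 20, seed = 5)
  expect_equal(nrow(empty), 0L)

  age_min <- min(cohort$records$age)
  expect_warning(
    skipped <- cutoff_sweep(cohort$profile, cohort$records,
                            c(age_min - 1L, 40L), selector = "tfidf",
                            n_features = 5, n_runs = 3, subset_size = 20, seed = 5),
    "skipped")
  expect_equal(nrow(skipped), 1L)
})

test_that("null-cohort confidence intervals cover chance in most meta-trials", {
  covered <- vapply(1:5, function(trial) {
    cohort <- generate_cohort(synthetic_config(n_samples = 24, n_features = 50,
                                               seed = 1000 + trial))
    row <- subset_experiment(cohort$profile, cohort$records, 40,
                             selector = "tfidf", n_features = 5,
                             n_runs = 8, subset_size = 16, seed = trial)
    row$ci_low <= 0.5 && 0.5 <= row$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.8)
})

test_that("run results expose tidy and glance views", {
  cohort <- tiny_cohort(seed = 41, n_samples = 20, n_features = 40)
  run <- loo_run(cohort$profile, label_by_cutoff(cohort$records, 40),
                 selector = "tfidf", n_features = 5)
  td <- tidy(run)
  expect_named(td, c("sample_id", "truth", "score", "predicted"))
  gl <- glance(run)
  expect_true(gl$auc >= 0 && gl$auc <= 1)
  expect_true(gl$accuracy >= 0 && gl$accuracy <= 1)
  expect_s3_class(autoplot(cutoff_sweep(cohort$profile, cohort$records, c(39, 41),
                                        selector = "tfidf", n_features = 5,
                                        n_runs = 2, subset_size = 14, seed = 2)),
                  "ggplot")
})
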