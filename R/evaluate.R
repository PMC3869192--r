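#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC computed as the Mann-Whitney probability that a random positive
#' (old) sample outscores a random negative (young) sample, with ties
#' credited one half:
#' \deqn{\mathrm{AUC} = \frac{\#\{s_o > s_y\} + \tfrac12 \#\{s_o = s_y\}}
#'   {n_{old}\, n_{young}}}
#' implemented via midranks, which is algebraically identical.
#'
#' @param scores Numeric decision scores (higher = more "old").
#' @param labels Binary labels; `"old"` (or the positive class) and
#'   `"young"`.
#' @param positive Which label is the positive class (default `"old"`).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, positive = "old") {
  labels <- as.character(labels)
  if (length(scores) != length(labels)) stop_parameter("scores and labels must align")
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop_parameter("both classes must be present for AUC")
  r <- rank(scores)                       # midranks give half-credit for ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

select_features <- function(x, labels, selector, n_features, config) {
  switch(selector,
    tfidf = tfidf_rank(x, n = n_features,
                       aggregate = config$tfidf_aggregate %||% "max",
                       log_base = config$tfidf_log_base %||% exp(1)),
    mrmr = mrmr_select(x, labels, n = n_features,
                       t = config$mrmr_threshold %||% 1,
                       combination = config$mrmr_combination %||% "difference"),
    grubbs = suppressWarnings(
      grubbs_weighted_select(x, labels, n = n_features,
                             alpha = config$grubbs_alpha %||% 0.05,
                             cost = config$cost %||% 1)),
    stop_parameter(paste0("unknown selector: ", selector))
  )
}

#' Leave-one-out cross-validation with in-fold feature selection
#'
#' For every sample in turn, the selector is run on the remaining samples
#' only (no information from the held-out sample leaks into selection), a
#' linear SVM is fitted on those samples restricted to the selected
#' features, and the held-out sample's decision score and predicted label
#' are recorded. Because fold models differ slightly, each held-out score is
#' centred by the mean decision score of that fold's training samples before
#' pooling (`center_scores = FALSE` in `config` restores raw pooling); this
#' removes the pessimistic bias of pooled leave-one-out scoring, under which
#' label-permuted data would systematically score below 0.5. AUC is then
#' computed on the pooled centred scores; accuracy is the fraction of
#' correct held-out predictions (from the uncentred model sign). Folds whose
#' training set loses a class are skipped with a warning and excluded from
#' both denominators. A fold in which the selector returns no feature falls
#' back to the training-majority prediction with score 0.
#'
#' @param x A [fp_profile] (or samples x features matrix).
#' @param labeling An `fp_labeling` from [label_by_cutoff()], aligned by
#'   `sample_id` to the rows of `x`.
#' @param selector `"tfidf"`, `"mrmr"` or `"grubbs"`.
#' @param n_features Number of features to select per fold (default 10).
#' @param config Optional list of tuning parameters: `cost`, `scale`,
#'   `center_scores`, `tfidf_aggregate`, `tfidf_log_base`, `mrmr_threshold`,
#'   `mrmr_combination`, `grubbs_alpha`.
#' @return An `fp_run`: list with `per_sample` (tibble: `sample_id`,
#'   `truth`, `score`, `predicted`), `auc`, `accuracy`, `selected` (tibble:
#'   `fold`, `sample_id`, `features` list-column), `subset_sample_ids`.
#' @export
loo_run <- function(x, labeling, selector = c("tfidf", "mrmr", "grubbs"),
                    n_features = 10, config = list()) {
  selector <- rlang::arg_match(selector)
  m <- fp_matrix(x)
  lab <- labeling$label[match(rownames(m), labeling$sample_id)]
  if (anyNA(lab)) stop_parameter("labeling does not cover every sample")
  lab <- as.character(lab)
  n <- nrow(m)
  rows <- vector("list", n)
  sel_log <- vector("list", n)
  for (i in seq_len(n)) {
    train_y <- lab[-i]
    if (length(unique(train_y)) < 2) {
      rlang::warn(sprintf("fold %d skipped: training set has a single class", i))
      next
    }
    train_x <- m[-i, , drop = FALSE]
    ranking <- select_features(train_x, train_y, selector, n_features, config)
    feats <- ranking$feature
    if (!length(feats)) {
      majority <- names(which.max(table(train_y)))
      score <- 0
      predicted <- majority
    } else {
      model <- fit_linear_svm(train_x[, feats, drop = FALSE], train_y,
                              cost = config$cost %||% 1,
                              scale = isTRUE(config$scale))
      score <- decision_score(model, m[i, feats, drop = FALSE])
      predicted <- predict_label(model, m[i, feats, drop = FALSE])
      if (!isFALSE(config$center_scores)) {
        score <- score - mean(decision_score(model, train_x[, feats, drop = FALSE]))
      }
    }
    rows[[i]] <- tibble::tibble(sample_id = rownames(m)[i], truth = lab[i],
                                score = unname(score), predicted = unname(predicted))
    sel_log[[i]] <- tibble::tibble(fold = i, sample_id = rownames(m)[i],
                                   features = list(feats))
  }
  per_sample <- dplyr::bind_rows(rows)
  if (!nrow(per_sample)) stop_parameter("every fold was skipped; no evaluable sample")
  res <- list(
    per_sample = per_sample,
    auc = roc_auc(per_sample$score, per_sample$truth),
    accuracy = mean(per_sample$predicted == per_sample$truth),
    selected = dplyr::bind_rows(sel_log),
    subset_sample_ids = rownames(m)
  )
  class(res) <- "fp_run"
  res
}

#' @export
print.fp_run <- function(x, ...) {
  cat(sprintf("Leave-one-out run: %d samples, AUC %.3f, accuracy %.3f\n",
              nrow(x$per_sample), x$auc, x$accuracy))
  invisible(x)
}

#' @rdname loo_run
#' @param ... Unused.
#' @export
tidy.fp_run <- function(x, ...) x$per_sample

#' @rdname loo_run
#' @export
glance.fp_run <- function(x, ...) {
  tibble::tibble(auc = x$auc, accuracy = x$accuracy, n = nrow(x$per_sample))
}

#' Repeated random-subset evaluation at one age cutoff
#'
#' Draws `n_runs` subsets of `subset_size` samples uniformly without
#' replacement (a fresh, seeded draw per run), performs a leave-one-out run
#' on each, and aggregates: mean AUC with a 95% t-interval across runs
#' (\eqn{\bar a \pm t_{0.975, n-1}\, s/\sqrt n}), mean accuracy, and
#' per-feature selection rates pooled over every fold of every run. Runs
#' whose subset contains a single class are skipped with a warning.
#'
#' @inheritParams loo_run
#' @param records Metadata tibble (see [read_metadata()]).
#' @param cutoff Age cutoff in years; young = age at or below it.
#' @param n_runs Number of random-subset repetitions (default 20).
#' @param subset_size Samples per subset.
#' @param seed Integer seed; the whole experiment is reproducible from it.
#' @return A one-row `fp_sweep` tibble (see [cutoff_sweep()]).
#' @export
subset_experiment <- function(x, records, cutoff, selector = "tfidf",
                              n_features = 10, n_runs = 20, subset_size,
                              seed = 1, config = list()) {
  m <- fp_matrix(x)
  if (subset_size > nrow(m)) stop_parameter("subset_size exceeds the cohort size")
  if (n_runs < 2) stop_parameter("need at least 2 runs for a confidence interval")
  pos <- match(rownames(m), records$sample_id)
  if (anyNA(pos)) stop_parameter("metadata does not cover every sample")
  records <- records[pos, ]
  aucs <- accs <- rep(NA_real_, n_runs)
  sel_counts <- list()
  total_folds <- 0L
  for (r in seq_len(n_runs)) {
    idx <- withr::with_seed(derive_seed(seed, "run", r),
                            sample.int(nrow(m), subset_size))
    sub_rec <- records[idx, ]
    lab <- tryCatch(label_by_cutoff(sub_rec, cutoff), agemark_labeling_error = function(e) NULL)
    if (is.null(lab)) {
      rlang::warn(sprintf("run %d skipped: single class in subset at cutoff %d", r, cutoff))
      next
    }
    run <- loo_run(m[idx, , drop = FALSE], lab, selector = selector,
                   n_features = n_features, config = config)
    aucs[r] <- run$auc
    accs[r] <- run$accuracy
    total_folds <- total_folds + nrow(run$selected)
    sel_counts[[r]] <- unlist(run$selected$features)
  }
  ok <- !is.na(aucs)
  if (sum(ok) < 2) stop_parameter("fewer than 2 evaluable runs; cannot form an interval")
  mean_auc <- mean(aucs[ok])
  half <- stats::qt(0.975, df = sum(ok) - 1) * stats::sd(aucs[ok]) / sqrt(sum(ok))
  rates <- table(unlist(sel_counts)) / total_folds
  row <- tibble::tibble(
    cutoff = as.integer(cutoff), mean_auc = mean_auc,
    ci_low = mean_auc - half, ci_high = mean_auc + half,
    mean_accuracy = mean(accs[ok]), n_runs = sum(ok),
    subset_size = as.integer(subset_size), selector = selector,
    n_features = as.integer(n_features)
  )
  attr(row, "selection_rate") <- tibble::tibble(
    cutoff = as.integer(cutoff),
    feature = names(rates), rate = as.numeric(rates)
  ) |> dplyr::arrange(dplyr::desc(.data$rate), .data$feature)
  attr(row, "per_run_auc") <- aucs[ok]
  class(row) <- c("fp_sweep", class(tibble::tibble()))
  row
}

#' Sweep age cutoffs
#'
#' Runs [subset_experiment()] at every cutoff (independently seeded per
#' cutoff from the master seed) and stacks the rows, giving the
#' classification-performance profile across the age axis. Cutoffs that
#' leave a class empty in the full cohort are skipped with a warning.
#'
#' @inheritParams subset_experiment
#' @param cutoffs Integer vector of age cutoffs (years).
#' @return An `fp_sweep` tibble: one row per evaluated cutoff with
#'   `mean_auc`, `ci_low`, `ci_high`, `mean_accuracy`, `n_runs`,
#'   `subset_size`, `selector`, `n_features`; attribute `selection_rate`
#'   pools per-feature selection frequencies.
#' @export
cutoff_sweep <- function(x, records, cutoffs, selector = "tfidf",
                         n_features = 10, n_runs = 20, subset_size,
                         seed = 1, config = list()) {
  rows <- list()
  rates <- list()
  for (ct in cutoffs) {
    valid <- tryCatch({label_by_cutoff(records, ct); TRUE},
                      agemark_labeling_error = function(e) FALSE)
    if (!valid) {
      rlang::warn(sprintf("cutoff %d skipped: empty class in the full cohort", ct))
      next
    }
    row <- subset_experiment(x, records, ct, selector = selector,
                             n_features = n_features, n_runs = n_runs,
                             subset_size = subset_size,
                             seed = derive_seed(seed, "cutoff", ct),
                             config = config)
    rates[[as.character(ct)]] <- attr(row, "selection_rate")
    rows[[as.character(ct)]] <- row
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "selection_rate") <- dplyr::bind_rows(rates)
  class(out) <- c("fp_sweep", class(tibble::tibble()))
  out
}

#' @rdname cutoff_sweep
#' @export
selection_rates <- function(x) attr(x, "selection_rate") %||%
  tibble::tibble(cutoff = integer(), feature = character(), rate = double())

#' @rdname cutoff_sweep
#' @param object An `fp_sweep`.
#' @param ... Unused.
#' @export
autoplot.fp_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cutoff, y = .data$mean_auc)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "Age cutoff (years)", y = "Mean AUC",
                  title = sprintf("Age-cutoff sweep (%s, %d runs of %d samples)",
                                  object$selector[1], object$n_runs[1],
                                  object$subset_size[1])) +
    ggplot2::theme_minimal()
}

#' @rdname cutoff_sweep
#' @export
glance.fp_sweep <- function(x, ...) {
  best <- which.max(x$mean_auc)
  tibble::tibble(best_cutoff = x$cutoff[best], best_mean_auc = x$mean_auc[best],
                 n_cutoffs = nrow(x))
}
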