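#' Grubbs single-outlier statistic
#'
#' \eqn{G = \max_i |v_i - \bar v| / s} with the sample (n-1) standard
#' deviation, compared against the two-sided critical value
#' \deqn{G_{crit} = \frac{N-1}{\sqrt N}
#'   \sqrt{\frac{t^2}{N - 2 + t^2}}, \quad t = t_{\alpha/(2N),\, N-2}}
#' from the t distribution. A zero-variance vector has `G = 0` and no
#' outlier by definition.
#'
#' @param values Numeric vector, length at least 3.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A list: `G`, `outlier_index` (index of the most deviant value;
#'   `NA` when variance is zero), `is_outlier`, `critical`.
#' @export
grubbs_statistic <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3) stop_parameter("Grubbs test needs at least 3 values")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop_parameter("alpha must be in (0, 1)")
  s <- stats::sd(values)
  crit <- grubbs_critical(n, alpha)
  if (!is.finite(s) || s == 0) {
    return(list(G = 0, outlier_index = NA_integer_, is_outlier = FALSE, critical = crit))
  }
  dev <- abs(values - mean(values))
  idx <- which.max(dev)
  G <- dev[idx] / s
  list(G = unname(G), outlier_index = unname(idx),
       is_outlier = unname(G > crit), critical = crit)
}

#' @rdname grubbs_statistic
#' @param n Sample size.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  tcrit <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
}

#' Grubbs-test outlier-weighted feature selection
#'
#' A class-blind selection scheme that asks whether purely outlier-driven
#' features can classify: (i) every feature's abundance vector over the
#' training samples is Grubbs-tested, flagging (feature, sample) outlier
#' pairs; (ii) for each flagged sample, a linear SVM is trained on the
#' remaining training samples restricted to the features that flagged it and
#' used to classify the flagged sample — when correct, each of those features
#' gains weight 1; (iii) the `n` features with the highest accumulated
#' weights are returned (lexicographic tie-break). Features that never flag
#' a sample keep weight 0 and are never returned.
#'
#' @inheritParams mrmr_select
#' @param alpha Significance level of the per-feature Grubbs test.
#' @param cost SVM regularization constant for the inner classifiers.
#' @return A `fp_ranking` tibble (`feature`, `score` = weight, `rank`) with
#'   `method = "grubbs"`; empty (with a warning) when no feature flags any
#'   sample or no flagged sample is classified correctly.
#' @export
grubbs_weighted_select <- function(x, labels, n = 10, alpha = 0.05, cost = 1) {
  m <- fp_matrix(x)
  if (nrow(m) < 4) stop_parameter("need at least 4 training samples")
  labels <- as.character(labels)
  if (length(labels) != nrow(m)) stop_parameter("labels must align to samples")
  if (length(unique(labels)) != 2) stop_parameter("need exactly two classes")

  # vectorized Grubbs over feature columns
  nr <- nrow(m)
  mu <- colMeans(m)
  sig <- apply(m, 2, stats::sd)
  dev <- abs(sweep(m, 2, mu))
  idx <- apply(dev, 2, which.max)
  G <- dev[cbind(idx, seq_len(ncol(m)))] / ifelse(sig > 0, sig, Inf)
  flagged <- which(G > grubbs_critical(nr, alpha))

  weights <- stats::setNames(rep(0, ncol(m)), colnames(m))
  if (!length(flagged)) {
    rlang::warn("no feature flagged an outlier sample; empty ranking")
    return(new_ranking(character(), double(), method = "grubbs", n = n))
  }
  by_sample <- split(colnames(m)[flagged], idx[flagged])
  any_correct <- FALSE
  for (s_chr in names(by_sample)) {
    s <- as.integer(s_chr)
    feats <- by_sample[[s_chr]]
    train_y <- labels[-s]
    if (length(unique(train_y)) < 2) next
    model <- fit_linear_svm(m[-s, feats, drop = FALSE], train_y, cost = cost)
    if (predict_label(model, m[s, feats, drop = FALSE]) == labels[s]) {
      weights[feats] <- weights[feats] + 1
      any_correct <- TRUE
    }
  }
  if (!any_correct) {
    rlang::warn("no flagged sample classified correctly; empty ranking")
    return(new_ranking(character(), double(), method = "grubbs", n = n))
  }
  keep <- weights > 0
  new_ranking(names(weights)[keep], weights[keep], method = "grubbs", n = n)
}
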