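#' TF-iDF weights for a functional profile
#'
#' Term-frequency x inverse-document-frequency weighting of a samples x
#' features abundance table. For feature *i* in sample *j*,
#' \deqn{w_{ij} = \frac{n_{ij}}{\sum_k n_{kj}} \cdot
#'       \log\frac{|D|}{|\{j : n_{ij} > 0\}|}}
#' where the first factor is the feature's share of the sample's assignments
#' and the second is the log of cohort size over the number of samples
#' carrying the feature. Features present in every sample, and features
#' present in none, get weight 0 everywhere; an all-zero sample row gets an
#' all-zero weight row. The weighting never consults class labels.
#'
#' @param x A [fp_profile] (or samples x features matrix).
#' @param log_base Base of the iDF logarithm; natural log by default. The
#'   base rescales every weight by a constant and cannot change a ranking.
#' @return List with `weights` (samples x features matrix) and `log_base`.
#' @export
tfidf_weights <- function(x, log_base = exp(1)) {
  m <- fp_matrix(x)
  if (nrow(m) < 2) stop_parameter("TF-iDF needs at least 2 samples (iDF is degenerate)")
  if (!is.numeric(log_base) || log_base <= 0 || log_base == 1) {
    stop_parameter("log_base must be positive and != 1")
  }
  totals <- rowSums(m)
  tf <- m / ifelse(totals > 0, totals, 1)      # all-zero rows stay all-zero
  m_i <- colSums(m > 0)
  idf <- ifelse(m_i > 0, log(nrow(m) / pmax(m_i, 1), base = log_base), 0)
  w <- sweep(tf, 2, idf, `*`)
  w[, m_i == 0] <- 0
  list(weights = w, log_base = log_base)
}

#' Rank features by TF-iDF
#'
#' Scores each feature by aggregating its TF-iDF weight over the (training)
#' samples — by default the maximum, which targets features with high
#' within-sample frequency in few metagenomes ("accessory" features) — and
#' returns the top `n`. Features whose weight is identically zero (absent, or
#' present in every sample) are never returned, so fewer than `n` rows may
#' come back. Ties are broken by lexicographic feature id; the ranking is
#' fully deterministic.
#'
#' @inheritParams tfidf_weights
#' @param n Number of features to keep.
#' @param aggregate `"max"` (default) or `"sum"` over samples.
#' @return A `fp_ranking` tibble: `feature`, `score`, `rank`; attribute
#'   `method = "tfidf"`.
#' @export
tfidf_rank <- function(x, n = 10, aggregate = c("max", "sum"), log_base = exp(1)) {
  if (!is.numeric(n) || n <= 0) stop_parameter("n must be a positive integer")
  aggregate <- rlang::arg_match(aggregate)
  w <- tfidf_weights(x, log_base = log_base)$weights
  score <- switch(aggregate, max = apply(w, 2, max), sum = colSums(w))
  keep <- score > 0
  new_ranking(names(score)[keep], score[keep], method = "tfidf", n = n)
}

# Shared ranking constructor: order by score desc, lexicographic tie-break,
# truncate to n.
new_ranking <- function(features, scores, method, n, trace = NULL) {
  ord <- order(-scores, features)
  features <- features[ord][seq_len(min(n, length(ord)))]
  scores <- scores[ord][seq_len(min(n, length(ord)))]
  out <- tibble::tibble(feature = features, score = unname(scores),
                        rank = seq_along(features))
  attr(out, "method") <- method
  if (!is.null(trace)) attr(out, "trace") <- trace
  class(out) <- c("fp_ranking", class(tibble::tibble()))
  out
}

#' @export
print.fp_ranking <- function(x, ...) {
  cat(sprintf("# Feature ranking (%s), %d features\n", attr(x, "method") %||% "?", nrow(x)))
  NextMethod()
}

#' @rdname tfidf_rank
#' @param x A `fp_ranking`.
#' @param ... Unused.
#' @export
tidy.fp_ranking <- function(x, ...) {
  tibble::as_tibble(x)
}
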