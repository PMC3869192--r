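#' Three-level discretization of abundances
#'
#' Per feature column with mean \eqn{\mu} and sample standard deviation
#' \eqn{\sigma} over the (training) samples, a value maps to +1 when above
#' \eqn{\mu + t\sigma}, to -1 when below \eqn{\mu - t\sigma}, else to 0.
#' Constant columns (including all-zero) map to all zeros. `t = 1` is the
#' conventional default for mutual-information selection on abundance data.
#'
#' @inheritParams tfidf_weights
#' @param t Positive threshold in standard-deviation units.
#' @return List with `values` (integer matrix over \{-1, 0, +1\}) and
#'   `threshold`.
#' @export
discretize_profile <- function(x, t = 1) {
  if (!is.numeric(t) || t <= 0) stop_parameter("discretization threshold must be > 0")
  m <- fp_matrix(x)
  mu <- colMeans(m)
  sig <- apply(m, 2, stats::sd)
  sig[is.na(sig)] <- 0
  hi <- sweep(m, 2, mu + t * sig, `>`)
  lo <- sweep(m, 2, mu - t * sig, `<`)
  d <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  d[hi] <- 1L
  d[lo] <- -1L
  d[, sig == 0] <- 0L
  list(values = d, threshold = t)
}

#' Plug-in mutual information (bits)
#'
#' Empirical mutual information of two equal-length discrete vectors from
#' their joint contingency table, base-2 logarithm. `mutual_information(a, a)`
#' equals the empirical entropy of `a`.
#'
#' @param a,b Discrete vectors of equal length.
#' @return Non-negative mutual information in bits.
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b)) stop_parameter("vectors must have equal length")
  if (!length(a)) stop_parameter("vectors must be non-empty")
  joint <- table(a, b) / length(a)
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
}

# Fast path used in the greedy loop: vectors pre-coded as small integers.
mi_coded <- function(a, b, na, nb) {
  n <- length(a)
  joint <- tabulate(a + na * (b - 1L), nbins = na * nb) / n
  px <- rowSums(matrix(joint, na, nb))
  py <- colSums(matrix(joint, na, nb))
  pxy <- matrix(joint, na, nb)
  nz <- pxy > 0
  sum(pxy[nz] * log2(pxy[nz] / outer(px, py)[nz]))
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy forward selection on the discretized table. The first feature
#' maximizes relevance \eqn{I(x_i; c)} with the class vector; each subsequent
#' feature maximizes the difference criterion
#' \eqn{I(x_i; c) - \frac{1}{|S|}\sum_{x_j \in S} I(x_i; x_j)}
#' (the quotient form divides instead). Ties break lexicographically, so the
#' path is deterministic. The returned ranking carries a per-step trace of
#' the running relevance \eqn{D(S, c)} and redundancy \eqn{R(S)} (the mean
#' over all ordered pairs of selected features, self-pairs included).
#'
#' @inheritParams tfidf_weights
#' @param labels Binary class vector aligned to the rows of `x` (e.g. the
#'   young/old labels from [label_by_cutoff()]).
#' @param n Number of features to select.
#' @param t Discretization threshold passed to [discretize_profile()].
#' @param combination `"difference"` (default) or `"quotient"`.
#' @return A `fp_ranking` tibble (`feature`, `score` = step objective,
#'   `rank`) with attributes `method = "mrmr"` and `trace`, a tibble with
#'   columns `step`, `feature`, `relevance`, `redundancy`.
#' @export
mrmr_select <- function(x, labels, n = 10, t = 1,
                        combination = c("difference", "quotient")) {
  combination <- rlang::arg_match(combination)
  if (!is.numeric(n) || n <= 0) stop_parameter("n must be a positive integer")
  m <- fp_matrix(x)
  if (length(labels) != nrow(m)) stop_parameter("labels must align to samples")
  labels <- as.character(labels)
  if (length(unique(labels)) != 2) stop_parameter("mRMR needs exactly two classes")
  d <- discretize_profile(m, t = t)$values
  p <- ncol(d)
  n <- min(n, p)
  dcode <- d + 2L                              # {-1,0,1} -> {1,2,3}
  ccode <- as.integer(factor(labels))
  relevance <- vapply(seq_len(p), function(i) mi_coded(dcode[, i], ccode, 3L, 2L), double(1))
  names(relevance) <- colnames(d)

  selected <- integer(0)
  objective <- double(0)
  red_sum <- rep(0, p)                         # sum over selected of I(x_i; x_j)
  pair_sum <- 0                                # sum of I(x_i; x_j) over S x S
  trace <- vector("list", n)
  feats <- colnames(d)
  for (step in seq_len(n)) {
    cand <- setdiff(seq_len(p), selected)
    obj <- if (step == 1) {
      relevance[cand]
    } else if (combination == "difference") {
      relevance[cand] - red_sum[cand] / length(selected)
    } else {
      relevance[cand] / pmax(red_sum[cand] / length(selected), .Machine$double.eps)
    }
    pick <- cand[order(-obj, feats[cand])][1]
    objective <- c(objective, unname(obj[match(pick, cand)]))
    picked_col <- dcode[, pick]
    # R(S) over all ordered pairs (self-pairs included), updated incrementally
    pair_sum <- pair_sum + 2 * red_sum[pick] + mi_coded(picked_col, picked_col, 3L, 3L)
    selected <- c(selected, pick)
    trace[[step]] <- tibble::tibble(step = step, feature = feats[pick],
                                    relevance = mean(relevance[selected]),
                                    redundancy = pair_sum / length(selected)^2)
    # redundancy bookkeeping for the next step's objective
    if (step < n) {
      upd <- setdiff(seq_len(p), selected)
      red_sum[upd] <- red_sum[upd] +
        vapply(upd, function(i) mi_coded(dcode[, i], picked_col, 3L, 3L), double(1))
    }
  }
  ranking <- tibble::tibble(feature = feats[selected], score = objective,
                            rank = seq_along(selected))
  attr(ranking, "method") <- "mrmr"
  attr(ranking, "trace") <- dplyr::bind_rows(trace)
  class(ranking) <- c("fp_ranking", class(tibble::tibble()))
  ranking
}
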