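#' Hellinger transform
#'
#' Square root of within-sample relative abundance,
#' \eqn{y_{ji} = \sqrt{x_{ji} / \sum_i x_{ji}}}, which puts community count
#' data on a scale where Euclidean distances (and hence PCA) behave
#' sensibly. Every transformed row has unit Euclidean norm.
#'
#' @inheritParams tfidf_weights
#' @return Numeric matrix, samples in rows.
#' @export
hellinger_transform <- function(x) {
  m <- fp_matrix(x)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop_validation(paste0("all-zero sample row(s): ",
                           paste(rownames(m)[totals == 0], collapse = ", ")))
  }
  sqrt(m / totals)
}

#' Transformation-based PCA
#'
#' Hellinger-transforms the table (after restricting to `feature_subset`
#' when given — relative abundances are then recomputed within the subset so
#' the transform stays a valid composition on the reduced table),
#' column-centers it, and eigendecomposes the covariance. Component signs
#' are fixed so that each component's largest-magnitude loading is positive,
#' making scores deterministic across runs and platforms.
#'
#' @inheritParams tfidf_weights
#' @param n_components Number of principal components to return.
#' @param feature_subset Optional character vector of feature ids (e.g. a
#'   ranking's features) to ordinate on.
#' @return An `fp_ordination`: list with `sample_scores` (tibble:
#'   `sample_id`, `PC1`, ...), `explained_fraction`, `loadings`,
#'   `component_count`.
#' @export
tbpca <- function(x, n_components = 3, feature_subset = NULL) {
  m <- fp_matrix(x)
  if (!is.null(feature_subset)) {
    keep <- intersect(feature_subset, colnames(m))
    if (!length(keep)) stop_parameter("feature_subset shares no feature with the profile")
    m <- m[, keep, drop = FALSE]
    nonzero <- rowSums(m) > 0
    if (!all(nonzero)) {
      rlang::warn(sprintf("%d sample(s) with no abundance on the subset dropped",
                          sum(!nonzero)))
      m <- m[nonzero, , drop = FALSE]
    }
  }
  h <- hellinger_transform(m)
  max_rank <- min(nrow(h) - 1L, ncol(h))
  if (n_components > max_rank) stop_parameter("n_components exceeds the matrix rank bound")
  pca <- stats::prcomp(h, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  rot <- pca$rotation[, k, drop = FALSE]
  scores <- pca$x[, k, drop = FALSE]
  # sign convention: largest |loading| positive per component
  flip <- vapply(k, function(j) {
    l <- rot[, j]
    sign(l[which.max(abs(l))])
  }, double(1))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, `*`)
  scores <- sweep(scores, 2, flip, `*`)
  ev <- pca$sdev^2
  res <- list(
    sample_scores = tibble::as_tibble(as.data.frame(scores), rownames = "sample_id"),
    explained_fraction = (ev / sum(ev))[k],
    loadings = rot,
    component_count = as.integer(n_components)
  )
  class(res) <- "fp_ordination"
  res
}

#' @export
print.fp_ordination <- function(x, ...) {
  cat(sprintf("tbPCA ordination: %d samples, %d components (%.1f%% variance)\n",
              nrow(x$sample_scores), x$component_count,
              100 * sum(x$explained_fraction)))
  invisible(x)
}

#' @rdname tbpca
#' @param ... Unused.
#' @export
tidy.fp_ordination <- function(x, ...) {
  x$sample_scores |>
    tidyr::pivot_longer(-"sample_id", names_to = "component", values_to = "score")
}

#' @rdname tbpca
#' @export
glance.fp_ordination <- function(x, ...) {
  tibble::tibble(component_count = x$component_count,
                 explained_total = sum(x$explained_fraction))
}

#' @rdname tbpca
#' @param object An `fp_ordination`.
#' @param records Optional metadata tibble; when it has an `age` column,
#'   points are coloured by age decade (70+ pooled), mirroring the usual
#'   presentation of age-group ordinations.
#' @param components Which two components to plot.
#' @export
autoplot.fp_ordination <- function(object, records = NULL,
                                   components = c(1, 2), ...) {
  nm <- paste0("PC", components)
  df <- object$sample_scores
  pct <- 100 * object$explained_fraction[components]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[nm[1]]], y = .data[[nm[2]]]))
  if (!is.null(records) && "age" %in% names(records)) {
    dec <- pmin(records$age[match(df$sample_id, records$sample_id)] %/% 10L, 7L)
    df$age_group <- factor(paste0(dec * 10, ifelse(dec >= 7, "+", "s")))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[nm[1]]], y = .data[[nm[2]]],
                                          colour = .data$age_group))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("%s (%.1f%%)", nm[1], pct[1]),
                  y = sprintf("%s (%.1f%%)", nm[2], pct[2]),
                  colour = "Age group") +
    ggplot2::theme_minimal()
}
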