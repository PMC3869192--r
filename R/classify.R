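#' Label a cohort young/old by an age cutoff
#'
#' `young` means age at or below the cutoff, `old` means above it.
#'
#' @param records Metadata tibble with `sample_id` and `age`
#'   (see [read_metadata()]).
#' @param cutoff Integer age in years.
#' @return An `fp_labeling`: tibble `sample_id`, `age`, `label`
#'   (factor young/old) with attribute `cutoff`.
#' @export
label_by_cutoff <- function(records, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1) stop_parameter("cutoff must be a single number")
  lab <- factor(ifelse(records$age <= cutoff, "young", "old"), levels = c("young", "old"))
  counts <- table(lab)
  if (any(counts == 0)) {
    abort_agemark(sprintf("cutoff %d leaves the '%s' class empty", cutoff,
                          names(counts)[counts == 0][1]),
                  "agemark_labeling_error")
  }
  out <- tibble::tibble(sample_id = records$sample_id, age = records$age, label = lab)
  attr(out, "cutoff") <- as.integer(cutoff)
  class(out) <- c("fp_labeling", class(tibble::tibble()))
  out
}

#' Fit a linear soft-margin SVM
#'
#' Thin wrapper around the libsvm solver (via e1071) that fits a
#' linear-kernel maximal-margin classifier and extracts the primal weight
#' vector and intercept, with the decision orientation fixed so that a
#' positive score means the positive class (`"old"` when the labels are
#' young/old, otherwise the lexicographically larger class). Features are
#' not scaled: abundance tables are sparse and the zero pattern is part of
#' the signal; optional per-feature z-scoring with training statistics is
#' available behind `scale`.
#'
#' @param x Numeric matrix (samples x selected features) with column names.
#' @param y Binary label vector aligned to rows.
#' @param cost Soft-margin regularization constant C (default 1).
#' @param scale Z-score features with training-set statistics before
#'   fitting (default `FALSE`).
#' @return An `fp_linear_model`: list with `feature_ids`, `weights`,
#'   `intercept`, `cost`, `positive_class`, `classes`, and scaling centers /
#'   spreads when `scale = TRUE`.
#' @export
fit_linear_svm <- function(x, y, cost = 1, scale = FALSE) {
  if (!is.numeric(cost) || cost <= 0) stop_parameter("cost must be > 0")
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop_parameter("need exactly two classes to fit")
  positive <- if ("old" %in% classes) "old" else classes[2]
  center <- scl <- NULL
  if (scale) {
    center <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    x <- sweep(sweep(x, 2, center), 2, scl, `/`)
  }
  fit <- e1071::svm(x, factor(y, levels = classes), kernel = "linear",
                    cost = cost, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm's positive decision value belongs to the first label it saw;
  # reorient so positive score = positive class.
  first_seen <- classes[fit$labels[1]]
  if (first_seen != positive) {
    w <- -w
    b <- -b
  }
  structure(list(feature_ids = colnames(x), weights = unname(w), intercept = unname(b),
                 cost = cost, positive_class = positive, classes = classes,
                 center = center, scale = scl),
            class = "fp_linear_model")
}

#' Decision score of a linear model
#'
#' Returns \eqn{w \cdot x + b} for each row of `x`, after aligning columns to
#' the model's features (features unseen at fit time are dropped; fitted
#' features absent from `x` contribute 0). A positive score predicts the
#' positive class (old).
#'
#' @param model An `fp_linear_model`.
#' @param x Numeric matrix or vector of feature values; columns named when
#'   alignment is needed.
#' @return Numeric vector of decision scores.
#' @export
decision_score <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    if (ncol(x) != length(model$feature_ids)) {
      stop_parameter("unnamed input must match the model's feature count")
    }
    colnames(x) <- model$feature_ids
  }
  aligned <- matrix(0, nrow(x), length(model$feature_ids),
                    dimnames = list(rownames(x), model$feature_ids))
  shared <- intersect(colnames(x), model$feature_ids)
  aligned[, shared] <- x[, shared, drop = FALSE]
  if (!is.null(model$center)) {
    aligned <- sweep(sweep(aligned, 2, model$center), 2, model$scale, `/`)
  }
  drop(aligned %*% model$weights) + model$intercept
}

predict_label <- function(model, x) {
  sc <- decision_score(model, x)
  negative <- setdiff(model$classes, model$positive_class)
  ifelse(sc > 0, model$positive_class, negative)
}

#' @rdname fit_linear_svm
#' @param x An `fp_linear_model`.
#' @param ... Unused.
#' @export
tidy.fp_linear_model <- function(x, ...) {
  tibble::tibble(term = c("(intercept)", x$feature_ids),
                 estimate = c(x$intercept, x$weights))
}

#' @rdname fit_linear_svm
#' @export
glance.fp_linear_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$feature_ids), cost = x$cost,
                 positive_class = x$positive_class)
}

#' @export
print.fp_linear_model <- function(x, ...) {
  cat(sprintf("Linear SVM: %d features, C = %g, positive class = %s\n",
              length(x$feature_ids), x$cost, x$positive_class))
  invisible(x)
}
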