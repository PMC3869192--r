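#' Functional profile tables
#'
#' A functional profile is a samples-by-features abundance table: one row per
#' metagenomic sample, one column per functional feature (a Pfam family, KEGG
#' pathway, KEGG Ontology identifier or GO term), and entries counting the
#' distinct non-redundant proteins of that sample assigned to the feature.
#' Counts measure the diversity of proteins within a family, not gene
#' expression. `fp_profile()` builds one from a wide data frame whose first
#' column is `sample_id`; the result is a tibble subclass carrying the feature
#' namespace as an attribute, so it pipes through dplyr like any tibble.
#'
#' @param x A data frame with a `sample_id` column followed by one numeric
#'   column per feature, or a numeric matrix with sample ids as row names.
#' @param namespace Feature namespace, one of `"pfam"`, `"kegg_pathway"`,
#'   `"kegg_ko"`, `"go"`.
#' @return A `fp_profile` tibble (first column `sample_id`).
#' @examples
#' fp_profile(data.frame(sample_id = c("S1", "S2"), PF1 = c(4, 0), PF2 = c(4, 4)))
#' @export
fp_profile <- function(x, namespace = c("pfam", "kegg_pathway", "kegg_ko", "go")) {
  namespace <- rlang::arg_match(namespace)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) stop_validation("matrix input needs sample ids as row names")
    x <- tibble::as_tibble(as.data.frame(x), rownames = "sample_id")
  }
  x <- tibble::as_tibble(x)
  if (!"sample_id" %in% names(x)) stop_format("profile needs a 'sample_id' column")
  x <- dplyr::relocate(x, "sample_id")
  x$sample_id <- as.character(x$sample_id)
  validate_fp_profile(x)
  attr(x, "namespace") <- namespace
  class(x) <- c("fp_profile", class(tibble::tibble()))
  x
}

validate_fp_profile <- function(x) {
  if (anyDuplicated(x$sample_id)) {
    stop_format(paste0("duplicate sample identifier: ",
                       paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", ")))
  }
  feats <- setdiff(names(x), "sample_id")
  if (anyDuplicated(feats)) stop_format("duplicate feature identifier")
  vals <- as.matrix(x[feats])
  if (length(vals) && !is.numeric(vals)) stop_format("feature columns must be numeric")
  if (length(vals) && (anyNA(vals) || any(vals < 0))) {
    stop_validation("abundances must be non-negative and non-missing")
  }
  invisible(x)
}

#' @export
print.fp_profile <- function(x, ...) {
  cat(sprintf("# Functional profile: %d samples x %d features [%s]\n",
              nrow(x), ncol(x) - 1L, fp_namespace(x)))
  NextMethod()
}

#' Extract the abundance matrix / feature ids / namespace of a profile
#'
#' @param x A `fp_profile` (or any data frame with a `sample_id` column).
#' @return `fp_matrix()`: a numeric matrix, samples in rows (named);
#'   `fp_features()`: character vector of feature ids; `fp_namespace()`: the
#'   namespace tag (`"pfam"` when untagged).
#' @export
fp_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  feats <- setdiff(names(x), "sample_id")
  m <- as.matrix(as.data.frame(x)[feats])
  if (!is.numeric(m)) m <- matrix(as.numeric(m), nrow(x), dimnames = list(NULL, feats))
  rownames(m) <- x$sample_id
  m
}

#' @rdname fp_matrix
#' @export
fp_features <- function(x) if (is.matrix(x)) colnames(x) else setdiff(names(x), "sample_id")

#' @rdname fp_matrix
#' @export
fp_namespace <- function(x) attr(x, "namespace") %||% "pfam"

# matrix -> fp_profile, preserving namespace
as_fp_profile <- function(m, namespace = "pfam") fp_profile(m, namespace = namespace)

#' Merge single-sample (or partial) profiles into one table
#'
#' Rows are stacked in input order; the feature set is the union across parts,
#' zero-filled where a part lacks a feature. All parts must share a namespace
#' and have distinct sample ids.
#'
#' @param parts List of `fp_profile` objects.
#' @return A single `fp_profile`.
#' @export
merge_profiles <- function(parts) {
  if (!length(parts)) stop_parameter("no profiles to merge")
  ns <- unique(vapply(parts, fp_namespace, character(1)))
  if (length(ns) != 1) stop_validation("profiles mix feature namespaces")
  ids <- unlist(lapply(parts, function(p) p$sample_id))
  if (anyDuplicated(ids)) {
    stop_validation(paste0("duplicate sample id across parts: ",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  wide <- dplyr::bind_rows(lapply(parts, tibble::as_tibble))
  wide[is.na(wide)] <- 0
  fp_profile(wide, namespace = ns)
}
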