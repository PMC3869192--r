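#' Read an abundance table from disk
#'
#' On disk, tables are tab-separated with features as rows: the first column
#' (`feature_id`) holds feature identifiers and the remaining column headers
#' are sample identifiers. Lines starting with `#` (reproducibility headers
#' written by the pipeline) are skipped. In memory the table is transposed to
#' samples x features.
#'
#' @param path Path to a TSV file.
#' @inheritParams fp_profile
#' @return A [fp_profile] tibble.
#' @export
read_abundance_table <- function(path, namespace = "pfam") {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         na = character())
  if (ncol(tab) < 2) stop_format("abundance table needs a feature column and at least one sample")
  feats <- as.character(tab[[1]])
  if (anyDuplicated(feats)) stop_format("duplicate feature identifier in table")
  samples <- names(tab)[-1]
  if (anyDuplicated(samples)) stop_format("duplicate sample identifier in table")
  m <- sapply(tab[-1], function(col) {
    col <- as.character(col)
    col[!nzchar(col)] <- "0"          # missing cells count as 0
    v <- suppressWarnings(as.numeric(col))
    if (anyNA(v)) stop_format("non-numeric abundance cell")
    v
  })
  m <- matrix(m, nrow = length(feats), dimnames = list(feats, samples))
  if (any(m < 0)) stop_validation("negative abundance in table")
  fp_profile(t(m), namespace = namespace)
}

#' Write an abundance table (features as rows)
#'
#' @param x A [fp_profile].
#' @param path Output path.
#' @param header Optional character vector of comment lines (without `#`)
#'   prepended to the file.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path, header = NULL) {
  m <- t(fp_matrix(x))
  out <- tibble::as_tibble(as.data.frame(m), rownames = "feature_id")
  if (!is.null(header)) writeLines(paste0("# ", header), path)
  readr::write_tsv(out, path, append = !is.null(header), col_names = TRUE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Expects a tab-separated file with header columns `sample_id`, `age`,
#' `country` and optionally `ibd` and `obese`. Ages are integer years and
#' must lie in \[1, 120\]. Missing optional flags stay `NA` (unknown), not
#' `FALSE`.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `sample_id`, `age`, `country`, `ibd`, `obese`.
#' @export
read_metadata <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("sample_id", "age", "country")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop_format(paste0("metadata lacks required column(s): ", paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    sample_id = as.character(tab$sample_id),
    age = as.integer(tab$age),
    country = as.character(tab$country),
    ibd = if ("ibd" %in% names(tab)) as.logical(tab$ibd) else NA,
    obese = if ("obese" %in% names(tab)) as.logical(tab$obese) else NA
  )
  validate_metadata(out)
}

validate_metadata <- function(records) {
  if (any(!nzchar(records$sample_id))) stop_validation("empty sample_id in metadata")
  if (anyDuplicated(records$sample_id)) stop_validation("duplicate sample_id in metadata")
  bad <- is.na(records$age) | records$age < 1L | records$age > 120L
  if (any(bad)) {
    stop_validation(paste0("age outside [1, 120] for sample(s): ",
                           paste(records$sample_id[bad], collapse = ", ")))
  }
  records
}

#' @rdname read_metadata
#' @param records Metadata tibble.
#' @inheritParams write_abundance_table
#' @export
write_metadata <- function(records, path, header = NULL) {
  if (!is.null(header)) writeLines(paste0("# ", header), path)
  readr::write_tsv(records, path, append = !is.null(header), col_names = TRUE)
  invisible(path)
}
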