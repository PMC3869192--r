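#' Parse HMMER tabular Pfam hits
#'
#' Reads the HMMER 3 space-delimited tabular output (`--tblout`, one line per
#' target/query pair, or `--domtblout`, one line per domain) as produced by
#' `hmmscan` run against Pfam, where the target is the Pfam model and the
#' query is a protein sequence. Lines beginning with `#` are comments. Hits
#' are recorded as reported: the gathering-threshold (GA) filter is the
#' search tool's job (`--cut_ga`), since GA values live in the Pfam model
#' files, not in the hit table. A query may legitimately have zero or many
#' hits.
#'
#' @param path Path to a HMMER tabular output file.
#' @return A tibble of hits: `query_id`, `target_id` (the Pfam accession, or
#'   model name when no accession is present), `evalue`, `score`,
#'   `above_threshold` (always `TRUE`; see Details).
#' @export
parse_pfam_hits <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (!length(rows)) {
    return(tibble::tibble(query_id = character(), target_id = character(),
                          evalue = double(), score = double(),
                          above_threshold = logical()))
  }
  parsed <- lapply(rows, function(i) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    # domtblout rows carry a numeric model length in field 3 and >= 23 fields;
    # tblout rows have the query name there and >= 18 fields.
    is_dom <- length(f) >= 23 && !is.na(suppressWarnings(as.numeric(f[3])))
    if (is_dom) {
      query <- f[4]; acc <- f[2]; ev <- f[13]; sc <- f[14]
    } else if (length(f) >= 18) {
      query <- f[3]; acc <- f[2]; ev <- f[5]; sc <- f[6]
    } else {
      stop_format(sprintf("malformed HMMER tabular line %d (%d fields)", i, length(f)))
    }
    ev <- suppressWarnings(as.numeric(ev)); sc <- suppressWarnings(as.numeric(sc))
    if (is.na(ev) || is.na(sc) || ev < 0) {
      stop_format(sprintf("malformed HMMER tabular line %d (bad e-value/score)", i))
    }
    target <- if (acc == "-") f[1] else sub("\\.\\d+$", "", acc)
    tibble::tibble(query_id = query, target_id = target, evalue = ev,
                   score = sc, above_threshold = TRUE)
  })
  dplyr::bind_rows(parsed)
}

#' Parse BLAST 12-column tabular output
#'
#' Standard `-outfmt 6`: query, subject, identity, alignment length,
#' mismatches, gap opens, qstart, qend, sstart, send, evalue, bitscore.
#'
#' @param path Path to a BLAST tabular file.
#' @return A tibble of hits with columns `query_id`, `target_id`, `evalue`,
#'   `score` (bitscore), `above_threshold` (`TRUE`; thresholding happens at
#'   transfer time).
#' @export
parse_blast_hits <- function(path) {
  cols <- c("query_id", "target_id", "identity", "length", "mismatches", "gaps",
            "qstart", "qend", "sstart", "send", "evalue", "score")
  tab <- readr::read_tsv(path, col_names = cols, comment = "#", show_col_types = FALSE)
  if (any(is.na(tab$evalue)) || any(tab$evalue < 0)) stop_format("bad e-value in BLAST table")
  tibble::tibble(query_id = as.character(tab$query_id),
                 target_id = as.character(tab$target_id),
                 evalue = as.numeric(tab$evalue),
                 score = as.numeric(tab$score),
                 above_threshold = TRUE)
}

#' Read a UniProt accession to GO-term map
#'
#' Two-column TSV: accession, comma-separated GO identifiers.
#'
#' @param path Path to the map file.
#' @return Named list mapping accession to a character vector of GO ids.
#' @export
read_go_map <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("accession", "go_ids"),
                         comment = "#", show_col_types = FALSE)
  stats::setNames(
    lapply(strsplit(as.character(tab$go_ids), ","), trimws),
    as.character(tab$accession)
  )
}

#' Transfer GO terms from best BLAST matches
#'
#' For each query the best match is the hit with the smallest e-value (ties
#' broken by highest bitscore, then lexicographic target id). GO terms are
#' transferred from that match only when its e-value is at or below
#' `evalue_max`; queries whose best hit fails the threshold, or whose best
#' target has no GO mapping, are dropped.
#'
#' @param blast_hits Hit tibble from [parse_blast_hits()].
#' @param go_map Named list from [read_go_map()].
#' @param evalue_max Transfer threshold on the best-match e-value
#'   (default `1e-5`).
#' @return Named list: query id -> character vector of GO ids.
#' @export
transfer_go_terms <- function(blast_hits, go_map, evalue_max = 1e-5) {
  if (!is.numeric(evalue_max) || evalue_max <= 0) stop_parameter("evalue_max must be > 0")
  if (!length(go_map)) stop_parameter("empty GO map")
  best <- blast_hits |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$score), .data$target_id) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE) |>
    dplyr::filter(.data$evalue <= evalue_max)
  out <- lapply(seq_len(nrow(best)), function(i) {
    terms <- go_map[[best$target_id[i]]]
    if (is.null(terms) || !length(terms)) NULL else unique(terms)
  })
  names(out) <- best$query_id
  out[!vapply(out, is.null, logical(1))]
}

#' Per-sample feature counts from protein assignments
#'
#' The count for feature `f` is the number of distinct query proteins whose
#' assignment set contains `f` — the diversity of non-redundant proteins per
#' family, not an expression level.
#'
#' @param assignments Named list: query id -> character vector of feature ids.
#' @param sample_id Identifier for the sample.
#' @param namespace Feature namespace tag.
#' @param all_features Optional feature universe; features never assigned get
#'   count 0.
#' @return A one-sample [fp_profile].
#' @export
counts_from_assignments <- function(assignments, sample_id,
                                    namespace = "pfam", all_features = NULL) {
  pairs <- tibble::tibble(
    query = rep(names(assignments), lengths(assignments)),
    feature = unlist(assignments, use.names = FALSE) %||% character()
  )
  counts <- pairs |>
    dplyr::distinct() |>
    dplyr::count(.data$feature, name = "n")
  feats <- union(all_features %||% character(), counts$feature)
  v <- stats::setNames(rep(0, length(feats)), feats)
  v[counts$feature] <- counts$n
  m <- matrix(v, nrow = 1, dimnames = list(sample_id, feats))
  fp_profile(m, namespace = namespace)
}
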