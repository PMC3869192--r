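# Plain-text fixtures written programmatically at test time.

write_hmmer_tblout <- function(path, hits) {
  # hits: data.frame with target, acc, query, evalue, score
  lines <- c(
    "#                                                               --- full sequence ---- --- best 1 domain ---- --- domain number estimation ----",
    "# target name        accession  query name           accession    E-value  score  bias   E-value  score  bias   exp reg clu  ov env dom rep inc description of target"
  )
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    lines <- c(lines, paste(h$target, h$acc, h$query, "-",
                            format(h$evalue), format(h$score), "0.1",
                            format(h$evalue), format(h$score), "0.1",
                            "1.0", "1", "0", "0", "1", "1", "1", "1",
                            "synthetic fixture", sep = " "))
  }
  writeLines(lines, path)
  path
}

write_blast_tab <- function(path, hits) {
  # hits: data.frame with query, target, evalue, bitscore
  rows <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    paste(h$query, h$target, "85.0", "120", "18", "0", "1", "120", "1", "120",
          format(h$evalue), format(h$bitscore), sep = "\t")
  }, character(1))
  writeLines(rows, path)
  path
}

write_go_map <- function(path, map) {
  writeLines(vapply(names(map), function(acc) {
    paste(acc, paste(map[[acc]], collapse = ","), sep = "\t")
  }, character(1)), path)
  path
}

tiny_cohort <- function(seed = 42, n_samples = 30, n_features = 60,
                        planted = planted_age_effects(cutoff = 40)) {
  generate_cohort(synthetic_config(
    n_samples = n_samples, n_features = n_features,
    planted = planted, seed = seed))
}

# label prediction from decision scores (positive = positive class)
predict_label_for_test <- function(model, x) {
  sc <- decision_score(model, x)
  neg <- setdiff(model$classes, model$positive_class)
  ifelse(sc > 0, model$positive_class, neg)
}

labels_for <- function(cohort, cutoff) {
  lab <- label_by_cutoff(cohort$records, cutoff)
  as.character(lab$label[match(cohort$profile$sample_id, lab$sample_id)])
}
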