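test_that("abundance tables round-trip through disk exactly", {
  withr::with_seed(1, {
    m <- random_count_matrix(5, 12)
    p <- fp_profile(m, namespace = "kegg_ko")
    path <- withr::local_tempfile(fileext = ".tsv")
    write_abundance_table(p, path)
    back <- read_abundance_table(path, namespace = "kegg_ko")
    expect_equal(fp_matrix(back), fp_matrix(p))
    expect_identical(back$sample_id, p$sample_id)
    expect_identical(fp_namespace(back), "kegg_ko")
  })
})

test_that("an all-zero table keeps its shape and ids", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tS1\tS2", "A\t0\t0", "B\t0\t0", "C\t0\t0"), path)
  p <- read_abundance_table(path)
  expect_equal(dim(fp_matrix(p)), c(2L, 3L))
  expect_true(all(fp_matrix(p) == 0))
})

test_that("malformed abundance tables are rejected with typed errors", {
  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tS1", "A\t-1"), neg)
  expect_error(read_abundance_table(neg), class = "agemark_validation_error")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tS1", "A\t1", "A\t2"), dup)
  expect_error(read_abundance_table(dup), class = "agemark_format_error")

  expect_error(fp_profile(data.frame(sample_id = c("S1", "S1"), A = c(1, 2))),
               class = "agemark_format_error")
})

test_that("metadata parses, validates ages, and leaves unknown flags NA", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tage\tcountry", "S1\t43\tSpain", "S2\t61\tDenmark"), path)
  rec <- read_metadata(path)
  expect_equal(rec$age, c(43L, 61L))
  expect_true(all(is.na(rec$ibd)))   # unknown, not FALSE

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tage\tcountry", "S1\t0\tSpain"), bad)
  expect_error(read_metadata(bad), class = "agemark_validation_error")

  nocol <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcountry", "S1\tSpain"), nocol)
  expect_error(read_metadata(nocol), class = "agemark_format_error")
})

test_that("a 52-row metadata file yields 52 records", {
  path <- withr::local_tempfile(fileext = ".tsv")
  withr::with_seed(5, {
    rows <- sprintf("P%02d\t%d\t%s", 1:52, sample(22:87, 52, replace = TRUE),
                    sample(c("Spain", "Denmark", "Japan", "USA", "France", "Italy"),
                           52, replace = TRUE))
  })
  writeLines(c("sample_id\tage\tcountry", rows), path)
  expect_equal(nrow(read_metadata(path)), 52L)
})

test_that("HMMER tabular hits parse as reported, multiple hits per query allowed", {
  empty <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c("# comment only", "# another"), empty)
  expect_equal(nrow(parse_pfam_hits(empty)), 0L)

  withr::with_seed(2, {
    fix <- data.frame(
      target = paste0("Fam", 1:10), acc = sprintf("PF%05d.3", 1:10),
      query = c("q1", "q1", paste0("q", 2:9)),
      evalue = signif(10^runif(10, -30, -5), 3), score = round(runif(10, 20, 300), 1))
  })
  path <- write_hmmer_tblout(withr::local_tempfile(fileext = ".tbl"), fix)
  hits <- parse_pfam_hits(path)
  expect_equal(nrow(hits), 10L)
  expect_equal(hits$query_id, fix$query)
  expect_equal(hits$target_id, sprintf("PF%05d", 1:10))
  expect_equal(hits$evalue, fix$evalue)
  expect_equal(sum(hits$query_id == "q1"), 2L)   # multiple Pfams, one protein

  bad <- withr::local_tempfile(fileext = ".tbl")
  writeLines("Fam1 PF00001 q1 - only five fields", bad)
  expect_error(parse_pfam_hits(bad), "line 1", class = "agemark_format_error")
})

test_that("GO transfer uses the best hit and an upper e-value bound", {
  go_map <- list(U1 = "GO:0006909", U2 = c("GO:0001974", "GO:0047849"),
                 U3 = "GO:0030683")
  hits <- data.frame(
    query = c("qA", "qB", "qC", "qC"),
    target = c("U1", "U1", "U2", "U3"),
    evalue = c(1e-10, 1e-3, 1e-8, 1e-12),
    bitscore = c(200, 50, 150, 180))
  path <- write_blast_tab(withr::local_tempfile(fileext = ".tsv"), hits)
  parsed <- parse_blast_hits(path)
  out <- transfer_go_terms(parsed, go_map, evalue_max = 1e-5)
  expect_equal(out$qA, "GO:0006909")
  expect_false("qB" %in% names(out))            # best e-value 1e-3 fails 1e-5
  expect_equal(out$qC, "GO:0030683")            # 1e-12 beats 1e-8, terms from U3 only
  expect_error(transfer_go_terms(parsed, go_map, evalue_max = 0),
               class = "agemark_parameter_error")
})

test_that("best-hit choice matches a brute-force scan on a random fixture", {
  withr::with_seed(9, {
    hits <- data.frame(
      query = sample(paste0("q", 1:8), 40, replace = TRUE),
      target = sample(paste0("U", 1:6), 40, replace = TRUE),
      evalue = signif(10^runif(40, -20, -6), 4),
      bitscore = round(runif(40, 30, 400), 1))
  })
  go_map <- stats::setNames(lapply(1:6, function(i) paste0("GO:000000", i)), paste0("U", 1:6))
  out <- transfer_go_terms(
    parse_blast_hits(write_blast_tab(withr::local_tempfile(fileext = ".tsv"), hits)),
    go_map, evalue_max = 1e-5)
  for (q in unique(hits$query)) {
    sub <- hits[hits$query == q, ]
    sub <- sub[order(sub$evalue, -sub$bitscore, sub$target), ]
    best <- sub[1, ]
    if (best$evalue <= 1e-5) {
      expect_equal(out[[q]], go_map[[best$target]])
    } else {
      expect_false(q %in% names(out))
    }
  }
})

test_that("assignment counts measure distinct proteins per feature", {
  empty <- counts_from_assignments(list(), "S1", all_features = c("A", "B"))
  expect_true(all(fp_matrix(empty) == 0))

  p <- counts_from_assignments(list(q1 = "A", q2 = c("A", "B")), "S1")
  m <- fp_matrix(p)
  expect_equal(m[1, "A"], 2)
  expect_equal(m[1, "B"], 1)
  # row sum equals the number of (query, feature) assignment pairs
  expect_equal(sum(m), 3)

  many <- counts_from_assignments(stats::setNames(rep(list("A"), 100), paste0("q", 1:100)), "S1")
  expect_equal(unname(fp_matrix(many)[1, "A"]), 100)
})

test_that("merging profiles zero-fills the feature union and preserves counts", {
  a <- counts_from_assignments(list(q1 = "A", q2 = "A"), "S1")
  b <- counts_from_assignments(list(q1 = "B"), "S2")
  merged <- merge_profiles(list(a, b))
  m <- fp_matrix(merged)
  expect_equal(m["S1", "B"], 0)
  expect_equal(m["S2", "A"], 0)
  expect_equal(m["S1", "A"], 2)

  expect_identical(fp_matrix(merge_profiles(list(a))), fp_matrix(a))
  expect_error(merge_profiles(list(a, a)), class = "agemark_validation_error")

  # merge -> split by sample -> re-merge is the identity
  withr::with_seed(3, {
    parts <- lapply(1:4, function(i) {
      fp_profile(matrix(rpois(6, 4), 1,
                        dimnames = list(paste0("S", i),
                                        sample(LETTERS[1:10], 6))))
    })
  })
  merged <- merge_profiles(parts)
  resplit <- lapply(seq_len(nrow(merged)), function(i) {
    fp_profile(fp_matrix(merged)[i, , drop = FALSE])
  })
  expect_equal(fp_matrix(merge_profiles(resplit)), fp_matrix(merged))
  for (part in parts) {
    pm <- fp_matrix(part)
    expect_equal(unname(fp_matrix(merged)[rownames(pm), colnames(pm)]), unname(pm[1, ]))
  }
})
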