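Package: agemark
Title: Age-Discriminative Feature Selection for Gut Metagenome Functional Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies functional signatures (Pfam, KEGG pathway, KEGG
    Ontology, Gene Ontology features) that discriminate human gut
    metagenomes by host age. Implements TF-iDF and minimum-redundancy
    maximum-relevance (mRMR) feature ranking, a Grubbs-test
    outlier-weighted selector, linear support-vector-machine
    classification under leave-one-out cross-validation with in-fold
    selection, repeated random-subset evaluation with AUC confidence
    intervals, a per-year age-cutoff sweep, and Hellinger-transform
    (transformation-based) PCA ordination. Includes readers for
    abundance tables, sample metadata, HMMER and BLAST tabular output
    with GO-term transfer, and a seeded synthetic-cohort generator with
    planted age effects for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
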