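Package: pgxsafety
Title: Personal-Genome Deleteriousness Scores for Drug Safety
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Scores drugs for population-level genomic risk from
    multi-sample genotypes and per-variant deleteriousness predictions.
    Per-variant SIFT-style scores are aggregated by geometric mean into
    per-individual gene scores, then into per-individual drug scores over
    each drug's pharmacokinetic/pharmacodynamic gene set; averaging over a
    cohort yields a per-drug population score (AUC) and the vulnerable
    fraction below a risk threshold. Includes a Cochran-Armitage trend
    test across AUC bins, one-way ANOVA with Tukey post-hoc comparisons
    across drug-status categories, a gene-count sensitivity sweep, and a
    synthetic-cohort simulator with an AUC-linked withdrawal model.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    graphics,
    grDevices,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
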