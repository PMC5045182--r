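# Shared fixture builders and independent oracles. The oracles deliberately
# avoid the package's code paths: nested loops and direct products instead
# of log-space matrix algebra.

# Nested-loop brute-force scorer: for each individual and drug, collect the
# raw per-gene variant products and take n-th roots directly.
brute_force_scores <- function(carriage, annotations, map, epsilon = 0.001) {
  ann <- annotations[!duplicated(annotations[c("key", "gene")]), ]
  inds <- carriage$individuals
  drugs <- names(map$gene_sets)
  out <- matrix(NA_real_, length(inds), length(drugs),
                dimnames = list(inds, drugs))
  for (i in seq_along(inds)) {
    for (d in seq_along(drugs)) {
      gs <- numeric(0)
      for (g in map$gene_sets[[d]]) {
        rows <- ann[ann$gene == g & ann$key %in% colnames(carriage$carriage), ]
        v <- numeric(0)
        for (r in seq_len(nrow(rows))) {
          if (carriage$carriage[i, rows$key[r]])
            v <- c(v, max(rows$sift[r], epsilon))
        }
        gs <- c(gs, if (length(v) == 0) 1 else prod(v)^(1 / length(v)))
      }
      out[i, d] <- prod(gs)^(1 / length(gs))
    }
  }
  out
}

# Independent signed trend statistic (naive arithmetic, no shared code).
oracle_trend_z <- function(events, totals, scores = seq_along(events)) {
  N <- sum(totals)
  pbar <- sum(events) / N
  num <- 0
  for (i in seq_along(events))
    num <- num + scores[i] * (events[i] - totals[i] * pbar)
  den <- sqrt(pbar * (1 - pbar) *
                (sum(totals * scores^2) - sum(totals * scores)^2 / N))
  num / den
}

# Exhaustive permutation distribution of the trend statistic: every
# assignment of the pooled events to observations, margins fixed.
perm_trend_p <- function(events, totals, scores = seq_along(events)) {
  zobs <- oracle_trend_z(events, totals, scores)
  bin_of <- rep(seq_along(totals), totals)
  cases <- utils::combn(sum(totals), sum(events))
  zs <- apply(cases, 2L, function(ix)
    oracle_trend_z(tabulate(bin_of[ix], length(totals)), totals, scores))
  mean(abs(zs) >= abs(zobs) - 1e-12)
}

# Small in-memory cohort with hand-controllable carriage.
make_toy_cohort <- function(n_ind = 3L, ann_df = NULL, carriage_lgl = NULL) {
  if (is.null(ann_df)) {
    ann_df <- data.frame(
      chrom = "1", pos = c(100L, 200L, 300L, 400L),
      ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"),
      gene = c("GENE1", "GENE1", "GENE2", "GENE3"),
      consequence = "nonsynonymous",
      sift = c(0.1, 0.4, 0.05, 0.9), stringsAsFactors = FALSE)
  }
  ann_df$key <- variant_key(ann_df$chrom, ann_df$pos, ann_df$ref, ann_df$alt)
  ann <- structure(ann_df, n_dropped = 0L,
                   class = c("variant_annotation", "data.frame"))
  inds <- sprintf("IND%02d", seq_len(n_ind))
  if (is.null(carriage_lgl))
    carriage_lgl <- matrix(FALSE, n_ind, nrow(ann_df))
  dimnames(carriage_lgl) <- list(inds, ann_df$key)
  car <- structure(list(individuals = inds,
                        variants = ann_df[c("chrom", "pos", "ref", "alt",
                                            "key")],
                        carriage = carriage_lgl, n_missing = 0L),
                   class = "genotype_carriage")
  list(carriage = car, annotations = ann)
}

# Random small cohort + map for property tests (uses ambient RNG).
random_cohort <- function(n_ind, n_genes, vpg, n_drugs, gpd) {
  genes <- sprintf("GN%02d", seq_len(n_genes))
  nv <- n_genes * vpg
  ann_df <- data.frame(
    chrom = "1", pos = seq_len(nv) * 10L, ref = "A", alt = "T",
    gene = rep(genes, each = vpg), consequence = "nonsynonymous",
    sift = round(runif(nv), 3), stringsAsFactors = FALSE)
  toy <- make_toy_cohort(n_ind, ann_df,
                         matrix(runif(n_ind * nv) < 0.4, n_ind, nv))
  pairs <- do.call(rbind, lapply(seq_len(n_drugs), function(d)
    data.frame(drug_id = sprintf("DR%02d", d),
               gene = sample(genes, gpd), stringsAsFactors = FALSE)))
  c(toy, list(map = drug_gene_map(pairs, min_genes = min(gpd, 5L))))
}

table1_path <- function() {
  system.file("extdata", "table1_trend_counts.tsv", package = "pgxsafety")
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
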