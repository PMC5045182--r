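# Synthetic cohorts: genotypes under Hardy-Weinberg carriage, bimodal
# SIFT-like scores, a bipartite drug-gene map, and withdrawal labels whose
# probability falls with the drug's population score. Defaults mirror the
# scale of the study design this package targets: 2504 genomes, 2807 PK/PD
# genes, ~1041 drugs with >= 5 genes each (~12.4 genes per drug on average),
# and an overall withdrawal rate near 15%.

#' Simulation configuration
#'
#' @param n_individuals Cohort size (default 2504).
#' @param n_genes Number of PK/PD genes (default 2807).
#' @param n_drugs Number of drugs (default 1041).
#' @param variants_per_gene Poisson mean of nonsynonymous variant count per
#'   gene (default 3).
#' @param allele_freq_shape Beta shape parameters of the alternate-allele
#'   frequency distribution (default `c(0.5, 3)`, right-skewed: most
#'   variants rare).
#' @param sift_mixture Two-component mixture on \[0, 1\]: a near-zero
#'   deleterious component and a near-one tolerated component, mimicking the
#'   bimodal SIFT landscape. List with `weight_deleterious` (default 0.3),
#'   `deleterious_shape` (Beta, default `c(0.6, 8)`) and `tolerated_shape`
#'   (Beta, default `c(4, 1.5)`).
#' @param genes_per_drug List with `min` (lower support, default 5, so every
#'   drug clears the default inclusion threshold) and `mean_extra` (Poisson
#'   mean added on top, default 7.4, giving ~12.4 genes per drug).
#' @param withdrawal_link List with `intercept` (default 1) and `slope`
#'   (default -5) of the logistic model P(withdrawn) =
#'   plogis(intercept + slope * AUC); at a typical mean AUC near 0.55 these
#'   defaults give an overall withdrawal rate near 15%. `precaution_intercept`
#'   (default 0.45) plays the same role for the two precaution flags.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 2504L, n_genes = 2807L,
                       n_drugs = 1041L, variants_per_gene = 3,
                       allele_freq_shape = c(0.5, 3),
                       sift_mixture = list(weight_deleterious = 0.3,
                                           deleterious_shape = c(0.6, 8),
                                           tolerated_shape = c(4, 1.5)),
                       genes_per_drug = list(min = 5L, mean_extra = 7.4),
                       withdrawal_link = list(intercept = 1, slope = -5,
                                              precaution_intercept = 0.45),
                       seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_genes = as.integer(n_genes), n_drugs = as.integer(n_drugs),
              variants_per_gene = variants_per_gene,
              allele_freq_shape = allele_freq_shape,
              sift_mixture = sift_mixture,
              genes_per_drug = genes_per_drug,
              withdrawal_link = withdrawal_link,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_individuals > 0L, n_genes > 0L, n_drugs > 0L,
              variants_per_gene >= 0,
              all(allele_freq_shape > 0),
              length(sift_mixture$deleterious_shape) == 2L,
              length(sift_mixture$tolerated_shape) == 2L,
              genes_per_drug$min >= 1L, genes_per_drug$mean_extra >= 0,
              is.finite(withdrawal_link$intercept),
              is.finite(withdrawal_link$slope))
    w <- sift_mixture$weight_deleterious
    if (w < 0 || w > 1)
      stop("mixture weight must lie in [0, 1]", call. = FALSE)
    if (genes_per_drug$min > n_genes)
      stop("genes_per_drug support exceeds n_genes", call. = FALSE)
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a synthetic cohort
#'
#' Draws, reproducibly from `config$seed`: per-gene variant counts (Poisson),
#' SIFT-like scores from the two-component mixture, alternate-allele
#' frequencies from a Beta distribution, carriage per individual under
#' Hardy-Weinberg (carriage probability 1 - (1-f)^2, independent across
#' variants and individuals), and drug gene sets sampled without
#' replacement. No linkage disequilibrium or population substructure is
#' modelled.
#'
#' @param config A [sim_config()] object.
#' @return List with elements `carriage` (`genotype_carriage`),
#'   `annotations` (`variant_annotation`), `map` (`drug_gene_map`) and
#'   `config`. The ambient RNG state is restored on exit.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)

  genes <- sprintf("G%04d", seq_len(config$n_genes))
  individuals <- sprintf("IND%05d", seq_len(config$n_individuals))

  kg <- stats::rpois(config$n_genes, config$variants_per_gene)
  nv <- sum(kg)
  if (nv == 0L)
    stop("simulation produced zero variants; raise variants_per_gene",
         call. = FALSE)
  gene_of <- rep(genes, kg)

  mix <- config$sift_mixture
  del <- stats::runif(nv) < mix$weight_deleterious
  sift <- numeric(nv)
  sift[del] <- stats::rbeta(sum(del), mix$deleterious_shape[1L],
                            mix$deleterious_shape[2L])
  sift[!del] <- stats::rbeta(sum(!del), mix$tolerated_shape[1L],
                             mix$tolerated_shape[2L])

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1L))
  ann <- data.frame(chrom = "1", pos = seq_len(nv) * 100L,
                    ref = ref, alt = alt, gene = gene_of,
                    consequence = "nonsynonymous", sift = sift,
                    row.names = NULL, stringsAsFactors = FALSE)
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  annotations <- structure(ann, n_dropped = 0L,
                           class = c("variant_annotation", "data.frame"))

  f <- stats::rbeta(nv, config$allele_freq_shape[1L],
                    config$allele_freq_shape[2L])
  p_carry <- 1 - (1 - f)^2
  carriage_m <- matrix(stats::runif(config$n_individuals * nv) <
                         rep(p_carry, each = config$n_individuals),
                       nrow = config$n_individuals,
                       dimnames = list(individuals, ann$key))
  carriage <- structure(list(individuals = individuals,
                             variants = ann[c("chrom", "pos", "ref", "alt",
                                              "key")],
                             carriage = carriage_m, n_missing = 0L),
                        class = "genotype_carriage")

  sizes <- pmin(config$genes_per_drug$min +
                  stats::rpois(config$n_drugs,
                               config$genes_per_drug$mean_extra),
                config$n_genes)
  drug_ids <- sprintf("DRG%04d", seq_len(config$n_drugs))
  pairs <- data.frame(
    drug_id = rep(drug_ids, sizes),
    gene = unlist(lapply(sizes, function(k) sample(genes, k))),
    role = sample(c("target", "enzyme", "carrier", "transporter"),
                  sum(sizes), replace = TRUE),
    stringsAsFactors = FALSE)
  map <- drug_gene_map(pairs, min_genes = min(config$genes_per_drug$min, 5L))

  list(carriage = carriage, annotations = annotations, map = map,
       config = config)
}

#' Simulate withdrawal and precaution labels from population scores
#'
#' Each drug's withdrawn indicator is Bernoulli with success probability
#' `plogis(intercept + slope * auc)`; a negative slope reproduces the
#' study's direction (lower population score, higher withdrawal
#' probability). Withdrawn drugs are attributed to the UN/EMA/DrugBank
#' source flags at random (each with probability 0.5, at least one); the
#' Beers and FDA precaution flags are drawn independently from the same
#' link with `precaution_intercept`.
#'
#' @param auc Named numeric vector of per-drug population scores in
#'   \[0, 1\] (names = drug ids).
#' @param intercept,slope Logistic coefficients for withdrawal (defaults
#'   1, -5).
#' @param precaution_intercept Intercept for the two precaution flags
#'   (default 0.45, same slope).
#' @param seed Integer seed; ambient RNG state is restored on exit.
#' @return `drug_status` data frame (see [read_drug_status()]).
#' @export
simulate_status <- function(auc, intercept = 1, slope = -5,
                            precaution_intercept = 0.45, seed = 1L) {
  stopifnot(is.numeric(auc), length(auc) > 0L,
            is.finite(intercept), is.finite(slope))
  ids <- if (is.null(names(auc))) sprintf("DRG%04d", seq_along(auc))
         else names(auc)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  n <- length(auc)
  withdrawn <- stats::runif(n) < stats::plogis(intercept + slope * auc)
  src <- matrix(stats::runif(3L * n) < 0.5, nrow = n)
  none <- !rowSums(src)
  src[cbind(which(none), sample.int(3L, sum(none), replace = TRUE))] <- TRUE
  src <- src & withdrawn
  p_prec <- stats::plogis(precaution_intercept + slope * auc)
  out <- data.frame(drug_id = ids,
                    withdrawn_UN = src[, 1L],
                    withdrawn_EMA = src[, 2L],
                    withdrawn_DrugBank = src[, 3L],
                    precaution_Beers = stats::runif(n) < p_prec,
                    precaution_FDA = stats::runif(n) < p_prec,
                    stringsAsFactors = FALSE)
  out$withdrawn <- withdrawn
  out$other <- !out$withdrawn & !out$precaution_Beers & !out$precaution_FDA
  structure(out, class = c("drug_status", "data.frame"))
}

#' Write a minimal multi-sample VCF for a carriage matrix
#'
#' Emits a valid VCF 4.2 file with one biallelic record per variant and
#' genotype `0/1` where the individual carries the alternate allele, `0/0`
#' otherwise. Intended for integration tests of the VCF reader; zygosity is
#' not modelled (carriage is boolean throughout).
#'
#' @param carriage A `genotype_carriage` object.
#' @param path Output path (`.vcf`).
#' @export
write_cohort_vcf <- function(carriage, path) {
  stopifnot(inherits(carriage, "genotype_carriage"))
  v <- carriage$variants
  ord <- order(v$chrom, v$pos)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=pgxsafety-simulator",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", carriage$individuals),
                     collapse = "\t")), con)
  gt <- ifelse(t(carriage$carriage[, v$key[ord], drop = FALSE]), "0/1", "0/0")
  lines <- paste(v$chrom[ord], v$pos[ord], ".", v$ref[ord], v$alt[ord],
                 ".", "PASS", ".", "GT",
                 apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write a variant annotation TSV
#'
#' @param annotations A `variant_annotation` data frame.
#' @param path Output path.
#' @param meta Optional named list of `# key=value` header comments.
#' @export
write_annotations <- function(annotations, path, meta = NULL) {
  cols <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "sift")
  .write_tsv(annotations[cols], path, meta = meta)
}

#' Write a drug-gene map TSV
#'
#' @param map A `drug_gene_map` object (the full pair table is written).
#' @param path Output path.
#' @param meta Optional header comments.
#' @export
write_drug_gene_map <- function(map, path, meta = NULL) {
  stopifnot(inherits(map, "drug_gene_map"))
  .write_tsv(map$pairs, path, meta = meta)
}

#' Write a drug status TSV
#'
#' @param status A `drug_status` data frame.
#' @param path Output path.
#' @param meta Optional header comments.
#' @export
write_drug_status <- function(status, path, meta = NULL) {
  .write_tsv(status[c("drug_id", .status_flags)], path, meta = meta)
}
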