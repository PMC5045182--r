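# The deleteriousness score hierarchy: V per variant, G per (individual,
# gene), D per (individual, drug), P = AUC per drug, V_t per (drug,
# threshold). G and D are geometric means, computed in log space.

#' Clamp a variant deleteriousness score
#'
#' The variant score V is the SIFT-style prediction in \[0, 1\] (lower =
#' more deleterious), floored at `epsilon`. SIFT emits exact zeros, and a
#' single zero annihilates every geometric mean above it; the clamp keeps
#' zero-scored variants maximally deleterious in effect while preserving the
#' multiplicative model. Order among scores above `epsilon` is preserved.
#'
#' @param sift Numeric vector of raw scores in \[0, 1\].
#' @param epsilon Lower clamp in (0, 1); default 0.001.
#' @return `pmax(sift, epsilon)`.
#' @export
clamp_variant_score <- function(sift, epsilon = 0.001) {
  stopifnot(is.numeric(sift), is.numeric(epsilon), length(epsilon) == 1L)
  if (epsilon <= 0 || epsilon >= 1)
    stop("epsilon must lie in (0, 1)", call. = FALSE)
  if (anyNA(sift) || any(sift < 0) || any(sift > 1))
    stop("sift scores must lie in [0, 1]", call. = FALSE)
  pmax(sift, epsilon)
}

#' Gene deleteriousness score
#'
#' G is the geometric mean of the clamped variant scores V for the
#' nonsynonymous variants the individual carries in one gene. An individual
#' carrying no variant in the gene has an unimpaired gene: G = 1.
#'
#' @param v_scores Numeric vector of clamped V scores in (0, 1\]; may be
#'   empty.
#' @return Scalar G in (0, 1\].
#' @export
gene_score <- function(v_scores) {
  if (length(v_scores) == 0L) return(1)
  if (any(v_scores <= 0) || any(v_scores > 1))
    stop("v_scores must lie in (0, 1]; clamp scores first", call. = FALSE)
  exp(mean(log(v_scores)))
}

#' Drug deleteriousness score
#'
#' D is the geometric mean of the G scores over all of the drug's PK/PD
#' genes, equally weighted; genes in which the individual carries no variant
#' contribute G = 1. D = 1 iff every gene is unimpaired.
#'
#' @param g_scores Numeric vector with one G score per gene in the drug's
#'   gene set (must be nonempty: drugs below the gene-count threshold are
#'   excluded upstream).
#' @return Scalar D in (0, 1\].
#' @export
drug_score <- function(g_scores) {
  if (length(g_scores) == 0L)
    stop("empty gene list: drug should have been excluded by the map filter",
         call. = FALSE)
  if (any(g_scores <= 0) || any(g_scores > 1))
    stop("g_scores must lie in (0, 1]", call. = FALSE)
  exp(mean(log(g_scores)))
}

#' Score a cohort: per-individual drug deleteriousness
#'
#' The central fitting function. For every individual and every included
#' drug it computes D = geometric mean over the drug's gene set of
#' G = geometric mean of the clamped SIFT scores of the variants the
#' individual carries in that gene (G = 1 for genes without carried
#' variants). Deterministic given its inputs.
#'
#' @param carriage A `genotype_carriage` object (see [read_vcf_carriage()]).
#' @param annotations A `variant_annotation` data frame; its variants should
#'   be a subset of the carriage columns (others are ignored with a message).
#' @param map A `drug_gene_map`. Genes in the map with no annotated variant
#'   contribute G = 1 for everyone; drugs none of whose genes carry
#'   annotated variation score D = 1 for all individuals and are flagged.
#' @param epsilon Lower clamp applied to the variant scores (default 0.001).
#' @param keep_gene_scores Keep the individuals x genes G matrix on the
#'   returned object (default TRUE).
#' @return An object of class `dscore_fit`: list with `individuals`, `drugs`,
#'   `d_scores` (individuals x drugs matrix in \[epsilon, 1\]), `g_scores`
#'   (individuals x genes, or NULL), `genes`, `epsilon`, `map`, and a `log`
#'   list (`n_clamped`, `genes_unannotated`, `drugs_without_variation`).
#' @seealso [summary.dscore_fit()], [population_auc()],
#'   [vulnerability_fraction()]
#' @export
score_cohort <- function(carriage, annotations, map, epsilon = 0.001,
                         keep_gene_scores = TRUE) {
  stopifnot(inherits(carriage, "genotype_carriage"),
            inherits(annotations, "variant_annotation"),
            inherits(map, "drug_gene_map"))
  if (length(map$gene_sets) == 0L)
    stop("drug-gene map contains no included drugs", call. = FALSE)

  ann <- annotations
  # duplicate (variant, gene) annotations count once per gene; a variant
  # annotated to several genes contributes independently to each
  ann <- ann[!duplicated(ann[c("key", "gene")]), , drop = FALSE]
  known <- ann$key %in% colnames(carriage$carriage)
  if (!all(known)) {
    message(sum(!known), " annotated variant(s) absent from the carriage ",
            "matrix; ignored")
    ann <- ann[known, , drop = FALSE]
  }
  if (nrow(ann) == 0L)
    stop("no annotated variant overlaps the carriage matrix", call. = FALSE)

  v <- clamp_variant_score(ann$sift, epsilon)
  n_clamped <- sum(ann$sift < epsilon)
  logv <- log(v)

  genes <- sort(unique(unlist(map$gene_sets, use.names = FALSE)))
  gidx <- match(ann$gene, genes)
  in_map <- !is.na(gidx)
  genes_annotated <- unique(ann$gene[in_map])
  genes_unannotated <- setdiff(genes, genes_annotated)

  car <- carriage$carriage[, ann$key[in_map], drop = FALSE]
  storage.mode(car) <- "double"
  nv <- sum(in_map)
  n_ind <- length(carriage$individuals)

  # individuals x genes log-G: mean of log V over carried variants, 0 (G=1)
  # where nothing is carried
  if (nv > 0L) {
    Zw <- Matrix::sparseMatrix(i = seq_len(nv), j = gidx[in_map],
                               x = logv[in_map],
                               dims = c(nv, length(genes)))
    Z1 <- Matrix::sparseMatrix(i = seq_len(nv), j = gidx[in_map], x = 1,
                               dims = c(nv, length(genes)))
    S <- as.matrix(car %*% Zw)
    C <- as.matrix(car %*% Z1)
    logG <- S / pmax(C, 1)
  } else {
    logG <- matrix(0, n_ind, length(genes))
  }
  dimnames(logG) <- list(carriage$individuals, genes)

  drugs <- names(map$gene_sets)
  sizes <- lengths(map$gene_sets)
  di <- rep.int(seq_along(drugs), sizes)
  gj <- match(unlist(map$gene_sets, use.names = FALSE), genes)
  Gd <- Matrix::sparseMatrix(i = gj, j = di, x = rep.int(1 / sizes, sizes),
                             dims = c(length(genes), length(drugs)))
  d_scores <- exp(as.matrix(logG %*% Gd))
  dimnames(d_scores) <- list(carriage$individuals, drugs)

  no_var <- drugs[vapply(map$gene_sets,
                         function(g) !any(g %in% genes_annotated),
                         logical(1L))]
  if (length(no_var) > 0L)
    message(length(no_var), " drug(s) have no annotated variant in any of ",
            "their genes; D = 1 for everyone (genetically ideal)")

  structure(list(individuals = carriage$individuals, drugs = drugs,
                 d_scores = d_scores,
                 g_scores = if (keep_gene_scores) exp(logG) else NULL,
                 genes = genes, epsilon = epsilon, map = map,
                 log = list(n_clamped = n_clamped,
                            genes_unannotated = genes_unannotated,
                            drugs_without_variation = no_var)),
            class = "dscore_fit")
}

#' Population deleteriousness score (AUC)
#'
#' P, the population score of a drug, is the arithmetic mean of the
#' per-individual D scores — equivalently the area under the sorted
#' D-score curve (not a ROC AUC). 1 − AUC is the drug's distance from a
#' genetically ideal drug.
#'
#' @param d_scores Nonempty numeric vector of per-individual D scores in
#'   (0, 1\].
#' @return Scalar AUC in (0, 1\].
#' @export
population_auc <- function(d_scores) {
  if (length(d_scores) == 0L)
    stop("empty population", call. = FALSE)
  if (any(d_scores <= 0) || any(d_scores > 1))
    stop("d_scores must lie in (0, 1]", call. = FALSE)
  mean(d_scores)
}

#' Vulnerable fraction of the population
#'
#' V_t is the proportion of individuals whose D score lies strictly below
#' the risk threshold t — the genetically vulnerable subpopulation for the
#' drug. As a function of t it is the (left-continuous) empirical CDF of D.
#'
#' @param d_scores Nonempty numeric vector of per-individual D scores.
#' @param t Risk threshold in \[0, 1\].
#' @return Fraction in \[0, 1\].
#' @export
vulnerability_fraction <- function(d_scores, t) {
  if (length(d_scores) == 0L)
    stop("empty population", call. = FALSE)
  stopifnot(is.numeric(t), length(t) == 1L)
  if (is.na(t) || t < 0 || t > 1)
    stop("threshold t must lie in [0, 1]", call. = FALSE)
  mean(d_scores < t)
}

#' Per-drug population summary
#'
#' @param fit A `dscore_fit` object.
#' @param thresholds Risk thresholds for the vulnerable fraction V_t
#'   (default `c(0.3, 0.7)`).
#' @param status Optional `drug_status` data frame joined on `drug_id`.
#' @return Data frame of class `population_summary` with one row per drug:
#'   `drug_id`, `n_individuals`, `auc`, `distance` (= 1 − auc), one `v_<t>`
#'   column per threshold, and the status flags when supplied.
#' @export
population_summary <- function(fit, thresholds = c(0.3, 0.7), status = NULL) {
  stopifnot(inherits(fit, "dscore_fit"))
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  out <- data.frame(drug_id = fit$drugs,
                    n_individuals = length(fit$individuals),
                    auc = colMeans(fit$d_scores),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$distance <- 1 - out$auc
  for (t in thresholds)
    out[[sprintf("v_%g", t)]] <- apply(fit$d_scores, 2L,
                                       vulnerability_fraction, t = t)
  if (!is.null(status)) {
    stopifnot(inherits(status, "drug_status"))
    out <- merge(out, status, by = "drug_id", all.x = TRUE, sort = FALSE)
  }
  attr(out, "epsilon") <- fit$epsilon
  attr(out, "min_genes") <- fit$map$min_genes
  class(out) <- c("population_summary", "data.frame")
  out
}
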