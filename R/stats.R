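# Validation statistics: AUC binning, relative frequencies, the
# Cochran-Armitage trend test, one-way ANOVA with Tukey post-hoc across drug
# categories, and the gene-count sensitivity sweep.

#' Assign population scores to equal-width bins
#'
#' Bins are equal-width and right-closed on (0, 1\]: bin k covers
#' ((k-1)/n, k/n\]. A score of exactly 0 goes to bin 1. Comparisons use a
#' 1e-9 guard so that e.g. 0.7 lands in bin 7 despite floating-point
#' representation.
#'
#' @param auc Numeric vector of scores in \[0, 1\].
#' @param n_bins Number of bins (default 10).
#' @return Integer vector of bin indices in 1..n_bins.
#' @export
assign_bins <- function(auc, n_bins = 10L) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 2L)
  if (anyNA(auc) || any(auc < 0) || any(auc > 1))
    stop("auc values must lie in [0, 1]", call. = FALSE)
  pmin(pmax(as.integer(ceiling(auc * n_bins - 1e-9)), 1L), n_bins)
}

#' Bin labels in the "~0.1 ... ~1.0" style
#'
#' @param n_bins Number of bins.
#' @return Character vector labelling each bin by its upper edge.
#' @export
bin_labels <- function(n_bins = 10L) {
  sprintf("~%.*f", max(1L, nchar(n_bins) - 1L),
          seq_len(n_bins) / n_bins)
}

#' Per-bin relative frequencies
#'
#' @param events Per-bin event counts.
#' @param totals Per-bin totals; bins with total 0 yield `NA` (undefined),
#'   never 0.
#' @return Numeric vector `events / totals` with `NA` at empty bins.
#' @export
relative_frequencies <- function(events, totals) {
  if (length(events) != length(totals))
    stop("events and totals differ in length", call. = FALSE)
  if (any(events < 0) || any(totals < 0))
    stop("counts must be nonnegative", call. = FALSE)
  if (any(events > totals))
    stop("event count exceeds total in bin ",
         which(events > totals)[1L], call. = FALSE)
  ifelse(totals > 0, events / totals, NA_real_)
}

#' Cochran-Armitage test for trend in proportions
#'
#' Asymptotic two-sided test of a linear trend in binomial proportions
#' across ordered bins. The signed statistic is
#' \deqn{z = \sum_i s_i (e_i - n_i \bar p) \Big/
#'   \sqrt{\bar p (1-\bar p)\left[\sum_i n_i s_i^2 -
#'   (\sum_i n_i s_i)^2 / N\right]},}
#' with default equally spaced scores 1..k, no continuity correction;
#' `z^2` is the usual trend chi-square on 1 df. The statistic is invariant
#' to affine transformations of the scores and flips sign when the scores
#' are reversed. Degenerate tables (no events, all events, or fewer than
#' two occupied bins) return p = 1 with `degenerate = TRUE` rather than an
#' error.
#'
#' @param events Per-bin event counts.
#' @param totals Per-bin totals (positive wherever events are positive).
#' @param scores Strictly increasing bin scores; default `seq_along(events)`.
#' @return Object of class `trend_test`: list with `statistic` (signed z),
#'   `chisq`, `p_value` (two-sided), `scores`, `n_bins`, `degenerate`.
#' @references Armitage, P. (1955) Tests for linear trends in proportions
#'   and frequencies. Biometrics 11, 375-386.
#' @export
cochran_armitage_trend <- function(events, totals,
                                   scores = seq_along(events)) {
  if (length(events) != length(totals) || length(scores) != length(events))
    stop("events, totals and scores must have equal length", call. = FALSE)
  if (length(events) < 2L)
    stop("need at least 2 bins", call. = FALSE)
  if (any(events < 0) || any(totals < 0))
    stop("counts must be nonnegative", call. = FALSE)
  if (any(events > totals))
    stop("event count exceeds total in bin ",
         which(events > totals)[1L], call. = FALSE)
  if (any(diff(scores) <= 0))
    stop("scores must be strictly increasing", call. = FALSE)

  N <- sum(totals)
  pbar <- sum(events) / N
  occupied <- sum(totals > 0)
  degenerate <- pbar == 0 || pbar == 1 || occupied < 2L
  if (degenerate) {
    res <- list(statistic = 0, chisq = 0, p_value = 1, scores = scores,
                n_bins = length(events), degenerate = TRUE)
    return(structure(res, class = "trend_test"))
  }
  num <- sum(scores * (events - totals * pbar))
  den2 <- pbar * (1 - pbar) *
    (sum(totals * scores^2) - sum(totals * scores)^2 / N)
  z <- num / sqrt(den2)
  structure(list(statistic = z, chisq = z^2,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 scores = scores, n_bins = length(events),
                 degenerate = FALSE),
            class = "trend_test")
}

#' @export
print.trend_test <- function(x, ...) {
  cat("Cochran-Armitage trend test (", x$n_bins, " bins)\n", sep = "")
  if (x$degenerate) {
    cat("  degenerate table: no estimable trend (p = 1)\n")
  } else {
    cat("  z = ", format(x$statistic, digits = 4),
        "  chisq = ", format(x$chisq, digits = 4),
        "  two-sided p = ", format.pval(x$p_value, digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' Trend tests for every event row of a binned count table
#'
#' @param counts A `binned_counts` object.
#' @param scores Bin scores; default equally spaced 1..k.
#' @return Data frame with one row per event series: `row`, `n_events`,
#'   `statistic`, `chisq`, `p_value`, `degenerate`.
#' @export
trend_table <- function(counts, scores = NULL) {
  stopifnot(inherits(counts, "binned_counts"))
  if (is.null(scores)) scores <- seq_along(counts$bins)
  res <- lapply(seq_len(nrow(counts$events)), function(i)
    cochran_armitage_trend(counts$events[i, ], counts$totals, scores))
  data.frame(row = rownames(counts$events),
             n_events = rowSums(counts$events),
             statistic = vapply(res, `[[`, numeric(1L), "statistic"),
             chisq = vapply(res, `[[`, numeric(1L), "chisq"),
             p_value = vapply(res, `[[`, numeric(1L), "p_value"),
             degenerate = vapply(res, `[[`, logical(1L), "degenerate"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group AUC values by drug-status category
#'
#' Categories follow the study design and may overlap: a withdrawn drug
#' listed in the Beers criteria contributes to both groups; "other" means
#' no flag at all.
#'
#' @param summary_df A [population_summary()] data frame containing status
#'   flags (built with `status =`).
#' @param categories Which categories to extract.
#' @return Named list of per-drug AUC vectors.
#' @export
auc_by_category <- function(summary_df,
                            categories = c("withdrawn", "beers", "fda",
                                           "other")) {
  stopifnot(is.data.frame(summary_df),
            all(c("auc", "withdrawn", "precaution_Beers",
                  "precaution_FDA", "other") %in% names(summary_df)))
  pick <- list(withdrawn = summary_df$withdrawn,
               beers = summary_df$precaution_Beers,
               fda = summary_df$precaution_FDA,
               other = summary_df$other)
  lapply(pick[categories], function(sel) summary_df$auc[sel %in% TRUE])
}

#' One-way ANOVA with Tukey post-hoc comparisons
#'
#' Compares per-drug AUC values across drug categories with a fixed-effects
#' one-way ANOVA followed by Tukey honest significant differences.
#' Membership may overlap (the pooled observation list is analysed as
#' given); categories with fewer than two values are excluded with a
#' warning.
#'
#' @param auc_by_category Named list mapping category to a numeric vector of
#'   per-drug AUC values (e.g. from [auc_by_category()]).
#' @return Object of class `group_comparison`: list with `groups` (data
#'   frame category/n/mean/sd), `f_statistic`, `df`, `p_value`, `tukey`
#'   (data frame comparison/diff/lwr/upr/p_adj), `excluded`.
#' @export
anova_tukey <- function(auc_by_category) {
  stopifnot(is.list(auc_by_category), !is.null(names(auc_by_category)))
  sizes <- lengths(auc_by_category)
  excluded <- names(auc_by_category)[sizes < 2L]
  if (length(excluded) > 0L) {
    warning("excluding category(ies) with < 2 values: ",
            paste(excluded, collapse = ", "), call. = FALSE)
    auc_by_category <- auc_by_category[sizes >= 2L]
  }
  if (length(auc_by_category) < 2L)
    stop("need at least 2 categories with >= 2 values each", call. = FALSE)

  long <- data.frame(
    auc = unlist(auc_by_category, use.names = FALSE),
    category = factor(rep(names(auc_by_category),
                          lengths(auc_by_category)),
                      levels = names(auc_by_category)))
  fit <- stats::aov(auc ~ category, data = long)
  tab <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$category
  groups <- data.frame(
    category = names(auc_by_category),
    n = lengths(auc_by_category),
    mean = vapply(auc_by_category, mean, numeric(1L)),
    sd = vapply(auc_by_category, stats::sd, numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(groups = groups,
                 f_statistic = tab[1L, "F value"],
                 df = tab[["Df"]],
                 p_value = tab[1L, "Pr(>F)"],
                 tukey = data.frame(comparison = rownames(tk),
                                    diff = tk[, "diff"], lwr = tk[, "lwr"],
                                    upr = tk[, "upr"], p_adj = tk[, "p adj"],
                                    row.names = NULL,
                                    stringsAsFactors = FALSE),
                 excluded = excluded),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("One-way ANOVA across drug categories\n")
  print(x$groups, digits = 3)
  cat("  F(", x$df[1L], ",", x$df[2L], ") = ",
      format(x$f_statistic, digits = 4), ", p = ",
      format.pval(x$p_value, digits = 3), "\n", sep = "")
  cat("Tukey HSD:\n")
  print(x$tukey, digits = 3)
  invisible(x)
}

#' Gene-count inclusion-threshold sensitivity sweep
#'
#' Re-runs map filtering, cohort scoring and the category ANOVA for each
#' inclusion threshold (minimum number of PK/PD genes per drug), reporting
#' the included-drug count and the group comparison per threshold. Included
#' drug sets are nested: raising the threshold only removes drugs.
#'
#' @param carriage A `genotype_carriage` object.
#' @param annotations A `variant_annotation` data frame.
#' @param map A `drug_gene_map`; its full (unfiltered) pair table is
#'   refiltered at each threshold.
#' @param status A `drug_status` data frame.
#' @param min_genes Integer vector of thresholds (default 1:10).
#' @param epsilon Variant-score clamp passed to [score_cohort()].
#' @return Object of class `sensitivity_sweep`: list with `table` (data
#'   frame: min_genes, n_drugs, f_statistic, p_value, and the Tukey p for
#'   each category vs "other") and `comparisons` (list of
#'   `group_comparison`).
#' @export
sensitivity_sweep <- function(carriage, annotations, map, status,
                              min_genes = 1:10, epsilon = 0.001) {
  stopifnot(inherits(map, "drug_gene_map"))
  comparisons <- vector("list", length(min_genes))
  names(comparisons) <- as.character(min_genes)
  rows <- vector("list", length(min_genes))
  for (i in seq_along(min_genes)) {
    m <- drug_gene_map(map$pairs, min_genes = min_genes[i])
    fit <- score_cohort(carriage, annotations, m, epsilon = epsilon,
                        keep_gene_scores = FALSE)
    summ <- population_summary(fit, thresholds = numeric(0), status = status)
    cmp <- anova_tukey(auc_by_category(summ))
    comparisons[[i]] <- cmp
    p_other <- vapply(c("withdrawn", "beers", "fda"), function(cat) {
      hit <- cmp$tukey$comparison %in% paste0(c(cat, "other"),
                                              "-", c("other", cat))
      if (any(hit)) cmp$tukey$p_adj[hit][1L] else NA_real_
    }, numeric(1L))
    names(p_other) <- paste0("p_", names(p_other), "_vs_other")
    rows[[i]] <- c(list(min_genes = min_genes[i],
                        n_drugs = length(m$gene_sets),
                        f_statistic = cmp$f_statistic,
                        p_value = cmp$p_value), as.list(p_other))
  }
  structure(list(table = do.call(rbind, lapply(rows, as.data.frame)),
                 comparisons = comparisons),
            class = "sensitivity_sweep")
}

#' @export
print.sensitivity_sweep <- function(x, ...) {
  cat("Inclusion-threshold sensitivity sweep\n")
  print(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}
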