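# S3 methods for the fitted scoring object.

#' @export
print.dscore_fit <- function(x, ...) {
  cat("Cohort deleteriousness scores (dscore_fit)\n")
  cat("  individuals:", length(x$individuals),
      " drugs:", length(x$drugs),
      " genes:", length(x$genes), "\n")
  cat("  epsilon clamp:", x$epsilon,
      " (", x$log$n_clamped, "variant score(s) clamped )\n")
  if (length(x$log$drugs_without_variation) > 0L)
    cat("  genetically ideal drugs (no annotated variation):",
        length(x$log$drugs_without_variation), "\n")
  auc <- colMeans(x$d_scores)
  cat("  AUC: min", format(min(auc), digits = 3),
      " median", format(stats::median(auc), digits = 3),
      " max", format(max(auc), digits = 3), "\n")
  invisible(x)
}

#' Summarize a fitted scoring object
#'
#' @param object A `dscore_fit` object.
#' @param thresholds,status Passed to [population_summary()].
#' @param ... Unused.
#' @return A [population_summary()] data frame.
#' @export
summary.dscore_fit <- function(object, thresholds = c(0.3, 0.7),
                               status = NULL, ...) {
  population_summary(object, thresholds = thresholds, status = status)
}

#' Per-drug population scores of a fit
#'
#' @param object A `dscore_fit` object.
#' @param ... Unused.
#' @return Named numeric vector of per-drug AUC values (the population
#'   deleteriousness scores).
#' @export
coef.dscore_fit <- function(object, ...) {
  colMeans(object$d_scores)
}

#' @export
fitted.dscore_fit <- function(object, ...) {
  object$d_scores
}

#' Sorted per-drug D-score curves
#'
#' Plots, for each selected drug, the per-individual D scores sorted in
#' ascending order against the population quantile; the area under such a
#' curve is the drug's AUC, and the horizontal crossing of a risk threshold
#' marks the vulnerable fraction V_t.
#'
#' @param x A `dscore_fit` object.
#' @param drugs Drug ids to draw (default: up to 6 with the lowest AUC).
#' @param threshold Optional risk threshold drawn as a horizontal line.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.dscore_fit <- function(x, drugs = NULL, threshold = NULL, ...) {
  if (is.null(drugs)) {
    auc <- colMeans(x$d_scores)
    drugs <- names(sort(auc))[seq_len(min(6L, length(auc)))]
  }
  m <- apply(x$d_scores[, drugs, drop = FALSE], 2L, sort)
  q <- seq_along(x$individuals) / length(x$individuals)
  graphics::matplot(q, m, type = "l", lty = 1L, ylim = c(0, 1),
                    xlab = "population quantile", ylab = "D score", ...)
  if (!is.null(threshold))
    graphics::abline(h = threshold, lty = 2L)
  graphics::legend("bottomright", legend = drugs, lty = 1L,
                   col = seq_along(drugs), bty = "n", cex = 0.8)
  invisible(x)
}

#' Simulate withdrawal labels from a fitted scoring object
#'
#' Draws per-drug withdrawal indicators from the logistic link
#' `P(withdrawn) = plogis(intercept + slope * AUC)`, the generative model
#' used by the synthetic-cohort module (a negative slope makes low-scoring
#' drugs more likely to be withdrawn).
#'
#' @param object A `dscore_fit` object.
#' @param nsim Number of label vectors to draw.
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @param intercept,slope Logistic link coefficients (defaults 1, -5).
#' @param ... Unused.
#' @return Data frame: `drug_id` plus `nsim` logical columns `sim_1`, ...
#' @export
simulate.dscore_fit <- function(object, nsim = 1, seed = NULL,
                                intercept = 1, slope = -5, ...) {
  auc <- colMeans(object$d_scores)
  p <- stats::plogis(intercept + slope * auc)
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
  }
  out <- data.frame(drug_id = object$drugs, stringsAsFactors = FALSE)
  for (s in seq_len(nsim))
    out[[paste0("sim_", s)]] <- stats::runif(length(p)) < p
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
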