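test_that("bin assignment is right-closed on equal-width bins", {
  expect_equal(assign_bins(0.05), 1L)
  expect_equal(assign_bins(0.10), 1L)
  expect_equal(assign_bins(0.1000001), 2L)
  expect_equal(assign_bins(1.0), 10L)
  expect_equal(assign_bins(0), 1L)
  expect_equal(assign_bins(0.7), 7L)    # guards the 0.7*10 float artifact
  expect_equal(assign_bins(c(0.25, 0.5), n_bins = 4), c(1L, 2L))
  expect_error(assign_bins(1.2), "\\[0, 1\\]")
})

test_that("relative frequencies guard empty bins", {
  expect_equal(relative_frequencies(c(1, 4), c(5, 14)), c(0.2, 4 / 14))
  expect_equal(relative_frequencies(c(3, 2), c(3, 2)), c(1, 1))
  expect_equal(relative_frequencies(c(0, 1), c(0, 2)), c(NA, 0.5))
  expect_error(relative_frequencies(c(-1, 0), c(1, 1)), "nonnegative")
  expect_error(relative_frequencies(c(2, 0), c(1, 1)), "exceeds")
})

test_that("trend test matches the naive oracle and prop.trend.test", {
  set.seed(101)
  for (rep in 1:10) {
    k <- sample(3:10, 1)
    tot <- rpois(k, 30) + 5L
    ev <- rbinom(k, tot, seq(0.1, 0.6, length.out = k))
    res <- cochran_armitage_trend(ev, tot)
    expect_equal(res$statistic, oracle_trend_z(ev, tot), tolerance = 1e-12)
    ref <- suppressWarnings(stats::prop.trend.test(ev, tot, score = 1:k))
    expect_equal(res$chisq, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("trend statistic sign flips under score reversal, p unchanged", {
  ev <- c(1, 2, 5, 3, 21, 23, 23, 11, 3, 1)
  tot <- c(5, 14, 34, 68, 144, 217, 234, 167, 88, 70)
  a <- cochran_armitage_trend(ev, tot, scores = 1:10)
  b <- cochran_armitage_trend(rev(ev), rev(tot), scores = 1:10)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)
  # affine invariance of the scores
  c_ <- cochran_armitage_trend(ev, tot, scores = 0.05 + (1:10) * 0.1)
  expect_equal(a$statistic, c_$statistic, tolerance = 1e-12)
})

test_that("proportional events give a null trend by construction", {
  tot <- c(10, 20, 30, 40)
  res <- cochran_armitage_trend(tot / 10, tot)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  expect_false(res$degenerate)
})

test_that("degenerate tables flag instead of erroring", {
  res0 <- cochran_armitage_trend(c(0, 0, 0), c(5, 5, 5))
  expect_true(res0$degenerate)
  expect_equal(res0$p_value, 1)
  res1 <- cochran_armitage_trend(c(5, 5, 5), c(5, 5, 5))
  expect_true(res1$degenerate)
  res2 <- cochran_armitage_trend(c(1, 0), c(9, 0))
  expect_true(res2$degenerate)
  expect_error(cochran_armitage_trend(c(1, 2), c(5, 5), scores = c(2, 1)),
               "strictly increasing")
  expect_error(cochran_armitage_trend(c(6), c(5)), "at least 2 bins")
})

test_that("on 2-bin tables the trend test is the two-proportion z-test", {
  set.seed(202)
  for (rep in 1:10) {
    n <- c(sample(10:80, 1), sample(10:80, 1))
    e <- c(rbinom(1, n[1], 0.3), rbinom(1, n[2], 0.5))
    if (sum(e) == 0 || sum(e) == sum(n)) next
    res <- cochran_armitage_trend(e, n)
    # pooled two-proportion z-test, no continuity correction
    p1 <- e[1] / n[1]; p2 <- e[2] / n[2]; pp <- sum(e) / sum(n)
    z <- (p2 - p1) / sqrt(pp * (1 - pp) * (1 / n[1] + 1 / n[2]))
    expect_equal(res$statistic, z, tolerance = 1e-10)
    expect_equal(res$chisq, z^2, tolerance = 1e-10)
  }
})

test_that("trend table runs every event row of the printed count table", {
  counts <- read_binned_counts(table1_path())
  res <- trend_table(counts)
  expect_equal(nrow(res), 9L)
  expect_true(all(res$statistic < 0))   # withdrawals concentrate at low AUC
  expect_true(all(res$p_value < 0.06))
  expect_false(any(res$degenerate))
})

test_that("ANOVA/Tukey recovers group structure", {
  g1 <- c(0.5, 0.52, 0.48, 0.51)
  same <- anova_tukey(list(a = g1, b = g1))
  expect_lt(same$f_statistic, 1e-10)
  expect_gt(same$tukey$p_adj[1], 0.999)

  sep <- anova_tukey(list(lo = c(0.01, 0.012, 0.009),
                          hi = c(0.99, 0.988, 0.991)))
  expect_lt(sep$p_value, 1e-10)

  # means and sds reproduce exactly; singleton categories are excluded
  expect_warning(
    cmp <- anova_tukey(list(w = c(0.5, 0.6, 0.4), o = c(0.7, 0.8, 0.9),
                            tiny = 0.2)),
    "tiny")
  expect_equal(cmp$groups$mean, c(0.5, 0.8))
  expect_equal(cmp$groups$sd, c(sd(c(0.5, 0.6, 0.4)), sd(c(0.7, 0.8, 0.9))))
  expect_equal(cmp$excluded, "tiny")
  # permutation invariance within groups
  cmp2 <- suppressWarnings(
    anova_tukey(list(w = c(0.4, 0.6, 0.5), o = c(0.9, 0.7, 0.8),
                     tiny = 0.2)))
  expect_equal(cmp2$f_statistic, cmp$f_statistic)
})

test_that("groups drawn at the published category means separate", {
  # four overlapping drug categories with the reported means/SDs/sizes;
  # "other" should differ from each at Tukey p < 0.001 in most draws
  mu <- c(withdrawn = 0.558, beers = 0.549, fda = 0.542, other = 0.635)
  sdv <- c(0.170, 0.153, 0.145, 0.187)
  n <- c(154, 90, 96, 752)
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    groups <- mapply(function(m, sd_, nn) rnorm(nn, m, sd_),
                     mu, sdv, n, SIMPLIFY = FALSE)
    cmp <- anova_tukey(groups)
    vs_other <- cmp$tukey$p_adj[grepl("other", cmp$tukey$comparison)]
    if (length(vs_other) == 3L && all(vs_other < 0.001)) hits <- hits + 1L
  }
  expect_gte(hits, 12L)
})

test_that("sensitivity sweep nests drug sets and keeps the effect sign", {
  set.seed(303)
  rc <- random_cohort(n_ind = 30, n_genes = 20, vpg = 3, n_drugs = 80,
                      gpd = 6)
  # re-map with variable gene-set sizes so thresholds bite
  sizes <- sample(2:10, 80, replace = TRUE)
  pairs <- do.call(rbind, lapply(seq_len(80), function(d)
    data.frame(drug_id = sprintf("DR%02d", d),
               gene = sample(sprintf("GN%02d", 1:20), sizes[d]))))
  map <- drug_gene_map(pairs, min_genes = 1)
  fit <- suppressMessages(score_cohort(rc$carriage, rc$annotations, map))
  status <- simulate_status(coef(fit), intercept = 15, slope = -30, seed = 9)
  sw <- suppressWarnings(suppressMessages(
    sensitivity_sweep(rc$carriage, rc$annotations, map, status,
                      min_genes = c(2L, 5L, 8L))))
  expect_true(all(diff(sw$table$n_drugs) <= 0))
  d5 <- names(drug_gene_map(map$pairs, 5)$gene_sets)
  d8 <- names(drug_gene_map(map$pairs, 8)$gene_sets)
  expect_true(all(d8 %in% d5))
  # injected effect: withdrawn mean AUC below "other" at every threshold
  for (cmp in sw$comparisons) {
    g <- cmp$groups
    expect_lt(g$mean[g$category == "withdrawn"],
              g$mean[g$category == "other"])
  }
})
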