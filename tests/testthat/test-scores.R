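test_that("variant score clamping floors at epsilon and preserves order", {
  expect_equal(clamp_variant_score(0.37, 0.001), 0.37)
  expect_equal(clamp_variant_score(0, 0.001), 0.001)
  expect_equal(clamp_variant_score(1, 0.001), 1)
  expect_equal(clamp_variant_score(c(0, 0.5, 1), 0.01), c(0.01, 0.5, 1))
  expect_error(clamp_variant_score(1.5), "\\[0, 1\\]")
  expect_error(clamp_variant_score(0.5, epsilon = 0), "epsilon")
})

test_that("gene and drug scores are geometric means with G=1 convention", {
  expect_equal(gene_score(numeric(0)), 1)
  expect_equal(gene_score(0.04), 0.04)
  # frozen from the direct-product oracle (0.1*0.4*0.9)^(1/3)
  expect_equal(gene_score(c(0.1, 0.4, 0.9)), 0.3301927, tolerance = 1e-6)
  expect_equal(gene_score(c(0.1, 0.4, 0.9)), (0.1 * 0.4 * 0.9)^(1 / 3))
  expect_error(gene_score(c(0.5, 0)), "clamp")

  expect_equal(drug_score(rep(1, 5)), 1)
  expect_equal(drug_score(c(0.25, 0.64)), 0.4)          # sqrt(0.16)
  expect_equal(drug_score(c(0.5, 1, 1, 1, 1)), 0.5^(1 / 5))
  expect_error(drug_score(numeric(0)), "excluded")
})

test_that("population AUC is the order-invariant mean of D scores", {
  expect_equal(population_auc(rep(1, 10)), 1)
  expect_equal(population_auc(c(0.2, 0.4, 0.6, 0.8)), 0.5)
  d <- runif(50, 0.01, 1)
  expect_equal(population_auc(d), population_auc(sort(d)))
  expect_equal(1 - population_auc(d), mean(1 - d))
  expect_error(population_auc(numeric(0)), "empty")
})

test_that("vulnerable fraction is the strict-inequality empirical CDF", {
  d <- c(0.1, 0.25, 0.35, 0.9)
  expect_equal(vulnerability_fraction(d, 0), 0)
  expect_equal(vulnerability_fraction(d, 0.3), 0.5)   # brute force: 2/4
  expect_equal(vulnerability_fraction(d, 1), 1)
  expect_equal(vulnerability_fraction(d, 0.25), 0.25) # strict: 0.25 excluded
  expect_error(vulnerability_fraction(d, 1.5), "\\[0, 1\\]")
  # nondecreasing in t; matches a sort-and-count oracle
  set.seed(7)
  for (rep in 1:5) {
    d <- runif(40, 0.001, 1)
    ts <- sort(runif(9))
    vt <- vapply(ts, function(t) vulnerability_fraction(d, t), numeric(1))
    expect_true(all(diff(vt) >= 0))
    expect_equal(vt, vapply(ts, function(t) sum(sort(d) < t) / 40, numeric(1)))
  }
})

test_that("cohort scoring composes the V->G->D hierarchy", {
  # one individual carries one variant (V=0.2) in one of a drug's 5 genes
  ann_df <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G",
                       gene = "GENE1", consequence = "nonsynonymous",
                       sift = 0.2, stringsAsFactors = FALSE)
  toy <- make_toy_cohort(3L, ann_df, matrix(c(TRUE, FALSE, FALSE), 3, 1))
  map <- drug_gene_map(data.frame(
    drug_id = "DRUGX", gene = c("GENE1", "GENE2", "GENE3", "GENE4", "GENE5")))
  fit <- suppressMessages(
    score_cohort(toy$carriage, toy$annotations, map))
  expect_s3_class(fit, "dscore_fit")
  expect_equal(unname(fit$d_scores[, "DRUGX"]), c(0.2^(1 / 5), 1, 1))
  expect_equal(unname(fit$g_scores["IND01", "GENE1"]), 0.2)

  # nobody carries anything -> ideal-drug limit
  toy0 <- make_toy_cohort(4L)
  map0 <- drug_gene_map(data.frame(drug_id = "D",
                                   gene = c("GENE1", "GENE2", "GENE3")),
                        min_genes = 3)
  fit0 <- score_cohort(toy0$carriage, toy0$annotations, map0)
  expect_true(all(fit0$d_scores == 1))
  expect_equal(unname(coef(fit0)), 1)
})

test_that("cohort scoring matches the nested-loop brute-force oracle", {
  set.seed(11)
  for (rep in 1:4) {
    rc <- random_cohort(n_ind = sample(2:10, 1), n_genes = 8, vpg = 2,
                        n_drugs = sample(2:4, 1), gpd = 5)
    fit <- suppressMessages(
      score_cohort(rc$carriage, rc$annotations, rc$map, epsilon = 0.001))
    oracle <- brute_force_scores(rc$carriage, rc$annotations, rc$map, 0.001)
    expect_equal(fit$d_scores, oracle[rownames(fit$d_scores),
                                      colnames(fit$d_scores)],
                 tolerance = 1e-12)
  }
})

test_that("adding a carried deleterious variant strictly lowers D", {
  set.seed(23)
  rc <- random_cohort(n_ind = 5, n_genes = 6, vpg = 2, n_drugs = 2, gpd = 5)
  fit <- suppressMessages(score_cohort(rc$carriage, rc$annotations, rc$map))
  # flip one uncarried variant of a mapped gene to carried with V < 1
  drug <- names(rc$map$gene_sets)[1]
  g <- rc$map$gene_sets[[drug]][1]
  keys <- rc$annotations$key[rc$annotations$gene == g]
  ind <- which(!rc$carriage$carriage[, keys[1]])[1]
  rc$annotations$sift[rc$annotations$key == keys[1]] <- 0.3
  rc$carriage$carriage[ind, keys[1]] <- TRUE
  fit2 <- suppressMessages(score_cohort(rc$carriage, rc$annotations, rc$map))
  expect_lt(fit2$d_scores[ind, drug], fit$d_scores[ind, drug])
  # with V = 1 the score is unchanged
  rc$annotations$sift[rc$annotations$key == keys[1]] <- 1
  fit3 <- suppressMessages(score_cohort(rc$carriage, rc$annotations, rc$map))
  expect_equal(fit3$d_scores[ind, drug],
               unname(brute_force_scores(rc$carriage, rc$annotations,
                                         rc$map)[ind, drug]))
})

test_that("scores obey the geometric-mean bounds", {
  set.seed(31)
  for (rep in 1:3) {
    rc <- random_cohort(n_ind = 6, n_genes = 7, vpg = 3, n_drugs = 3, gpd = 5)
    fit <- suppressMessages(score_cohort(rc$carriage, rc$annotations, rc$map))
    expect_true(all(fit$d_scores >= fit$epsilon & fit$d_scores <= 1))
    expect_true(all(fit$g_scores >= fit$epsilon & fit$g_scores <= 1))
    # min G over the drug's genes <= D <= 1
    for (d in names(rc$map$gene_sets)) {
      gmin <- apply(fit$g_scores[, rc$map$gene_sets[[d]], drop = FALSE], 1, min)
      expect_true(all(fit$d_scores[, d] >= gmin - 1e-12))
    }
  }
})

test_that("permuting individual order permutes rows but changes no value", {
  set.seed(41)
  rc <- random_cohort(n_ind = 6, n_genes = 6, vpg = 2, n_drugs = 2, gpd = 5)
  fit <- suppressMessages(score_cohort(rc$carriage, rc$annotations, rc$map))
  perm <- sample(seq_along(rc$carriage$individuals))
  rc2 <- rc
  rc2$carriage$individuals <- rc$carriage$individuals[perm]
  rc2$carriage$carriage <- rc$carriage$carriage[perm, , drop = FALSE]
  fit2 <- suppressMessages(score_cohort(rc2$carriage, rc$annotations, rc$map))
  expect_equal(fit2$d_scores[rc$carriage$individuals, ], fit$d_scores)
})

test_that("population summary reports auc, distance and thresholds", {
  set.seed(5)
  rc <- random_cohort(n_ind = 8, n_genes = 6, vpg = 2, n_drugs = 3, gpd = 5)
  fit <- suppressMessages(score_cohort(rc$carriage, rc$annotations, rc$map))
  summ <- summary(fit, thresholds = c(0.3, 0.7))
  expect_equal(summ$auc, unname(colMeans(fit$d_scores)))
  expect_equal(summ$distance, 1 - summ$auc)
  expect_true(all(summ$v_0.3 <= summ$v_0.7))
  expect_equal(summ$n_individuals, rep(8L, 3))
  st <- simulate_status(coef(fit), seed = 2)
  summ2 <- summary(fit, status = st)
  expect_true(all(c("withdrawn", "other") %in% names(summ2)))
})
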