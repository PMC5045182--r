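# pgxsafety

Drug safety scored from personal-genome variability.

A drug's behaviour depends on its pharmacokinetic/pharmacodynamic (PK/PD)
genes — targets, metabolizing enzymes, carriers, transporters. `pgxsafety`
asks how much deleterious variation a population carries in those genes,
drug by drug, and whether that burden tracks real-world safety actions
(market withdrawals, Beers-criteria listings, FDA pharmacogenomic labels).
It is aimed at pharmacogenomics and drug-safety researchers who have
multi-sample genotypes, per-variant deleteriousness predictions, and a
drug–gene map, and want population-level risk measures per drug.

## The score hierarchy

For an individual and a drug with PK/PD gene set $S$:

- $V \in [0,1]$ — the variant deleteriousness score (SIFT-style; lower =
  more damaging), clamped below at $\varepsilon = 0.001$;
- $G = \big(\prod_{i=1}^{n} V_i\big)^{1/n}$ over the $n$ variants the
  individual carries in the gene ($G = 1$ if none);
- $D = \big(\prod_{g \in S} G_g\big)^{1/|S|}$, all genes equally weighted;
- $\mathrm{AUC} = \frac{1}{N}\sum_{j=1}^{N} D_j$ over the cohort — the
  population score, the area under the ascending sorted D-score curve
  ($1-\mathrm{AUC}$ is the distance from a "genetically ideal" drug);
- $V_t = \frac{1}{N}\,\#\{j : D_j < t\}$ — the vulnerable fraction at risk
  threshold $t$ (defaults 0.3 and 0.7).

Validation statistics: Cochran–Armitage trend tests of
withdrawal/precaution frequency across ten equal-width AUC bins, one-way
ANOVA + Tukey HSD of AUC across (overlapping) drug categories, and a
sensitivity sweep over the minimum-PK/PD-gene inclusion threshold (1–10,
default 5). A synthetic-cohort generator with Hardy–Weinberg carriage, a
bimodal SIFT-like score mixture, and an AUC-linked logistic withdrawal
model makes the whole pipeline testable end to end.

## Worked example

```r
library(pgxsafety)

sim    <- simulate_cohort(sim_config(n_individuals = 300, n_genes = 500,
                                     n_drugs = 600, seed = 11))
fit    <- score_cohort(sim$carriage, sim$annotations, sim$map)
status <- simulate_status(coef(fit), seed = 12)   # low AUC -> withdrawal
summ   <- summary(fit, status = status)
anova_tukey(auc_by_category(summ))
```

```
One-way ANOVA across drug categories
   category   n  mean    sd
1 withdrawn  87 0.520 0.115
2     beers  46 0.502 0.132
3       fda  55 0.513 0.126
4     other 440 0.581 0.113
  F(3,624) = 14.91, p = 2.21e-09
```

Drugs simulated as withdrawn or precautionary have visibly lower
population scores than the rest (mean AUC 0.50–0.52 vs 0.58), and Tukey
comparisons put each flagged group below "other" at p < 0.001 while the
flagged groups are indistinguishable from one another — the qualitative
signature the scoring method is designed to surface. Binning the same
AUCs and testing withdrawal frequency for trend:

```r
bins <- assign_bins(summ$auc)
cochran_armitage_trend(tabulate(bins[summ$withdrawn], 10), tabulate(bins, 10))
#> Cochran-Armitage trend test (10 bins)
#>   z = -3.935  chisq = 15.49  two-sided p = 8.31e-05
```

The negative z says withdrawal frequency falls as the population score
rises. The same test applied to the published binned count table shipped
in `inst/extdata/table1_trend_counts.tsv` gives, for example, p = 2.1e-05
for all withdrawn drugs pooled (154 of 1041) and p = 4.6e-04 for the
Beers-criteria row.

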