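# rectalCR

Cohort-level genomic comparison of complete (CR) and incomplete (ICR)
responders to neoadjuvant chemoradiation in rectal cancer, from pre-treatment
somatic mutation calls and clinical covariates.

Only a minority of locally advanced rectal cancers respond completely to
chemoradiation, and complete responders can increasingly avoid surgery, so
pre-treatment markers of response matter clinically. An observational CR/ICR
contrast is confounded — age, BMI, gender and tumor size shift both the
chance of complete response and the mutation landscape — so this package
treats confounder balancing as a first-class analysis stage and validates
every stage on synthetic cohorts with known generative truth.

## What it computes

* **Variant filtering and burden** (`read_maf`, `filter_variants`,
  `compute_tmb`): MAF ingestion; exclusion of variants with depth < 30 or
  allele fraction < 0.1; coding nonsynonymous restriction; tumor mutation
  burden as mutations per coding megabase.
* **Matching-weight balancing** (`fit_propensity`, `matching_weights`,
  `iterate_balance`, `compare_tmb_weighted`): propensity score `e` for CR
  from a logistic model; matching weights `min(e, 1-e)/e` (CR) and
  `min(e, 1-e)/(1-e)` (ICR); iterative refitting (squares, then
  interactions, of the worst-balanced covariates) until every weighted
  standardized difference is below 10%; weighted Welch t-test with
  reliability weights and effective sample sizes `(Σw)²/Σw²`.
* **Mutation structure** (`compare_gene_frequencies`,
  `pairwise_interactions`, `repair_panel_fraction`,
  `classify_group_specific`): Fisher exact comparison of genes above 5%
  frequency; co-occurrence (p < 0.05, OR > 1) and mutual exclusivity
  (p < 0.05, OR < 1) over the top 25 mutated genes; the DNA-repair panel
  fraction contrast with a Yates-corrected chi-squared test; CR-/ICR-specific
  classification of external per-gene q-values (q < 0.05 in one group,
  > 0.05 in the other).
* **Response prediction** (`screen_predictors`, `build_features`,
  `fit_response_model`, `select_model`, `performance_metrics`): bivariate
  Fisher screen at p < 0.1; features = tumor size, AJCC stage, any-screened-
  gene indicator, and the 0 / 1–2 / 3-or-more screened-pair count category;
  logistic fits (categorical vs continuous count) selected by lowest AIC with
  a Tjur R² tie-break; Wald odds-ratio intervals, a likelihood-ratio test for
  the count term, and training-set sensitivity/specificity/PPV/NPV.
* **Synthetic cohorts** (`simulation_preset`, `simulate_cohort`,
  `write_fixture_bundle`): study-scale cohorts (104 CR / 260 ICR) with
  confounded assignment, CR-enriched repair genes, planted co-occurring
  pairs calibrated to an exact dependence odds ratio, age-dependent
  passenger burden, below-threshold decoy variants, and an optional
  closed-loop mode that regenerates the response from known logistic
  coefficients.

The statistical core (exact 2×2 test with the hypergeometric
probability-mass rule, Yates chi-squared, Benjamini–Hochberg step-up,
weighted Welch t, IRLS logistic MLE, Tjur R²) is implemented in-package and
cross-checked against independent oracles in the test suite.

## Worked example

```r
library(rectalCR)

params <- simulation_preset("paperlike", seed = 1)
cohort <- simulate_cohort(params)

kept <- filter_variants(cohort$maf, filter_config())
mat  <- build_mutation_matrix(kept, cohort$clinical$sample_id)
tmb  <- compute_tmb(kept, cohort$clinical$sample_id, coding_length_mb = 38)

balanced <- iterate_balance(cohort$clinical,
                            propensity_spec(c("age", "gender", "bmi", "tumor_size")))
print(balanced)
#> Balanced cohort: 364 samples (104 CR / 260 other), 0 excluded
#>   converged after 1 iteration(s); terms: age, gender, bmi, tumor_size
#>    covariate before after
#> 1        age  31.71  0.05
#> 2     gender  19.96  0.17
#> 3        bmi   7.01  1.48
#> 4 tumor_size  31.46  0.38

test <- compare_tmb_weighted(tmb[match(balanced$sample_ids, names(tmb))],
                             balanced$group, balanced$matching_weights)
print(test)
#> Weighted Welch two-sample t-test (reliability weights)
#>   statistic = 5.3874, estimate = 0.127545, df = 152.47, p = 2.65883e-07

panel <- repair_panel_fraction(mat, cohort$clinical$response)
round(100 * panel$fractions)
#>  CR ICR
#>  50  33
signif(panel$test$p_value, 2)
#> [1] 0.0039
```

Reading the output: before weighting, age, gender and tumor size are badly
imbalanced (standardized differences of 20–32%); one round of
matching-weight balancing brings every covariate under 1.5%, well inside the
10% convention. On the balanced cohort the CR group carries an excess burden
of ~0.13 mutations/Mb (the generator plants group means of 14 vs 10
mutations over 38 Mb), and half of CR tumors versus a third of ICR tumors
carry a mutation in the DNA-repair panel.

The numbered scripts under `analysis/` run the same pipeline end to end
(simulation → filtering/TMB/balancing → mutation networks → response model)
and write their tables under `results/`. Setting the environment variable
`RECTALCR_DATA_DIR` to a directory containing `clinical.tsv` and
`mutations.maf` (for example a reformatted export of the public cBioPortal
`rectal_msk_2022` study) switches stages 2–4 from synthetic to real input;
`replication_targets()` lists the published cohort-level quantities that are
only reachable that way.

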