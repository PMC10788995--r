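# lncpairsig

Rank-based lncRNA-pair prognostic signatures for survival risk
stratification.

## The problem

Most transcriptomic prognostic signatures weight *absolute* expression
levels of individual genes, which makes them fragile: a signature trained
on FPKM from one pipeline rarely transfers to TPM from another without
recalibration. `lncpairsig` implements the alternative strategy of building
signatures from **within-sample rank comparisons** of long noncoding RNAs
(lncRNAs). For an ordered pair of lncRNAs $(a, b)$ and sample $s$, the
feature is

$$x_{ab}(s) \;=\; \mathbf{1}\{\,e_a(s) > e_b(s)\,\},$$

a 0-or-1 indicator that is invariant to any per-sample monotone transform
of expression — so no normalisation, batch alignment or platform
calibration is needed to apply a fitted signature to a new cohort. The
risk model is a sparse Cox model on these indicators, summarised as the
exponentiated score

$$\mathrm{score}(s) \;=\; \exp\Big(\textstyle\sum_i \beta_i\, x_i(s)\Big),$$

with patients split into high- and low-risk groups at the Youden-optimal
cutoff of a time-dependent ROC curve. The motivating application is
overall survival in hepatocellular carcinoma, where the candidate lncRNAs
are first screened for co-expression with a curated vascular-invasion gene
set and for tumour-versus-normal differential expression; the package
ships the published five-pair signature for that setting as
`published_signature()` (coefficients 0.3776, −0.3176, −0.3402, −0.3572,
0.4547; reference cutoff 1.395).

The pipeline stages — input parsing (expression TSV, clinical TSV, GTF
biotypes, gene sets, IC50 matrices), co-expression screening, moderated
differential expression, pair construction with the 20% validity filter,
univariate Cox screening, cross-validated LASSO-Cox selection, risk
scoring, IPCW time-dependent ROC / Kaplan–Meier / log-rank / multivariate
Cox evaluation, and risk-group association analyses — are exposed as
composable functions that take and return tibbles, plus a synthetic-cohort
generator (`simulate_cohort()`) with known ground truth for end-to-end
validation. See the methods vignette
(`vignettes/pair-signature-methods.Rmd`) for the statistical details and
design decisions.

## Worked example

A TCGA-scale synthetic cohort (365 tumours, 50 normals, five planted
prognostic pairs, ~65% censoring), analysed end to end:

```r
library(lncpairsig)

sim <- simulate_cohort(sim_config(seed = 42))
res <- run_pair_pipeline(sim$expression, sim$clinical,
                         sim$gene_set, sim$samples, seed = 1)

length(res$de_lnc)   # 14 differentially expressed lncRNAs (14 planted)
nrow(res$pairs)      # 36 valid pairs after the 20% filter
res$model
#> <pair_signature> 5 pair(s), provenance: fitted, lambda: 0.002502
#> # A tibble: 5 x 4
#>   pair_id       lnc_a  lnc_b    beta
#>   <chr>         <chr>  <chr>   <dbl>
#> 1 LNC001|LNC007 LNC001 LNC007  0.466
#> 2 LNC002|LNC003 LNC002 LNC003  0.288
#> 3 LNC002|LNC007 LNC002 LNC007  0.451
#> 4 LNC002|LNC010 LNC002 LNC010  0.192
#> 5 LNC005|LNC006 LNC005 LNC006 -0.382

glance(res$roc)      # 1-year IPCW time-dependent ROC
#>     auc horizon n_cases n_controls
#> 1 0.610     365      43        232

res$cutoff           # Youden-optimal score cutoff: 1.70593
table(res$strata$risk)
#>  low high
#>  198  167

res$logrank          # high- vs low-risk survival separation
#>    chi2    df           p n_high n_low
#> 1  27.0     1 0.000000206    167   198

res$cox_multivariate # the score is prognostic independent of clinical covariates
#>   term            beta    hr ci_low ci_high            p     n n_events
#> 1 risk_score  0.511    1.67   1.39     2.00 0.0000000352   365      130
#> 2 age        -0.000633 0.999  0.985    1.01 0.932          365      130
#> 3 sex         0.0537   1.06   0.721    1.54 0.782          365      130
#> 4 grade      -0.0726   0.930  0.725    1.19 0.567          365      130
#> 5 stage      -0.0558   0.946  0.784    1.14 0.561          365      130
```

The log-rank test and the multivariate Cox model recover the planted
prognostic structure: the five selected pairs are combinations of the
planted signature lncRNAs, the stratification separates survival at
$p < 10^{-6}$, and the risk score stays significant (HR 1.67, 95% CI
1.39–2.00) with age, sex, grade and stage in the model, while the
(independently simulated) clinical covariates are correctly null.

Scoring a new cohort with the published signature needs no refitting:

```r
sig <- published_signature()
tidy(sig)
#>   pair_id                estimate    hr
#> 1 AC099850.4|MIR4435-2HG    0.378 1.46
#> 2 AC048341.2|LENG8-AS1     -0.318 0.728
#> 3 AC048341.2|GIHCG         -0.340 0.712
#> 4 AC048341.2|LINC01436     -0.357 0.700
#> 5 MIR4435-2HG|AC110285.2    0.455 1.58

pm     <- build_pair_matrix(expr_lnc)          # expression of the 7 lncRNAs
scores <- compute_risk_score(pm, sig)
strata <- stratify(scores, cutoff = 1.395)     # published reference cutoff
```

Each result object has `tidy()` / `glance()` methods, and `autoplot()`
(ROC), `plot_km()` and `plot_risk_scores()` produce the standard figures.

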