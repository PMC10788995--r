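---
title: "Rank-based lncRNA-pair signatures: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based lncRNA-pair signatures: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncpairsig)
library(dplyr)
```

## The model

`lncpairsig` builds prognostic signatures for survival outcomes (the
motivating application is overall survival in hepatocellular carcinoma) from
*within-sample rank comparisons* of long noncoding RNA expression. For an
ordered pair of lncRNAs $(a, b)$ and sample $s$, the feature is the binary
indicator

$$x_{ab}(s) = \mathbf{1}\{\,e_a(s) > e_b(s)\,\},$$

where $e_g(s)$ is any monotone-consistent abundance measure (FPKM, TPM,
counts-per-million after the same pipeline, ...). Because only the ordering
of the two genes *within* each sample enters, the indicator — and everything
downstream of it — is invariant to per-sample strictly increasing
transforms. This is the method's central selling point: signatures transfer
across platforms and normalisation pipelines without recalibration, since no
absolute expression level is ever used.

The fitted object is a sparse linear model on indicators with Cox partial
likelihood behind it, summarised as the exponentiated risk score

$$\mathrm{score}(s) = \exp\!\Big(\sum_i \beta_i \, x_i(s)\Big),$$

so a sample in which no signature pair "fires" scores exactly 1, and each
active pair multiplies the score by $e^{\beta_i}$.

The full pipeline is:

1. **Co-expression screen** (`coexpression_screen()`): lncRNAs correlated
   with a phenotype gene set (here, a curated vascular-invasion set) at
   $r > 0.4$ and $p < 0.001$. Correlations are computed on $\log_2(x+1)$:
   the log is monotone (so Spearman is untouched) and makes Pearson a
   sensible linear measure for right-skewed abundance data. Pearson is the
   default; Spearman is available.
2. **Moderated differential expression** (`moderated_de()`): tumour versus
   normal on $\log_2(x+1)$, with empirical-Bayes variance shrinkage (see
   below), gated at FDR $< 0.05$ and $|\log_2 \mathrm{FC}| > 2$.
3. **Pair construction and validity filtering** (`build_pair_matrix()`,
   `filter_valid_pairs()`): all $K(K-1)/2$ ordered pairs of the
   differentially expressed lncRNAs, keeping only pairs whose indicator
   classes each exceed 20% of samples — a pair that is (nearly) always 0 or
   always 1 ranks no one and cannot carry prognostic signal.
4. **Signature selection** (`univariate_cox_screen()`, `fit_lasso_cox()`):
   single-covariate Cox screening at Wald $p < 0.05$, then L1-penalised Cox
   over the survivors with the penalty chosen at the minimum of the 10-fold
   cross-validated partial-likelihood deviance.
5. **Evaluation** (`survival_roc()`, `optimal_cutoff()`, `stratify()`,
   `kaplan_meier()`, `logrank_test()`, `multivariate_cox()`,
   `compare_roc_features()`): time-dependent ROC with
   inverse-probability-of-censoring weights, Youden-optimal cutoff, high/low
   stratification, Kaplan–Meier and log-rank comparison, and joint Cox
   models against clinical covariates.
6. **Association analyses** (`risk_group_expression()`,
   `subtype_comparison()`, `chi_square_proportions()`,
   `drug_sensitivity_compare()`): rank-based comparisons of gene expression,
   immune subtypes, clinical proportions and drug IC50 between risk groups.

The published five-pair hepatocellular-carcinoma signature ships as
`published_signature()` (coefficients 0.3776, −0.3176, −0.3402, −0.3572,
0.4547; reference cutoff 1.395) so that cohorts carrying those lncRNAs can
be scored without refitting.

## Moderated t-statistics

`moderated_de()` implements the standard two-group empirical-Bayes moderated
t. Per gene, the pooled residual variance $s^2$ has $d = n_t + n_n - 2$
degrees of freedom; across genes, $\log s^2$ is moment-matched against a
scaled-F model (digamma/trigamma method) to estimate a prior
$(d_0, s_0^2)$; the posterior variance
$\tilde{s}^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ replaces $s^2$ in the t
statistic, which then has $d_0 + d$ degrees of freedom (capped at the summed
residual df across genes — the prior cannot contribute more information than
the data it was estimated from). Two edge cases are handled the way the
established estimator behaves, and a unit test cross-checks the whole fit
against `limma` on a shared fixture:

* when the observed dispersion of $\log s^2$ does not exceed its chi-square
  sampling noise, the prior is degenerate ($d_0 = \infty$) and every
  variance shrinks fully to the plain average of the per-gene variances;
* `d0 = 0` (offered as an override) reproduces the ordinary equal-variance
  t-test exactly, which the tests verify against `t.test()`.

## Thresholds and their readings

Several published thresholds admit more than one reading; the package
implements a default and exposes the alternative:

* **"Correlation larger than 0.4"** is a *signed* threshold $r > 0.4$ by
  default, with `use_abs = TRUE` for the $|r|$ convention.
* **"log FC > 2"** is $|\log_2 \mathrm{FC}| > 2$ by default
  (`direction = "both"`); one-sided gates are available. (In the motivating
  study all hits were upregulated, so the two readings coincide there.)
* **The 20% pair-validity bound** is strict on both sides:
  $0.2 < \bar{x} < 0.8$. Under this reading a constant indicator is always
  removed, which is the only interpretation under which the filter does its
  job; boundary pairs are reported in a message.
* **Ties** in the pair rule score 0 ("else it is 0"); `ties_high = TRUE`
  flips this. With continuous abundances ties are measure-zero, so the
  choice matters only for heavily rounded input.
* **Pair orientation** follows input row order, making outputs
  deterministic; reversing the input order flips every indicator and leaves
  the filtered pair *set* unchanged (a tested invariance).
* **Pairing cohort**: pairs are built on the samples handed in; the
  pipeline wrapper uses the tumour cohort, since the survival model concerns
  tumours.

## Time-dependent ROC and the cutoff

`survival_roc()` uses the cumulative-case / dynamic-control estimator:
cases are samples with an observed event by the horizon $t$, controls are
samples event-free beyond $t$, and censoring before $t$ is handled by
inverse-probability-of-censoring weights $1/\hat{G}(T_i^-)$ from the
Kaplan–Meier estimate $\hat{G}$ of the censoring distribution. This
estimator was chosen over nearest-neighbour smoothing because it is
deterministic, has no bandwidth, and reduces *exactly* to the empirical
binary ROC when there is no censoring (a tested property, checked against a
pairwise-concordance oracle). The AUC is the trapezoidal area.

The "optimal" cutoff is the Youden maximiser
$\arg\max_c \{\mathrm{sens}(c) + \mathrm{spec}(c) - 1\}$, the standard
operationalisation of the "highest inflection point" of an ROC curve. Ties
are broken toward the *larger* threshold, which calls fewer patients
high-risk — a deterministic and clinically conservative rule.
Stratification is strict (`score > cutoff` is high-risk), so a patient
scoring exactly the cutoff is low-risk.

The evaluation horizon defaults to **365 days** (1-year survival). The
horizon behind the published cutoff 1.395 is not documented anywhere we
could find; it is therefore an explicit argument surfaced in every relevant
function rather than a constant.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates cohorts with the statistical structure the
pipeline assumes, so that every stage can be tested against known ground
truth:

* a latent per-sample phenotype activity $v_s \sim N(0,1)$;
* gene-set members loading on $v_s$ with loadings drawn once from
  $U(0.5, 0.9)$; "linked" lncRNAs sharing a common loading
  (`factor_loading`, default 0.7); all other genes pure noise. Expression is
  generated on the $\log_2$ scale with unit variance around gene-specific
  means and then exponentiated, which guarantees non-negativity, mirrors
  log-normal bulk RNA-seq abundance, and makes the log-scale Pearson
  correlation of a linked lncRNA with the factor equal its loading;
* a tumour-only shift of `de_log2fc` (default 3) for `n_de_lnc` (default
  14) of the linked lncRNAs — the planted differential-expression truth;
* exponential survival with hazard
  $h_0 \exp(\sum_p \beta_p x_p(s))$ driven by the planted pair indicators,
  and independent exponential censoring whose rate is solved
  deterministically (monotone root-finding on the closed-form
  exponential/exponential censoring probability) to hit the target censored
  fraction in expectation;
* categorical clinical covariates with a male-skewed sex ratio, mostly
  G2/G3 grades, mostly stage I/II, and immune subtypes concentrated in
  C1–C4 with C5/C6 nearly absent — so the subtype analysis naturally drops
  sparse levels, as real pan-cancer immune-subtype data does;
* an IC50 matrix in which half the drugs increase monotonically with the
  true log risk (planted sensitivity signal) and half are noise.

Two generator details are deliberate design choices rather than neutral
defaults. First, members of a planted signature pair share a baseline mean:
if the two genes differed by several $\log_2$ units at baseline, the
planted indicator would be nearly constant, carry no signal, and be removed
by the very validity filter it is supposed to exercise. Second, the default
cohort dimensions (365 tumours, 50 normals, ~two-thirds censoring, median
survival near four years at average risk) mirror the scale of a TCGA-style
liver-cancer cohort, so "default" simulations exercise the pipeline at a
realistic size.

What the simulator does **not** model: library-size or batch effects (the
pair indicator is invariant to the per-sample component of these by
construction, so simulating them would test nothing new), read-level noise,
gene–gene correlation beyond the single factor, non-proportional hazards,
and informative censoring. Passing tests therefore demonstrate correctness
and calibration of the machinery under the model's assumptions — not
robustness to violations of them, which on real data should be assessed
with the usual proportional-hazards and sensitivity checks.

Because the co-expression structure is confounded with the tumour-only
differential-expression shift when both groups are pooled, the pipeline
wrapper screens on tumour samples only. The screen itself is agnostic: it
correlates whatever sample columns it is handed.

## Numerical choices and degenerate inputs

* Cox models use the Efron approximation for tied event times throughout
  (the de-facto default of mainstream survival software, more accurate than
  Breslow); confidence intervals and p-values are Wald-type, matching the
  convention of published HR/CI/p triples.
* Pair indicators enter Cox models unstandardised, so coefficients are on
  the 0/1 indicator scale and scores are interpretable multiplicatively
  around 1.
* Cross-validation folds for the LASSO are stratified by event status and
  derived from an explicit integer seed; the penalty is the deviance
  minimiser (`lambda.min`), not the 1-SE rule — with only a dozen candidate
  features, the 1-SE rule routinely empties the model.
* A fully shrunk (all-zero) signature raises an explicit "empty signature"
  error rather than returning a useless model.
* Constant expression vectors are excluded from correlation screening with
  a warning (their correlation is undefined); a rank-sum comparison of two
  identical constant groups reports $p = 1$ and direction `none`.
* Non-convergent univariate Cox fits (e.g. monotone likelihood under
  perfect separation) are flagged, reported, and excluded from the
  significant set rather than silently kept.
* Correlation p-values use the exact t transform for Pearson and the
  large-sample t approximation for Spearman — deterministic, no
  resampling. Rank-sum tests enumerate exactly for combined $n \le 20$
  without ties, and otherwise use the tie-corrected normal approximation
  with continuity correction.
* Expression parsing uses a strtod-exact reader so that
  `write_expression()` / `read_expression()` round-trips are bit-identical
  (values are written with 17 significant digits).

One naming discrepancy is handled explicitly: published methods text
sometimes describes the high- versus low-risk IC50 comparison as a
"Wilcoxon signed-rank" test, but a paired test is impossible for two
independent groups; the rank-sum (Mann–Whitney) test is the only defensible
reading and is what `wilcoxon_rank_sum()` computes. Similarly, figure
labels use protein names (PD1, PD-L1, TIM3) where matrices carry gene
symbols; a small alias table (`resolve_gene_alias()`) bridges the two.

## Problem sizes used in the shipped checks

The package's own validation (unit tests plus `scripts/acceptance.R`) runs
simulations at sizes chosen to make the statistical claims testable while
keeping a full run comfortably interactive: screening recovery at 300
tumours over 20 seeds, selection consistency at 400 tumours over 20 seeds,
log-hazard-ratio recovery over 50 seeds, null ROC calibration at $n =
2000$, and type-I-error calibration over 200 replicates. These sizes are
the package's choices; all of them can be scaled up by editing one
`sim_config()` call.

## Known limitations

* The pair indicator discards within-pair magnitude: two samples where
  $e_a - e_b$ differs a thousand-fold score identically. That is the price
  of normalisation-free transfer.
* With $K$ differentially expressed lncRNAs the candidate matrix grows as
  $K(K-1)/2$; beyond a few hundred input genes the univariate screen
  dominates runtime.
* The LASSO's selection among strongly correlated pairs (pairs sharing a
  member are mechanically correlated) is known to be somewhat arbitrary;
  the package reports the selected set and its cross-validation curve
  inputs but does not attempt stability selection.
* `published_signature()` is only applicable to cohorts whose annotation
  contains the five pairs' lncRNAs under the same symbols.
* No proportional-hazards diagnostics, competing risks, or external-cohort
  validation harness are included.
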