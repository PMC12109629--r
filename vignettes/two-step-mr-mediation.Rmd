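---
title: "Two-step Mendelian randomization mediation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step Mendelian randomization mediation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediation)
```

## The problem and the model

Observational associations between plasma lipid species and skeletal
disease are confounded by diet, adiposity and medication. Mendelian
randomization (MR) sidesteps this by using genetic variants as
instrumental variables: a variant robustly associated with an exposure,
independent of confounders, and affecting the outcome only through the
exposure supports a causal reading of the exposure-outcome association.
`mrmediation` implements the two-sample, two-step flavour of this design
over GWAS summary statistics, asking not only *whether* an exposure (a
lipid species, say) affects a binary outcome (osteoporosis, on the
log-odds scale), but *how much of that effect travels through a
mediator* such as an immune-cell trait.

Per variant $j$, the two-sample setting provides the estimated
exposure association $\hat\beta_{Xj}$ with standard error $s_{Xj}$ and
the outcome association $\hat\beta_{Yj}$ with $s_{Yj}$, from
non-overlapping cohorts. The per-variant (Wald) causal estimate is
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order standard
error $s_{Yj}/|\hat\beta_{Xj}|$. The five estimators combine these in
different ways:

* **IVW** — weighted regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$
  through the origin with weights $1/s_{Yj}^2$; equivalently the
  inverse-variance weighted mean of Wald ratios. Unbiased when all
  instruments are valid. The default multiplicative random-effects
  variant inflates the standard error by $\sqrt{Q/(n-1)}$ when Cochran's
  $Q$ exceeds its expectation, and never deflates it.
* **MR-Egger** — the same regression with a free intercept, after
  orienting every instrument to $\hat\beta_{Xj} \ge 0$. The slope is a
  pleiotropy-robust estimate under the InSIDE assumption; a non-zero
  intercept indicates directional pleiotropy. Inference uses the $t$
  distribution with $n-2$ degrees of freedom, with the residual scale
  floored at 1.
* **Weighted median** — the 0.5 point of the weight-ordered ratio
  distribution; consistent while valid instruments carry more than half
  the weight.
* **Simple and weighted mode** — the mode of the kernel-smoothed ratio
  distribution; consistent while the largest group of instruments
  sharing an effect is valid.

Mediation follows the product-of-coefficients rule. With
$\beta_X$ the exposure-to-mediator IVW estimate, $\beta_Y$ the
mediator-to-outcome IVW estimate, and $\beta_T$ the total
exposure-to-outcome effect:

$$\beta_{XY} = \beta_X \,\beta_Y, \qquad
  \text{direct} = \beta_T - \beta_{XY}, \qquad
  \text{proportion mediated} = \beta_{XY}/\beta_T .$$

The decomposition closes by construction. A mediated effect sharing the
sign of a negative (protective) total effect is *partial mediation in
the negative direction*; an opposing sign is *attenuation* with a
negative proportion.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `p_threshold` | 5e-8 | genome-wide significance; instruments need `p < threshold` (strict) |
| `clump_r2` | 0.001 | maximum squared LD correlation between retained instruments |
| `clump_window_kb` | 10,000 | window within which the r² ceiling applies (ignored without positions) |
| `f_min` | 10 | minimum instrument F-statistic $\beta^2/\mathrm{SE}^2$; `F >= 10` is kept |
| `effects_model` | multiplicative random | IVW standard-error model |
| `n_boot` | 1000 | parametric bootstrap replicates for median/mode standard errors |
| `bandwidth_factor` | 1 | multiplier on the modified Silverman bandwidth $0.9\min(\mathrm{sd},\mathrm{mad})n^{-1/5}$ |
| `n_sim` | 1000 | MR-PRESSO simulations; note the outlier test's p-value resolution is $n_{\mathrm{snp}}/(n_{\mathrm{sim}}+1)$, so `n_sim` must exceed $n_{\mathrm{snp}}/\alpha$ for the Bonferroni-adjusted test to be able to reject |
| `seed` | 42 | every resampling routine is deterministic given its seed |

Screening a pair requires all three of: IVW $p$ below the stage
threshold (0.05 for exposure screens, 0.01 for the mediator-to-outcome
screen), concordant signs across all available estimators, and an
MR-Egger intercept $p$ *strictly* greater than 0.05. Pairs passing all
three are *significant* below the Bonferroni-corrected level
$0.05/n_{\mathrm{tests}}$ and *suggestive* otherwise. Both thresholds
and the family size are configurable per stage
(`screen_criteria()`), since different stages of a cascade legitimately
use different stringency.

## Harmonization choices

Outcome effects are re-expressed for the exposure's effect allele;
swapped allele labels flip the beta sign and complement the frequency,
and strand-complemented codes are recognized for non-palindromic
variants. Palindromic variants (A/T, C/G) default to
frequency-based inference, dropped when either study's frequency lies
in [0.42, 0.58] or is missing; a `drop` policy removes them outright.
Duplicate variant IDs within a study keep the smallest p-value. These
conventions match common two-sample MR practice; they are explicit
choices where the field tolerates several.

## Numerical conventions

* 95% intervals use the conventional multiplier 1.96 throughout, and
  standard errors recovered from printed intervals use width/3.92.
* The weighted median interpolates the centred cumulative weight
  $S_j = (\sum_{k\le j} w_k - w_j/2)/\sum_k w_k$ crossing 0.5; an
  instrument carrying a strict majority of weight short-circuits to the
  exact 0.5 quantile (that ratio).
* An exactly-consensus ratio set short-circuits the mode estimator to
  that value with zero bootstrap standard error (degenerate ratio
  distribution).
* The delta-method variance for the product omits the second-order
  $s_X^2 s_Y^2$ term, and the proportion interval divides the product
  interval by the *point* total effect, preserving division order;
  uncertainty in the total effect is ignored. These are the conventions
  that reproduce published second-pathway interval arithmetic exactly.
* Clumping ties on p-value break lexicographically by variant ID, for
  determinism across platforms.
* Greedy clumping treats variants missing from the LD matrix as
  independent (with a message); without positions the kb window is
  waived and r² alone governs.
* Single-instrument IVW falls back to the Wald ratio with a message;
  estimators requiring three instruments refuse loudly rather than
  degrade silently.

## What the synthetic generator emulates — and what it does not

`simulate_tripartite()` draws a tripartite scenario: exposure
instruments with per-allele effects $\gamma_j \sim N(0.15, 0.03^2)$,
mediator instruments likewise, MAF uniform on [0.1, 0.4], and the
structural model $M = \alpha X$, $Y = \tau' X + b_M M$ (+ optional
per-instrument pleiotropy, independent of instrument strength — the
InSIDE condition). Estimated betas add noise with
$\mathrm{SE} = 1/\sqrt{2f(1-f)n}$; the binary outcome is simulated
directly on the log-odds summary-statistic scale, since two-sample MR
consumes only summary statistics. Defaults: $\alpha = 0.4$,
$b_M = 0.25$, $\tau' = 0.1$ (so the true mediated proportion is
exactly 0.5), $n = 10^5 / 8\times10^3 / 2\times10^5$ for
exposure/mediator/outcome. The mediator sample size is deliberately
immunophenotype-scale: it keeps exposure-transmitted effects
($\alpha\gamma_j$) safely below genome-wide significance in the
mediator study, so the two instrument sets stay essentially disjoint,
as in real two-step designs. A quarter of variants receive palindromic
allele pairs and a random 30% of downstream-study rows are reported
with swapped allele labels, so harmonization is exercised on every run.

Significance-threshold selection leaves small, well-understood
finite-sample effects that the generator reproduces rather than hides:
marginal mediator instruments suffer winner's curse (estimates slightly
inflated, ratios slightly deflated), and occasionally an
exposure-transmitted effect sneaks over the threshold in the mediator
study. At the default scales each distortion is below about 2% of the
step-2 estimate, so the package states its recovery precision for the
mediated proportion as ±1.5 percentage points around the true 50%
(measured over 200 replicates), rather than claiming exact
unbiasedness. The exposure-side instruments are far from the threshold,
so IVW recovery of the total effect is tested at the strict
3-Monte-Carlo-SE level and interval coverage sits in the nominal
93–97% band.

What the generator does **not** emulate: individual-level genotypes,
realistic LD panels (LD is block-constant and supplied explicitly),
allele-frequency differences between cohorts, sample overlap, and
case-control ascertainment effects on the log-odds scale. Passing
tests therefore validate the estimators and the pipeline plumbing
under the stated statistical shape, not robustness to those
real-data complications.

## Problem sizes used in the shipped checks

Test and script problem sizes are the package's own choices: 30
instruments per trait; 500 replicates for IVW recovery; 2000 for Egger
intercept calibration (rejection rate in [0.03, 0.07] at the default
pleiotropy scale 0.01); 100 planted-outlier seeds for MR-PRESSO
detection (`n_sim` 1000); 1000 replicates for interval coverage; 200
for mediated-proportion recovery; exhaustive clumping-oracle comparison
on all instances up to 8 variants. The acceptance script uses slightly
smaller replicate counts (reported in its output as `n`) to stay
desk-fast while keeping Monte-Carlo error well inside the margins
above.

## Known limitations

* The per-SNP outlier test in MR-PRESSO performs one removal round (no
  recursion), and its distortion test resamples non-outlier subsets of
  the same size; very high outlier fractions (more than half the
  instruments) are reported but not corrected.
* The published first-pathway product interval could not be reproduced
  by the delta method from the published stage estimates; the package
  reports the delta-method interval it computes and makes no attempt to
  guess an alternative convention.
* Mediators are treated one at a time; there is no multivariable-MR
  joint decomposition, no Steiger directionality filtering, and no
  liftover/VCF handling.

## A worked synthetic run

```{r example, eval = FALSE}
sim <- simulate_tripartite(synthetic_config(seed = 7))
med <- two_step_mediation(sim$exposure, sim$mediator, sim$outcome)
med
sim$truth$mediated_proportion_true  # exactly 0.5 by construction
```
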