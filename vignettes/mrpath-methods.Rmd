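---
title: "Two-sample Mendelian randomization with mrpath: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpath)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure on an outcome from
GWAS summary statistics alone. Each instrument j contributes a pair
(&gamma;~j~, &Gamma;~j~): its association with the exposure and with the
outcome, measured in two non-overlapping samples. Under the three
instrumental-variable assumptions — relevance (the variant is associated
with the exposure), exchangeability (no association with confounders) and
exclusion restriction (no effect on the outcome except through the
exposure) — the per-variant Wald ratio &Gamma;~j~/&gamma;~j~ is a
consistent estimate of the causal effect &theta;, and combining many
instruments buys power and robustness diagnostics.

`mrpath` implements the full workflow a two-sample MR study of a
microbiome-style exposure, a lipid-style mediator panel and a binary
disease outcome needs: instrument selection and harmonization,
a five-estimator univariable suite, heterogeneity/pleiotropy/outlier
diagnostics, multivariable MR, Bayesian model averaging over candidate
risk factors (MR-BMA), and two-step mediation with delta-method
intervals. A synthetic summary-statistics generator with known causal
structure makes every stage testable end to end.

## Instrument selection and harmonization

Instruments are selected by a strict p-value filter (default
p&nbsp;&lt;&nbsp;1&times;10^-5^ for under-powered exposures such as
microbial genera; 5&times;10^-8^ for well-powered traits and for the
reverse direction), then pruned by greedy LD clumping: variants are
ranked by p-value (ties broken lexicographically by variant ID for
determinism) and any variant with r&sup2; &ge; 0.001 with a better-ranked
variant inside the window is discarded — the boundary value is excluded,
exactly as the "r&sup2; &ge; 0.001" rule reads. The clumping window is
not universally standardized; we default to 10,000 kb, the common choice
for sparse-signal exposures, and apply LD pruning genome-wide when
positions are unavailable. Missing LD pairs are treated as independent
(r&sup2; = 0), so supplying no LD table reduces clumping to a p-value
sort.

Instrument strength is screened with
F = R&sup2;(n − k − 1)/(k(1 − R&sup2;)), where R&sup2; is the exposure
variance explained by the k instruments in a sample of size n; sets with
F &lt; 10 are flagged weak (F = 10 exactly is retained). The package
offers two standard R&sup2; approximations — the allele-frequency form
&Sigma; 2 maf(1 − maf)&beta;&sup2; and the t-statistic form
&Sigma; t&sup2;/(t&sup2; + n − 2) — choosing the frequency form when
frequencies are complete and the t-statistic form otherwise, since
source GWAS rarely document their R&sup2; convention. Per-SNP
F = (&beta;/se)&sup2; is reported for diagnostics.

Harmonization aligns every outcome record to the exposure's effect
allele, covering identical, swapped, strand-complement and
complement-swap orientations (a swap negates the outcome effect and
reflects its allele frequency). Palindromic variants (A/T, C/G) cannot be
strand-resolved from alleles; they are aligned by allele-frequency
concordance when both frequencies are informative, and dropped when the
minor-allele frequency exceeds 0.42 on either side — we apply the
intermediate-frequency rule to both studies because a frequency near 0.5
in either one makes the orientation call unreliable — or when a frequency
is missing. Every exclusion is logged with a reason
(`not_in_outcome`, `palindromic_high_maf`, `allele_mismatch`,
`duplicate`); nothing is dropped silently.

## The estimator suite

* **IVW** — inverse-variance-weighted meta-analysis of Wald ratios,
  equivalently zero-intercept weighted regression of &Gamma; on &gamma;
  with weights 1/se&sup2;~&Gamma;~. The random-effects version (the
  primary model) inflates the fixed-effects standard error by
  max(1, &radic;(Q/(J−1))): multiplicative over-dispersion, floored so it
  can never be anti-conservative when instruments are homogeneous.
* **MR-Egger** — the same regression with a free intercept, fitted after
  orienting all exposure effects non-negative. The slope is robust to
  directional pleiotropy under the InSIDE assumption; the intercept
  estimates the average pleiotropic effect, and its two-sided test is the
  Egger intercept test. Standard errors use the same floored
  multiplicative scaling; p-values are normal-approximation throughout
  the package for cross-method consistency (Egger t-based p-values
  differ noticeably only at very small J).
* **Weighted median** — the inverse-variance-weighted median of the
  Wald ratios via cumulative-rank interpolation
  p~j~ = (S~j~ − w~j~/2)/S~J~; consistent when valid instruments carry
  at least half the weight. Standard error by seeded parametric
  bootstrap.
* **Simple and weighted mode** — the argmax of a normal-kernel density
  over the Wald ratios with Silverman-type bandwidth
  h = &phi;·0.9·min(sd, IQR/1.349)·J^−1/5^ (the MAD-style IQR guard
  protects against heavy-tailed ratios); &phi; = 1 by default since the
  source method names the estimators without parameters. The argmax is
  located on the ratio values and refined by golden-section search
  within the best bracket; identical ratios (zero bandwidth) return the
  common ratio. Bootstrap standard errors use the MAD of resampled
  modes, which is stable when the mode jumps between clusters.

Ratio weights are first-order (se~&Gamma;~/|&gamma;|) by default — the
convention of the reference implementations — with second-order
propagation available by flag. A single instrument degenerates to the
Wald ratio; this dispatch lives in `mr_all_methods()` /
`mr_univariable()`, while `ivw()` itself insists on two or more
instruments. For binary outcomes all estimation is on the log-odds
scale; `to_odds_ratio()` exponentiates only for reporting.

## Sensitivity analysis

Cochran's Q (at the fixed-effects IVW estimate, where it is minimal)
tests instrument homogeneity against &chi;&sup2;~J−1~; p &lt; 0.05 is
the conventional heterogeneity trigger. Leave-one-out analysis
re-estimates the effect omitting each variant in turn.

MR-PRESSO detects pleiotropic outliers by simulation: the observed
residual sum of squares around leave-one-out IVW predictions is compared
with a parametric null in which each &Gamma;&ast;~j~ and
&gamma;&ast;~j~ are redrawn at their nominal standard errors (global
test); per-variant residuals give Bonferroni-adjusted outlier p-values;
and a distortion test compares the raw-vs-corrected shift with the
shifts from removing random variant subsets of the same size. Empirical
p-values use the (1 + x)/(n~sim~ + 1) convention so they are never
exactly zero; the default 1000 simulations resolves p down to ~0.001.
At least 4 instruments are required so that each leave-one-out fit keeps
3. The distortion test is computed but optional in reports, since many
applied analyses (including the motivating one) report only the global
and outlier components.

## Multivariable MR and MR-BMA

`mvmr_ivw()` regresses outcome effects on the J&times;K matrix of
exposure effects without intercept (weights 1/se&sup2;~&Gamma;~),
giving each exposure's direct effect conditional on the others; standard
errors again use floored multiplicative scaling, and rank-deficient
designs raise a collinearity error naming the offending exposures. The
joint instrument set is the union of the exposures' clumped instruments
with every effect re-expressed on the outcome's reported effect allele;
variants missing an effect for any exposure are excluded by default
(strict mode), with zero-imputation behind an explicit flag — silent
zero-imputation can masquerade as evidence of no direct effect.

MR-BMA scores every non-empty subset S of the K candidate risk factors
(the empty model is included in the normalization so inclusion
probabilities are calibrated under the null). After inverse-se
standardization (dividing &Gamma;~j~ and each row of the effect matrix
by se~&Gamma;j~, which makes the residual variance unity and leaves
causal effects on their original scale), the marginal likelihood of the
conjugate model with independent N(0, &sigma;&sup2;) priors is closed
form:

log ml(S) = −&frac12; log det(I + &sigma;&sup2;X~S~X~S~&prime;)
− &frac12; y&prime;(I + &sigma;&sup2;X~S~X~S~&prime;)^−1^y + const,

evaluated through the K&times;K Woodbury form for speed. Subset priors
are &pi;^|S|^(1−&pi;)^K−|S|^ with defaults &pi; = 0.1,
&sigma;&sup2; = 0.25 following the original MR-BMA release. Reported per
factor: MIP (summed posterior over models containing it) and MACE (the
posterior-weighted model-specific posterior-mean effect, zero when
absent). Exhaustive enumeration is guarded at K = 25; `max_model_size`
truncates the model space for larger panels.

Permutation p-values permute the outcome vector (with its standard
errors) across variants and recompute each factor's MIP; MIP is the
permuted statistic because it is the ranking statistic. The empirical
p-value (1 + #{MIP&ast; &ge; MIP})/(B + 1) with B = 1000 by default is
then BH-FDR adjusted (`bh_fdr()` wraps `stats::p.adjust`).

Before the final fit, one influence-filtering pass removes variants that
dominate the best preliminary model: heterogeneity outliers with squared
standardized residual above the upper 0.05/J &chi;&sup2;~1~ quantile,
and influential points with Cook's distance above the median of its
F(m, J−m) reference distribution. We use the F-median calibration — the
classical Cook's-distance cutoff and the one the original MR-BMA
workflow adopts — rather than the popular 4/J rule of thumb, because
4/J flags several percent of perfectly clean points and an automatic
filter should be quiet on clean data. The pass runs once
(fit &rarr; exclude &rarr; refit), not iteratively, mirroring the
single-exclusion reporting of applied analyses; both thresholds are
configurable.

## Two-step mediation

With &beta;~1~ (exposure &rarr; mediator), &beta;~2~
(mediator &rarr; outcome) and &beta;~3~ (total exposure &rarr; outcome),
the indirect effect is &beta;~1~&beta;~2~ with Sobel variance
&beta;~2~&sup2;se~1~&sup2; + &beta;~1~&sup2;se~2~&sup2; (the legs come
from non-overlapping samples, so no covariance term), and the proportion
mediated is &beta;~1~&beta;~2~/&beta;~3~. The default delta-method
variance of the proportion also propagates se~3~
(Var = Var(ind)/&beta;~3~&sup2; + ind&sup2;se~3~&sup2;/&beta;~3~&sup4;);
a `fixed_total` mode treats &beta;~3~ as fixed. Both are reported
because the interval convention behind published mediation CIs is often
unstated and the two modes can differ materially when the total effect
is imprecise; no claim is made that either reproduces any particular
published interval. Binary-outcome coefficients enter on the log-odds
scale, never as odds ratios. An indirect effect of opposite sign to the
total effect is flagged as inconsistent mediation rather than silently
folded into a negative proportion.

Estimator choice per leg follows the heterogeneity rule: the MR-PRESSO
outlier-corrected estimate when Cochran's Q has p &lt; 0.05 (strictly),
otherwise random-effects IVW; the selection is recorded with the result.

```{r mediation-example}
two_step_mediation(0.023, 0.009, log(1.159), 0.0486, log(1.110), 0.0497)
```

## The synthetic-data generator

`simulate_two_sample()` generates summary statistics directly on the
summary-statistic scale — no individual-level genotypes — which is
sufficient for every estimator in scope and orders of magnitude faster.
Its defaults emulate the motivating study design: an exposure GWAS of
n = 18,473, a case-control outcome of 8,288 cases / 68,969 controls
(log-odds standard errors use the standard
1/&radic;(2 maf(1−maf) n &phi;(1−&phi;)) approximation with case
fraction &phi;), minor-allele frequencies uniform on (0.05, 0.5), and
true instrument effects |N(0, 0.05&sup2;)| — oriented positive, i.e.
reported for the trait-increasing allele, so that directional
pleiotropy keeps a well-defined sign under Egger's orientation
convention. Effects are redrawn until both the implied and the observed
exposure p-values pass the instrument threshold, so generated sets
always survive significance filtering and the F screen; under a null
causal effect the outcome noise is independent of this selection, so
type-I-error calibration is untouched, while recovery studies should
use larger exposure samples (we use n = 5&times;10^5^ in the
calibration runs) where the residual winner's-curse selection is
negligible. Pleiotropy is N(&mu;~&alpha;~, &tau;~&alpha;~&sup2;) per
variant (balanced when &mu;~&alpha;~ = 0); outliers shift observed
outcome effects by a stated number of standard errors. Instruments are
independent by construction — LD, and therefore clumping behaviour on
real correlated panels, is not emulated — and allele dosages,
sample overlap and population stratification are likewise out of the
generator's scope, so passing tests validate the estimators'
statistical behaviour, not robustness to those data pathologies.

`simulate_mediation_triplet()` adds a mediator: over the exposure's
instruments the mediator effect is &beta;~1~&gamma;~j~ and the outcome
effect (direct + &beta;~1~&beta;~2~)&gamma;~j~, with three independent
noise draws (three non-overlapping samples); a separate set of
genome-wide-significant instruments for the mediator itself supports the
&beta;~2~ leg. `simulate_multivariable()` draws per-variant effects on K
factors from a K-variate normal with common correlation &rho;
(defaults K = 3, &rho; = 0.7, emulating a strongly correlated lipid
panel), with the outcome built from a designated causal subset.

One caveat the calibration studies make explicit: the plug-in proportion
&beta;&#770;~1~&beta;&#770;~2~/&beta;&#770;~3~ is a ratio with a noisy
denominator. At the motivating study's precision (the real total effect
had p = 0.036), its unconditional replicate mean is inflated by
E[1/&beta;&#770;~3~] &gt; 1/&beta;~3~ and by occasional near-zero
denominators. The pipeline — like the applied workflow it mirrors — only
computes a proportion for exposures whose total effect is detected
(IVW p &lt; 0.05), and all recovery summaries condition on that gate;
with it, the mean recovered proportion sits within a few percent of the
simulated truth (0.375) at the default conditions (J = 20,
study-scale sample sizes).

## The two-stage pipeline

`run_stage1()` runs, per exposure: selection &rarr; harmonization &rarr;
the estimator suite &rarr; Q, Egger intercept and leave-one-out
(&ge; 3 instruments) &rarr; MR-PRESSO when heterogeneity is detected
(&ge; 4 instruments). "Detected" means random-effects IVW p &lt; 0.05
with no multiple-testing correction — deliberately mirroring the
hypothesis-generating convention of the applied setting — with optional
BH-FDR across exposures behind a flag. Detected exposures get a
reverse-direction MR (outcome instruments at 5&times;10^-8^) and enter a
joint multivariable IVW. Exposures with fewer than two surviving
instruments are reported as `insufficient_instruments`, never fatal.
`run_stage2()` estimates each mediator's effect on the outcome,
prioritizes detected mediators with MR-BMA (influence filter,
permutation p, FDR) when two or more are detected, estimates each
detected exposure's effect on each prioritized mediator, and combines
the legs via the heterogeneity rule into mediation reports.
`render_reports()` writes plot-ready TSVs (forest, scatter with fitted
lines, leave-one-out, diagnostics, MVMR, BMA, mediation); re-rendering
the same bundle is byte-identical.

The package is function-first: an analysis is an R script calling
`run_config()`, `run_stage1()`, `run_stage2()` and `render_reports()`,
which keeps every threshold and intermediate object inspectable; there
is no shell entry point.

## Numerical and reproducibility choices

* Wald 95% intervals use the conventional 1.96 multiplier exactly.
* Weighted regressions solve the normal equations directly (Cholesky),
  so exact-fit fixtures (zero residual) are handled without 0/0.
* All log-marginal arithmetic in MR-BMA is done in log space with a
  log-sum-exp normalization; posterior probabilities sum to 1 at machine
  precision on every run.
* Every stochastic routine (bootstrap, MR-PRESSO, permutations,
  simulators) takes an explicit seed; there is no hidden global RNG
  state contract, and same-seed runs are bit-reproducible.
* Empirical p-values always use (1 + x)/(n + 1).
* Test and calibration problem sizes (500 replicates for calibration
  and recovery, 200 for outlier detection at 500 simulations, 100 for
  BMA prioritization) were chosen to keep Monte-Carlo error a small
  fraction of the acceptance bands while the whole suite runs in about
  a minute of compute.

## Known limitations

* No LD computation from genotypes: LD is supplied or assumed absent;
  no liftover, rsID resolution or multi-allelic handling.
* No MR-RAPS, debiased IVW, Steiger filtering, Rucker model selection,
  radial MR, conditional F-statistics or stochastic-search BMA.
* Genetic-correlation (LD-score regression) analysis is out of scope:
  it requires external LD-score reference panels.
* The mediation module implements the product-of-coefficients method
  only, not the multivariable-MR difference method.
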