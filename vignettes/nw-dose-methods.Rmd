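---
title: "Modelling nitrogen-by-water dose responses: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nitrogen-by-water dose responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nwdose)
```

This vignette records the statistical model behind `nwdose`, the choices
that were genuinely open during its design, and what validation on
synthetic data does and does not establish about real data.

## The dose model

Each gene's counts are modelled with a negative-binomial log-link GLM on
four predictors derived from the treatment design: nitrogen amount (N),
water volume (W), nitrogen concentration (N/W) and their product (N×W),
plus a log size-factor offset (median-of-ratios normalization). Key
conventions:

* **Units and encoding.** Lab nitrogen is recorded as an absolute amount
  in mmol (supplied concentration × the 130 mL saturating feed volume);
  water as a volume in mL; their ratio is a concentration. Since all
  predictors are standardized to mean 0 / unit variance before fitting,
  any affinely equivalent encoding yields identical inference — the mmol
  convention is kept for dimensional honesty.
* **The interaction column** is the product of the *standardized* main
  effects, itself re-standardized. Products of raw dose columns are
  nearly collinear with the main effects on these geometric dose grids;
  centering first removes that.
* **Standardization and the weight statistic.** The N-weight
  `100·|β_N|/(|β_N|+|β_N/W|)` presupposes that the two coefficients are
  comparable; standardized predictors supply exactly that. Absolute
  values keep the weight well defined for repressed genes.
* **Dispersion** is estimated per gene by maximum likelihood
  (method-of-moments fallback when the likelihood fit fails, floored at
  1e-8). No empirical-Bayes shrinkage across genes is applied; this
  costs a little power at 48 samples but keeps the per-gene model
  self-contained.
* **Wald tests with a t reference.** Per-term significance uses the Wald
  statistic referenced against t(n − p) rather than the normal. With the
  dispersion estimated from the same few dozen samples the normal
  reference is anti-conservative; with the t reference the fraction of
  null genes with raw p < 0.05 is ≈ 0.064 at the 48-sample design —
  close to nominal, with the residual excess attributable to maximum
  likelihood's downward dispersion bias.

## Backward model simplification

Every gene starts at the full four-term model. At each stage, raw
per-term p-values are adjusted by Benjamini–Hochberg *per term across all
genes whose current model contains that term*; a gene whose every current
term passes adjusted p < 0.005 is accepted at its current form; otherwise
its worst term is dropped and the gene refit, down to one-term models.
Genes accepted by no form are `unclassified` and excluded downstream.
Notes:

* The elimination is greedy and single-path, not an exhaustive search
  over the 14 reduced forms — the procedure, not an optimality claim.
* Ties on the worst adjusted p are broken by dropping the later term in
  the fixed order N, W, N/W, N×W; arbitrary but deterministic.
* The adjustment family could equally be per-term across genes or pooled
  over all term×gene tests; per-term was chosen as the standard workflow
  convention for this kind of screen.
* Because BH is adaptive, the effective raw-p threshold loosens as the
  proportion of truly responsive genes in the dataset rises. On
  realistic, mostly-null transcriptomes the null leakage stays near the
  nominal level (≈1% of null genes at the study's design size).

## Time-course differential expression

The time-course model is specified as a cubic spline with 5 df and 3
knots. A natural cubic spline with 3 interior knots spans 4 basis
columns; adding the arm intercept shift gives a 5-df treatment
difference — the reading adopted here. `nwdose` fits, per gene,
log2(normalized count + 1) on

```
y ~ arm + spline(time) + arm:spline(time)
```

with interior knots at the 25/50/75% quantiles of the time grid
(boundary knots at its range), and tests the arm difference (arm shift +
interactions, 5 numerator df) by an F-test. Choices worth recording:

* A Gaussian working model on the log2-normalized scale is used, pooling
  replicates rather than averaging them — using all data, at the cost of
  treating replicate noise and count noise identically.
* Size factors are computed jointly across both arms; the pseudocount 1
  precedes the log.
* Fold changes for binning are ratios of treated-arm mean normalized
  counts at t versus the same arm's t = 0 mean (pseudocount 1 on both
  means); binning thresholds are strict (a ratio of exactly 1.25 is not
  binned), and a gene may occupy several timepoints.
* Eligibility requires combined counts across both arms and all
  timepoints strictly above 100.

## Field analysis

Field data carry categorical N (fertilized or not), categorical W
(replete/deplete) and cultivar. The per-gene model is
`~ N + W + N:W + genotype`; term significance is analysis of deviance on
nested fits at the full model's dispersion. The deviance difference is
scaled by the full model's residual deviance per degree of freedom and
referenced against F (the quasi-likelihood convention): with a plain
chi-square reference the null interaction p-values were visibly
anti-conservative (7.5% below 0.05; Kolmogorov–Smirnov distance 0.105
from uniform on 400 null genes), while the F reference gives 3.9% and
KS 0.027 at 1000 null genes. N and W main effects are tested within the
additive model (type-II ordering).

A significant interaction is binned by the sign of its log2 fold change:
positive (expression driven by high-N/high-W or low-N/low-W) is the
synergy class N×W; negative is the molarity class N/W. Genes with a
significant main effect, the other main effect and interaction
non-significant, are N- or W-class. Regulation direction is the sign of
the high-N/high-W vs low-N/low-W contrast of normalized means — a unit-interval heatmap normalization
carries no direction, so this contrast convention is used for field
genes, and the sign of the largest-magnitude accepted coefficient for
lab genes.

## Eigengenes, permutation nulls and overlaps

A gene set's eigengene is the first principal component of its log2
normalized expression across samples (genes centered, SVD). Scores are
defined up to sign; the association statistic is therefore |Pearson r|,
and the reported sign convention (largest-magnitude loading positive)
matters only for reproducibility. The permutation null rebuilds the
eigengene from random same-size gene sets drawn without replacement from
the declared background — genes surviving the count filter — and the
p-value uses the add-one convention `(1 + exceedances)/(1 + n_perm)`, so
it is never exactly zero. Monte-Carlo overlap tests draw |A|-size sets
uniformly from the background and compare the overlap with B; on random
configurations they agree with the hypergeometric tail within Monte-Carlo
error.

## The synthetic-data generator

The generator inverts the fitted model: NB counts
(variance = μ + φμ²) with log-means linear in the standardized
predictors. Defaults mirror the study conditions: the 4×4 factorial in
triplicate (48 samples), 19 cultivars × 2×2 × 3 (228 samples), the
10-point 0–120 min grid in triplicate; dispersion φ = 0.05; log-scale
effect size 1; baselines uniform on log(50)–log(500); 60% null genes.
Field genotype effects are per-gene, per-cultivar Gaussian offsets
(sd 0.3). Responder onsets default to the 5–30 min window. The
¹⁵N-uptake curve is `1 − exp(−t/30 min)` — only monotone saturation is
relied on. Induced and repressed genes are split exactly 50/50 within
each class: on an iid draw a small simulated panel retains a net
per-condition expression shift that median-of-ratios normalization
misreads as depth (real transcriptomes are large enough for an iid draw
to balance; a few-hundred-gene panel is not).

What the generator does **not** emulate: library-size heterogeneity,
gene-gene correlation, outliers, batch effects, or any empirical
effect-size distribution (none is published; the defaults are
calibration conditions, not estimates). Passing the validation suite
therefore shows the procedures are implemented correctly and calibrated
under the generating model — not that real data meet that model.

## Problem sizes and degenerate inputs

The validation suite runs the classifier at 2500 genes (500 per
single-term class + 500 null) on the 48-sample design, the field
sign-rule at 200 genes on the 228-sample design, time-course calibration
at 1000 null genes, and eigengene calibration at 500 repeats of a
200-permutation test — sizes chosen to give stable rates while keeping a
full run in minutes on one core.

Degenerate inputs are handled explicitly rather than by failure:
constant genes and constant phenotypes are flagged with a reason (never
significant); an all-zero sample or an empty post-filter matrix gives a
named error or a warning plus empty result; non-converging GLMs fall
back to a fixed-dispersion fit and, failing that, leave the gene
`unclassified`; a significant interaction with an exactly zero fold
change is flagged `tie`, never silently assigned.

## Known limitations

* No shrinkage of dispersions or fold changes; at 48 samples this mainly
  costs power for weakly expressed genes.
* The greedy elimination path can settle on a proxy model when
  predictors are strongly collinear (on the default grids the N/W column
  correlates 0.63 with N and −0.53 with W); at the validated effect
  sizes this affects ≈1% of single-term genes.
* The Gaussian spline model treats counts on the log scale; very low
  count time courses are better served by the count-filter rule than by
  the model itself.
* Monte-Carlo overlap p-values are bounded below by 1/(n_perm + 1);
  deeply significant overlaps saturate at that floor.
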