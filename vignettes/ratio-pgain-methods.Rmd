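---
title: "Ratio phenotypes, the p-gain statistic, and the ratiogain pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratio phenotypes, the p-gain statistic, and the ratiogain pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratiogain)
```

## The statistical problem

Quantitative metabolomic panels — here the motivating case is an NMR
lipoprotein panel of 168 traits (cholesterol, cholesteryl ester,
triglyceride, phospholipid and particle-number measures across 14
lipoprotein size classes) — are tested for association with genetic
variants one trait at a time.  Testing *ratios* of traits in addition to
the traits themselves can increase power dramatically, because the
log-ratio

$$\log(A/B) = \log A - \log B$$

cancels variance shared by the two traits.  Two distinct mechanisms
produce this gain:

1. **Opposed genetic effects.**  A variant pushes $A$ up and $B$ down
   (substrate–product pairs of an enzymatic reaction are the canonical
   example).  The ratio's effect is the *sum* of the two magnitudes while
   its residual variance is no larger, so the association sharpens.
2. **Shared non-genetic confounder.**  Only $A$ carries the genetic
   effect, but both traits load on a common environmental/physiological
   factor.  Dividing by $B$ strips that factor from $A$, shrinking the
   unexplained variance of the test.  The denominator needs *no* genetic
   effect at all.

The **p-gain** quantifies the improvement:

$$\mathrm{pgain} = \frac{\min(p_A, p_B)}{p_{A/B}},$$

i.e. on the scale the package works on,
$\log_{10}\mathrm{pgain} = (-\log_{10} p_{A/B}) - \max(-\log_{10} p_A, -\log_{10} p_B)$.
A p-gain above 10 is significant at the 0.05 level for a single ratio
test; the Bonferroni-corrected threshold for a hypothesis-free scan is
$10 \times 10^6 \times m(m+1)/2$ for a panel of $m$ traits (the $10^6$
factor is the conventional genome-wide number of independent tests).
`compute_pgain()` performs this as exact arithmetic on negative-log10
p-values and never re-exponentiates, so gains of thousands of orders of
magnitude are exact.

## The association model

Every analysis phenotype — single traits and ratios alike — is built as
`INT(log x)` or `INT(log A − log B)`, where INT is the rank-based
inverse-normal transform; this makes the test family uniform (one
$m(m+1)/2$ multiple-testing burden) and robust to the outliers that
division by small denominators can produce.  `fit_linear_assoc()` then
fits

$$y = \beta_0 + \beta_g\, g + \gamma^\top c + \varepsilon$$

with additive dosage $g$ (fractional imputed dosages used as-is) and
covariates $c$ (age, age², sex, lipid-lowering medication, optional
principal components and conditional-variant dosages), reporting the
dosage term with a two-sided t-test.

**Numerical choices.**

* *Extreme p-values.*  `neglog10_p_from_t()` works entirely in log space.
  Finite df ≤ 1e5 uses the log-scale t survival function (regularized
  incomplete beta).  The normal regime uses the plain survival function
  up to $|z| = 37$ (where $p \approx 5\times10^{-300}$ is still
  representable) and the Mills-ratio asymptotic expansion
  $\ln p = \ln 2 + \ln\varphi(z) - \ln z + \ln(1 - z^{-2} + 3z^{-4} -
  15z^{-6} + 105z^{-8})$ beyond.  The truncation error at the seam is
  $O(z^{-10}) \approx 10^{-13}$ relative, and the test suite pins both
  branches to an arbitrary-precision oracle within $10^{-6}$ relative
  over $|z| \in [1, 300]$, df ∈ {30, 1000, ∞}.
* *Fast scan path.*  For a scan of thousands of tests per variant,
  `scan_variant()` applies Frisch–Waugh–Lovell: phenotypes are grouped by
  missingness pattern, and per group the covariates are projected out of
  the dosage and the whole phenotype block once; each per-test slope is
  then a simple regression of residuals with $df = n - k - 1$ matching
  the full model *exactly* (same complete-case set per group).  A naive
  per-test OLS engine is retained and the suite asserts agreement within
  $10^{-8}$ on $-\log_{10} p$.
* *Missing data.*  Listwise deletion per model over the union of that
  model's variables; the complete-case n is reported per result.
* *Perfect fits.*  Zero-residual fits are flagged and reported at a
  finite cap (9999 on the $-\log_{10} p$ scale) so downstream matrices
  stay finite.
* *Degenerate tests* (constant dosage or phenotype after deletion) are
  returned as flagged rows, never aborting a scan.

## Thresholds and curation

`compute_thresholds()` derives every level from the genome-wide alpha
($5\times10^{-8}$) and the family sizes: dividing by 5 (reference
lipids), by $m$ (the trait panel), by a curated-ratio-subset size, and by
$m(m+1)/2$ (all ratios and traits); the p-gain threshold is
$\log_{10}(10 \cdot 10^6 \cdot m(m+1)/2)$.  Nothing is hand-set; display
rounds to one decimal while files keep full precision.  The genome-wide
$10^6$ multiplier is kept literal (configurable) rather than scaled to
the synthetic variant count — it models the number of independent
variants in a genome, not the size of this scan.

`curate_variants()` applies the lead-variant rules of a targeted design:
MAF strictly above 1%, best association at $-\log_{10} p \geq 8$,
duplicate conditional models collapsed to the strongest, then greedy LD
pruning ($r^2 \geq 0.7$ to a kept variant drops the weaker one) walking
in descending strength with lexicographic tie-break — the pruning
algorithm itself is unspecified upstream, so the deterministic greedy
order is this package's choice.

## The clustering stage

Loci whose lead ratio carries a Bonferroni-significant p-gain form the
columns of a lead-ratio × locus matrix of $\log_{10}$ p-gains
(`build_pgain_matrix()`; absent cells are 0, "no evidence", rather than
missing — normalized p-gain is an evidence score with a natural floor).
Each column is divided by its own maximum (`normalize_per_locus()`) so
loci with very different absolute signal strengths become comparable,
then rows and columns are clustered independently
(`hierarchical_cluster()`).  No distance or linkage is prescribed
upstream; the defaults are Euclidean distance with average linkage — the
most common heatmap defaults — and both are parameters.  Whether to
cluster rows and columns jointly was an open question; independent
clustering is implemented as the standard heatmap practice.  Cluster
*curation* (picking representative ratios) is left manual: the tree cut
height is a user parameter.

## Replication and survival

`replication_test()` uses the strict rule $p < 0.05 / n_\text{discovered}$
(a p-value exactly at the threshold does not replicate).
`replication_power()` draws subsamples of the replication cohort's size
from the discovery cohort *without replacement* — the faithful reading of
"randomly sampling records" — refits the lead association each time, and
reports the fraction reaching the replication level.  Note one statistical
subtlety, documented because it matters for validating the estimator
against the closed form $\Phi(-z_{\alpha/2} + \theta\sqrt{n\,2f(1-f)}/\sigma)$:
the subsamples resample around the *realized* cohort effect, not the
generative one, so the closed form should be evaluated at the realized
effect; without-replacement overlap additionally tightens the subsample
estimates by a finite-population factor $(1 - n_\text{sub}/N)$.

For fixed-horizon risk, events dated strictly after the assessment date
are incident; an event *on* the assessment day counts as prevalent
("later than" read strictly) and is excluded.  The marker median is
computed after that exclusion on the full included set (the ordering
relative to medication-use stratification was ambiguous upstream; this
choice is configurable), ties at the median go to "low", and the four
groups are {high, low} × {medication, none}.  `km_risk()` evaluates the
product-limit survival at the horizon via `survival::survfit`; risk is
$1 - S(h)$ with a symmetric 95% normal CI from the Greenwood variance of
$S$, clipped to $[0,1]$ — the upstream description names no CI method, so
the simplest transparent one is used.

## The synthetic cohort: what it emulates and what it does not

There is no published generative model for this design, so the generator
is the minimal model that provably exhibits both p-gain mechanisms with
closed-form truth:

* genotypes: Hardy–Weinberg, $g \sim \mathrm{Binomial}(2, \mathrm{MAF})$,
  independent across variants (no LD);
* traits: lognormal,
  $\log x_{it} = \mu_t + \lambda_t c_i + \textstyle\sum_v E_{vt} g_{iv} +
  \text{covariate terms} + \varepsilon_{it}$,
  with one shared confounder $c_i \sim N(0, \sigma_c^2)$;
* "opposed" variants write $+\theta_\text{num}$ and $-\theta_\text{den}$
  on their trait pair (ratio-scale effect exactly
  $\theta_\text{num}+\theta_\text{den}$); "confounded" variants write
  $+\theta_\text{num}$ on the numerator only;
* missingness: completely at random, NA and exact-zero cells injected
  disjointly at the platform's aggregate rates
  ($20{,}856/46{,}092{,}312 \approx 0.045\%$ NA and
  $5{,}940/46{,}092{,}312 \approx 0.013\%$ zeros) — only aggregate rates
  are reported upstream, so uniform MCAR is the stated world;
* outcomes: exponential event times with rate
  $r_0 e^{\beta \cdot \text{marker}}$, administratively censored at the
  horizon, plus a prevalent fraction dated before assessment.

Default magnitudes, chosen once: $\theta = 0.05$ per allele on the log
scale (a strong but realistic lipid-locus effect, ~0.1–0.3 SD on the INT
scale depending on trait variance), $\lambda_t = 0.5$ with
$\sigma_c = 1$ and $\sigma_t = 0.2$ (so the shared confounder dominates
trait variance, the regime in which mechanism 2 is interesting), age
uniform on 40–70, medication rate 0.15, covariate effects 0.002/yr, 0.05
(sex), −0.05 (medication) on the log scale.  Effect magnitudes are not
reported upstream at any locus; these are tuning choices and are flagged
as such.

Deliberately **not** emulated: the real platform's trait correlation
structure, LD between loci, and multi-ancestry allele-frequency
differences.  Consequently a green end-to-end test establishes that the
machinery (transforms, scan, p-gain arithmetic, thresholds, clustering,
power estimation) is correct under the stated model — it does not
establish that the biological conclusions of any particular cohort would
reproduce.  Equal confounder loadings across all traits also mean that
*any* ratio containing an affected trait cancels the confounder equally
well, so for "confounded" loci the lead ratio's partner trait is
noise-determined; tests assert membership of the affected trait, not the
exact pair.

## Orchestration and reproducibility

`run_pipeline()` executes simulate → preprocess → assoc → pgain →
cluster → replicate → survive from a single JSON-serializable config with
one master seed; per-stage seeds derive via a fixed affine counter
scheme, so config + seed reproduce every product bit-for-bit.  All
products are TSV with headers (trait matrices carry a JSON stage
sidecar; genotypes are also exported as VCF with a DS dosage field), and
a manifest — config echo, derived seeds, md5 checksums, per-stage wall
time, captured warnings, and the failure point if any — is written even
on partial failure.  The spec'd YAML config/manifest is realized as JSON
(no YAML parser among the pinned dependencies; JSON is a YAML subset).

## Known limitations

* No mixed models or relatedness correction; PCs are accepted as input
  columns only.
* No Cox regression or competing risks — the survival stage is the
  Kaplan–Meier group comparison only.
* The fast scan path falls back to naive fits for missingness-pattern
  groups with fewer than 10 complete cases.
* The null-calibration guarantee is for the marginal distribution of
  p-values; tests sharing a trait are dependent, as in any real scan.
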