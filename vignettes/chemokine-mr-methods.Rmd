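---
title: "Two-sample Mendelian randomization for chemokine panels: models, choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization for chemokine panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemomr)
```

## The question and the design

Circulating chemokines shape the tumour immune microenvironment, but
observational associations between plasma chemokine levels and breast cancer
are confounded by everything that influences both. Two-sample Mendelian
randomization (MR) sidesteps that confounding by using germline variants as
instruments: a pQTL GWAS supplies per-SNP effects on a standardized plasma
chemokine, a large case-control (or survival) GWAS supplies the same SNPs'
effects on the outcome, and under the instrumental-variable assumptions the
ratio of the two identifies the causal effect of the chemokine. `chemomr`
implements this design end to end for a *panel* of exposures against a panel
of outcomes, and ships a synthetic generator with known ground truth so the
entire pipeline is testable without any external download.

The package is organized as an analysis: the numbered drivers under
`analysis/` simulate a chemokine-like panel, run the scan, validate the
estimators, and build polygenic scores, each a thin script over exported
functions.

## Instrument selection and strength

Instruments are SNPs associated with the exposure at genome-wide
significance, `p < 5e-8`, strict inequality. Correlated instruments are
removed by greedy LD pruning: visiting SNPs in ascending p-value order, a
SNP is kept only if its r² with every already-kept SNP is below 0.01. The r²
matrix is an explicit input — the package never consults a reference panel,
so the LD source is always visible in the analysis; the generator emits
block matrices for testing. Greedy-by-p is a declared convention: it
guarantees each LD block is represented by its most significant SNP, and the
suite checks it against an exhaustive enumeration on small block designs.

Instrument strength uses the standard variance-explained decomposition for a
standardized trait,

$$R^2_j = \frac{2\beta_j^2 q_j(1-q_j)}{2\beta_j^2 q_j(1-q_j) + se(\beta_j)^2\, 2N q_j(1-q_j)},$$

with $q_j$ the minor-allele frequency (`min(eaf, 1-eaf)`; the expression is
symmetric in $q$ so the EAF/MAF distinction is immaterial here), summed over
the pruned instruments (independence is a fair assumption after pruning at
r² < 0.01), and

$$F = \frac{R^2 (N - 1 - k)}{(1 - R^2)\,k}.$$

F > 10 is the conventional weak-instrument floor; the synthetic panel's
defaults are chosen so per-exposure F lands in the tens to hundreds,
matching the strong-pQTL regime this design assumes.

## Harmonization

Exposure and outcome effects must refer to the same allele. The rules, in
order:

* exact allele match — keep;
* alleles swapped — flip (negate the outcome beta, complement its EAF);
* non-palindromic mismatch — try the strand complement, then the two rules
  above; otherwise remove as `allele mismatch`;
* palindromic (A/T, C/G) pairs — strand cannot be read from labels. If the
  EAF is *intermediate* (inside the open window 0.42–0.58) in **either**
  study, frequency cannot resolve it and the SNP is removed as
  `palindromic intermediate AF`; otherwise the SNP is aligned by frequency
  agreement (same side of 0.5 means same allele).

The window bounds are configurable (`palindrome_af_low/high`); (0.42, 0.58)
is the conventional two-sample-MR default. Checking both studies' EAF is the
conservative reading; removing rather than proxying missing-in-outcome
instruments reflects that no proxy lookup exists here by design. Every
decision is recorded: the harmonized set carries a per-variant audit row,
and counts always satisfy `n_input = n_final + n_removed`. Re-harmonizing a
harmonized set is the identity, and all downstream estimates are invariant
to relabeling any input's allele coding — both are property-tested.

## The estimator suite

With aligned pairs $(\hat\beta_{X,j}, \hat\beta_{Y,j})$ and outcome SEs
$\sigma_{Y,j}$:

**Wald ratio** (single instrument): $\hat\theta_j = \hat\beta_{Y,j}/\hat\beta_{X,j}$, with
first-order delta-method SE
$\sqrt{\sigma_{Y,j}^2/\hat\beta_{X,j}^2 + \hat\beta_{Y,j}^2\sigma_{X,j}^2/\hat\beta_{X,j}^4}$.
The delta approximation is validated against a $10^6$-draw Monte-Carlo SD of
the ratio (agreement within 2% at realistic instrument strength).

**Fixed-effect IVW** (the primary estimator, used whenever k ≥ 2):

$$\hat\theta_{IVW} = \frac{\sum_j \hat\beta_{X,j}\hat\beta_{Y,j}\sigma_{Y,j}^{-2}}{\sum_j \hat\beta_{X,j}^2\sigma_{Y,j}^{-2}},
\qquad se = \Big(\textstyle\sum_j \hat\beta_{X,j}^2\sigma_{Y,j}^{-2}\Big)^{-1/2}.$$

The weights deliberately carry outcome error only — the classical
fixed-effect form — so the SE is the origin-constrained WLS SE with the
residual dispersion fixed at one. The suite verifies the closed form against
`stats::lm` weighted fits to 1e-10. Because exposure error is ignored, the
estimator inherits two small, well-understood finite-sample effects that the
validation experiments quantify rather than hide: regression dilution
proportional to $\sigma_X^2/E[\beta_X^2]$ (negligible for strong pQTLs), and
type-I error very slightly above nominal (the null-calibration experiment
measures ~0.05 within its tolerance band).

**MR-Egger** adds a free intercept to the same weighted regression after
orienting all exposure effects non-negative (flipping the outcome sign with
them); the intercept estimates directional pleiotropy, the slope the causal
effect. Egger SEs use the weighted residual dispersion (`summary.lm`
convention) so the intercept's uncertainty reflects the pleiotropy scatter
itself. One caveat the robustness experiment makes visible: when the
residual variance is dominated by a homoskedastic pleiotropy term, the
1/σ² weights are misspecified and the naive WLS SE is mildly
anticonservative, so intercept CI coverage sits a few points below the
nominal 95%. That is a property of standard MR-Egger, not of this
implementation; the experiment reports the measured coverage as-is.

**Weighted median**: per-SNP ratios are sorted, weighted by inverse
delta-method variance, and the estimate is the value at normalized
cumulative weight 0.5 using the percentile convention
$p_i = \mathrm{cumsum}(w)_i - w_i/2$ with linear interpolation — a declared
rule, frozen in a test against an independent brute-force evaluation. The SE
comes from a parametric bootstrap (redraw both betas from their Gaussians;
default 1000 replicates, mandatory explicit seed). The estimator is
consistent while valid instruments carry a majority of the weight, which is
exactly what the 40%-invalid robustness experiment exercises.

**Heterogeneity**: Cochran's $Q = \sum_j w_j(\hat\theta_j - \hat\theta_{IVW})^2$
on k−1 df and $I^2 = \max(0, (Q - df)/Q) \times 100$, floored at zero. Q's
χ² p-value is reported, never used as a filter.

P-values are two-sided standard-normal on beta/se for every method,
including Egger, for consistency with the normal-theory CI
(beta ± 1.96·se); with the instrument counts this package targets (k
mostly 4–50) the difference from t-based inference is small and the choice
is uniform.

**Multiple testing**: Bonferroni within each outcome across the exposure
panel — flag at p < 0.05/m strict, adjusted p = min(1, p·m). The default m
is the panel width (30 for a full chemokine panel; 6 in the shipped
synthetic analysis).

## Polygenic risk scores

PRS = $\sum_k \beta_k x_k$ over effect-allele dosages $x_k \in [0,2]$.
Dosage columns counted on a different allele are reconciled (2 − x when the
counted allele is neither the effect allele nor its strand complement).
The weight source is an explicit analyst choice: the natural weights for a
chemokine PRS are the instruments' pQTL betas on the chemokine (the shipped
analysis uses these), but disease-association log-odds weights are equally
accepted — the profile structure does not privilege either, since both
readings are defensible for scores built from MR instruments. Scores are
categorized into tertiles at the empirical 1/3 and 2/3 quantiles, boundary
ties assigned to the lower tertile for determinism. Association modelling on
the tertiles (logistic/Cox) is deliberately out of scope; the package emits
the analysis-ready `individual_id  prs  tertile` table.

## The synthetic generator

`mr_scenario()` fixes a data-generating process: true exposure effects
$\beta_j \sim N(\mu_\beta, \sigma_\beta)$, EAFs uniform, analytic GWAS
standard errors $1/\sqrt{2Np(1-p)}$ for a standardized trait, observed
effects = truth + noise, and outcome effects
$\theta\beta_j + \alpha_j$ with $\alpha_j$ nonzero for an
`invalid_fraction` of instruments (directional or balanced). Exposure,
outcome and cohort draws use separate RNG streams derived from one
mandatory seed, enforcing the two-sample independence the method assumes,
and the caller's RNG state is never touched.

Default study conditions: exposure N = 3,301 (a plasma-proteome pQTL study
of that size), outcome N = 247,173 (a large breast-cancer case-control
meta-analysis; 96,661 for the survival file in the shipped analysis), true
effect log(0.89) — a protective effect of the size reported for CCL5 — and
exposure effects 0.3 ± 0.1 SD per allele, which puts per-SNP F around
100–150, inside the 29.7–1,879 range strong-pQTL panels exhibit. The
palindromic and intermediate-AF fractions exist to build harmonization
fixtures: with k = 91, a 14/91 palindromic fraction and half of those at
intermediate frequency, harmonization removes exactly 7 and keeps 84 — the
attrition pattern of a real 91-instrument chemokine panel. Intermediate
palindromes are drawn well inside the AF window and the other palindromes
well outside it (a 0.02 margin), so fixture counts are exact by
construction, not by luck.

What the generator does *not* emulate: LD between instruments (LD enters
only through the explicit r² matrix), sample overlap between the two
studies, allele-frequency differences between studies, indels and
multi-allelics, and survival-time outcomes (survival GWAS are consumed as
log-hazard summary files). Passing tests therefore demonstrate estimator
correctness under the stated model, not robustness to those real-data
complications.

## Validation experiments

The suite's statistical checks, re-run from scratch by
`scripts/acceptance.R` and `analysis/03_validation.R`:

1. **Oracle equivalence** — 100 random harmonized sets, k ∈ 3..30:
   closed-form IVW and Egger against independent `lm` WLS fits, 1e-10.
2. **Parameter recovery** — θ = log(0.89), k = 20, outcome N = 200,000,
   200 replicates: the mean IVW estimate within 2 Monte-Carlo SE of truth.
   This experiment uses exposure N = 50,000 so that regression dilution
   (~0.7% of θ at the default N = 3,301) is negligible at the experiment's
   Monte-Carlo resolution — the check isolates estimator bias, not
   instrument strength.
3. **Null calibration** — θ = 0, 500 replicates: two-sided rejection at
   α = 0.05 within [0.035, 0.065]; 95% CI coverage within [0.925, 0.975].
4. **Robustness** — 40% invalid instruments, directional pleiotropy
   N(0.05, 0.02), θ = 0.2, k = 50, 200 replicates: the weighted median
   closer to truth than IVW in ≥ 90% of replicates; the Egger intercept CI
   covering the population mean pleiotropy (0.4 × 0.05 = 0.02) at a rate in
   [0.90, 0.99] — the band acknowledges the WLS-weight caveat above.
5. **Attrition fixture** — 91 → 84 with a 7-row removal log, reasons all
   `palindromic intermediate AF`.
6. **Formula spot checks** — R²(β=0.1, eaf=0.5, se=0.01, N=10⁴) = 0.009901
   and F(R²=0.5, N=1001, k=1) = 999 against direct evaluation.
7. **Delta-method check** — Wald SE within 2% of a 10⁶-draw Monte-Carlo SD.

Problem sizes (replicate counts, k, bootstrap sizes) are chosen so each
experiment resolves its question at the stated tolerance while the whole
suite stays comfortably interactive; the weighted median inside replicated
experiments uses 100 bootstrap draws (the floor) since only its point
estimate enters those comparisons.

## Degenerate inputs and tie-breaks

* `beta_exp = 0` instruments are a hard error for the Wald ratio (the ratio
  is undefined), never silently dropped.
* R² = 1 or N ≤ k+1 are hard errors in the F statistic (division by zero /
  negative df).
* All-identical PRS scores yield all-T1 with a warning; tertile boundary
  ties go to the lower tertile.
* Weighted-median cumulative weight outside the first/last percentile
  bracket clamps to the extreme ratio.
* Empty harmonized sets are a hard error at estimation time, but a failing
  exposure×outcome cell is caught, logged and skipped by the panel scan —
  one bad exposure never kills the panel.
* Validation drops dirty summary-statistics rows with a per-row reason log
  rather than failing the file; a missing mapped column is a hard error.

## Known limitations

Fixed-effect IVW only (no multiplicative random-effects variant); no
MR-PRESSO, mode-based, multivariable MR or Steiger filtering; no LD-proxy
substitution; no liftover or indel support; the PRS module reads plain
dosage matrices only. These are scope decisions, not oversights: the
package implements the panel-scan design faithfully and stops where
individual-level modelling would begin.
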