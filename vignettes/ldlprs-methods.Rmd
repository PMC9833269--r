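---
title: "Methods: LDL-C polygenic scores, APOE diplotypes and cohort emulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LDL-C polygenic scores, APOE diplotypes and cohort emulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldlprs)
```

## The score model

The 12-SNP LDL-C polygenic score is a fixed-weight allele score: for
subject $i$,

$$\mathrm{PRS}_i = \sum_{j=1}^{10} w_j\, d_{ij} \;+\; w_{APOE}(D_i),$$

with $d_{ij} \in \{0,1,2\}$ the risk-allele dosage at weighted SNP $j$,
$w_j \ge 0$ the published per-allele effect on the mg/dL scale, and
$w_{APOE}(D_i)$ a haplotypic term indexed by the APOE $\varepsilon$
diplotype $D_i$. The 6-SNP reduction keeps the four largest-effect
weighted SNPs (rs629301, rs1367117, rs4299376, rs6511720) plus the APOE
term. Weights are constants shipped in the packaged panel; the package
never re-estimates them (a stated non-goal). The weight table's source
labels the units mg/dL, but the magnitudes are treated as opaque "score
units" throughout — no unit conversion is attempted or needed, since every
analysis is invariant to a common scale factor.

With no missing data the score is bounded by the all-minimum and
all-maximum genotypes: $[-34.75,\, 65.22]$ for 12 SNPs and
$[-34.75,\, 46.60]$ for 6 SNPs; these hand-summed extremes are asserted in
the tests.

### Risk-allele orientation

The panel stores each SNP's published *minor*-allele frequency per cohort
plus a `risk_is_minor` flag; the risk-allele frequency is $f$ or $1-f$
accordingly. Orientation mistakes are the classic failure mode of allele
scores, so the packaged orientations are cross-validated *jointly*: the
analytic group means they imply must land within 0.2 score units of the
published cohort means for all three groups and both panel sizes (a single
flipped SNP moves at least one mean by $2 w_j |1 - 2f_j|$, which exceeds
the band for every panel SNP). For one SNP (rs3757354) the source
typography is ambiguous about which allele is bold; the packaged choice
(risk = C, the common allele) is the only one consistent with that joint
check — the alternative shifts the control mean by about 1.45 units.

### APOE diplotypes

rs429358 and rs7412 define the $\varepsilon$ haplotypes
($\varepsilon2$ = T–T, $\varepsilon3$ = T–C, $\varepsilon4$ = C–C). From
two unphased genotypes the diplotype is uniquely determined except for the
double heterozygote (CT, CT), which is either $\varepsilon2/\varepsilon4$
or $\varepsilon1/\varepsilon3$. The caller resolves it to `E2E4`:
$\varepsilon1$ (C–T) is vanishingly rare and the published diplotype table
has no $\varepsilon1$ class. Combinations that *require* $\varepsilon1$
(e.g. CC at rs429358 with any T at rs7412) return `UNKNOWN`. The caller is
tested against an independent brute-force enumeration of haplotype pairs
over all nine genotype combinations.

## Analytic oracles

Under Hardy–Weinberg equilibrium and linkage equilibrium,

$$E[\mathrm{PRS}] = \sum_j w_j \cdot 2 f_j + \sum_d \pi_d w_d,
\qquad
\mathrm{Var}[\mathrm{PRS}] = \sum_j w_j^2\, 2 f_j (1-f_j)
  + \Big(\sum_d \tilde\pi_d w_d^2 - \big(\sum_d \tilde\pi_d w_d\big)^2\Big).$$

One deliberate asymmetry: the *expectation* uses the diplotype frequencies
$\pi_d$ exactly as published — they sum to ≈1 but not exactly (0.885 for
the mutation-positive column) — because that reproduces the arithmetic
context of the published group means. The *variance* and the simulator use
renormalized $\tilde\pi_d$, because sampling requires a proper
distribution. Reproduction fidelity and probabilistic validity serve
different masters; both choices are documented at the function level and
the small resulting offset in the simulator's target mean is accounted for
explicitly in the simulator–oracle equivalence tests. Published cohort
score SDs additionally reflect real linkage disequilibrium and are *not* a
reproduction target; `scoreVarianceHwe()` exists to calibrate and verify
the generator, not to match printed SDs.

## Missing-data policies

`computePrs()` defaults to `fail`, because the source analyses implicitly
use complete data and silent degradation of a score is worse than an
error. `omit` zeroes missing terms and reports `n_missing` (counted over
all 12 panel entries, the APOE diplotype counting once); `expected_impute`
replaces a missing dosage with $2 f$ of a stated reference group and an
`UNKNOWN` diplotype with the group's mean diplotype weight under
renormalized frequencies — the natural extension of dosage imputation to
the haplotypic term. Imputation never happens at the I/O layer.

## Phenotype conventions

* **Treatment correction.** On-treatment LDL-C of statin/ezetimibe users
  is multiplied by 1.43 to estimate the untreated value; a measured
  pre-treatment baseline, when available, always takes precedence. The
  provenance of the single constant (and whether it should vary with
  statin intensity) is outside this package's scope.
* **CAC categories.** Agatston 0 / 1–99 / 100–400 / >400, with the binary
  high-burden outcome defined as $\ge 100$ so that the flagged categories
  are exactly MODERATE and SEVERE. Both 100 and 400 close on the MODERATE
  side; exact-boundary scores are rare and the source is silent, so the
  convention is fixed and documented rather than configurable.

## Association analyses

Quantile cuts use the standard linear-interpolation empirical quantiles
(`stats::quantile` type 7) with ties assigned to the lower group; the
source does not state its rule and group summaries are insensitive at
these sample sizes. Linear association is OLS with
$R^2_{adj} = 1-(1-R^2)(n-1)/(n-p-1)$. The quartile logistic model codes
quartiles as indicators against quartile 1, adjusts for age (per year) and
sex, and reports Wald 95% CIs ($e^{\hat\beta \pm 1.96\,SE}$), matching the
symmetric-on-log-scale intervals such analyses print; the trend OR comes
from a second fit with quartile as an ordinal numeric. Fits that do not
converge or show quasi-separation (SE > 50 on the log-odds scale) raise
errors with diagnostics rather than returning absurd intervals. 2×2
contingency tables use the Yates continuity correction — verified to be
the convention that reproduces the published myocardial-infarction
(p = 0.011) and stroke (p = 0.988) comparisons, where the uncorrected
statistic gives 0.008 and 0.83. Kruskal–Wallis post-hoc comparisons are
pairwise Mann–Whitney with Bonferroni adjustment ("multiple post-hoc test
comparison" left the adjustment open; Bonferroni is the conservative
default). All tests are two-sided at $\alpha = 0.05$. Fully tied rank-test
inputs (identical distributions by construction) return p = 1 instead of
the degenerate 0/0 normal approximation.

## The synthetic cohort generator

The generator exists so that every pipeline stage is testable without any
genotype download; it emulates the *statistical structure the analyses
assume*, not any individual-level data.

* **Genotypes.** Each weighted-SNP dosage is Binomial(2, $f$) at the
  group's risk-allele frequency; loci are independent (HWE, linkage
  equilibrium — no LD, a stated non-goal). The APOE diplotype is drawn
  from the renormalized group table and back-converted to SNP genotypes
  (`E2E4` → the doubly heterozygous pair, which the caller resolves back
  to `E2E4`, making the diplotype distribution recoverable).
* **LDL-C.** Baseline LDL = intercept + `effect_scale` × (PRS − group
  mean) + Normal(0, `residual_sd`). Defaults: intercepts at the published
  group medians (127 / 239 / 277 mg/dL), `effect_scale` = 1 (the
  generative model is aligned with the score's own additive assumption),
  `residual_sd` = 40 mg/dL — chosen once so that score variance / total
  variance ≈ 75/(75+1600) ≈ 0.045 in controls, matching the published
  adjusted R² ≈ 0.044. FH ascertainment is modelled as rejection sampling
  on baseline LDL ≥ 210 mg/dL (the screening program's inclusion
  criterion); this is a modelling interpretation, and it is mechanically
  what attenuates the within-FH PRS–LDL association that the tests check
  (truncation removes low-score/low-LDL subjects preferentially). The
  rejection loop has a hard iteration cap with an actionable error.
* **Treatment.** Therapy is Bernoulli (defaults 0.05 control — not
  published, chosen as a realistic general-population rate; 0.71 / 0.82
  for the FH groups as published); treated subjects' observed LDL is the
  baseline reduced by a truncated-normal percentage (means 30% control,
  consistent with the 1.43 correction factor; 49% / 48% for FH groups,
  back-computed from the published baseline medians vs on-treatment
  means).
* **Age, sex.** Truncated normals / Bernoulli at the published medians,
  IQR-derived SDs and sex ratios.
* **CAC.** Zero-inflated: P(CAC = 0) is logistic in age and sex,
  calibrated so ≥ 70% of controls are zero; the positive part is
  log-normal (inverse-CDF truncated below 100, folded-normal excess above
  100) with a top-quartile log-odds tilt of ln 1.7 on P(CAC ≥ 100). The
  source makes no generative claim about continuous CAC beyond prevalence
  and the quartile OR, so this sub-model is calibration plumbing — a green
  CAC test establishes that the pipeline recovers planted effects, not
  that the generator reproduces any real CAC distribution.
* **Clinical events** (MI, stroke, revascularization, hypertension,
  smoking) are placeholder frequencies with mild age/sex/burden gradients
  so that downstream contingency code paths run on realistic shapes; they
  reproduce nothing.

All randomness flows from one seed per cohort: genotypes use `seed`,
phenotypes `seed + 500000` (a documented sub-stream, so regenerating
phenotypes never perturbs genotype draws). Outputs are byte-stable per
seed.

### What a green test does and does not establish

Simulated cohorts share the published frequency tables, effect structure
and group sizes, but have no LD, no ancestry admixture, no genotyping
error, and phenotypes generated exactly from the assumed model. Green
calibration tests therefore establish internal consistency (the pipeline
recovers what the generator plants, at the published operating point) —
they do not reproduce per-subject real-data results, and the package makes
no such claim: published real-cohort quantities needing the actual data
(the CAC OR 1.70 itself, the CVD OR 2.64, per-subject R²) are covered by
recovery properties, not claimed as reproductions.

## Numerical and interface choices

* Matching genotypes to the panel is by rsID only; coordinates and genome
  build are ignored (the score definition identifies variants only by
  rsID). Consequence: assay strand errors are *not* detectable from
  position. Allele mismatches are hard errors; automatic strand
  complementing is refused because two panel SNPs are
  complementary-ambiguous and 12 SNPs give no frequency-based resolution.
* Scores are written to files at 2 decimals; internal arithmetic is full
  precision.
* The `cli` surface is exported R functions (`cmdScore`, `cmdSimulate`,
  `cmdAnalyze`) plus a thin Rscript wrapper; exit statuses are returned,
  errors become single-line diagnostics.
* The LDL-used-in-regression question (whether control-group analyses
  corrected the minority on therapy by 1.43) is left open by the source;
  `preparePhenotypes(..., ldlAdjust = "factor" | "none")` exposes both,
  with `factor` the default.

## Known limitations

No LD or ancestry structure in the generator; no imputation, liftover or
genotype calling; no survival analysis; weights are fixed constants; the
APOE $\varepsilon1$ haplotype is unrepresentable by design. The published
diplotype frequency columns' failure to sum to 1 is preserved as printed
(expectation) and renormalized (sampling) — if the discrepancy is a
transcription artefact upstream, the expectation oracle inherits it, which
is the intended behaviour for reproduction.
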