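# ldlprs

Polygenic risk scores for LDL cholesterol in familial-hypercholesterolemia
(FH) studies, with the downstream association analyses that typically
accompany them.

## The problem

A clinical FH phenotype (LDL-C ≥ 210 mg/dL with familial aggregation) is
explained by a pathogenic variant in *LDLR*, *APOB* or *PCSK9* in well under
half of screened index cases. For a fraction of the mutation-negative
remainder, hypercholesterolemia is *polygenic*: an unlucky combination of
common small-effect alleles. The standard instrument to quantify that is a
weighted allele score over 12 LDL-C-raising SNPs (with a validated 6-SNP
reduction):

```
PRS_i = Σ_j w_j · d_ij + w_APOE(D_i)
```

where `d_ij ∈ {0,1,2}` counts risk alleles of SNP `j` in subject `i`, `w_j`
is the published per-allele effect (mg/dL scale), and the two *APOE* SNPs
(rs429358, rs7412) contribute not per-allele but through the ε-diplotype
`D_i ∈ {ε2ε2 … ε4ε4}` via a haplotypic weight table (ε2ε2 −34.75 … ε4ε4
+7.72; ε3ε3 = 0).

The package implements, as tested reusable components:

* **panel** — the score definition (weights, risk-allele orientations,
  6-SNP membership, per-group allele and diplotype frequencies) as a
  validated, file-backed `ScorePanel` S4 object;
* **genotype I/O** — VCF (rsID-matched, risk-allele-oriented, strict about
  allele mismatches) and dosage-table readers into `CohortGenotypes`, and
  the ε-diplotype caller for rs429358/rs7412;
* **scoring** — `computePrs()` with explicit missing-data policies, plus
  analytic oracles `expectedScore()` and `scoreVarianceHwe()` that give the
  population mean and Hardy–Weinberg variance of the score from a frequency
  table alone;
* **phenotype** — the 1.43 multiplicative LDL-C correction for
  statin/ezetimibe users, percent treatment response, and Agatston coronary
  calcium categories (0 / 1–99 / 100–400 / >400, binary flag at ≥ 100);
* **association** — tertile/quartile stratification, LDL-C ~ PRS linear
  regression (adjusted R²), the age- and sex-adjusted quartile logistic
  model for CAC ≥ 100 with Wald CIs, and χ²/Mann–Whitney/Kruskal–Wallis
  group comparisons (Yates correction on 2×2 tables);
* **synthetic cohorts** — a seeded generator emulating a control population
  (n = 1605) and two FH case groups (mutation-negative n = 491,
  mutation-positive n = 193) from the packaged frequency tables, with an
  additive PRS→LDL effect, therapy assignment, ascertainment truncation at
  baseline LDL-C ≥ 210 for FH groups, and a zero-inflated CAC model.

## Worked example

```r
library(ldlprs)

panel <- defaultPanel()                      # the packaged 12-SNP definition
cfg   <- cohortSimConfig("CONTROL", n = 1605, seed = 7)
sim   <- simulateCohort(cfg, panel)          # genotypes + phenotypes
scores <- computePrs(sim$genotypes, panel)
head(scores, 3)
#>      subject_id prs12  prs6 apoe_diplotype n_missing missing_policy_applied
#> 1 CONTROL_00001 32.92 21.04           E3E3         0                   fail
#> 2 CONTROL_00002 35.20 26.20           E3E4         0                   fail
#> 3 CONTROL_00003 34.53 27.54           E3E4         0                   fail

expectedScore(panel, "CONTROL", 12)          # analytic mean: 33.11

linearAssoc(sim$phenotypes$ldl_baseline_mgdl, scores$prs12)
#> Linear score association (n = 1605)
#>   slope 0.8930 mg/dL per score unit (p = 5.35e-14)
#>   R2 0.0347, adjusted R2 0.0341

high <- categorizeCac(sim$phenotypes$cac)$binary_high    # CAC >= 100
q    <- assignQuantiles(scores$prs12, 4)
logisticQuartileOr(high, q, sim$phenotypes$age, sim$phenotypes$sex)
#> Quartile logistic model (n = 1605), reference: quartile 1
#>  quartile   or ci_lo ci_hi p_value
#>         1 1.00    NA    NA      NA
#>         2 0.96  0.65  1.44   0.850
#>         3 0.68  0.45  1.05   0.080
#>         4 1.52  1.03  2.22   0.033
#>   trend OR 1.11 (0.98, 1.26), p = 0.105
```

Reading of the numbers: each score unit of the 12-SNP PRS carries ~0.9
mg/dL of baseline LDL-C in this simulated control cohort, the score
explains ~3–4% of LDL-C variance (the calibration target is adjusted
R² ≈ 0.044), and subjects in the top score quartile have elevated odds of a
coronary calcium burden ≥ 100 Agatston units after age/sex adjustment (the
generator plants a Q4 log-odds tilt of ln 1.7).

A shell entry point with `score` / `simulate` / `analyze` subcommands ships
at `inst/scripts/ldlprs`.

## Acceptance script

`scripts/acceptance.R` recomputes, from the installed package, the analytic
expected 12-SNP and 6-SNP scores for each of the three cohorts from the
packaged frequency tables (targets `t1`–`t6`), cross-checks them at run time
against freshly simulated cohorts, and writes the values as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
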