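---
title: "Methods: EHR-based PheWAS with BMI-mediation contrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EHR-based PheWAS with BMI-mediation contrast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What the pipeline computes

A phenome-wide association study (PheWAS) inverts the usual GWAS design: one
genetic variant is tested against hundreds of clinical phenotypes mined from
electronic health records. `phewascan` implements the complete analysis
chain for billing-code phenomes:

1. **Phenotype construction.** ICD-9 billing events are grouped into
   phecodes via a user-supplied map. A person is a *case* for a phenotype
   when codes mapping to its phecode occur on at least two distinct calendar
   days. A person is *excluded* from the control group when they carry any
   code inside the phenotype's exclusion range — an interval of related
   phecodes — or when a sex restriction conflicts with (or cannot be
   verified against) their recorded sex. Everyone else is a *control*.
   Phenotypes with fewer than `min_cases` (default 20) cases are dropped.
2. **Genotype QC.** SNPs are kept when call rate exceeds 0.99 and minor
   allele frequency exceeds 0.01, both strict, and when an imputation info
   score, if present, is at least 0.7. Imputed posterior triples can be
   hard-called at the maximum posterior. Relatedness is handled by keeping
   one random member of each connected component of the pi-hat > 0.25 graph.
3. **Association scans.** For each SNP and phenotype, logistic regression of
   case status on allele dosage (additive coding) adjusted for age, sex,
   site indicators, and the first three principal components; optionally
   also for average BMI. BMI is averaged per person over measurements inside
   the inclusive window [15, 70] kg/m^2. SNP-BMI effects use ordinary least
   squares with the same covariates.
4. **Meta-analysis.** Per-cohort log odds ratios are pooled by fixed-effects
   inverse-variance weighting over the intersection of SNPs and phenotypes
   testable in every cohort.
5. **Multiple testing.** Bonferroni (`alpha/m`), the Benjamini–Hochberg
   step-up threshold at `q`, and a simpleM-style effective number of tests
   from the eigenvalue spectrum of a correlation matrix.

The scientific use of the BMI-adjusted pass is a mediation contrast: an
association that survives BMI adjustment is compatible with a direct
(BMI-independent) pathway, while one that collapses toward OR = 1 is
compatible with mediation through the variant's effect on adiposity.

# Model and assumptions

The per-cell model is

$$\operatorname{logit} P(\text{case}) = \beta_0 + \beta_g g +
\gamma^\top z \;(+\, \beta_b \bar b),$$

with $g \in \{0,1,2\}$ the effect-allele dosage, $z$ the covariates, and
$\bar b$ the cleaned average BMI. Reported quantities are Wald: OR =
$e^{\beta_g}$, 95% CI = $e^{\beta_g \pm z_{0.975}\,\mathrm{se}}$, two-sided
p from the normal approximation. Assumptions worth keeping in mind:

- **Additivity** on the log-odds scale in allele count.
- **Linear BMI adjustment**: BMI enters the logit linearly; a spline or
  categorical adjustment is a reasonable sensitivity analysis the package
  does not perform.
- **Independence across individuals** after relatedness pruning; no mixed
  models.
- **Complete-case analysis**: rows with missing dosage, covariates, or
  (when adjusting) average BMI are dropped per fit; no covariate
  imputation.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_cases` | 20 | cases | below this, logistic Wald inference is unstable and single-site coding noise dominates |
| `min_call_rate` | 0.99 (strict) | fraction | standard array-QC cut |
| `min_maf` | 0.01 (strict) | fraction | rarer variants need specialized tests |
| `min_info` | 0.7 (inclusive) | score | conventional imputation-quality floor |
| `ibd_threshold` | 0.25 (strict) | pi-hat | second-degree relatives and closer |
| BMI window | [15, 70] inclusive | kg/m^2 | plausibility band for adult EHR BMI; entry errors fall outside |
| `alpha` | 0.05 | — | family-wise rate for Bonferroni and simpleM |
| `fdr_q` | 0.05 | — | BH false discovery rate |
| `simplem_c` | 0.995 | — | variance-explained cutoff conventional for simpleM |

LD groups relative to an index SNP use $r^2 > 0.80$ (high),
$0.60 < r^2 \le 0.80$ (moderate), $r^2 \le 0.60$ (low), with $r^2$ the
squared Pearson correlation of unphased dosages (composite LD) — the
standard choice when haplotype phase is unavailable.

# Numerical choices

- **IRLS** maximizes the binomial likelihood with convergence declared at
  max |score| < 1e-8 or relative log-likelihood change < 1e-10, capped at 25
  iterations. Standard errors come from the inverse observed information.
- **Quasi-separation** is flagged, not penalized: non-convergence or any
  dosage standard error above 10 log-odds units marks the cell
  `converged = FALSE`, and such cells are omitted from meta-analysis. Firth
  or ridge fits would report numbers for these cells; flagging keeps the
  pooled estimates honest instead.
- $z_{0.975}$ is the exact normal quantile (1.959964...), not 1.96; this
  moves CIs in the fourth decimal.
- **Hard-call ties** break toward the lower dosage, a measure-zero event in
  real posteriors but needed for determinism.
- **simpleM** clips numerically negative eigenvalues to zero before
  accumulating the spectrum.
- Exclusion intervals are **closed** on both ends, and a phecode always lies
  in its own interval, so a single mention of the target phenotype excludes
  the person from its controls.
- Meta-analysis reports Cochran's Q and I^2 for information only; no
  heterogeneity gating is applied, and the model is fixed-effects
  throughout.

# Design decisions on genuinely open points

- **Single-mention individuals** (exactly one distinct day with the target
  phecode) are excluded from controls rather than counted as controls —
  the conservative reading of the two-distinct-days rule: one mention is
  weak evidence of disease, enough to contaminate a control group.
- **"Two relevant codes" across different ICD-9 codes** of the same phecode
  count: the distinct-date criterion applies at the phecode level, since the
  phecode is the phenotype being asserted.
- **Sex-restricted controls** are map-driven: a `sex` column restricts both
  cases' eligibility in the generator and control eligibility in the
  matrix builder. Unknown sex conflicts with any restriction (eligibility
  cannot be verified, so the person is kept out of controls).
- **Relatedness per connected component**, not per listed pair: retaining
  one member per component is the only rule consistent with chains of
  pairs.
- **QC scope is per cohort**: call rate and MAF are computed within each
  cohort before its scan, matching per-platform processing.
- **simpleM input matrix**: the effective test count for a SNP-by-phenotype
  scan factorizes as Meff(SNP dosage correlation) x Meff(phenotype
  case-indicator correlation) — the natural product rule; either side can
  be used alone. Phenotype indicators are correlated pairwise-complete with
  excluded entries treated as missing.
- **Threshold family**: the Bonferroni denominator is the number of
  phenotypes shared by all cohorts (a single-SNP, phenome-wide family), and
  the BH threshold is computed from the index SNP's meta-analysis p-values.
- **Cells untestable in any cohort are omitted** from meta-analysis rather
  than pooled over the remaining cohorts, mirroring a shared-phenotype
  design.

# What the synthetic cohorts emulate — and what they do not

`generate_study()` plants the statistical structure the pipeline is meant
to detect, with defaults fixed at the study conditions the package targets:
two cohorts of 10,487 and 13,711 individuals; an index SNP at MAF 0.41;
latent BMI ~ Normal(29.5, 7.0^2) kg/m^2 shifted 0.535 kg/m^2 per effect
allele, with honest measurements clipped into the [15, 70] plausibility
band so that out-of-window values arise only from injected corruption; satellites generated by haplotype
copying with probability $\sqrt{r^2}$, which hits the target $r^2$ in
expectation at equal MAFs (with unequal MAFs the attainable $r^2$ is
capped); and phenotype models of three kinds — fully BMI-mediated
(overweight, obesity, morbid obesity, sleep apnea), partially mediated
(type 2 diabetes, fatty liver), and direct (fibrocystic breast disease,
protective and female-only; infections; periodontitis at OR 1.25), plus
nulls. Baseline prevalences were calibrated once so marginal case fractions
land near the case counts typical of adult EHR populations; measurement
noise (1.5 kg/m^2), 1–4 BMI measurements per person, a 2% corrupted-
measurement rate, 2–5 billing codes per true case, and a 5% single-mention
rate among non-cases are realism choices of the same kind. Demographics
(age uniform 40–80, 53% female, site labels, token PCs) are plumbing.

The generator deliberately does *not* emulate: ICD-9 co-occurrence and
comorbidity structure beyond the planted effects, longitudinal disease
progression, coding-intensity differences between sites, population
stratification beyond token PCs, or genotyping batch effects. Passing
tests therefore demonstrate that the statistical machinery recovers planted
effect architectures under clean sampling assumptions — not that any
particular clinical association is real, nor that the pipeline is robust
to every failure mode of real billing data.

Test and acceptance runs use scaled problem sizes chosen as a matter of
design: 5,000 individuals x 500 null phenotypes for the type-I-error
property, 20,000 individuals for parameter recovery (where every planted
log OR sits well above its standard error), and sub-2,000-person cohorts
for structural and determinism checks.

# Known limitations

- No Firth correction: rare phenotypes with sparse dosage cells are flagged
  untestable rather than estimated.
- ICD-9 only; no ICD-10 mapping and no hierarchical phecode roll-up beyond
  the exclusion-interval mechanism.
- PCs are consumed as supplied covariates; the package does not compute
  population structure.
- Fixed-effects meta-analysis only; with two cohorts a random-effects model
  would be poorly identified anyway.
- The bundled phecode map is a synthetic miniature for examples and tests;
  real analyses should load a production map with `read_phecode_map()`.
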