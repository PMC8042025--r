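---
title: "Methods: local-ancestry-aware association and risk prediction for clozapine-induced neutropenia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local-ancestry-aware association and risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clozapine is the only effective antipsychotic for treatment-resistant
schizophrenia, but it can induce neutropenia (absolute neutrophil count,
ANC, at or below 1500 cells/mm³) and agranulocytosis (ANC at or below
500 cells/mm³), which is why treatment requires intensive blood
monitoring. A candidate risk variant in the MHC class II region (an
*HLA-DQB1* intronic G allele at roughly 2% frequency in European-ancestry
populations) has repeatedly been associated with these reactions. The MHC
is also a region of unusual haplotype diversity with an excess of *local
ancestry switches*: short stretches whose haplotypes derive from a
different ancestral population than the genome-wide background.

`clozanc` implements the full case–control workflow around such a variant:

1. **Cohort ingestion** — a one-site VCF (GT + genotype probabilities), a
   phenotype/covariate table, and a long-format local-ancestry dosage
   table (ELAI-style: per subject and marker, K = 3 dosages in [0, 2]
   summing to 2).
2. **Hard-calling and QC** — best-guess genotypes from posterior
   probabilities, and missingness/MAF/Hardy–Weinberg filters.
3. **Phenotype definition** — ANC thresholding with clinical-judgement
   fallback.
4. **Local-ancestry summarisation** — windowed dosage means, normed
   differences, permutation group comparisons.
5. **Association** — additive logistic regression with principal
   components and, optionally, local-ancestry covariates; ANC-threshold
   sweeps with a weighted OR trend.
6. **Prediction** — carrier-based risk classification, optionally widened
   by local ancestry, with prevalence-recalibrated predictive values.
7. **Synthetic cohorts** — a generator that emulates the statistical
   structure these analyses assume, so every stage is testable without
   consortium-held genotypes.

## Phenotype and stratum definitions

ANC thresholds are inclusive: ANC ≤ 500 is agranulocytosis, ANC ≤ 1500 is
neutropenia, anything above is a control. Agranulocytosis is a subset of
neutropenia by construction. Subjects without a recorded ANC are
classified only if a clinical-judgement flag is set (`"1"` → neutropenia,
`"agran"` → agranulocytosis); otherwise they are reported as
unclassifiable, never silently dropped. The flag must carry the severity
distinction because an ANC-free record cannot be thresholded.

Hard calls keep the argmax genotype when its posterior probability is at
least 0.7; the comparison is inclusive because the exclusion rule is
stated for probabilities *below* the threshold. Ties go missing. The
PLINK-style distance-to-integer dialect of hard-calling is not separately
implemented: the max-posterior rule is the one that matters for the
focal-variant calls this pipeline consumes.

Ancestry strata use global ancestry fractions (supplied, not estimated):
at least 80% European → `EUR`, at least 80% African → `AFR`, else
`admixed`. Association and prediction run on the `EUR` stratum.

## Local-ancestry summaries

Dosages are averaged, unweighted, over all markers within 1 kb either
side of the focal variant (window inclusive at both edges; an empty
window is an error naming the bounds). For two populations with window
means $a$ and $b$, the normed difference is

$$d(a, b) = \frac{a - b}{a + b} \in [-1, 1],$$

a signed, scale-free contrast; it is undefined (returned `NA`, with a
warning) when both dosages are zero, which genuinely occurs for
European-dominant subjects when contrasting AFR and EAS.

Group comparisons use the **mean of per-subject normed differences**, not
the normed difference of group means. The two agree to three decimals at
the group means this package is designed to reproduce, but only the
per-subject version admits a subject-relabelling permutation null, so it
is the default (both are computable from `group_summary()` output).

The permutation test shuffles group labels without replacement, keeping
group sizes fixed, and compares the absolute difference of group means —
two-sided, the conservative choice where sidedness is not dictated.
Permutations are drawn with replacement from the relabelling space
(standard Monte-Carlo). The point estimate is the add-one estimator
$(k+1)/(N+1)$; when no permutation reaches the observed statistic the
display string is `<1/N` (e.g. `<1.00E-04` at $N = 10^4$), matching the
usual reporting convention. Tests verify the Monte-Carlo p against
exhaustive enumeration at small n and the empirical size at
$\alpha = 0.05$ over 2000 null datasets.

Kendall's tau-b (tie-corrected, normal-approximation p) is provided to
check whether local and global African ancestry co-vary; it wraps
`stats::cor.test` and is verified against an $O(n^2)$ concordance-count
oracle.

## Association model

The association model is ordinary maximum-likelihood logistic regression
(IRLS via `stats::glm`, convergence tightened to `epsilon = 1e-10`), with
additive 0/1/2 allele coding and Wald standard errors from the observed
information; 95% CIs are $\exp(\hat\beta \pm 1.96\,\mathrm{SE})$. Wald
was chosen over profile likelihood because it matches the convention of
the standard single-variant tooling this pipeline mirrors. No Firth-type
penalisation is applied; perfect separation is *flagged* in the result
rather than silently returned as a divergent estimate. Subjects missing
the dose or any active covariate are excluded from that fit with a count,
not imputed. Covariate models: "global ancestry" uses PC1–PC7; "global
and local ancestry" appends the windowed AFR and EAS dosage means as two
additive linear covariates — additivity of the local-ancestry effect is
an assumption, made explicit here.

### ANC-threshold sweep

The sweep refits the model while the case-defining ANC threshold moves
over 500–1500 in steps of 100; controls are always ANC > 1500. The
exclusion direction is deliberately an explicit three-way mode rather
than a single behaviour, because "excluding cases" is ambiguous:

* `cumulative` — cases are ANC ≤ T;
* `exclude_agranulocytosis` — cases are 500 < ANC ≤ T, with
  agranulocytosis subjects dropped entirely (isolates the non-severe
  signal);
* `exclude_neutropenia_band` — cases are ANC ≤ T and subjects in
  (T, 1500] are dropped entirely, never recycled as controls (profiles
  the variant as a predictor of increasingly severe outcomes).

A threshold with zero cases is skipped with a logged reason. The trend
line regresses the **OR itself** (not the log-OR) on the threshold,
minimising $\sum w_i (OR_i - a - bT_i)^2$ with $w_i = 1/\mathrm{SE}_i$ —
reciprocal standard errors, not reciprocal variances — where
$\mathrm{SE}(OR) = OR \cdot \mathrm{SE}(\beta)$ by the delta method.
This mirrors how such OR-vs-threshold trends are conventionally drawn;
it is a display regression, not an inferential model.

## Predictive characteristics

Two total classification rules:

* `genotype_only` — high risk iff carrying the risk allele;
* `genotype_plus_lae` — additionally, non-carriers are high risk when
  their windowed AFR dosage strictly exceeds EAS; an exact tie is low
  risk (the widening condition is a strict comparison).

Because the second rule only promotes subjects to high risk, its
sensitivity can never fall below and its specificity can never rise above
the genotype-only rule — a structural monotonicity the tests assert on
every synthetic cohort.

Confusion matrices are tallied per case definition; the agranulocytosis
tally excludes neutropenia-only subjects while keeping the same control
set. Predictive values are recalibrated to an assumed population risk
$p$ (defaults 3.8% neutropenia, 0.9% agranulocytosis) by Bayes' rule:

$$\mathrm{PPV} = \frac{s\,p}{s\,p + (1-c)(1-p)}, \qquad
  \mathrm{NPV} = \frac{c\,(1-p)}{c\,(1-p) + (1-s)\,p},$$

with $s$ = sensitivity and $c$ = specificity fed **unrounded** (rounding
first visibly corrupts the fourth decimal of the relative risk). The risk
in the high-risk group is the adjusted PPV, the risk in the low-risk
group is one minus the adjusted NPV, and the relative risk is
$p / \mathrm{risk}_{high}$. When $p$ equals the sample case fraction the
adjusted values collapse to the raw sample PPV/NPV — an algebraic
identity the tests verify on random confusion matrices.

The clinical-utility bound inverts the low-risk-group risk: the minimum
sensitivity so that residual risk among test-negatives falls to an
acceptable level $r$ is, under the perfect-specificity convention,

$$s_{\min} = 1 - \frac{r\,(1-p)}{p\,(1-r)}.$$

At $r = 0.13\%$ and $p = 0.9\%$ this gives 85.7%. The perfect-specificity
convention is the default because the bound is about missed cases, not
false alarms; the general inversion with $c < 1$ is exposed via the
`spec` argument, and at these inputs both conventions agree to three
significant figures, so the choice is not empirically distinguishable
here.

## The synthetic-cohort generator

The generator emulates the statistical structure the analyses assume; its
defaults are fixed once and are not tuned per analysis.

**Admixture tracts.** Each haplotype is tiled by ancestry tracts from a
homogeneous Poisson switch process (`switch_rate` switch points per Mb,
default 3 — a deliberately switch-rich region) with tract labels drawn
iid from the subject's global ancestry proportions. This is a
continuous Markov switch process, not a generation-explicit pedigree
simulator: the analyses consume dosages, not pedigrees, and the process
is O(switches) per haplotype. Switch points are process events, so
consecutive tracts may share a label. Per-subject global proportions are
Dirichlet with concentration (0.75, 0.75, 13.5) for (AFR, EAS, EUR):
mean fractions (5%, 5%, 90%), so most subjects pass the 80% EUR filter
and a minority are admixed. This emulates a European-dominant cohort
well; it does *not* produce an AFR-dominant subgroup (the real cohort had
a small one), which downstream analyses never use.

**Focal genotypes.** A haplotype carries the risk allele with a
probability set by its local ancestry at the focal position — defaults
(AFR 0.01, EAS 0.15, EUR 0.01) give an overall allele frequency near 2%
with the allele riding mostly on East-Asian local haplotypes, the
enrichment pattern the local-ancestry analyses are designed to detect.
Genotype probabilities are a point mass on the truth unless a miscall
rate is configured, in which case a fraction of triplets is blurred so
some calls drop below the 0.7 threshold.

**Liability and ANC.** Case status follows
$\mathrm{logit}\,P = \beta_0 + \beta_G G + \beta_{LA}\, d\,[G{=}0]$,
where $d$ is the per-subject AFR-vs-EAS normed difference of true window
dosages. Defaults: $\beta_0 = \mathrm{logit}(0.038)$ (the reported 3.8%
incidence of clozapine-induced neutropenia), $\beta_G = \log 6.2$ (a
study-scale allele effect), $\beta_{LA} = \log 3$ (chosen once to
reproduce the qualitative AFR-excess in non-carrier cases; no published
coefficient exists for this term). ANC is drawn conditional on status so
the threshold-based phenotype definition recovers the simulated status:
controls from a log-normal (median 4000, log-sd 0.3) truncated above
1500; cases from a two-band mixture — uniform on (0, 500] with
probability `p_agran` (default 60/178), else uniform on (500, 1500] —
with the agranulocytosis weight shifted by `agran_shift` (default 1.0)
log-odds per risk allele, so carrier cases skew severe, consistent with
the larger observed agranulocytosis effect. A fraction of cases (22/178)
is recorded by clinical judgement (ANC missing, flag set; 3/22 of those
flagged as agranulocytosis), and 5% of controls have ANC unrecorded,
exercising the pipeline's missing-ANC paths. No published ANC
distribution for controls exists; the log-normal is a declared default,
not an inference.

**Emission.** Emitted local-ancestry dosages are the true integer
dosages plus Gaussian noise (sd 0.05), clipped to [0, 2] and renormalised
to sum to 2, emulating HMM-estimated dosages; the liability model always
uses the *true* dosages. All draws come from one RNG stream seeded once
per cohort, in a documented order (global proportions, tracts, labels,
alleles, liability, ANC, missingness, covariates, dosage noise), so
fixed-seed cohorts are byte-stable on disk.

**What the generator does not emulate:** linkage disequilibrium between
multiple variants, coalescent tract-length heterogeneity, HLA allele
structure, genotyping batch effects, and — notably — the *absence* of
correlation between local and global African ancestry: because tract
labels are drawn from global proportions, local and global ancestry are
positively coupled here, whereas the motivating observation in real data
is a local effect independent of global background. Passing tests
therefore demonstrate correctness of the statistical machinery, not
realism of MHC population genetics.

## Numerical choices and problem sizes

* HWE exact test: standard two-sided conditional exact test (probability
  mass of all heterozygote configurations no more probable than the
  observed one), no mid-p; verified against a log-factorial enumeration
  oracle up to n = 200.
* Permutation p-values use add-one estimators, seeds derive
  deterministically from a single base seed, and ties in the exceedance
  comparison are resolved toward exceedance (`>=` with a 1e-12 guard).
* Logistic fits reject constant or collinear design columns by QR rank
  with the offending columns named.
* Coordinates are 1-based and closed throughout; tracts tile the region
  exactly and dosages at any position are integers summing to 2.
* Test problem sizes were chosen to make Monte-Carlo bands decisive at
  desk scale: parameter recovery uses 100 cohorts of 5000 subjects
  (median fitted OR checked against the generating log 6.2); the
  permutation size check uses 2000 null datasets; the threshold-sweep
  direction check uses 50 cohorts of 2500 subjects with the severity
  shift raised to 2.5 — a deliberately strong planted gradient, so the
  check probes the sweep machinery rather than the default generator's
  signal-to-noise.

## Known limitations

* Single biallelic variant only; no multi-allelic sites, no
  chromosome-wide VCF streaming, no imputation or phasing.
* No Firth correction: sparse strata (e.g. a threshold band with no
  carrier cases) yield flagged, unusable estimates by design.
* The "info" imputation-quality metric is carried as metadata only; its
  construction is upstream of this pipeline.
* Predictive characteristics assume the sampled controls are
  exchangeable with the population at the assumed risk; the
  recalibration corrects prevalence, not spectrum bias.
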