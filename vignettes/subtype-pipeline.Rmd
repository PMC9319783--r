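---
title: "Methods: multi-cohort schizophrenia subtype discovery and panel scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort schizophrenia subtype discovery and panel scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scztype)
```

# Overview

`scztype` stratifies schizophrenia cases into two transcriptomic subtypes
across several overlapping bulk RNA-seq cohorts and scores
neuroinflammation gene panels within the resulting groups. The pipeline is
deliberately modular: each stage is an exported function with a tested
contract, and `run_pipeline()` only sequences them. This vignette explains
the statistical model behind each stage, the tunable parameters and their
defaults, what the bundled simulator does and does not emulate, and the
numerical decisions that were genuinely open.

# The analysis model

## Filtering

Two filters precede everything else. Genes whose mean count across samples
falls **strictly below** the 15% quantile of all per-gene mean counts are
removed; the quantile uses the linear "type 7" interpolation rule so the
threshold is pinned exactly (`filter_low_expression()`, `q = 0.15`).
Samples are kept when `age > 25` (strict) and the diagnosis is `control`
or `scz` (`filter_subjects()`, `min_age = 25`). Both inequalities are
strict because the procedure is phrased as "less than" / "over"; with
continuous simulated ages the boundary case is measure-zero anyway, but
the choice must be fixed for exact tests. Subjects are filtered before the
filtering quantile is computed; the run log records both counts.

## Per-gene differential expression

Counts are transformed to log2 counts per million with a prior count of
0.5: `log2((c + 0.5) / (L + 1) * 1e6)`. Precision weights follow the
familiar mean-variance-trend idea for bulk RNA-seq: an ordinary
least-squares fit per gene on the full design, a lowess smooth
(span 0.5, 3 robustness iterations) of the square-root residual standard
deviations against per-gene mean log2-CPM, and per-observation weights
`predicted_sqrt_sd^-4` evaluated at each fitted value. Residual SDs are
floored (1e-4, and predictions at 1e-3) so constant genes keep finite
weights.

Each gene is then fit by weighted least squares on
`~ group + age + sex + race + rin`, with controls as the reference level.
Residual variances are moderated empirically: with `d` residual df and
per-gene `s²`, the prior `(d0, s0²)` is estimated by a closed-form method
of moments on `log s²` (using the trigamma inverse), and the posterior
variance is `s²_post = (d0 s0² + d s²)/(d0 + d)`. The moderated t uses
`d0 + d` df. Closed-form moments were chosen over iterative maximum
likelihood because they are deterministic, testable, and adequate at this
scale; `moderate = FALSE` recovers ordinary per-gene OLS t-tests exactly
(a tested identity). Benjamini-Hochberg step-up adjustment
(`bh_adjust()`) controls FDR, and "DE" always means `padj < 0.05`,
matching the significance convention used throughout the panel figures.

## VST and covariate adjustment

Clustering operates on variance-stabilized expression. Size factors are
median-of-ratios: for sample *j*, the median over all-positive genes of
`count_gj / geometric_mean_g`. The dispersion trend `α(μ) = a0 + a1/μ`
(count variance `μ(1 + a1) + a0 μ²`) is fitted by per-gene method-of-moments
dispersions regressed on `1/μ` with Huber M-estimation, `a0` clamped to
≥ 1e-8 and `a1` to ≥ 0. The transform itself is the closed form

```
vst(x') = log2( (1 + a1 + 2 a0 x' + 2 sqrt(a0 x' (1 + a1 + a0 x'))) / (4 a0) )
```

with `x'` the size-factor-normalized count; it is strictly increasing and
approaches `log2(x')` for large counts. On simulated counts with a known
trend, per-gene SDs vary by only a few percent across mean-quintile bins,
versus roughly threefold for `log2(x + 1)` — the property the test suite
checks.

Nuisance covariates (age, sex, race, RIN) are removed per gene by fitting
least squares on the combined design `[keep | remove]` and subtracting only
the fitted `remove` contribution. The `keep` design always contains the
diagnosis (and implicitly the subtype) structure, so the adjustment can
never absorb the disease signal — the same protection the standard
batch-removal tools apply. The removal columns are mean-centered so the
grand expression level stays put; the operation is idempotent.

One ordering decision: the transformation and adjustment are fitted on all
filtered genes and samples, and the restriction to DE genes happens at
feature-selection time (clustering), not before the VST. The per-gene
transform is monotone, and pooling all genes makes the fitted dispersion
trend and size factors more stable; the two orders select identical
feature values up to that more stable fit.

## Subtype discovery and labeling

Cases are clustered with k-means, k = 2 (the pipeline is two-cluster by
design and rejects other k): Lloyd's algorithm with k-means++
initialization, best of `n_starts = 25` restarts by within-cluster sum of
squares, mandatory seed. Feature genes are standardized to mean 0 / SD 1
across the clustered samples first; without standardization a handful of
high-variance genes dominates the Euclidean metric. The first pass uses
the pooled SCZ-versus-control DE genes as features.

Cluster indices are arbitrary; subtype labels are semantic. Each cluster
is run through the full DE stack against controls, and the cluster with
**fewer** DE genes becomes Type 1. Ties break toward the smaller mean
|log2FC| and are logged. Because labels are derived from this rule, no
cluster-alignment step is needed when comparing datasets.

## The discriminative gene list

Per dataset, candidate genes are those (i) DE in Type 2 versus controls
and (ii) with a Welch t-test p < 0.05 between Type 1 and Type 2 adjusted
expression. Welch rather than pooled-variance is the safe default when the
test variant is not otherwise pinned, and the choice is recorded in the
result's provenance. The final list is the **strict intersection** of the
candidate sets over all datasets ("recurring across datasets" read
literally); `min_datasets` relaxes it when wanted. The list size is a
data-dependent output, not a constant. Each dataset is then re-clustered
on the list (restricted to the genes it actually measured, with a logged
count of absences) and re-labeled by the DE-count rule.

## Consensus and hold-out agreement

For case subjects present in every dataset, consensus is strict unanimity:
Type 1 only if labeled Type 1 everywhere, Type 2 likewise, otherwise Mix.
Unanimity (not majority) is used because the Mix group is defined as "not
consistently clustered"; a corollary the tests enforce is monotonicity —
adding a dataset can move subjects into Mix but never out of it. Controls
never enter consensus. Pairwise dataset agreement is the fraction of
shared subjects with identical labels; hold-out agreement scores a new
cohort's labels against consensus Type 1/Type 2 subjects only (Mix
excluded), the design used for validating on a fourth dataset.

## Panel statistics

Seven gene panels ship as data (`inst/extdata/neuroinflammation_panels.csv`):
complement, microglia (with M1/M2 tags), astrocyte, pro-inflammatory
mediators, BMEC/blood-brain-barrier, chemokines, and peripheral immune
cells. Symbols are typed exactly as the source material prints them —
including several apparent typos and swapped aliases — and a sidecar file
(`panel_symbol_notes.csv`) flags the probable corrections instead of
silently applying them. Panels are editable data, not code.

Three statistics are computed per panel: (1) per-gene, per-group log2FC
with DE flags, collected from the group-versus-control DE tables (genes
missing from a dataset are reported, never imputed); (2) a one-way ANOVA
on |log2FC| treating the panel's genes as observations within each group
(Pooled, Type 1, Mix, Type 2), with all-pairs Tukey-Kramer HSD
`q_ij = |ȳ_i − ȳ_j| / sqrt((MS_w/2)(1/n_i + 1/n_j))` and p-values from the
studentized-range distribution on `N − k` df; and (3) per-gene group
comparisons of `log2(normalized count + 1)` expression across Control /
Type 1 / Mix / Type 2, again via ANOVA + Tukey. Degenerate inputs are
handled explicitly: zero within-group variance gives p = 1 for equal means
and p = 0 for unequal means.

# The synthetic study

The real cohorts are consortium-held, so the generator
(`simulate_cohorts()`) stands in for them. Its defaults are the package's
study conditions and were chosen once, on the scale of the original
datasets, not tuned to test outcomes:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2000 | genes per cohort (desk-scale stand-in for ~20k) |
| `n_controls` | 100 | controls per cohort |
| `n_type1`, `n_type2`, `n_mix` | 40 / 30 / 30 | planted case groups per cohort |
| `n_cohorts` | 3 | overlapping cohorts |
| `shared_fraction` | 0.65 | cases present in every cohort (~107 shared of ~168 in the emulated studies) |
| `n_de_genes` | 1500 | planted Type 2 DE genes (the "thousands of DE genes" regime) |
| `lfc_range` | 0.5–2.5 | planted `abs(log2FC)`, signs random; some genes exceed 1 by design |
| `mix_attenuation` | 0.3–0.7 | per-subject attenuation λ of the Type 2 effect |
| `mix_sample_jitter_sd` | 0.15 | per-sample (subject-by-cohort) deviation around λ, truncated to (0, 1) |
| `a0`, `a1` | 0.05, 1 | dispersion trend α(μ) = a0 + a1/μ |
| `covariate_effect_sd` | 0.1 | SD of per-gene covariate coefficients (log2 units; age per decade, RIN per unit) |
| `cohort_bias_sd` | 0.2 | SD of the per-gene additive log2 offset shared by a cohort's samples |
| `libsize_sd` | 0.2 | SD of log library-size factors |
| baseline | log2 mean ~ U[1, 10] | realistic dynamic range for the filter and VST |

Counts are negative binomial with mean
`baseline · 2^(covariates + cohort bias + effective subtype log2FC) · libsize`.
Type 1 cases have effective log2FC 0 on every gene; Type 2 the full planted
effect; Mix `λ_eff ·` the planted effect. Shared subjects keep identical
IDs, demographics and planted labels across cohorts, with counts resampled
independently per cohort (a fresh tissue aliquot and library per dataset).
Ages are uniform on 18–90 so the age filter has work to do; race is
3-level, sex 2-level, RIN per sample.

Two generator decisions deserve comment. First, Mix is modeled as an
attenuated Type 2 effect rather than a third discrete profile — the
descriptive reading of a group that may represent a continuum of
inflammatory status. Second, the attenuation has a per-sample component:
the subject-level λ is jittered per cohort (SD 0.15, truncated). Without
it, a Mix subject's cluster assignment is decided by λ alone and is almost
perfectly reproducible across cohorts — averaging over ~1500 signal genes
leaves essentially no assignment noise — so *no* subject would ever be
inconsistently clustered and the Mix phenomenon could not exist in the
simulation. The jitter models within-subject variability across tissue
aliquots, library preparations and platforms; both the subject λ and every
per-sample effective λ are recorded in the truth object.

What the generator does **not** emulate: gene-gene correlation networks
(genes are conditionally independent given the design), microarray
intensity data, platform-specific probe effects beyond an additive
per-gene cohort offset, hippocampal tissue, and any clinical covariates
beyond the modeled four. Passing tests therefore demonstrate that the
pipeline recovers structure of this statistical shape at these effect
sizes — not that the original biological claims hold, and the default
effect sizes must not be read as estimates of the real cohorts.

# Numerical choices and degenerate inputs

- Quantile interpolation: type 7, pinned for exact tests.
- lowess span 0.5 with 3 robustness iterations; not data-adaptive, for
  reproducibility.
- Moderation prior by moments on log-variances; `d0 = Inf` (all posterior
  variances equal to `s0²`) when the observed log-variance spread is below
  the theoretical sampling spread.
- k-means: k-means++ seeding, emptied clusters re-seeded with the farthest
  point, 100 Lloyd iterations maximum, inertia ties broken by first
  restart. Constant standardized features are set to 0 rather than NaN.
- Tukey with zero within-group variance: p = 1 for equal means, p = 0
  otherwise; F = 0 with p = 1 when all values are identical.
- BH: step-up with reverse cumulative minimum, capped at 1; exact
  agreement with the quadratic-time definition is a test.
- Seeds are mandatory wherever randomness exists (simulation, clustering);
  derived stage seeds are small offsets of the run seed and stay below
  2^31.

# Problem sizes used by the checks

The automated checks run the pipeline end-to-end at the default synthetic
scale above (three analysis cohorts plus a fourth held-out cohort in the
acceptance script), 100 global-null replicates of 1000 genes × 40 samples
for FDR calibration, 200 random vectors (up to length 1000) against the
brute-force BH oracle, 100 two-group fixtures for the Tukey/t identity,
and 200 replicates of a planted Type 2-only panel elevation (Δ = 1 log2
unit, n = 25 per group) for panel power. These sizes are the package's
own reproducibility envelope: large enough for the properties to be
sharp, small enough that the whole suite runs in well under an hour on a
laptop core.

# Interfaces

`run_pipeline()` accepts a YAML file or list (keys: `seed`, `sim`,
`filter`, `de`, `genelist`, `cluster`, `holdout`, `panels`) and, given an
output directory, writes every stage artifact (TSV/CSV/YAML) with MD5
hashes in the returned manifest; identical configurations reproduce
identical files. There is no separate shell executable: the exported
functions, `run_pipeline()` and `scripts/acceptance.R` are the intended
entry points for an analysis package of this kind. Counts are read and
written as TSV or MatrixMarket, metadata as CSV, the gene list and truth
records as TSV.

# Known limitations

- The gene-list and consensus logic assume exact gene-identifier matches
  across cohorts; probe-level mapping between platforms is out of scope.
- The Mix group is reported descriptively; the pipeline does not attempt
  to decide whether it reflects a continuum, a third class, or
  classification noise.
- The per-gene |log2FC| ANOVA treats genes as independent observations
  within a panel; correlated genes make its p-values optimistic, which is
  one reason the panel statistics are descriptive rather than
  confirmatory.
- Moderation variants (robust empirical Bayes, mean-trended priors) are
  not implemented; `moderate = on/off` is the only switch.
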