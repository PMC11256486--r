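---
title: "Methods: serum TMT proteomics of neurological recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum TMT proteomics of neurological recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sciserum)
```

## The problem and the study design

After traumatic spinal cord injury, some motor-complete patients recover
substantial sensorimotor function between 30 and 120 days post-injury while
others do not.  `sciserum` implements an analysis pipeline for finding serum
proteins associated with that difference: low-abundance serum proteins are
quantified by TMT 11-plex tandem mass spectrometry in patients with no
recovery (NR) versus strong recovery (SR), tested for differential abundance
with covariate-adjusted moderated t-statistics, screened through a
variance-adaptive fold-change threshold, summarised by FDR-controlled power,
annotated by Fisher-exact term enrichment, and validated by ELISA.

The emulated design is 30 patients — 20 NR and 10 SR — distributed over
three TMT 11-plexes.  Each plex carries ten experimental samples plus one
pooled-reference channel mixing all samples, so reporter-ion ratios to the
pool are comparable across plexes.  The raw patient-level data are not
publicly deposited, so the package ships a first-class synthetic-data module
that reproduces the statistical structure the analysis depends on; every
stage is exercised and tested against it.

## PSM-to-peptide assembly

The pipeline's entry point is a PSM-level table of 11 reporter intensities
per spectrum match.  Assembly proceeds in the workflow's order:

1. **Filtering** (`filter_psms()`): only non-redundant (rank-1) PSMs with a
   protein-group accession are quantified, and PSMs with isolation
   interference above 45% are dropped.  The boundary is inclusive (exactly
   45% is retained) — the source states only a threshold value, and the
   inclusive reading is the conventional one.  PSMs with no recorded
   interference are retained: the filter removes demonstrated co-isolation,
   not missing QC values.  The threshold is a configuration value; the 45%
   default was originally chosen from the interference density's valley, a
   judgement the analyst can re-make on their own data.
2. **Isotope impurity correction** (`correct_impurities()`): per PSM the
   linear system `impurity %*% x = observed` is solved, rows/columns of
   missing channels deleted, negative components clamped to zero.  Without
   a lot-specific certificate the default matrix is the identity — then the
   correction is a documented no-op, not an approximation.
3. **Median scaling** (`median_scale()`): within each plex, every channel is
   scaled so all channel medians equal the plex's grand median.  Scaling
   within plex (rather than across the experiment) is the natural reading
   because ratios are taken within plex immediately afterwards; the
   operation is idempotent either way.
4. **Reference ratios** (`compute_ratios()`): log2(sample / reference pool),
   per plex.  Zeros propagate to missing here (log of zero), never earlier:
   a zero intensity is data until it has to be divided by.
5. **Peptide roll-up** (`rollup_peptides()`): the median of a peptide's PSM
   ratios per sample; the peptide's accession set is the union over its
   PSMs.

## Preprocessing

1. **Missingness filter** (`filter_missing()`): a peptide is kept only when
   its missing fraction is ≤ 0.36 in *every* recovery group.  A per-group
   rule is ambiguous between "any group" and "every group"; the stricter
   reading is the default and the threshold is configurable.
2. **Imputation** (`impute_ipca()`): iterative PCA — fill missing cells with
   row means, then alternate column-centred rank-*k* truncated-SVD
   reconstruction with re-filling until the largest change in an imputed
   cell is below `tol` (default 1e-6).  The scheme is deterministic (mean
   initialisation, no randomness), never touches observed cells, and
   exactly recovers masked entries of rank-*k* matrices — the package's
   strongest testable guarantee for it.  The default `k = 2` reflects the
   two dominant structured axes the generator plants (group and batch);
   for real data `k` should be chosen by cross-validation, which the
   package deliberately does not automate.
3. **Quantile normalization** (`quantile_normalize()`): columns are mapped
   onto the mean order statistics (via `limma::normalizeQuantiles`,
   mid-rank ties).  Idempotent.
4. **Batch correction** (`remove_batch()`): per feature, least squares on
   the combined design [intercept + group | plex dummies | centre dummies],
   subtracting only the fitted batch contribution
   (`limma::removeBatchEffect` with the group protected).  Group remains a
   covariate again in the later models; this double appearance is kept
   deliberately because correction and modelling serve different matrices
   (the peptide matrix also feeds enrichment).  Batch correction uses the
   imputed values; the alternative of re-masking imputed cells afterwards
   is not taken, since every downstream consumer requires a complete
   matrix anyway.
5. **Unique-group filter and protein roll-up**
   (`filter_unique_groups()`, `rollup_proteins()`): peptides mapping to
   more than one protein group are removed; proteins are the 20% trimmed
   mean of their peptides (plain mean below 3 peptides — a symmetric trim
   is undefined there).  The trim fraction is the single most influential
   roll-up knob and is exposed prominently in `run_config()`.

## Differential abundance

Per feature, ordinary least squares on a treatment-coded design: recovery
group (reference SR — so positive logFC means higher in NR), injury level
(ref. paraplegia), centre (ref. Toledo), sex (ref. female), centred age and
storage time, plus AIS grade (ref. A) at the protein level only.  The
moderated t machinery is implemented in the package: residual variances get
a scaled inverse-chi-square prior whose parameters (d0, s0²) are estimated
by moment-matching on log s² (digamma/trigamma inversion — chosen over
likelihood maximisation for determinism), posterior variances
s̃² = (d0·s0² + d·s²)/(d0 + d), t = β̂/(u·s̃) on d0 + d degrees of freedom.
Two degenerate cases are defined explicitly: literally identical variances
give d0 = ∞ with s0² equal to the common value (moderated t = ordinary t),
and a forced d0 = 0 recovers the ordinary t-test.  The implementation
agrees with `limma::eBayes` to 1e-8 on heterogeneous-variance data; limma
serves as an independent cross-check in the tests, never as the
implementation.

The fold-change threshold adapts to the data's variability
(`compute_fct()`):

> log2(FCT) = 1.47 × median per-feature SD

With the study's median protein SD of 0.4375 this gives FCT = 1.56 ≈ 1.6;
the peptide-level value in that cohort was 1.8.  Significance classes
combine p ≤ α (0.01 peptides / 0.05 proteins) with |logFC| ≥ log2(FCT), BH
adjustment across features, and an FDR ≤ 0.1 protein filter.  Fold
enrichments are reported per direction as 2^|logFC| rounded half-even to
two decimals.

## FDR-controlled power

`fdr_power()` solves, by bisection on (1e-12, 0.5] to |Δα| < 1e-10, the
fixed point

> π0·α / ((1 − π0)·P(α)) = f / (1 − f),

with P(α) the two-sided noncentral-t power at df = 2(n − 1) and
ncp = Δ/(σ·√(2/n)).  The left side is FP/TP in expectation, so the fixed
point targets a *realized* false discovery proportion of f among the
declared discoveries — equivalently, what a π0-adaptive BH procedure (level
f/π0) attains.  The tests verify this reading against a 50,000-test
simulation oracle: plain BH at level f only realizes FDR π0·f and sits
several points below, while the adaptive oracle agrees within a fraction of
a percentage point.  At the study's parameters (Δ = 0.68 — the protein
log2 FCT — σ = 0.4375, π0 = 0.66, f = 0.1, two-sided) the achieved power is
0.9109 at n = 10 per group and 0.8142 at n = 8, so `min_n_for_power(0.8)`
returns 8.  Equal group sizes are assumed; an unbalanced study is
summarised by its smaller group, which is how the 10-patient SR arm enters.
`estimate_pi0()` is a Storey smoother: pi0(λ) on λ ∈ {0.05, …, 0.95}, a
df-3 smoothing spline, evaluated at the largest λ and clipped into (0, 1].

## Functional enrichment

Regulated peptides (p ≤ 0.01 and |FC| ≥ FCT) are mapped to identifiers via
their protein group and tested term-by-term with the two-sided Fisher exact
test (minimum-likelihood convention) against the background of non-regulated
identifiers — regulated and background sets are disjoint by construction.
Terms need at least 2 matched regulated identifiers to be tested; BH runs
across tested terms only; adjusted p < 0.3 is the reporting rule.  Both
over- and under-representation are labelled.  Terms are flat sets (GMT
files); no ontology-graph propagation is attempted, since there is no
evidence the original analysis propagated.

## ELISA reduction

Standard curves are fitted both as a five-parameter logistic
OD = d + (a − d)/(1 + (x/c)^b)^g (Levenberg–Marquardt) and as a simple
linear regression; the higher-r² model wins, and r² ≤ 0.99 is flagged
against the acceptance rule.  Concentrations are interpolated through the
curve inverse and multiplied by the dilution factor; ODs outside the
invertible range or the standard range are flagged rather than
extrapolated.  Limits follow the CLSI-style formulas on the OD scale
(LoB = mean_blank + 1.645·SD_blank; LoD = LoB + 1.645·SD_lowest-standard);
samples at or below LoD are flagged for re-assay.  Duplicate CV = sd/mean.
Group comparisons are gated per group by Shapiro–Wilk at 0.05: any
rejection (or an undefined test, e.g. a constant group) routes to the
two-sided Mann–Whitney test, otherwise the pooled-variance Student t.  No
multiplicity correction is applied across analyte-wise comparisons,
matching the validation procedure being emulated.

## The synthetic-data generator

`generate_study()` draws, on the log2 scale, latent intensity = protein
baseline (N(17, 1.2²)) + peptide ionization offset (N(0, 1)) + group effect
+ plex offset (N(0, 0.30²)) + centre offset (N(0, 0.15²)) + protein-level
cell noise + peptide-level cell noise (N(0, 0.25²)), with PSM-level noise
(N(0, 0.15²)) on top; reporter intensity is 2^latent.  The reference pool
is the all-sample mean of the linear-scale latents, re-measured per plex
with N(0, 0.10²) log-noise.  Missingness is logistic in the latent
intensity (slope 1 around the 5th percentile) over a 2% MCAR floor, so low
intensity cells vanish more often — the mechanism the missingness filter
assumes.  Defaults mirror the study: 20 NR / 10 SR over 3 plexes,
effect size 0.68 with random sign on 34% of proteins (the complement of
the study's π0 = 0.66), demographics drawn to the cohort's group-wise
marginals, centre crossed with group so batch correction stays
identifiable.  The protein-level cell noise is derived from the calibration
target (median per-protein SD 0.4375) by subtracting the expected
contribution of peptide/PSM/reference noise after roll-up over a typical
~10-peptide protein; the suite verifies the realised median SD lands within
15% of target.  Default catalogue sizes (300 proteins, 1–20 peptides each,
1–5 PSMs per peptide and plex) are conventional choices — the study's
54,770 peptides are not derivable from the text and only scale the counts,
not the structure.  Tests use a 120-protein reduction of the same design.

What the generator does *not* emulate: chromatographic fractions, charge
states, spectral or interference-driven ratio compression, correlated
peptide missingness within a protein, non-Gaussian heavy-tailed batch
structure.  Green tests therefore certify the pipeline's statistical
machinery under the stated model, not performance on any real cohort.

`generate_elisa_plate()` produces duplicate sample wells, serial-dilution
standards from a known 5PL truth, blanks at the lower asymptote, and
multiplicative OD noise at a given CV (study-wide mean 8.5% is the
default), enabling loop-closure and calibration tests.

## Numerical choices and degenerate inputs

* Bisection bracket (1e-12, 0.5] for α_c; a constraint still slack at 0.5
  returns the bracket edge, an infeasible constraint returns power 0 with a
  diagnostic note rather than an error.
* Noncentral-t powers use `pt(..., ncp)` directly; its last-digit precision
  warnings are far below the α tolerance and are suppressed.
* Quantile-normalization ties share mid-rank means.
* Fisher p-values are clamped at 1 (the minimum-likelihood sum can exceed 1
  by rounding) before BH.
* A completely tied Mann–Whitney comparison (zero-variance rank statistic)
  is reported as p = 1.
* Empty feature matrices are representable (zero-row), so filters can
  legitimately empty a matrix and the orchestrator turns that into an
  explicit error at the imputation precondition.
* All generators and the pipeline are deterministic given their seeds; the
  pipeline itself contains no randomness beyond the seed it sets
  defensively.

## Known limitations

* The identity impurity default means impurity correction only has effect
  when a lot certificate is supplied.
* π0 estimation needs a few hundred p-values to be stable; it warns below
  100.
* The 5PL fit can be weakly identified (b–g trade-off) on sparse or noisy
  standards; the linear fallback and the r² flag make this visible rather
  than silent.
* Cohort-scale counts (54,770 peptides; 838 regulated peptides; 154/24/3
  proteins) depend on the unavailable raw data and are out of reach by
  design; the suite substitutes property-based checks (null FDR control,
  effect recovery, oracle equivalences) under the synthetic conditions.
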