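---
title: "Models and methods behind triomic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind triomic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(triomic)
```

# Scope

`triomic` integrates three stool-derived data types from longitudinal
paediatric case-control cohorts — 16S rRNA OTU counts, label-free
metaproteome intensities, and virome read counts — and asks which features,
functional groups and shared latent factors track islet-autoimmunity status,
time relative to seroconversion, and viral infection.  This vignette
documents the models, the numerical choices, and what the synthetic test
surface does and does not establish.

# 16S processing

**QC.** Samples with fewer than 100 total reads are treated as failed
sequencing reactions and removed (the comparison is strictly `< 100`).
Contaminant taxa (e.g. a suspect *Methanobrevibacter* genus) can be removed
by lineage label before any aggregation; we apply this exclusion before
amalgamation.

**Taxonomy-guided amalgamation.** With tens of samples, hundreds of OTUs
are mostly noise.  A feature is *retained* when it accounts for strictly
more than 0.1% of a sample's reads in at least 15% of samples (the
prevalence count is compared to `0.15 * n` without rounding).  Failing
features are collapsed to their nearest non-empty ancestor rank, counts
summed within each truncated lineage, and the evaluation repeated three
times; whatever still fails is excluded.  Conventions worth knowing:

* retained features are frozen and never absorb later collapses — an
  aggregate landing on the lineage of a frozen feature keeps its own
  identity (suffix `_agg`);
* grouping keys are full truncated lineages, so unclassified branches from
  different families never merge;
* relative abundances are recomputed each round against the original
  per-sample totals (which collapsing conserves exactly).

Per-sample totals over retained plus excluded features equal the input
totals as an exact integer identity, which the tests assert, alongside
feature-for-feature equality with a brute-force oracle implementation on
random toy taxonomies.

**Diversity and ordination.** Observed richness is the count of positive
entries; Shannon entropy uses the natural logarithm (configurable).
Bray-Curtis dissimilarities of total-sum-scaled counts feed a classical
PCoA (eigendecomposition of the double-centered `-D^2/2`); negative
eigenvalues are reported and their axes dropped, with a Cailliez correction
available behind a flag.  Modelling uses `asin(sqrt(p))` of relative
abundances.

# Metaproteome processing

**Detection and filtering.** Detection means a non-missing, nonzero
intensity (label-free zeros mean "not quantified", configurable).  Protein
groups detected in at least 50% of samples are kept; the filter is applied
jointly across all samples.

**Variance-stabilizing normalization.** Each sample gets an affine-arsinh
calibration `h_i(x) = asinh(a_i + b_i x)`, `b_i > 0`, under a model in
which each feature's transformed values are Gaussian with feature-specific
mean and a common variance.  The feature means and the common variance are
profiled out in closed form and the `2n` calibration parameters are
maximized by BFGS with analytic gradients (relative tolerance `1e-6`, at
most 200 iterations).  The calibration likelihood is degenerate at exact
zeros (their Jacobian term grows without bound in `b`), so zeros are
treated as missing — consistent with the detection dialect.  Because the
calibration is per sample, any age effect that is a *common-sign* intensity
shift is absorbed as it would be for a library-size effect; age gradients
survive only through differential (mixed-sign) feature behaviour, which is
how the synthetic fixtures plant them.

**BPCA imputation.** Missing values are imputed by an EM algorithm for
probabilistic PCA with per-axis automatic-relevance precisions: the E-step
infers factor scores per missingness pattern, the M-step updates axes
(ridge-regularized by the ARD precisions), feature offsets and the noise
variance.  Iteration stops when no imputed value moves by more than `1e-5`.
Observed entries are returned bit-unchanged.  Default dimensionality is
`min(n, d) - 1` capped at 20; initialization is a seeded randomized SVD of
the mean-completed matrix.

**COG aggregation.** Functional summaries sum raw intensities of all
non-human protein groups by the COG of their lead protein (missing
contributes zero, so total microbial intensity is conserved); groups
without a COG pool under `"unassigned"`.  The COG matrix receives its own
normalization pass before modelling — whether the original analysis reused
the protein-level calibration is ambiguous, and a separate fit is the more
conservative reading.

# Virome categories

A virus is detected in a sample at strictly more than 100 reads.  Three
binary categories are derived per sample — any virus, any enterovirus, any
mastadenovirus — and the same three per subject by OR over the subject's
samples.  An "eight-way classification" of such data can be read either as
the 2^3 combinations of the three sample-level flags or as the 3 + 3
sample/subject categories; the package exposes the six indicator
covariates plus the 8-way combination label and lets the association stage
choose.  Norovirus and parechovirus flags are computed but not modelled by
default (too sparse).

# Age deflation (analysis model 2)

Each variable is independently regressed on an intercept plus a natural
cubic spline basis of age (df = 4, knots at age quantiles; reports of this
kind typically state only "cubic spline regression", so df is configurable
and logged) and
replaced by its residuals.  Deflation is a linear projection (idempotent,
residuals orthogonal to the basis to machine precision).  Samples missing a
data type are deflated within the set of samples observed for that view.
Model 1 skips this step; model 2 applies it to every Gaussian view.

# Multi-view factor model

The integration stage is a group factor analysis
`x_nm = W_m z_n + e_nm` fit by mean-field variational inference:

* `z_n ~ N(0, I_K)` with `K_init` (default 15) overcomplete factors;
* Gaussian noise with feature-specific precision `tau_mj`;
* per-(view, factor) ARD precisions `alpha_mk` on weight columns;
* a feature-wise spike-and-slab prior `w = s * what`,
  `s ~ Bernoulli(theta_mk)` with a learned Beta(1,1) inclusion rate.

The spike-and-slab layer matters: with column-ARD alone, a spare factor
happily locks onto the top sampling eigenvalue of a small view (a 12-genus
binary block at n of a few hundred sits right at the detection edge), and
the noise view then appears to "explain" several percent of variance.
Feature-wise inclusion lets those weights collapse to exactly the shrunken
regime the prior intends.

Numerical choices, each of which the test suite pins down:

* **Inner ARD iterations.** The weight/precision/inclusion block is
  iterated (default 10 times) to its joint fixed point at fixed `q(Z)`:
  repeated coordinate updates remain exact ascent steps on the bound, and
  the collapsed solution for an irrelevant factor is reached in a few
  sweeps instead of drifting one increment per sweep.
* **Rotation refinement.** Coordinate ascent can converge with factors
  entangled by an invertible transform of the shared subspace — the
  likelihood is invariant, only the sparsity priors prefer aligned axes,
  and their pull is weak late in the fit.  At convergence the oblique
  (promax) rotation of the stacked weights is proposed, the updates resume,
  and the rotated solution is kept only if the bound ends higher (at most
  two attempts; the reported trace remains monotone).
* **Bernoulli views.** Binary views (virome presence/absence) use a
  logistic link through the Jaakkola-Jordan quadratic bound with a
  per-feature intercept.  They are fit *conditionally*: their weights are
  inferred, but they inform the scores only for samples with no Gaussian
  view.  A small binary block otherwise bends the latent space toward its
  own sampling noise — a local optimum we verified has a *worse* bound
  than the collapsed solution.  Scores are also initialized from the
  Gaussian views only, since pseudo-data scales are arbitrary.
* **Staged optimization.** Gaussian views are fit to convergence before
  Bernoulli views join, so irrelevant factors are already collapsed.
* **Identifiability conventions.** Scores are rescaled to unit variance
  (all scale in the weights), each factor's sign makes its largest-|weight|
  feature positive, and factors are ordered by total variance explained.

**Variance explained and selection.** Per (view, factor),
`R2 = 1 - SS_res/SS_tot` on the centered view with the single-factor
reconstruction; per-view totals use the full reconstruction; per-factor
totals pool sums of squares across views.  For Bernoulli views the sums of
squares are taken on the variational pseudo-data weighted by the bound's
per-entry precisions — reconstructions live on the logit scale and a
raw-scale comparison would be meaningless.  Factors with total variance
explained above 5% are selected (a max-over-views criterion is available;
either convention is defensible).

# Association models

Every feature (arcsin-sqrt abundance, normalized-imputed intensity, COG
sum, or factor score) is fit with the random-intercept linear mixed model

`y = b0 + b1 age + b2 HLA + b3 case + b4 time + b5 case*time + u_subject + e`

estimated by REML with the variance ratio `sigma2_b / sigma2_e` profiled
out and optimized by a bounded one-dimensional search (coarse log-scale
grid, then golden-section to 1e-8, with the boundary `lambda = 0` checked
explicitly — at which point the fit provably equals OLS).  Terms are tested
by likelihood ratio: the ML log-likelihood is evaluated at each model's
chosen ratio and `-2 (ll0 - ll1)` referred to chi-squared with one degree
of freedom per dropped column.  A Wald alternative was considered and
rejected: the LRT is self-contained and its null calibration at n = 80 is
itself an acceptance property (Kolmogorov-Smirnov uniformity over 1000 null
simulations).  Virus indicators enter separate models (age + HLA + case +
indicator), sample-level as a time-varying covariate and subject-level as a
subject constant.  Benjamini-Hochberg correction is applied within each
(model, term) family, significance at q < 0.1.  The per-feature fit costs
about a millisecond, which is what makes the 50-replicate calibration and
power studies feasible; `lme4` reproduces the estimates to 1e-6 and serves
as the independent cross-check in the tests, not as the implementation.

Repeated-measures correlation uses the analysis-of-covariance form:
`r = sign(slope) * sqrt(SS_x / (SS_x + SS_res))` from `y ~ subject + x`,
with `df = N - n_subjects - 1`.

# The synthetic cohort generator

`generate_cohort()` defines the study conditions every downstream stage is
tested against: 20 case-control pairs (40 subjects, 80 samples),
seroconversion at 3.4 ± 2.2 years, 1.4 ± 0.6 years between timepoints, 50%
male, 40% high-risk HLA, matched pairs sharing sex, HLA and age to ±0.5
years.  Structure:

* a **gut maturity** latent `1 - exp(-age/1.5)` (plus subject noise) drives
  both OTU occupancy (logistic, calibrated so observed richness averages
  about 90 OTUs in the first year of life versus about 174 after, at
  10,000 reads/sample over a 250-OTU pool) and microbial protein intensity
  — which, through intensity-dependent missingness, couples microbial
  protein detections to OTU richness the way repeated-measures correlation
  sees in real cohorts;
* OTU abundances are per-subject log-normal baselines sampled
  multinomially at depth; taxonomy is a random Greengenes-style tree over
  ~6 phyla with lineages truncated at genus/species to exercise
  amalgamation edge cases;
* **four latent axes** beyond age — two enterotype-like community
  gradients loading jointly on OTUs and microbial proteins, a host immune
  axis on human proteins, and a microbial metabolic axis — give the factor
  model the multi-factor structure real cohorts show (without them the
  only shared signal would be age);
* immunoglobulin variable-region intensities decline with age
  (slope −0.45 per year on the log scale);
* protein missingness is MNAR: a decreasing logistic in the latent
  log-intensity, steeper at low intensity (~30–35% missing overall);
* the **planted case-by-time cluster**: 20 microbial proteins labelled
  genus *Faecalibacterium*, category ABC-type transport, sharing a latent
  cluster score strong enough that the cluster surfaces as its own selected
  factor, with an additive case-by-time shift of 1 feature-SD;
* 28 proteins shift by 0.8 SD (20 down, 8 up) in mastadenovirus-positive
  samples; enterovirus positivity follows `logit p = 0.8 - 0.55 age`.

`mask_views()` strips a chosen fraction of samples of exactly one data
type, emulating cohorts where some samples lack one omic.

What passing tests on this generator do **not** show: real 16S data have
compositional correlations, overdispersion and batch structure the
multinomial model lacks; real proteomes have correlated peptide-level
missingness; the virome here is a toy presence process.  The tests
establish that the algorithms recover what was planted under the study's
sampling design, not that the biology of any particular cohort is
reproduced.

# Problem sizes and simulation design

Simulation scales were chosen once, as the smallest sizes at which each
property is statistically meaningful: 25 random tables for the
amalgamation oracle; 1000 null fits for LRT calibration; 50 replicates of
500 features (40 subjects × 2) for false-positive and power rates, with the
variance split `sigma2_subject = 0.65 / sigma2_resid = 0.35` — an
intraclass correlation of 0.65, a realistic within-subject stability for
repeated stool proteomes, fixed by a design power analysis before any
testing; 20 seeds of a 250-sample three-view fixture for factor recovery
(the planted factors carry pairwise-distinct view supports, since factors
with identical support are identifiable only up to rotation — a property of
the model class, not of any implementation); and 20 default cohorts for the
end-to-end planted-cluster check.  The in-sample variance a pure-noise view
appears to explain scales like K/n, so the noise-view fixture uses n = 250,
where the <1% bound is a meaningful discrimination and not a coin flip.

# Known limitations

* The LMM supports a single random intercept — the design of the emulated
  study — not nested or crossed random effects.
* The factor model's conditional treatment of binary views trades a small
  amount of statistical efficiency (binary data cannot sharpen scores for
  samples that have Gaussian data) for robustness against noise-driven
  factors; joint fitting is the behaviour for samples observed only in
  binary views.
* Amalgamation collapses one rank per round; an OTU with a named species
  label passes through the species rank before reaching its genus, so
  sibling OTUs with distinct species labels merge at the genus only from
  the second round on.
* PCoA axes with negative eigenvalues are dropped rather than corrected by
  default.
```
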