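---
title: "Methods: OSA parameters, microbiome association cascade, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OSA parameters, microbiome association cascade, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apneabiome)
```

# What this package computes

`apneabiome` implements a population-scale, cross-sectional association
analysis between obstructive sleep apnea (OSA) severity and the gut
microbiota, as a chain of testable stages:

1. **OSA parameters.** From nocturnal recording summaries it derives the
   apnea-hypopnea index (AHI, events/h of air-flow recording), the oxygen
   desaturation index (ODI, events/h of oximetry recording) and T90 (the
   percentage of the oximetry recording spent below 90% saturation), with a
   4-hour validity rule applied per channel. AHI additionally requires a
   valid oximetry channel because hypopnea scoring depends on desaturation.
2. **Diversity.** Shannon alpha diversity, Bray-Curtis beta diversity,
   principal coordinate analysis, and covariate-adjusted PERMANOVA across
   severity groups.
3. **Species associations.** Covariate-adjusted partial Spearman
   correlations run through a three-stage model cascade with
   Benjamini-Hochberg (BH) false discovery control, followed by sensitivity
   analyses, a hemoglobin effect-modification screen, multiple imputation
   of missing AHI, functional-module enrichment, species co-occurrence, and
   post hoc blood pressure/HbA1c models.

Because individual-level data of this kind are not public, the package
ships a seeded synthetic cohort generator with a planted-effect truth
ledger; every inferential stage is validated by how well it recovers what
was planted, and by oracle and calibration tests that do not involve the
generator at all.

# The association engine

## Partial Spearman correlation

Both variables are transformed to mid-ranks, each rank vector is
residualized by least squares on the covariate design matrix (categorical
covariates one-hot encoded, intercept included), and the coefficient is the
Pearson correlation of the residuals. Two-sided p-values use
$t = \rho\sqrt{(n-2-k)/(1-\rho^2)}$ on $n-2-k$ degrees of freedom, $k$
being the number of non-intercept design columns. With no covariates this
is exactly the classic Spearman correlation. The rank-then-residualize
("residual") variant was chosen over correlation-matrix inversion; the two
give identical coefficients, and the brute-force normal-equations variant
serves as the test oracle. Complete-case analysis throughout: rows missing
the exposure, feature or any covariate are dropped per model, so each
result reports its own `n`.

Degenerate designs fail loudly: a feature collinear with the covariates
produces a zero-variance residual error, never a silent number. Categorical
covariates that collapse to one level after exclusions are dropped with a
warning.

## The model cascade

Stage 1 (*screening*) adjusts for age, sex, smoking, alcohol and DNA
extraction plate — the main model **without BMI** — because BMI can be read
either as a confounder or as a downstream consequence of the microbiota;
screening without it retains species whose signal might flow through
either path. Stage 2 (*main*) adds BMI; stage 3 (*extended*) further adds
fiber intake, total energy intake, physical activity, education, birth
country and season. Stages 2 and 3 only re-test species that passed stage
1 at q < 0.05, and the final hit set is the stage-3 q < 0.05 set.

BH adjustment is applied within each (exposure, stage) family. The
reasoning: per-exposure q-values are reported downstream, so the narrowest
consistent family is per exposure and stage; the threshold and the family
definition are both arguments, not constants.

## Enrichment input

The ranked-p functional enrichment does **not** consume the staged cascade
table: stages 2-3 only carry screened survivors, which would leave the
ranked list without its null tail and the carrier/non-carrier comparison
without contrast. Instead `association_scan()` computes the extended-model
association for *every* prevalence-filtered species, and enrichment ranks
that full list. This mirrors how ranked-list enrichment is normally done:
the universe, not the hit set, is ranked.

## Sensitivity analyses, heterogeneity, imputation

Four pre-specified sensitivity variants re-test the hit set: adding
medication covariates, adding waist-to-hip ratio, excluding antibiotic
users, excluding lung disease. The hemoglobin screen stratifies at the
sex-specific median (ties assigned to the low stratum; a deterministic
rule the data cannot dictate), computes stratum-specific partial Spearman
coefficients with full-pipeline bootstrap standard errors (ranks and
residualization recomputed per resample, resampling within stratum), and
compares the pair on the raw coefficient scale,
$z = (\rho_{low}-\rho_{high})/\sqrt{se_{low}^2+se_{high}^2}$. The raw-scale
comparison matches the pairing of a two-group coefficient comparison with
bootstrap SEs of the coefficients themselves; a Fisher-z variant sits
behind a flag.

Missing AHI is multiply imputed by type-1 predictive mean matching: the
regression of AHI on the predictors is fit on observed rows, the residual
variance is drawn from its scaled inverse-$\chi^2$ posterior and the
coefficients from their normal posterior, observed predictions use the
least-squares fit, missing predictions the drawn coefficients, and each
missing row receives a donor drawn uniformly from the `k = 5` nearest
observed predictions (defaults `m = 10` imputations). One imputation round
is run per species, with the species' own rank-transformed abundance among
the predictors (ranks tame the heavy right tail of relative abundances).
Per-imputation coefficients are pooled by Rubin's rules on the Fisher-z
scale (variance $1/(n-3)$), then back-transformed: the z scale is the
standard pooling scale for a bounded coefficient; raw-scale pooling is
available behind a flag. With zero missingness the pooled inference
reduces exactly to the complete-case analysis, which the tests assert.

# Diversity internals

Bray-Curtis, PCoA and PERMANOVA are implemented directly (vegan serves as
an independent cross-check in the tests, never as the implementation):

* **PCoA** double-centers $-\tfrac12 d_{ij}^2$ (Gower) and
  eigendecomposes. Negative eigenvalues — expected for Bray-Curtis — are
  retained in the eigenvalue list but excluded from the explained-variance
  denominator; no Lingoes/Cailliez correction is applied by default, so
  coordinates of the leading axes are unaffected by the correction debate.
* **PERMANOVA** partitions the Gower matrix on nested least-squares
  projections with sequential (covariates-first) sums of squares and free
  permutation of samples, the common default of distance-based
  permutational ANOVA; 9,999 permutations by default, enough to resolve
  p-values near $10^{-4}$ (the pipeline driver scales this down to 999,
  which resolves the 0.001 floor it reports). Quantitative covariates are
  standardized before the partition purely for numerical conditioning; the
  plate factor enters as one-hot indicators. A design in which the group
  factor is collinear with the covariates is refused.
* **Shannon** uses natural logarithms (a `base` argument exists).

# Functional modules and co-occurrence

A species carries a gut metabolic module (GMM) when, on at least one
alternative path, the covered steps (a step is covered if any of its
KO alternatives is present) reach at least two-thirds of the path's steps
— *all* steps for paths of three or fewer. "At least two-thirds" is a
lower bound, hence the ceiling, and a module of exactly three steps falls
under the all-steps rule. The two-thirds criterion is counted over
**steps**, consistent with the all-steps rule being phrased in steps; a
per-KO-fraction variant is implemented behind `rule = "ko_fraction"` and
differs exactly when steps have unequal numbers of alternative KOs.

Enrichment within a direction stratum (species whose coefficient has the
given sign, ranked by ascending p) uses a one-sided Mann-Whitney rank-sum
statistic — carriers concentrated at low ranks — reported as a
standardized, tie-corrected, continuity-corrected z-score with its normal
p-value; BH across modules within (exposure, direction). A permutation
oracle validates the normal approximation in the tests. Modules carried by
fewer than three species (or missing three non-carriers) in a stratum are
skipped with a warning.

Pairwise co-occurrence uses the exact combinatorial model: with
prevalences fixed, the co-occurrence count under independent placement is
hypergeometric, and `p_gt`/`p_lt` are the upper/lower tail masses
including the observed point (so `p_lt + p_gt >= 1`). Presence is
abundance strictly greater than zero, the same convention as the
prevalence filter. Pairs are classified positive/negative/random at
alpha = 0.05 with no multiple-testing correction — the convention of
probabilistic co-occurrence analysis — so edge counts should be read
descriptively; pairs whose extreme attainable tails cannot reach alpha are
flagged untestable.

# The synthetic cohort generator

The generator is a first-class module: its defaults define the study
conditions under which recovery is scored.

**Exposures.** A latent severity factor $h$ receives the BMI latent with
weight `confounding_strength` (default 0.45, yielding the moderate positive
BMI-AHI rank correlation typical of apnea screening cohorts; the acceptance
script reports the realized value as `spearman_bmi_ahi`). The three
parameter latents load on $h$ (loadings 0.8, 0.8, 0.6) with residual
correlations solved so the *total* latent correlations equal the
Greiner-transformed Spearman targets $r = 2\sin(\pi\rho_s/6)$ — defaults
0.92 (AHI-ODI), 0.56 (AHI-T90), 0.63 (T90-ODI). Marginals: AHI and ODI are
exponentiated Gaussians with medians 3.8 and 4.1 events/h and log-scale SD
1.2, reproducing the right-skew of event rates; T90 is a hurdle variable
with a 25% point mass at zero (the "T90 = 0" severity group) and a
logistic-normal positive part with median 2% bounded in (0, 100). The
point mass ties attenuate the realized T90 rank correlations by roughly
0.03; the generator's contract (±0.08 of target at n ≥ 2,000) absorbs
this, and the attenuation is part of what the hurdle is meant to emulate.
Setting every target to 1 collapses all three parameters onto monotone
transforms of $h$, the degenerate case used to test monotonicity.

**Abundances.** Zero-inflated log-normal on a latent Gaussian scale:
species $j$ has $y_{ij} = \mu_j + \beta_j h_i + \gamma_j m_i +
\sigma_j\varepsilon_{ij}$ with $\mu_j \sim N(-2, 1.5^2)$,
$\sigma_j \sim U(0.8, 1.6)$, and presence probabilities Beta-distributed
with mean `1 - zero_inflation` (default 0.7), which produces the heavy
right tail, sparsity and prevalence spread of shotgun relative abundances
without fitting any real dataset. $\beta_j = \pm$ `effect_size` for the
planted positive/negative species. The BMI-confounded species load with
$\gamma_j$ on $m$, the standardized log of **observed** BMI — deliberately
not on the BMI latent: these species exist to be removed by the
BMI-adjustment stage, and only a path through the measured trait is fully
closed by conditioning on it. Planted species are held at presence
probability ≥ 0.5 so they survive the 1% prevalence filter. Rows are
renormalized to sum to one.

**Function, events, outcomes, missingness.** Module definitions are
generated with 2-8 steps, 1-3 alternative KOs per step and a second path
for about a third of modules, so all three detection-rule branches are
exercised; planted modules are carried by 85% of positive species versus
12% background, non-planted modules by 30% of everyone. Event records are
drawn so that recomputing AHI/ODI/T90 from them reproduces the tabulated
values to within event-count rounding, and the `missing_ahi_fraction`
(default 10%, near the valid-AHI versus valid-oximetry gap of screening
cohorts) receives an air-flow recording under 4 h while oximetry stays
valid. Outcome species add `bp_effect_size` (default 2 mm Hg per SD of
rank-normal abundance, 0.6x for diastolic) to blood pressure with the sign
of their hypoxia effect; HbA1c carries no planted effect, mirroring a null
finding. AHI missingness is MCAR by default with a MAR option whose
probability increases with the BMI latent, used to stress the imputation
module. Medication flags are independent Bernoulli draws at configurable
prevalences.

**What the generator does not emulate.** Phylogenetic correlation between
species, read-depth variation and compositional measurement error,
realistic KO biochemistry, seasonal or plate batch effects on abundances,
and selection into the cohort. Passing recovery tests therefore shows that
the inference machinery is correct and calibrated under a plausible
data-generating process — not that the pipeline would reproduce any
particular real-world effect estimate.

# Numerical and design choices

* Severity boundaries are closed on the left (AHI 5 is "mild", 30 is
  "severe"); tertile/quartile breaks use type-7 empirical quantiles with
  ties at a break assigned to the lower group.
* The event-rate denominators are channel-specific (flow time for AHI,
  oximetry time for ODI/T90) because validity is assessed per channel; the
  alternative single-denominator reading is a one-line change in
  `compute_osa_parameters()`.
* Energy cleaning flags entries beyond mean ± 3 SD of log intake, with
  mean and SD computed once on the analysis sample before flagging; a zero
  SD flags nothing.
* Missing data propagate as missing labels or `NA`, never as zeros.
* All randomness flows from explicit integer seeds; per-purpose seeds are
  derived deterministically and kept below $2^{31}$. Identical
  configuration and seed reproduce every output byte for byte.
* Abundance files are rejected unless every row sums to 1 within $10^{-6}$;
  the generator itself closes rows to within $10^{-9}$.

# Problem sizes used by the test-suite

The packaged tests validate oracle equality at small n (exact), null
calibration with 1,000-5,000 replicates per statistic, and planted-effect
recovery on 20 replicate cohorts of n = 2,000 participants x 300 species
at effect size 0.5 — sizes chosen so the full suite exercises every stage
at meaningful power while remaining a routine local run. The
`scripts/acceptance.R` script regenerates the headline quantities on a
fresh seeded cohort of the same size.

# Known limitations

Partial Spearman p-values rely on the t approximation, which is slightly
conservative at small n; the bootstrap SE path is available where exact
small-sample behavior matters. The PERMANOVA implementation offers
sequential sums of squares only (the marginal variant is out of scope) and
free permutation rather than residual permutation. Pair classifications in
the co-occurrence network are uncorrected by design. The imputation module
imputes a single variable (AHI); chained multivariate imputation is a
non-goal.
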