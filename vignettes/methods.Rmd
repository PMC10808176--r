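---
title: "Methods: from historical genebank records to donor selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from historical genebank records to donor selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genebankgp)
```

# The problem this package addresses

Genebanks hold large historical screenings of seed quality traits --
grain protein content (%) and lysine content (per mille of the grain dry
mass) -- collected over many years under designs that no modern
statistician would sign off on: one dominant year holding most records,
the majority of accessions tested exactly once, year-to-year differences
both in level and in measurement precision, and occasional gross
transcription or laboratory errors. genebankgp turns such records into
outlier-corrected best linear unbiased estimates (BLUEs, "adjusted entry
means"), links them to genotyping-by-sequencing marker matrices, compares
four genomic prediction models under replicated cross-validation, predicts
the whole collection, and short-lists donor accessions that combine high
protein with high protein-independent lysine.

Every stage is exercised end to end on synthetic data whose statistical
structure mirrors that design, so the pipeline is testable without any
proprietary records.

# Phenotype curation

## Trimming

Two rules are iterated to a fixed point by `trim_records()`: years whose
accession set shares no accession with any other retained year are
dropped (they contribute no cross-year information and disconnect the
design), and accessions left with a single record are dropped
(unreplicated data cannot support a reliable entry mean). The iteration
matters: removing a year can orphan an accession and vice versa.

## The year model

`fit_year_model()` fits, by REML,

$$y_{ij} = \mu + g_i + a_j + e_{i(j)},
  \qquad a_j \sim N(0, \sigma_a^2),
  \qquad e_{i(j)} \sim N(0, \sigma_{e_j}^2),$$

with a residual variance *specific to each year* $j$ -- the defining
feature of data measured by laboratory campaigns of varying precision.
Genotype effects $g_i$ are fixed when BLUEs are wanted and random (variance
$\sigma_G^2$) when heritability is wanted.

The engine runs expectation-maximization on the mixed-model equations:
each iteration solves one sparse system of dimension
(accessions + years), so cost scales with the number of accessions rather
than records. The restricted log-likelihood is monotone along EM
iterations and convergence is declared when it changes by less than
1e-8 (cap 2,000 iterations; typical fits converge within 200, while
small datasets with a weakly identified year variance can crawl for over
a thousand). Two practical points deserve mention:

* **Boundary variances.** When almost all records of a year come from
  accessions measured only once, that year's residual variance is weakly
  identified and its REML estimate can sit at zero. EM approaches such a
  boundary only geometrically, so a component whose update falls below
  0.1% of the phenotypic variance is pinned to a boundary value of 1e-4
  of the phenotypic variance (small enough to be "zero" for any
  scientific purpose, large enough to keep the equations well
  conditioned). At the iteration cap each component is additionally
  tested against the boundary directly, and the pin is kept only when it
  raises the restricted likelihood; a Nelder-Mead polish on the
  log-variances is the last resort. Years sitting at the boundary are
  reported in the fit and their records are refused by the outlier test
  (below), because a standardized residual with an effectively-zero
  denominator is meaningless.
* **Numerics.** The quadratic form $y'Py$ is evaluated as
  $\hat e'R^{-1}\hat e + \hat u'G^{-1}\hat u$, a sum of non-negative
  terms; the textbook form $y'R^{-1}\hat e$ cancels catastrophically when
  a year variance is small.

Standard errors of the BLUEs are the plug-in generalized-least-squares
ones at the converged variance components, i.e. the square roots of the
fixed-effect block of the inverse coefficient matrix. They condition on
the estimated variances, as is conventional for entry means.

## Outlier correction

`detect_outliers()` standardizes each record's residual by its
year-specific residual standard deviation, converts to two-sided normal
p-values, and controls the familywise error by Holm's step-down at
`alpha` (default 0.05; the level is configurable because screening
conventions differ). Plug-in standardization is used rather than
leverage-corrected studentization: with the historical design's single
records per accession-year the leverage correction is not identified per
cell, and the plain standardized residual is the method the curation
literature for such data describes. `compute_blues()` then loops --
fit, flag, remove, re-trim -- until no record is flagged (cap 10 rounds),
and reports heritabilities from random-genotype fits before the first and
after the last removal.

## Heritability

With $\bar N_Y$ the mean number of years in which an accession was
tested, `estimate_heritability()` evaluates the entry-mean form
$h^2 = \sigma_G^2 / (\sigma_G^2 + \bar\sigma_e^2 / \bar N_Y)$ and the
plot-based form
$h^2_{pb} = \sigma_G^2 / (\sigma_G^2 + \bar\sigma_e^2)$, where
$\bar\sigma_e^2$ is the arithmetic mean of the year-specific residual
variances. The first measures the precision of the reported entry means;
the second, the repeatability of a single observation.

# Adjusting lysine for protein and seed size

Lysine content correlates strongly positively with protein content and
negatively with thousand grain weight (TGW), so raw lysine mostly ranks
protein. `fit_adjustment()` regresses the lysine BLUEs on the protein and
TGW BLUEs (ordinary least squares with intercept, over the accessions
carrying all three traits) and `adjust_lysine()` applies

$$\mathrm{Lys}_{adj} = \mathrm{Lys}
  - b_{Prot}(\mathrm{Prot} - \overline{\mathrm{Prot}})
  - b_{TGW}(\mathrm{TGW} - \overline{\mathrm{TGW}}),$$

genotype-wise. By the OLS residual property the adjusted trait is exactly
orthogonal to both predictors on the fitting set while keeping the raw
lysine mean. The regression is unweighted -- the BLUE standard errors are
ignored -- because the adjustment is meant as a plain re-expression of
the trait, not an error-in-variables model. The fitted coefficients and
predictor means are stored so the same fixed transformation can be
applied to predicted phenotypes of accessions outside the fitting set.

# Markers, kinships and population structure

`filter_markers()` applies, in order: drop monomorphic markers; drop
markers with more than 10% missing calls; drop markers whose rarer
homozygote class is below 10% of non-missing calls; drop markers with
more than 1% heterozygous calls (a selfing-crop bound); impute remaining
missing calls to the homozygous code of the marker's more frequent
("dominant") allele; drop markers below 1% minor allele frequency after
imputation. Two readings were genuinely open and are package decisions:
the "minimum homozygous count" rule is read as a bound on the *rarer*
homozygote class, and dominant-allele imputation is read as imputing the
more frequent allele's homozygous code -- the natural readings for an
inbred crop. Allele frequencies used downstream are computed from the
post-imputation matrix, a single reproducible source; under the 10%
missingness cap the difference from pre-imputation frequencies is
negligible.

`compute_grm()` builds the additive relationship matrix by VanRaden's
first method, $G = ZZ' / (2\sum_k p_k(1-p_k))$ with $Z$ the codes
centered by twice the allele frequency; `compute_epistatic()` builds the
additive-by-additive kernel as the Hadamard square $H = G \odot G$,
positive semidefinite by the Schur product theorem. Note that in a fully
inbred panel the mean diagonal of $G$ is about 2 rather than 1; all
downstream quantities are invariant to that scale, which is simply
absorbed by the variance components.

`rogers_distance()` uses the classical allele-frequency distance; for
biallelic loci with individual frequencies in {0, 1/2, 1} it reduces to
half the mean absolute code difference and lies in [0, 1]. Heterozygotes
surviving the 1% filter contribute frequency 1/2 rather than being set
missing. `pcoa()` performs classical metric scaling (through
`stats::cmdscale`); negative eigenvalues are dropped without a Cailliez
correction, as Rogers' distances are near-Euclidean at these scales, and
explained proportions are reported over the positive eigenvalues only.

# Genomic prediction models

Four models predict BLUEs $y$ from genomic information:

* **G-BLUP** (`fit_gblup()`): $y = 1\mu + g + e$,
  $g \sim N(0, G\sigma_g^2)$. REML via the eigendecomposition of the
  training block of $G$ profiles the restricted likelihood down to a 1-D
  search over the variance ratio; predictions for any accession in $G$
  follow from the BLUP conditional expectation
  $\hat g_{all} = G_{all,train}(G_{train} + \delta I)^{-1}(y - \hat\mu)$,
  $\delta = \sigma_e^2/\sigma_g^2$.
* **EG-BLUP** (`fit_egblup()`): adds $g_1 \sim N(0, H\sigma_{g_1}^2)$.
  The two variance ratios are estimated by Nelder-Mead on their
  logarithms (three starts, residual variance profiled out). Setting the
  epistatic ratio to zero reproduces G-BLUP, a nesting the test suite
  verifies.
* **Bayes A** (`fit_bayes_a()`): marker effects with marker-specific
  variances under a scaled-inverse-chi-square prior (a scaled-t effect
  prior), Gibbs-sampled with the residual-update scheme; compiled inner
  loops keep 12,000 iterations cheap.
* **Bayesian Lasso** (`fit_bayesian_lasso()`): the Park-Casella
  hierarchy -- conditionally normal effects with exponential mixing
  variances (double-exponential marginal prior) and a Gamma hyperprior on
  $\lambda^2$, which can be pinned for diagnostic limits.

Chain defaults are 12,000 iterations, 2,000 burn-in, thinning 5;
Bayes A uses 5 prior degrees of freedom; prior scales attribute half the
phenotypic variance to the markers (`prior_r2 = 0.5`). These follow
common whole-genome-regression practice and are configurable -- no chain
settings are dictated by the data themselves. Samplers draw from R's RNG,
so a seed makes every chain exactly reproducible. The Bayesian models use
the same centered marker coding as $Z$ in $G$, which keeps the
G-BLUP/ridge-regression equivalence exact and the coding consistent with
$H$. BLUE standard errors are not propagated as weights into any model;
the models see the entry means as data, matching how such predictions are
reported.

# Evaluation, selection and passport association

`make_folds()` builds balanced five-fold partitions (sizes differ by at
most one, remainder spread after shuffling), repeated independently;
`cross_validate()` scores one prediction ability -- the Pearson
correlation between BLUEs and pooled test-set predictions -- per model
and repeat, with all models sharing identical folds within a repeat and
variance components re-estimated inside every training fold so nothing
leaks from test to train. Repeats with zero-variance predictions yield an
undefined ability, recorded as `NA` and excluded from summaries with a
logged count.

`compare_derived_strategies()` contrasts predicting adjusted lysine
directly with predicting the three component traits and deriving the
adjustment from the predictions; the adjustment is refit inside every
training fold -- the conservative, leakage-free choice.

`predict_collection()` fits the chosen model on all accessions with
BLUEs and predicts every genotyped accession, summarizing separately by
training membership. `culling_select()` sets, per trait, a threshold at
`mean + qnorm(level) * sd` of the predictions -- the culling levels
0.99 / 0.999 are read as cumulative probabilities of the normal
distribution -- and selects accessions exceeding both thresholds;
selections at stricter levels provably nest inside laxer ones. An
empirical-quantile mode is available for audiences skeptical of the
normality reading. `altitude_association()` reports Pearson correlations
of predictions with collecting-site altitude over the accessions whose
passport data contain one.

# The synthetic-data generator

`sim_config()` / `simulate_genotypes()` / `simulate_trial()` /
`simulate_correlated_traits()` emulate exactly the features the analysis
must survive:

* a dominant year (default 90% of accessions) plus partially covered
  years, so single-record accessions and year disconnection arise
  naturally; the default expected records per retained accession (~2.4)
  match a historical multi-stage screening;
* year effects and year-specific residual SDs (default multipliers 0.7 to
  1.3 around the trait's error scale);
* gross outliers at rate 1.3% shifted six residual SDs with random sign
  -- unsigned contamination being the harder detection case;
* genetic values built from marker effects, with an optional
  additive-by-additive share generated as products of centered codes over
  200 random marker pairs, residualized against the additive part and
  rescaled so the genetic variance calibrates exactly;
* three correlated seed traits via a shared-factor construction
  (per-marker effect vectors drawn from a trivariate normal with targets
  +0.63 lysine-protein, -0.28 TGW-protein, -0.27 TGW-lysine), with TGW
  recorded for a 60% subset of accessions as typical when seed weight
  comes from a separate campaign;
* a collecting-site altitude coupled to the lysine genetic value
  (default correlation 0.5, mean 1200 m, SD 600 m).

`heritability_target` controls the *plot-based* ratio
$var(g)/(var(g)+\bar\sigma_e^2)$, exactly, by rescaling the drawn
effects -- exact control beats asymptotic control in small fixtures. The
entry-mean heritability of a simulated trial is therefore higher than the
target whenever accessions are tested in more than one year on average,
and recovery tests check the plot-based ratio. Trait scales (protein
17.61%, lysine 4.17 per mille, TGW 45 g, with error variances of the
order 2.7, 0.17 and 4 in squared trait units) mirror the magnitudes of a
historical wheat quality screen.

What the generator does **not** emulate: linkage disequilibrium (markers
are independent, so there is no population structure for PCoA to find and
prediction abilities reflect direct marker tagging only), genotype-year
interaction, spatial field trends, selection-driven missingness (records
missing at random given the year plan, whereas historical re-testing
targeted high performers), and multi-allelic or structural variation.
Passing tests therefore demonstrate the estimators' correctness and
calibration under the stated model, not robustness to every pathology of
real archives.

# Problem sizes and runtime choices

The shipped tests run the pipeline at sizes a laptop handles comfortably:
trials of 300-500 accessions over five years (~1,300 records), marker
panels of 250-1,000, cross-validation with 5 folds and 20 repeats, and
Gibbs chains of 12,000 iterations on 300 x 500 marker matrices. These
sizes were chosen so each statistical check has adequate power while the
whole suite stays in the minutes range; the same functions run unchanged
at collection scale (tens of thousands of accessions for BLUEs; kinship
construction is the only quadratic-memory step).

# Known limitations

* Year-specific residual variances need accessions with records in
  several years; designs where a year is populated almost entirely by
  single-record accessions leave that year's variance unidentified
  (reported as a boundary year, its records untestable for outliers).
* BLUE standard errors condition on estimated variance components and so
  slightly understate uncertainty for poorly replicated accessions.
* EG-BLUP's epistatic kernel inherits the usual caveat that $H$ captures
  marked additive-by-additive relationships; with few interacting pairs
  and modest panels its advantage over G-BLUP is small, and the package
  reports both so users can judge.
* The lysine adjustment is a population-level linear correction; its
  coefficients are only valid for accession sets resembling the fitting
  set.
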