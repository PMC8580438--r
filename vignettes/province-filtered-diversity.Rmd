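---
title: "Province-filtered diversity gradients: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Province-filtered diversity gradients: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(divprov)
```

This vignette is the package's own account of the science it implements:
the models, the assumptions behind them, the parameters that matter, the
numerical choices, and what the synthetic-data tests do and do not
demonstrate about real data.

## The question

Latitudinal diversity gradients are usually modelled directly against
abiotic variables — temperature above all, under the species–energy
hypothesis. An alternative reading is that faunas are organized into
biogeographic provinces with internally homogeneous species pools; cells in
the same province then share similar richness regardless of local
conditions, and the large-scale gradient is produced by *transitions
between provinces*. Under that reading the environment acts on diversity
only indirectly, by setting province boundaries. `divprov` implements both
competing models in one regression framework so the data can arbitrate.

## From records to a community matrix

Occurrence databases deliver one row per specimen with a taxon name and
coordinates. Three filters are applied before any analysis:

* records without a full species-level binomial are dropped (a pluggable
  validity predicate replaces a live registry query; a file-backed synonym
  list can be supplied);
* both coordinates must *state* at least two decimal places. Precision is a
  property of the recorded string — `"151.2"` and `"151.20"` are the same
  float but different claims — so the test counts digits in the text,
  trailing zeros included;
* unparseable coordinates reject the record (reason `"malformed"`), never
  abort the run.

Records are pooled into 0.5° cells anchored at integer degrees with
half-open `[lower, lower + 0.5)` spans, matching the resolution and layout
of the gridded climatology. Cells with fewer than 10 species or fewer than
150 records are excluded; the 150 threshold is where the estimators
demonstrably stabilize (below). Counts of records per species within a cell
("incidences") stand in for abundance; occurrence data record presences,
so these counts track sampling effort as much as true abundance, which is
why the bioregionalization later binarizes them.

## Diversity estimation

Raw richness is strongly effort-dependent, so four standardized measures
are computed per cell alongside it:

* **Fisher's α** — the shape parameter of the log-series solving
  `S = α log(1 + n/α)`. Monotone in `S` at fixed `n`; defined for
  `1 ≤ S < n`. Solved by bracketed root-finding on `[1e-6, 1e6]` with a
  Newton polish to a relative tolerance of 1e-9 (deterministic; the
  acceptance script verifies the round-trip at machine precision).
* **Simpson's D** — the inverse of the *unbiased* concentration
  `Σ xᵢ(xᵢ−1) / (n(n−1))`, whose expectation is free of sample size. The
  inverse form puts D on an effective-species-number scale that suits
  log-scale plotting; the complement form `1 − C` is a config switch, since
  the literature uses several variants.
* **Chao1** — `S + s₁²/(2 s₂)`, with the bias-corrected
  `S + s₁(s₁−1)/(2(s₂+1))` when no doubletons exist.
* **Corrected first-order jackknife (cJ1)** — the classical
  `J1 = S + s₁ (n−1)/n` systematically overshoots when doubletons are
  plentiful (the sampling curve is already flattening). The package's
  corrected form shrinks the jackknife addition by the singleton odds:
  `cJ1 = S + s₁ ((n−1)/n) · s₁/(s₁ + s₂)`. It reduces to `J1` when
  `s₂ = 0`, to `S` when `s₁ = 0`, and always lies in `[S, J1]`, which makes
  it more stable than Chao1 whose `s₁²/(2s₂)` term explodes at small `s₂`.
  The classical estimator sits behind the same interface
  (`corrected = FALSE`) as a documented fallback, and the correction lives
  in one function so an alternative published correction can be swapped in
  at a single point.
* **Coverage-based rarefaction / SQS** — richness standardized to a fixed
  sample *coverage* (quorum `q`) rather than a fixed count. The analytic
  interpolation curves are used: expected richness
  `E[S(m)] = S − Σ C(n−xᵢ, m)/C(n, m)` and estimated expected coverage
  `Ĉ(m) = 1 − Σ (xᵢ/n) C(n−xᵢ, m)/C(n−1, m)`, with full-sample coverage
  from the Good–Turing family correction
  `1 − (s₁/n)·(n−1)s₁/((n−1)s₁ + 2s₂)`. The routine returns `E[S]`
  linearly interpolated in coverage between the bracketing subsample
  sizes. Quorums above the full-sample coverage are refused — the package
  standardizes downward only, never extrapolates. The default `q = 0.5` is
  a mid-range quorum; it is exposed in the interfaces because no single
  value is canonical.

The tests verify the analytic curves against a genuinely independent
Monte-Carlo oracle that *simulates* both curves by repeated subsampling
(share-sum coverage with the finite-sample factor, interpolated at the
quorum the same way) and compares at `q ∈ {0.3, 0.5, 0.7}`. Two numerical
points are worth recording. First, per-replicate stopping rules ("draw
until the subsample's own coverage reaches q") carry first-passage and
selection biases of a few tenths of a species — properties of the stopping
rule, not of the analytic estimator — so the oracle estimates the expected
curves and reads off at their crossing. Second, the oracle's standard error
is computed from batch means (20 × 50 replicates) because the
coverage-curve uncertainty is shared across replicates; with that SE the
analytic and Monte-Carlo values agree with no detectable central bias.

`size_profile()` subsamples an assemblage without replacement at a ladder
of sizes. On an ideal log-series community (built deterministically from
the distribution's quantiles, 50 000 individuals) the means at 150 vs 5000
individuals agree within 5% for Fisher's α and Simpson's D, while raw
richness keeps climbing and everything drifts below ~150 individuals —
the quantitative justification for the 150-record cell filter.

## Bioregionalization

Provinces are estimated as *continuous loadings*, not hard clusters. The
binarized cell × species matrix is correlated cell-by-cell (Q-mode), and
the correlation matrix is factored — minimum-residual extraction by
default (principal-axis as the alternative; maximum-likelihood is
deliberately not offered since binary-derived correlations violate its
distributional assumptions) — followed by orthogonal varimax rotation to a
convergence of 1e-6. Factor signs are fixed so each factor's
largest-magnitude loading is positive, and factors are ordered by explained
variance. A cell loading ≈ 1 on one factor sits in a province core; a cell
splitting moderate loadings across two factors sits in a transition zone.
This representation tests for sharp boundaries *and* smooth gradients at
once, which hard clustering cannot.

The factor count is chosen by **parallel analysis**: the observed
eigenvalue scree is compared, rank by rank, with the 95th percentile scree
of 100 matrices obtained by permuting the observed data within columns.
Permutation (rather than Gaussian noise) respects the binary marginals of
the data; the retained count is the leading run of observed eigenvalues
above the permutation threshold. One structural fact discovered in testing
and worth knowing: K equal-sized, fully symmetric blocks span only K−1
contrast dimensions after centering, so the K-th ("shared") eigenvalue is
much smaller than the rest and is the one that decides retention. Realistic
worlds — unequal province extents, richness gradients — keep it comfortably
above the threshold.

**PAM clustering** (on Sørensen dissimilarity by default, Jaccard by
config) and **correspondence analysis** (SVD of the standardized residual
matrix, with per-axis inertia shares) serve as categorical and ordination
cross-checks on the factor solution. The PAM implementation solves small
instances (≤ 5000 candidate medoid sets) *exactly* by enumeration and
falls back to the deterministic BUILD + SWAP heuristic above that size;
plain BUILD + SWAP is a local search that misses the global optimum on a
few percent of small random instances, and where exactness costs
microseconds there is no reason to accept a heuristic. All tie-breaks are
lowest-index, so no randomness is consumed anywhere in the clustering.

## Regression layer

The eight abiotic variables are collinear (temperature with oxygen,
nutrients with each other), so they are first collapsed by an R-mode
varimax factor analysis into three factors — a multivariate alternative to
model selection that keeps every variable's information as loadings.
Factor scores (regression method, unit variance) enter the models.

Diversity is regressed on the three abiotic scores (abiotic-only layout)
and on K province loadings plus the three scores (combined layout), one
model per diversity metric. The response is log-transformed (diversity is
multiplicative across its range) and standardized; predictors are
standardized; slopes are therefore beta coefficients, comparable across
predictors. Each model is fitted twice:

* a **spatial error model** `y = Xβ + u`, `u = λWu + ε`, by maximum
  likelihood. `W` is a row-standardized 5-nearest-neighbour weights matrix;
  the kNN graph is symmetrized (neighbourhood union) before
  row-standardization so that `W` is similar to a symmetric matrix and its
  spectrum is real, letting the log-determinant term `Σ log(1 − λeᵢ)` be
  evaluated exactly from the eigenvalues. λ is found by golden-section
  search on the concentrated log-likelihood; its p-value is a likelihood
  ratio against λ = 0. The spatial *lag* model is one switch away; the
  error model is the default because the purpose is absorbing residual
  autocorrelation, not modelling diffusion.
* an **OLS companion** of the same design, whose adjusted R² is reported
  and whose p-values drive the significance flags (the tabular convention
  of general linear models). The two sets of betas agree within 0.05
  whenever the fitted spatial parameter is near zero — an invariant the
  tests enforce.

Significance is flagged at p < 0.001 in the model suites and p < 0.01 in
the path suite, both configurable. No multiple-testing correction is
applied in the path suite; instead, a dedicated null simulation quantifies
the consequence: on fully independent variables, the realized false-edge
rate is statistically compatible with the nominal per-test level.

**Key variables.** For the path analysis the abiotic set is reduced to
seven: latitude (always included), the variable with the highest absolute
loading on each of the three abiotic factors, and the variables of highest
uniqueness (variance the factors fail to capture) until the set is full;
ties break by table order. Latitude enters only here, not the model-suite
tables — it is a geometric proxy, not an abiotic mechanism, and the
factor-score models already span the smooth spatial field (a config flag
can add it to the suites).

**Path suite.** Every node — each key abiotic variable, each province
loading, diversity — is taken in turn as the dependent variable of one
multiple regression on all permitted other nodes, and every significant
coefficient becomes a signed directed edge. Province loadings are never
regressed on one another: they derive from a common rotation and are
mathematically interdependent, so such edges would be artifacts. The edge
list is the package's emulation of a structural equation model; no latent
variables are estimated.

## The temperature-niche null model

If provinces are defined from species distributions and species
distributions follow temperature, a province–diversity association could
be circular. The null model checks this: each species gets a temperature
range (min and max SST over its occupied cells — degenerate for single-cell
species, never wider than the observed temperatures); each null world fills
every cell with exactly its observed number of species, drawn uniformly
without replacement from the species whose range covers the cell's SST
("point" rule — self-consistent, since the ranges were built from cell
means; an "interval" rule using the cell's mean ± SD is a config option).
Candidate pools can never undershoot the quota when ranges come from the
same matrix, and the implementation asserts it. Each replicate then gets
its own Q-mode factor analysis (same factor count as the real analysis;
principal-axis extraction by default here, because its non-iterative cost
suits thousands of replicates and it agrees with minres to within rotation
noise) and the combined regression is refit against the *observed*
diversity — the null targets biogeography, not diversity, though
recomputing diversity from the null world is a config switch. One master
seed spawns per-replicate seeds, so any replicate is individually
reproducible. The default replicate count in tests and the acceptance
script is 100; the full-scale analysis is the same call with `n_reps` set
higher.

On a world where diversity genuinely follows temperature, the null
provinces organize into temperature-aligned bands (the share of SST
variance explained by the simulated dominant-province partition exceeds
0.9 in the median) and the temperature factor stays significant in
essentially all replicates. A subtlety found during development: on a world
whose diversity follows *position* rather than realized temperature, the
band loadings and the smooth temperature scores span the same function
space along a one-dimensional coast, and collinearity leaves no term
individually significant — the informative null-model comparison requires
diversity to carry temperature's own signal, wiggles included.

## The synthetic world

The generator is the package's measurement instrument, so its defaults are
fixed study conditions, not tuning knobs: 120 half-degree coastline cells,
5 provinces, 300-species pools sharing 10% of species with each neighbour,
4-cell transition zones, expected richness declining linearly from 80 to 30
species per cell, per-cell effort log-uniform on [150, 5000], SST declining
linearly from 29 °C with province-level offsets (SD 0.5 °C) and 0.3 °C
noise, salinity and nutrient fields driven by smooth latent waves
independent of temperature, and 2% each of records corrupted by a dropped
epithet or a one-decimal coordinate (exactly the records the ingest filter
rejects — the tests assert the counts match to the record).

Three design choices deserve their rationale on record:

* **Occupancy first, abundance second.** A species' rank in its province
  pool is its province-wide commonness; a cell includes a species with
  probability given by a soft cutoff (logistic, width 2 ranks, floor 0.01)
  at the cell's target richness. Present species then receive abundances
  drawn from the log-series with the cell's target α (largest abundances to
  the commonest ranks), reconciled to the cell's effort exactly. This makes
  Fisher's α meaningful by construction, plants the richness gradient
  exactly, and gives same-province cells the high compositional correlation
  real provinces show. The earlier, more obvious design — sampling records
  multinomially from a rank-probability curve — collapses realized richness
  in low-effort cells and splits province factors by effort; it was
  replaced at design time and the reason is worth remembering. The 1%
  inclusion floor plants rare vagrant occurrences, so composition is never
  perfectly nested (a perfectly nested world has a degenerate cell that
  contains every species, which breaks any correlation-based method).
* **Transition zones ramp between 35/65 and 65/35 blends.** The zone is
  defined as the region of genuinely ambiguous faunal affinity: a cell
  blended more strongly than about 2:1 toward one province is empirically
  indistinguishable from a core cell (its maximum loading rises above the
  conventional 0.6 reading threshold), so labelling it "transition" would
  plant a truth the data cannot show. Within the zone, inclusion is
  patchy — each transition cell holds its own random blend — so zones do
  not form their own pseudo-provinces.
* **Scenario worlds.** `province_mediated` gives each province a fixed
  Fisher's-α level (25, 10, 18, 8, 14 — deliberately non-monotone along the
  coast, so province identity is decorrelated from the smooth temperature
  field and mediation is identifiable); `direct_environment` disables
  province turnover (one global pool) and sets α = 2 + 0.6·SST from the
  *realized* temperature; `null_flat` fixes α = 12 and randomizes each
  cell's rank order (pure noise turnover). These encode the competing
  hypotheses the regression layer is supposed to tell apart, and the tests
  confirm it does: province terms (and only they) are significant with
  ΔadjR² > 0.2 in the first world, the temperature factor in the second,
  nothing in the third.

What the generator does *not* emulate: two-dimensional coastline geometry
(cells are ordered along latitude; spatial weights still work but
east–west structure does not exist), taxonomic synonymy, spatially
autocorrelated sampling effort, detection differences among species, and
dispersal or phylogenetic structure. Passing the recovery tests therefore
shows the pipeline's inferential machinery is sound under its own
assumptions — not that any particular empirical dataset satisfies those
assumptions.

## Problem sizes, tolerances, degenerate inputs

The test suite and acceptance script run at deliberately modest sizes
chosen once: 120-cell worlds, 100 null-model replicates, 1000 Monte-Carlo
subsampling replicates per SQS comparison (20 batches), 80 subsampling
replicates per size-profile point, 10 seeds per recovery claim, 50 random
instances for PAM optimality, 100 seeds for path-suite calibration. Root
finding for α is deterministic to 1e-9 relative error; varimax converges at
1e-6; factor-analysis uniquenesses are bounded in [0.005, 1]; eigenvalue
thresholds treat values below 1e-10 as rank deficiency. Degenerate inputs
are refused loudly rather than patched: all-singleton assemblages have no
Fisher's α, an infinite inverse-Simpson, and zero estimated coverage;
quorums above the estimated coverage are unattainable; zero-variance cells
cannot be correlated; constant predictors and singular designs are named in
the error. Empty candidate pools in the null model name the offending cell.

## Known limitations

* The cJ1 correction is this package's documented shrinkage form (see
  above), isolated in one function precisely so a different published
  correction can replace it without touching anything else.
* SAR coefficient p-values are asymptotic (conditional on the ML spatial
  parameter); for the cell counts involved this is standard practice, but
  small-sample inference on λ itself rests on the likelihood-ratio
  approximation.
* The path suite is a screen, not a causal identification procedure: edges
  are conditional associations at a nominal level, with the false-edge
  rate quantified by simulation rather than corrected away.
* Parallel analysis on binary, structured data is known to be liberal;
  the dual reporting (parallel analysis plus scree inspection) exists
  because reasonable procedures disagree on real data.
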