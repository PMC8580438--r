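# divprov

Do large-scale diversity gradients track abiotic conditions directly, or are
they filtered through biogeographic province structure? `divprov` is an R
package for testing exactly that question on point occurrence records of
coastal marine faunas (or any gridded assemblage data). It implements a
complete, reproducible pipeline:

1. **Ingest** — filter Darwin-Core-like occurrence records (full binomial
   names; coordinates stated to ≥ 2 decimal places), pool them into 0.5°
   grid cells, drop cells with fewer than 10 species or 150 records, and
   build the cell × species incidence-count matrix joined to a per-cell
   environmental table (SST mean/SD, salinity mean/SD, oxygen, nitrate,
   silicate, phosphate).
2. **Diversity** — per-cell sampling-standardized diversity: Fisher's *α*
   (the *α* solving *S* = *α* ln(1 + *n*/*α*)), the inverse unbiased
   Simpson index 1 / [Σ *x*ᵢ(*x*ᵢ−1)/(*n*(*n*−1))], Chao1
   (*S* + *s*₁²/2*s*₂), a corrected first-order jackknife, and analytical
   coverage-based rarefaction (shareholder quorum subsampling) at a
   configurable coverage quorum *q*.
3. **Bioregion** — continuous biogeographic provinces as cell loadings from
   a Q-mode varimax factor analysis of the binarized cell × species matrix,
   with the factor count chosen by parallel analysis; PAM clustering and
   correspondence analysis as cross-checks. High loadings mark province
   cores, middling loadings mark transition zones.
4. **Models** — R-mode varimax factor analysis of the eight abiotic
   variables (3 factors), maximum-likelihood spatial-error autoregressions
   of log diversity on abiotic factors ± province loadings with
   standardized (beta) coefficients and OLS companions, key-variable
   selection by factor loadings and uniqueness, and a path-regression suite
   that emulates a structural equation model over environment, provinces
   and diversity.
5. **Null model** — a temperature-niche null: rebuild presence–absence
   worlds where each cell draws its observed number of species uniformly
   from the species whose temperature range (min/max SST over occupied
   cells) covers the cell, then rerun the bioregionalization and regression
   across replicates.
6. **Synth** — a synthetic-data generator with planted provinces,
   gradational transition zones, a latitudinal richness gradient, log-scale
   effort variation and record-level noise, so every claim the pipeline
   makes is testable against known truth.

## Worked example

Generate a world in which diversity is a pure function of province
identity, and ask the models which driver they see:

```r
library(divprov)

w   <- generate_scenario("province_mediated", seed = 1)
cm  <- ingest(w$records, w$env)
div <- diversity_table(cm)
fs  <- bioregion_fa(cm, n_factors = 5)
ab  <- abiotic_fa(cm$env)

m1 <- model_suite(div, ab, coords = cm$cells,
                  metrics = "fisher_alpha")$fisher_alpha
m2 <- model_suite(div, ab, provinces = fs$loadings, coords = cm$cells,
                  metrics = "fisher_alpha")$fisher_alpha
```

This prints (abbreviated):

```
> m1$adjusted_R2
[1] 0.236
> m2
regression_result [ fisher_alpha ] n = 117  adjR2 = 0.963  spatial error param = -0.218
       term    beta  p_value significant
1 province1  0.0596 5.02e-01       FALSE
2 province2  0.3245 4.48e-07        TRUE
3 province3 -0.2402 2.91e-04        TRUE
4 province4  0.6685 1.25e-12        TRUE
5 province5 -0.4858 1.30e-11        TRUE
6  abiotic1 -0.0028 9.67e-01       FALSE
7  abiotic2 -0.0259 7.79e-01       FALSE
8  abiotic3  0.0200 6.21e-01       FALSE
```

The abiotic factors alone explain 24% of the variance in Fisher's *α*;
adding the five province loadings raises the adjusted R² to 0.96, the
province terms carry the significance (p < 0.001), and no abiotic factor
retains any direct effect — the planted mediation structure, recovered.
Running the same models on a `"direct_environment"` world flips the verdict:
the temperature-dominated abiotic factor becomes the significant predictor.

A full run (including PAM clusters, correspondence analysis, the path suite
and the temperature null) is one call:

```r
run_all(list(out_dir = "run1", seed = 1,
             synth = list(scenario = "gradient"),
             nullsim = list(enabled = TRUE, n_reps = 100)))
```

which writes per-stage CSVs, a GeoJSON province map and a `manifest.json`
with per-stage output hashes.

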