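Package: divprov
Title: Province-Filtered Diversity Gradients from Occurrence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for testing whether continental-scale
    diversity gradients are governed by biogeographic province structure
    rather than directly by abiotic conditions. Grids point occurrence
    records into 0.5-degree cells, computes sampling-standardized diversity
    (Fisher's alpha, unbiased Simpson, Chao1, corrected jackknife, and
    analytical coverage-based rarefaction), derives continuous province
    loadings by Q-mode varimax factor analysis with parallel-analysis factor
    retention, fits spatial autoregressive and ordinary regressions of
    diversity on abiotic factors and province loadings, emulates a
    structural-equation path analysis with a suite of multiple regressions,
    and runs a temperature-niche null model of community assembly. A
    synthetic-data generator with planted provinces, transition zones and
    environmental gradients makes every stage testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    vegan,
    MASS
Config/testthat/edition: 3
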