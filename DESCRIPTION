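Package: paleofind
Title: Continental-Scale Fossil-Hunting Suitability Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples three per-grid-cell suitability models to rank where new
    fossils of a taxon are most likely to be found: a palaeo-climate envelope
    model of where the taxon lived (Bioclim, a MaxEnt-style penalised
    presence-background model, and a quadratic logistic GLM, combined as a
    skill-weighted ensemble over palaeoclimate time slices), a logistic model
    of geological suitability for fossil preservation (rock, lake and cave
    predictors), and a logistic model of present-day discovery suitability
    (erosion proxies) with sampling-bias correction via reciprocal-probability
    observation weights from a BIC-selected accessibility model. The three
    surfaces are rank-rescaled and averaged into a fossil-potential map, with
    cross-validation (true skill statistic, AUC), Kolmogorov-Smirnov and
    probability-ratio validation against independent sites, and a synthetic
    continent generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
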