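---
title: "Modelling fossil potential: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fossil potential: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`paleofind` ranks 1°×1° grid cells by their potential to yield new fossils
of a taxon. The premise is that a productive cell must satisfy three
conditions at once: the taxon lived there at some point while it existed
(climate), its remains could be trapped and preserved there (geology), and
present-day conditions expose and reveal them (erosion and
discoverability). Each condition gets its own presence-background model;
because true absences are unknowable for fossils, raw model outputs are
interpreted as *rankings*, rank-rescaled to [0, 1], and averaged with
equal weights into the final potential surface. This vignette explains the
models, the tunable parameters, the synthetic-data generator used to test
the pipeline end to end, and the design decisions taken where the
methodology was genuinely open.

## The three models

### Climate envelope through time

Only reliably dated fossils (age-quality grades A* and A) train the
climate model; cells containing nothing but unreliably dated fossils are
held out as independent validation sites. Each training fossil is matched
to the palaeoclimate stack by selecting all slices within `k_sd` age
standard deviations of its mean calibrated age (the nearest slice is
always included, so a zero age SD degrades gracefully to nearest-slice
matching) and averaging temperature and precipitation with Gaussian
weights `w_i ∝ exp(−(age_i − age_mean)² / (2·age_sd²))`. The kernel SD
equals the fossil's own age SD — the only uncertainty measure available —
so poorly dated fossils smear their climate over more slices. `k_sd`
defaults to 2; 1 is the other published setting, and a run may execute
both and average the resulting climate vectors. We do not interpolate
between slices.

Pseudo-absences come from fossil sites where the focal taxon is absent, so
they inherit the presences' sampling biases, and are restricted to
climates outside the presence envelope (temperature *or* precipitation
beyond the 5th–95th presence percentiles) to limit false absences. Ten are
drawn per presence; when fewer are eligible, all of them are used.

Three model types span the bias-variance range practitioners expect:

* **Bioclim** — a rectilinear percentile envelope. A point's score on one
  variable is `2·min(p, 1−p)` where `p` is its percentile position among
  presence values (share of presence values ≤ the point), and the overall
  score is the minimum across variables: 1 at the presence median, 0 at or
  beyond the presence range. This is the tail-doubling variant; a
  one-sided variant exists in the literature, and the choice matters only
  for asymmetric envelopes. A variable constant among presences scores 1
  at that value and 0 elsewhere.
* **Quadratic logistic GLM** — presence vs pseudo-absence on temperature,
  precipitation and their squares, allowing an interior optimum per axis.
  Product terms are omitted by default to keep the response surface
  axis-aligned and estimable from small samples. Because pseudo-absences
  are deliberately drawn outside the envelope, quasi-separation is common;
  it is detected and answered with a ridge-penalised fallback and a
  warning rather than silently divergent coefficients.
* **MaxEnt-style model** — an L1-penalised logistic presence-background
  fit on standardized linear, quadratic and product features, the
  penalised-GLM formulation equivalent to MaxEnt's feature-class model.
  The penalty (`regularization`, default 0.01 on standardized features)
  trades envelope sharpness against overfitting; scores are rescaled to
  [0, 1] by the background minimum/maximum.

Each model is cross-validated two ways: *spatio-temporal* (repeated random
5-fold over pooled presences and pseudo-absences) and *temporal-only* (one
round per time slice containing presences, holding that slice out — a
stricter transferability test). Each round reports the TSS at the
TSS-maximising threshold and the AUC on the held-out fold. The ensemble
projects each model onto every slice from the taxon's youngest fossil
backwards, weighting models by their median spatio-temporal TSS (negative
weights clipped to zero — a model with no skill should not vote), averages
across slices, flags cells whose climate falls outside the pooled training
range of any variable as extrapolation, and rank-rescales.

### Preservation

A logistic regression of all-taxa fossil presence per land cell — any
taxon, any age grade, since any fossil proves preservation is possible —
on suitable-rock cover, lake cover and cave presence. The response is
presence/absence rather than fossil counts to avoid double-counting
aggregated prospecting. Geology is treated as constant over the late
Quaternary. Continuous predictors are standardized before fitting
(coefficients are reported on both scales); whether the source analyses
transformed covers is not documented, so untransformed fractions are used.

### Discovery and sampling bias

Erosion exposes fossils: the discovery model regresses all-taxa fossil
presence on mean slope, rain intensity (annual precipitation divided by
annual rain days) and bare-soil cover. Because prospecting concentrates
near people, a plain fit would confuse accessibility with discoverability.
All 16 logistic models on subsets of four accessibility proxies
(population density, road density, distances to large and medium cities)
are ranked by BIC — ties resolved toward the smaller model — and the
winner's predicted sampling probability `p̂` yields observation weights
`1 / max(p̂, ε)`, normalized to mean 1 so the effective sample size is
preserved. The floor `ε` (default 0.01) bounds any single cell's weight at
`(1/ε)/mean(w)`; unbounded reciprocals would let one remote cell dominate
the fit. Predictions use the fitted coefficients with *no* weights:
accessibility affects whether a fossil has been recorded, not whether it
is physically discoverable.

A scope note on what this weighting can and cannot fix. Inverse-effort
weighting changes which parts of covariate space dominate a misspecified
fit; it cannot undo thinning of the response itself. In simulation, when
detection simply multiplies true presence probability everywhere
(`p_obs = q·s`), reciprocal weighting *amplifies* slope bias, because it
emphasises exactly the cells whose responses are most thinned. The regime
where it demonstrably helps — and the regime the package's bias-recovery
simulation encodes — is effort saturation: baseline prospecting suffices
to detect fossil-bearing cells everywhere, while surplus effort near
cities inflates apparent presence there. Downweighting the saturated,
accessible cells then recovers the erosion coefficients with smaller
absolute bias. Users should judge which regime their data resemble before
leaning on the corrected coefficients.

### Combination, thresholds and validation

Each surface is rank-rescaled — `(rank − 1)/(n − 1)` with average ranks
for ties (symmetric and standard; a constant surface maps to 0.5) — and
the combined potential is their weighted mean (equal weights by default;
skill-weighted combination is exposed via `weights` but not studied).
Extrapolation flags propagate as a union but never zero out values.

Binary "suitable areas" come from thresholds maximising TSS, with ties
resolved toward the *lower* threshold: for fossil hunting, missing a
presence costs more than surveying extra cells. Independent validation
uses the unreliably dated cells three ways: the two-sample
Kolmogorov–Smirnov statistic `D` against random land cells (an effect
size, not a test — no p-values are attached), the TSS against random
pseudo-absence sets (10 per validation presence), and probability ratios
`[|fossil ∩ area|/|area|] / [|fossil|/|land|]` for the climate area, the
preservation∩discovery overlap, and the three-way overlap. Every surface
is evaluated against the *same* random sets (common random numbers), so
comparisons between the combined map and its components are paired rather
than clouded by independent draw noise. Random sets exclude the validation
cells themselves but may include other fossil cells, matching
presence-background semantics; both choices are switchable.

## The synthetic continent

`synthetic_world_config()` defines a forward model that inverts every
assumption above, giving known ground truth:

* **Grid**: 60×60 one-degree cells, ~88% land (a smooth-field coastline).
* **Climate**: smooth present-day temperature (latitudinal gradient) and
  precipitation (west–east gradient) fields; 27 slices at tiered ages
  (2 ka steps to 22 ka, 6 ka to 80 ka, 8 ka to 120 ka), mirroring how
  reconstructions resolve the recent past more finely; a glacial
  excursion centred on 20 ka (−4 °C, −250 mm at full amplitude) plus a
  small drift-scaled per-slice anomaly. Setting the drift amplitudes to
  zero freezes the climate exactly.
* **Spatial grain**: climate fields are continental-scale smooth (few
  broad basis bumps), while geological and erosion fields (rock, lakes,
  caves, slope, bare soil) are deliberately much finer-grained (30–40
  small bumps). This mirrors reality — rock units and topography vary at
  ~100 km scales, climate at 1000 km scales — and it matters
  statistically: with only a handful of independent spatial degrees of
  freedom, per-world logistic recovery of the preservation coefficients is
  unstable, a weakness the real analysis would share if its predictors
  were as smooth as its climate.
* **Processes**: true occurrence is a bivariate Gaussian envelope in
  (T, P) (optimum 22 °C / 800 mm, tolerances 3 °C / 250 mm); true
  preservation and exposure are logistic in their layers (slopes 2, 1.5, 1
  for rock/lake/cave; 1, 0.6, 0.8 for slope/rain/bare on z-scales); the
  sampling probability is logistic in accessibility built from 2 large and
  6 medium synthetic cities.
* **Fossils**: 150 focal-taxon records land in (cell, slice) pairs with
  probability ∝ occurrence × preservation × exposure × sampling; 300
  background-taxa records omit the occurrence term and emulate the rest of
  a continental fossil database — they supply the pseudo-absence pool and
  the all-taxa response of the preservation and discovery models. Ages are
  snapped to slice ages before noise (SD 0.5 ka) so temporal-only
  cross-validation has well-defined rounds; per-record age SDs are drawn
  from 1–4 ka; 25% of focal records are graded B/C (unreliable), yielding
  ~25–40 independent validation cells per world, comparable to real
  validation sample sizes.

What passing tests on this world do *not* show: real palaeoclimate
reconstructions carry structured (not smooth-random) errors; real fossil
taphonomy is taxon- and facies-specific rather than a clean logistic;
translocation, dating error correlations and coastline change are absent;
and the generator's detection model is exactly the one the discovery
estimator assumes in its favourable regime.

## Numerical choices and problem sizes

Weights in the Gaussian age kernel are normalised to sum to one (asserted
to 1e−12); convexity bounds every matched climate between the per-slice
extremes. Threshold sweeps evaluate every distinct score, the midpoints
between consecutive distinct scores, and one candidate above the maximum
(the all-unsuitable rule). The AUC uses the midrank (Mann–Whitney)
formulation, ties counting one half. Degenerate inputs have defined
behaviour throughout: constant surfaces rank-rescale to 0.5, constant
Bioclim variables score as point masses, zero-rain-day cells with zero
precipitation yield zero rain intensity and error otherwise, and empty
classes raise errors rather than NaNs.

Default analysis effort reproduces the published settings (100 rounds of
5-fold cross-validation, 1000 random validation sets). The test suite and
the acceptance script run the same estimators at reduced effort — 2–3 CV
rounds, 100–200 random sets, 10–20 replicate worlds — which changes the
precision of skill estimates, not the data-generating conditions; those
sizes are stated in the tests themselves.

## Known limitations

The package inherits the method's core assumptions: two climate variables
may under-describe a taxon's niche; the preservation and discovery models
are deliberately simple logistic forms; the sampling-bias correction only
helps in the saturation regime discussed above; and cell counts (e.g. how
many cells "encompass" a continent) depend on the land mask supplied by
the user, so no fixed cell total is asserted anywhere. Raster I/O is a
plain-text CSV-plus-YAML-sidecar format and a tabular aggregation path for
finer grids; reprojection and sub-degree analysis are out of scope.
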