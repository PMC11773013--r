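---
title: "Methods: rarity, protection and timber availability from cluster-plot inventories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rarity, protection and timber availability from cluster-plot inventories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarewoods)
```

## The sampling design and why expansion factors exist

The package targets inventories built from cluster plots: 1 ha square
clusters with four 50 × 20 m (0.1 ha) plots at the corners. Every stem
with DBH ≥ 10 cm is measured over the whole plot; stems with
5 ≤ DBH < 10 cm are measured only in one 25 × 10 m subplot, a quarter of
the plot. A small stem recorded in the subplot therefore represents
`1 / subplot_fraction = 4` stems at plot scale, and any per-area quantity
must use this expansion factor. The DBH intervals are half-open
(`[5, 10)` subplot-only, `[10, 20)`, `[20, 30)` … for stem-form classes)
so a boundary stem is never counted twice; DBH is stored in cm at 0.1
precision.

Two deliberately different counting rules coexist:

* **Densities** (stems per hectare) are expansion-weighted:
  `stems_per_ha()` sums expansion factors and divides by
  `n_plots × plot_area_ha`, where `n_plots` counts all surveyed plots of
  the stratum, including plots without records.
* **Rarity and protection counts are raw.** The Rabinowitz abundance
  criterion ("abundance > 2") refers to recorded individuals, and the
  protection index is a ratio of occurrence records, so neither is
  expansion-weighted.

An *occurrence* is a plot-level presence: a species seen in a plot counts
once there, however many stems were measured. Protected-area membership is
treated as a property of the plot, not of the stem row. The geographic
occupancy unit defaults to the cluster — clusters are the spatially
independent sampling locations, while plots within a cluster sit 100 m
apart and are spatially dependent — with plot-level occupancy available via
`build_profiles(unit = "plot")`.

## The classification and index machinery

`classify_rabinowitz()` crosses three binary criteria, with the boundary
conventions applied as strict printed inequalities:

| criterion | favourable | unfavourable |
|---|---|---|
| geographic distribution | wide: occupancy > 10 % of units | narrow: ≤ 10 % |
| habitat specificity | various: > 1 habitat | single: 1 |
| population size | large: abundance > 2 | small: ≤ 2 |

yielding `Common` and forms 1–7 in the canonical order (wide/various/small
= Form 1 … narrow/single/small = Form 7). The abundance criterion defaults
to the **maximum per-habitat abundance** ("large somewhere"), matching the
framework's original intent; `rarity_thresholds(abundance_scope = "total")`
switches to the total. Exactly 10 % occupancy is narrow and abundance
exactly 2 is small, and the acceptance tests pin these boundaries.

The continuous indices in `maciel_indices()` are this package's own
normalizations of the three criteria (the literature gives the index names
and semantics but not closed forms): `gri = 1 − occupancy`,
`hsi = 1 − (h−1)/(H−1)` (1 by convention when the region has a single
habitat), and `psi = 1 − log(1+n)/log(1+n_max)`. The log compression makes
`psi` separate scarce species rather than re-ranking the dominant tail.
All are in [0, 1], higher = rarer, and `ri` is their mean. Values are
comparable within a run, not across implementations.

`protection_index()` is the exact ratio of in-PA occurrences to total
occurrences; the three status levels are boundary-exact (`highly` only at
PI = 1, `poorly` only at PI = 0).

## Richness and β-diversity

`chao1()` implements the bias-corrected estimator
`S_obs + f1(f1−1)/(2(f2+1))` with the standard companion variance, whose
square root is reported as a standard error (the "± value" convention).
`ace()` uses the conventional rare-species cutoff of 10; when every rare
species is a singleton the coverage estimate is zero and the function
falls back to Chao1 with a warning. ACE is clamped below at observed
richness: an extrapolative estimator under `S_obs` is uninterpretable.

`pairwise_beta()` and `multisite_beta()` implement the Sørensen
dissimilarity partition into Simpson turnover and nestedness-resultant
components, on presence/absence only (the compositional questions the
package answers are presence-based; abundance-weighted variants are out of
scope). The multiple-site form uses the pairwise-sum formulation and
reduces exactly to the pairwise partition at two sites. Degenerate
convention: against an empty assemblage the dissimilarity is pure
nestedness (turnover 0); two empty assemblages are an error.

## What the synthetic generator emulates

`generate_census()` simulates a complete enumeration (every stem ≥ 5 cm
over whole plots) of a community whose defaults are chosen once to mirror
the structure of a national miombo inventory at desk scale:

* **Frame**: 75 clusters (54 humid / 15 semi-arid / 6 rainy, the ~72/20/8
  plot proportions of the emulated survey), four 0.1 ha plots each — 30 ha
  surveyed. Plot-level PA membership with probabilities 0.24/0.20/0.27 by
  habitat.
* **Abundance**: lognormal (meanlog 3.0, sdlog 2.2), rounded, minimum 1.
  This reproduces the emulated inventory's singleton + doubleton share
  (~17 % of species) and keeps the majority of species below 1 stem/ha at
  the 30 ha scale. Full-scale percentages (e.g. 90 % of species below
  1/ha over hundreds of surveyed hectares) are not reproducible at desk
  scale, and the generator does not try: the scaled-down community is
  rarer-looking overall (~70 % of species rare).
* **Ranges**: contiguous cluster blocks within each habitat (cheap spatial
  aggregation). 33 % of species are narrow-ranged, with narrow ranges
  assigned preferentially to regionally scarce species — the classic
  positive abundance–occupancy relationship — while still allowing
  narrow-but-locally-abundant species (Form 6). 40 % of species are
  single-habitat specialists.
* **Stems**: DBH from a Weibull(1.3, 12) left-truncated at 5 cm
  (small-stem dominated; ~1 % of stems reach 40 cm), and stem form drawn
  per DBH class from `default_stem_form_probs()`, where straight SF1 stems
  dominate small classes (74 %) and deteriorate with size (47 % at
  ≥ 40 cm).

The truth table records each species' *realized* occupancy, habitats and
abundance and the rarity form obtained by applying the same thresholds to
those census quantities. Running the pipeline on the unthinned census must
therefore recover the true form for 100 % of species; this is a
self-consistency guarantee of the whole data path (profile building,
counting rules, boundary handling), not an inference claim.

`apply_measurement_protocol()` simulates the subplot rule as independent
thinning of small stems with retention probability `subplot_fraction`,
rather than placing stems in explicit within-plot geometry. The analysis
never uses within-plot coordinates; the only consequence of the subplot
rule it can see is the inclusion probability, which thinning reproduces
exactly. Consequently the expansion-weighted small-stem density is
design-unbiased for the census density, which the tests verify by
Monte-Carlo (200 thinning replicates; relative bias of the mean under
0.2 % in practice against a 2 % acceptance band). What thinning does *not*
emulate: within-subplot spatial clumping, measurement error, or detection
failure — so passing tests validate the estimators under the design
assumptions, not robustness to field imperfections.

## The timber screen

`assess_harvest()` evaluates each timber species per habitat, because a
species can be viable in one ecoregion and absent in another. The decision
requires, jointly: legal timber status; the rarity form `Common` when
`require_common` is on (a species exhibiting geographic rarity, numerical
rarity or habitat specificity may not be harvested); a habitat in
`allowed_habitats` (default humid only); and an expansion-weighted density
of stems at or above the species' minimum felling diameter — computed
outside protected areas only — of at least `min_harvest_density_per_ha`.
The default legal minimum of 1 stem/ha is the viability benchmark
commonly used for commercial-sized trees and is policy-configurable, as is
the default 40 cm MFD. All failed conditions are reported as denial codes
(`NOT_TIMBER`, `RARE_FORM`, `NOT_GENERALIST`, `HABITAT_RESTRICTED`,
`LOW_DENSITY`, `NO_HARVESTABLE_TREES`), never only the first, so a policy
change's effect can be read off the reason lists. Stems lacking a
stem-form score count in densities but are excluded from the per-class
SF1/SF2/SF3 profiles, which are conditional on scoring; empty DBH classes
are omitted rather than zero-filled.

## Numerical and degenerate-input choices

* Abundance vectors for richness estimators must be positive integers;
  empty vectors, zeros and non-integers are errors rather than silent
  drops.
* `ace()` with no rare species returns `S_abund` (= `S_obs`); with
  `N_rare = 1` the heterogeneity term is set to 0.
* A survey frame with a single occupied cluster makes every species
  geographically "wide" (occupancy 1); callers analysing a fragment of a
  larger survey should pass `total_units` explicitly.
* Species names are joined after trimming, whitespace-collapsing and
  case-folding only — no fuzzy matching, so metadata joins are
  deterministic.
* Report percentages are rounded half-up to integers, with raw proportions
  kept alongside.

## Problem sizes used in the tests

The default validation community is 200 species on 75 clusters
(~30,000–60,000 stems depending on seed); the ground-truth recovery
acceptance test uses 300 clusters and 200 species; oracle-equivalence
sweeps use 500 random instances per estimator and 1000 random presence
matrices for the partition identity; the unbiasedness check uses 200
thinning replicates of one census. These sizes give the Monte-Carlo checks
comfortable margins (e.g. the thinning check's standard error is ~0.1 %
against its 2 % band) while keeping the whole suite quick to run.

## Known limitations

* The Maciel-style indices are implementation-defined normalizations;
  cross-study numeric comparisons of `gri`/`hsi`/`psi`/`ri` are not
  meaningful.
* Occupancy-based range classification depends on the sampling frame: the
  "wide" threshold is a fraction of *surveyed* units, so occupancy
  proportions from differently sized frames are not comparable.
* The generator's contiguous-block ranges produce aggregation but no
  distance-decay or climate-driven suitability structure; habitat
  assignment of generalists is unweighted.
* Incidence-based estimators (Chao2/ICE), rarefaction curves and
  abundance-based β variants are intentionally out of scope.
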