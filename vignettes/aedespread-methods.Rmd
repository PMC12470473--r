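---
title: "Methods: municipal-scale surveillance analysis of invasive Aedes spread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: municipal-scale surveillance analysis of invasive Aedes spread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aedespread)
```

## The problem

Invasive *Aedes* mosquitoes (the tiger mosquito *Ae. albopictus*, the
yellow-fever mosquito *Ae. aegypti*, and the bush mosquito *Ae. japonicus*)
spread across a country municipality by municipality, through a mix of
short-range contagious dispersal and rare human-mediated long jumps. Two
surveillance strategies observe this process: professional field sampling
(ovitraps, larval surveys, adult captures), which is authoritative but
proximity-targeted and slow, and citizen-science reporting through a mobile
app, which is population-driven and reaches anywhere people live. This
package analyses a per-municipality table of first-detection years by
strategy, together with a municipality registry (LAU2 code, province,
surface, population, centroid), and answers three questions:

1. *Who found what first?* Five-category attribution per municipality and
   species: field-only, citizen-only, both in the same year, both in
   different years, no detection — plus annual/cumulative spread summaries,
   strategy shares, confirmation delays and trend statistics.
2. *Does the invasion track human density?* A province-stratified
   permutation test comparing the population density of newly detected
   municipalities against spatially matched non-detected ones, year by year.
3. *How far does each strategy see?* The great-circle distance from each new
   detection to the nearest municipality positive in any earlier year,
   compared between strategies with a t-test and a two-way ANOVA with Tukey
   contrasts.

Because the consolidated national dataset is an external download, the
package ships a stochastic invasion-plus-surveillance simulator with known
ground truth; every analysis stage is validated against it.

## Data model and attribution

A detection record holds, per municipality and species, a field first-year
and/or a citizen first-year; absence is an empty cell and never a zero,
since "no detection by that strategy" has no year. Field years start in 2004
and citizen years in 2014 (the platform's launch), both bounded above by a
configurable horizon (default 2024). The first detection is the earlier of
the two years; equal years are "simultaneous" unless a documented-sequence
override names the strategy whose chronological priority is established.
Overrides are representable but never inferred — the loader takes the file
as already reconciled.

Reported category counts always partition the registry per species, which is
the invariant the test suite asserts. Eradicated populations (an
archipelago-specific situation) are a municipality-level flag: listings
retain the detection, analyses exclude it through an exclusion rule.

Two reporting conventions matter when comparing against published summaries:

* period lengths are **inclusive** year counts (2004–2013 is 10 years,
  2014–2024 is 11), and
* a per-strategy annual rate counts simultaneous detections in **both**
  strategies' numerators — each strategy did make the finding that year —
  so the two rates deliberately double-count category-3 municipalities.

Percentages and distances are rounded half away from zero only at the
reporting layer (`round_half_up()`); every internal value keeps full
precision.

The trend fit (`linear_trend_r2()`) regresses the **annual new-detection
count** on calendar year by default. Fitting the cumulative series instead
is exposed as a switch (`on = "cumulative"`) because published R² values of
this kind are sometimes computed on either basis; the package asserts
nothing about which basis a given published figure used.

## The province-stratified permutation test

For each year with at least `min_n` new detections (default 3 — a first
invasion year seeded by a couple of municipalities carries no usable
signal), the observed statistic is computed on the newly detected set and
compared with B statistics (default 499) from province-matched random sets:

* the **pool** is every municipality with no detection of the species in any
  year up to the tested year — a municipality invaded earlier is not a valid
  null counterfactual;
* each null draw has exactly the detected set's per-province composition,
  sampled without replacement within province, so the null controls the
  provincial (spatial) structure of the invasion front;
* the statistic defaults to the mean of log10(density + ε), ε = 1e-9
  guarding zero-population municipalities; raw-mean and median variants are
  exposed in `permutation_config()` because the choice is a judgement call
  on which reasonable analysts differ — log densities respect the
  heavy-tailed distribution of municipal density;
* the p-value is one-sided ("detected municipalities are denser") with the
  add-one convention (1 + #{null ≥ observed}) / (1 + B), so ties count
  against significance and the floor at B = 499 is 0.002.

Strategies are pooled by default; a per-strategy run is available for the
preliminary check that field- and citizen-detected municipalities do not
differ in density.

Per-year RNG substreams are derived deterministically from (seed, year), so
extending an analysis by one year never perturbs the p-values of the
others. If a province's pool is smaller than its detected count (possible
only when a province is almost fully invaded), the default is an error;
`replace_fallback = TRUE` samples that province with replacement and flags
the result.

### Calibration

The test's validity is checked by simulation, not assumed. Under the
density-unbiased simulator scenario (bias exponent β = 0, see below) the
per-year rejection rate at α = 0.05 must sit inside the 99% binomial
envelope of 0.05; under β = 1 it must be strictly larger. The acceptance
suite runs 300 replicate worlds per arm (400 municipalities, 4 provinces,
a six-year invasion, B = 499) — roughly a thousand year-level tests per
arm. Calibration is evaluated on the *true* colonisation years rather than
on simulated observations, because the citizen observation process is
itself population-weighted: an imperfect, demographically biased observer
would put density signal into the detected set even when colonisation is
blind to density, which is a statement about the observer, not about the
test.

## Detection distances

`sphere_distance()` implements the spherical Vincenty arctangent
formulation on a sphere of radius 6,378,137 m (the conventional default of
spherical geodesy tools, documented so oracles can match it exactly). The
arctangent form is exact on the sphere and numerically stable at both tiny
and near-antipodal separations; the test suite checks it against an
independently coded haversine to 1e-9 relative tolerance and against the
closed forms for one degree of arc (111.3195 km) and the antipodal distance
(20,037.51 km).

For each newly detected municipality, `nearest_previous_positive()` takes
the minimum distance from its centroid to the centroids of all
municipalities first detected in **any earlier year** (cumulative
interpretation of "positive up to the previous year"); same-year positives
are never reference candidates, because their ordering within the year is
unknown. External `reference_points()` (e.g. an established population just
across a border) join the candidate set once active. Ties break towards the
smallest code, which cannot change the distance. A first-ever detection
with no usable reference is retained but flagged excluded.

Exclusion rules (`exclusion_rules()`, YAML-loadable) flag rather than
delete: simultaneous detections (ambiguous strategy), seed-year detections
(no prior reference), named codes (e.g. a suspected independent
introduction far from the front), and eradicated populations. Only
non-excluded records enter the strategy comparison.

`compare_strategies()` uses Welch's t-test by default — the variance
assumption behind a plain Student test is rarely defensible for distance
data — with a pooled-variance option; the two-way ANOVA uses sequential
sums of squares with year entered before strategy, and Tukey–Kramer
adjusted contrasts on the year-by-strategy cells. Distances enter untransformed
by default, with a log10 switch. The sequential decomposition identity
(effect SS summing to total SS) is asserted in the tests.

`polygon_centroid()` supports registries built from polygon cartography: it
projects each ring into a local Lambert cylindrical equal-area projection,
applies the planar shoelace centroid (signed-area weighted across parts,
so a part with three times the area pulls three times harder), and inverts
back to WGS84. For administrative-polygon extents the projection error is
far below the kilometre scale of the analysis.

## The synthetic world

`generate_world()` places municipalities uniformly in a bounding box,
partitions them into provinces by nearest-seed assignment (provinces are
therefore spatially contiguous, which is what makes province stratification
a genuine spatial control), and draws populations and surfaces from
log-normal laws. Defaults — 250 municipalities, 6 provinces, a roughly
330 × 340 km box, population median 5,000 with σ(log) = 1.4, surface
median 3,000 ha — give the heavy-tailed density distribution and
province sizes of a mid-scale national registry while staying desk-fast.

`simulate_invasion()` implements stratified dispersal: an uncolonised
municipality i is colonised each year with probability

$$1 - \exp\{-c \cdot K_i \cdot (d_i/\bar d)^\beta\}, \qquad
  K_i = \sum_{j \,\text{colonised}} e^{-d_{ij}/\lambda},$$

with kernel range λ = 15 km by default, plus a Poisson number of
long-distance jumps per year (mean 0.5) whose targets are drawn with weight
population^β. The exponent β is the single density-bias dial: β = 0 is the
null scenario in which **both** pathways are blind to demography (this is
why jump targets are weighted by population^β rather than by population
unconditionally — a population-weighted jump would contaminate the β = 0
null), and β = 1 makes contagion and jumps favour dense municipalities,
the pattern expected for a synanthropic urban mosquito. The contagion
constant c is calibrated at run time so the expected first-year spread
from the seed set is about one municipality, keeping scenarios in the
desk-scale regime across world sizes.

`simulate_surveillance()` observes the truth through the two imperfect
processes the analyses are designed to compare. Field sampling is
proximity-targeted: from its start year it monitors municipalities within
`field_radius_km` (default 20) of a municipality already detected in an
earlier year — plus the initial entry-point municipalities, which
surveillance knows from the outset — and detects a colonised, monitored
municipality each year with probability 0.6. Citizen reporting is
population-weighted and unconstrained by distance: detection probability
1 − exp(−citizen_rate × population) per year (default rate 5e-5: a
median town of 5,000 reports with probability ≈ 0.22 per year, a city of
100,000 almost surely), floored at 0.02, from 2014 by default (the
platform's historical start). The invasion and observation streams take
independent seeds, so redrawing the observers leaves the truth fixed —
the invariant behind every ground-truth comparison in the tests.

Simulator distances reuse `sphere_distance()`, so pipeline and generator
share one geometry implementation.

What the simulator deliberately does **not** emulate: mosquito population
dynamics (colonisation is binary per municipality-year), seasonal/tourist
population fluctuation, real national geography, reporting-effort
fluctuation over time, and misidentified or mislocated citizen reports.
Passing tests therefore show that the statistical machinery recovers known
mechanisms from data with realistic structure — not that any particular
real-world dataset satisfies those mechanisms.

### End-to-end recovery properties

Two mechanism-recovery properties anchor the acceptance suite:

* on matched seeds, the permutation test rejects (far) more often under
  β = 1 than under β = 0, where its rejection rate is binomially
  compatible with α;
* with proximity-constrained field sampling and population-weighted citizen
  reporting, the mean citizen-science nearest-previous-positive distance
  exceeds the field-sampling mean — citizen science sees jump colonies the
  field front has not reached — and Welch's test flags the gap in the
  large majority of 200 replicate worlds. This reproduces the *sign* of the
  published field/citizen detection-range contrast; the magnitude depends
  on the synthetic geography and is reported, not asserted.

## Numerical choices and degenerate inputs

* Missing years are `NA` end to end; zero is never a valid year.
* A zero-variance annual series returns R² = 0 (trend) or `NA` (Pearson
  correlation), never an error from a degenerate fit.
* Permutation p-values are bounded in [1/(B+1), 1] by construction.
* `stratified_null_sample()` with an exactly-sufficient pool returns the
  forced sample under any seed.
* Distance ties break on the municipality code; distances are reported to
  2 decimals, percentages to 1, both half-away-from-zero, and only at the
  reporting layer.
* All stochastic entry points (simulator, permutation test, CLI) are
  deterministic given their seeds; the CLI's outputs are byte-identical
  under a fixed `--seed`.

## Problem sizes used in the shipped checks

The acceptance suite and `scripts/acceptance.R` use 300 replicate worlds
per permutation-test arm (400 municipalities, 4 provinces, 2004–2009,
B = 499), 200 replicate worlds for the distance-contrast recovery (default
world and surveillance settings, 2004–2016), 1,000 random point pairs for
the geodesic oracle and 100 random registries (≤ 50 municipalities) for
the nearest-neighbour oracle. These sizes give roughly a thousand
year-level permutation tests per arm and sub-two-minute runtimes on a
single core.

## Known limitations

* The loader trusts the input file's reconciliation of conflicting sources;
  it validates structure, bounds and referential integrity only.
* The five-category attribution cannot distinguish the two causal scenarios
  behind a simultaneous detection (field check triggered by a citizen
  report vs a reporting surge after a field announcement); they are
  reported as one class.
* Nearest-previous-positive distance is a proximity summary, not a
  migration-flow model; a small distance does not imply direct spread.
* The per-year significance pattern of a specific historical dataset is not
  reproducible without that dataset (and depends on an unseeded historical
  RNG stream); the package instead validates the test's operating
  characteristics by simulation.
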