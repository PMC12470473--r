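# aedespread

Municipal-scale analysis of invasive *Aedes* mosquito spread observed by two
complementary surveillance strategies: professional **field sampling** and
**citizen-science reporting**.

Invasive container-breeding mosquitoes (*Aedes albopictus*, *Ae. aegypti*,
*Ae. japonicus*) colonise a country municipality by municipality through
stratified dispersal — short-range contagious spread plus rare
human-mediated long jumps. Public-health entomologists track this with
per-municipality *first-detection years*, recorded separately for field
surveillance and for app-based citizen reports. This package is for the
analysts of such tables: it provides the data model, the attribution logic,
the spread statistics, the density-association test and the
detection-distance comparison — together with a ground-truth simulator that
validates every stage.

## What it computes

**Attribution.** Each (municipality, species) falls into one of five
categories: (1) field-only, (2) citizen-only, (3) both in the same year,
(4) both in different years, (5) no detection. First year
`= min(year_field, year_citizen)`; simultaneous ties stay "simultaneous"
unless a documented chronological override names the strategy.

**Spread summaries.** Annual and cumulative municipality / surface /
population counts, strategy shares, inclusive-period mean annual rates
(with simultaneous detections counted in both strategies' numerators),
OLS trend R², mutual confirmation delays and the Pearson correlation of the
two strategies' annual series.

**Density test.** For each year, a one-sided province-stratified permutation
test (default B = 499) of

> mean log10(density of newly detected municipalities) vs
> province-matched random sets of never-yet-detected municipalities,

with p = (1 + #{null ≥ observed}) / (1 + B).

**Detection distances.** For each new detection, the great-circle distance
(spherical Vincenty arctangent formulation, R = 6 378 137 m) to the nearest
municipality positive in any earlier year (or to a configured external
reference point), with exclusion rules (simultaneous, seed-year, named
codes, eradicated), a Welch t-test of distance by strategy and a two-way
ANOVA (year × strategy, sequential SS) with Tukey contrasts.

**Simulator.** Synthetic registries (contiguous provinces, log-normal
populations), a colonisation process `P = 1 − exp(−c·K_i·(d_i/d̄)^β)` with
exponential kernel `K_i = Σ_j exp(−d_ij/λ)` plus Poisson long jumps, and the
two imperfect observers (proximity-targeted field sampling,
population-weighted citizen reporting) — all deterministic under seeds.

## Worked example

```r
library(aedespread)

reg   <- generate_world(world_config(seed = 11))
truth <- simulate_invasion(reg, invasion_config(seed = 12, density_bias = 1))
rec   <- simulate_surveillance(reg, truth, surveillance_config(seed = 13))

att <- attribution_table(rec, reg, species = "albopictus")
category_counts(att)
#>      species category_1 category_2 category_3 category_4 category_5 positive
#> 1 albopictus         12         18          7         39        174       76

run_density_tests(att, reg, permutation_config(seed = 99))
#>   year n_detected observed_stat p_value significant
#> 1 2014         35     1.0296057   0.002        TRUE
#> 2 2015         24     0.4230256   0.002        TRUE
#> 3 2016         16     0.3465051   0.004        TRUE

d <- apply_exclusions(detection_distances(att, reg))
compare_strategies(d)
#> Detection-distance comparison by surveillance strategy
#>   field:   n =   13, mean distance  11.48 km
#>   citizen: n =   55, mean distance  78.31 km
#>   t = -7.747, p = 2.109e-10
#>   ...
```

Reading: of 250 synthetic municipalities, 76 were detected; with a
density-biased colonisation (β = 1) every tested year's newly detected
municipalities are significantly denser than province-matched non-detected
ones (p = 0.002 is the floor at B = 499); and citizen science — which is
not tied to the advancing field-surveillance front — finds municipalities
about seven times farther from the nearest previous positive than field
sampling does, the mechanism behind the published field/citizen
detection-range contrast.

The same pipeline runs from a shell:

```sh
Rscript inst/cli/aedespread simulate --seed 1 --out-dir sim/
Rscript inst/cli/aedespread summarize --registry sim/registry.csv \
    --detections sim/detections.csv --out-dir out/
Rscript inst/cli/aedespread density-test --registry sim/registry.csv \
    --detections sim/detections.csv --iterations 499 --seed 1 --out-dir out/
Rscript inst/cli/aedespread distances --registry sim/registry.csv \
    --detections sim/detections.csv --compare --out-dir out/
```

Real data enter through `load_registry()` (CSV:
`code,name,province,autonomous_community,surface_ha,population,centroid_lat,centroid_lon`)
and `load_detections()` (one row per municipality, three columns per
species: `<species>_field_year`, `<species>_field_source`,
`<species>_citizen_year`; empty cell = not detected).

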