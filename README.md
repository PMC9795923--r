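# phenomatch

Cross-platform estimation and comparison of avian migration phenology in R.

## The problem

Two very different monitoring platforms measure the timing of bird
migration across a continent. Weather surveillance radar (WSR) captures
nocturnal migrants in flight: reflectivity aggregated over a station's
airspace yields a nightly passage rate, a taxon-blind measure of how many
birds crossed a 1-km transect that night. Community-science checklists,
turned into weekly relative-abundance surfaces by spatio-temporal models,
give species-specific but ground-based and diurnal information. Whether
the two platforms tell the same story about *when* migration happens — and
by how many days they disagree — matters to anyone combining them to track
phenological shifts.

`phenomatch` implements the full comparison pipeline for researchers in
quantitative ecology and aeroecology:

- **Radar side** — reflectivity factor to reflectivity,
  `η = 10^(dBZ/10) · 10³ π⁵ |Km|² / λ⁴` (cm² km⁻³); migration traffic rate
  per 100-m height bin, `(η/σ_bird) · groundspeed · Δh` (birds km⁻¹ h⁻¹);
  summed through the night into nightly passage (birds km⁻¹).
- **Abundance side** — weekly relative-abundance cells averaged
  (unweighted) within a 37.5-km great-circle buffer of each station.
- **Phenology statistic** — both series are smoothed with a penalized
  cubic B-spline GAM of ordinal date (year as a random intercept for the
  radar series) and reduced to the **half-max date**: the first date before
  the seasonal maximum on which the predicted curve reaches half its
  maximum. Abundance curves peaking at the season's start (before ordinal
  day 10 in spring, day 185 in autumn) fall back to the first date *after*
  the maximum that drops to half (falling edge). Estimates are retained
  only when adjusted R² > 0.25 and the date lies inside the seasonal
  window (1 March–15 June; 1 August–15 November).
- **Comparison** — per-station offsets (radar minus mean species date;
  negative = radar earlier), Pearson correlations with Fisher-z 95%
  intervals, one-way ANOVA and Tukey HSD across flyways (west of 103°W /
  103–90°W / east of 90°W), paired t tests on species richness, and the
  OLS regression of offset on latitude.
- **Synthetic world** — a seeded generator of stations, species
  (passage / breeder / winterer / resident archetypes with order-specific
  timing), nightly radar series and weekly abundance surfaces with
  closed-form ground-truth half-max dates, so the entire pipeline is
  testable without any external data.

## Worked example

```r
library(phenomatch)

# a small seeded world: 6 stations, 6 species, 4 years, both seasons
w <- simulate_world(n_stations = 6, n_species = 6, years = 2010:2013,
                    n_cells = 4, seed = 3)

# radar phenology: one half-max per station and season
hm_radar <- radar_halfmax_table(w$radar_nights)

# abundance phenology: buffer-average, then one half-max per species/station
sw <- aggregate_world_ebird(w, radius_km = 37.5)
hm_ebird <- ebird_halfmax_table(sw)

rec <- build_station_records(rbind(hm_radar, hm_ebird), w$stations, "spring")
rec[1, c("station_id", "radar_halfmax", "ebird_mean_halfmax", "offset_days")]
#>   station_id radar_halfmax ebird_mean_halfmax offset_days
#> 1       S001            89             109.75      -20.75

pearson_with_ci(rec$radar_halfmax, rec$ebird_mean_halfmax)
#> Pearson correlation [all]: r = 0.92, df = 4, p = 0.0086, 95% CI 0.45-0.99
```

The station's radar half-max (day 89) recovers the simulated truth (89.85);
the negative offset says radar dates this station's spring passage about
three weeks before the mixed-archetype species average, and the correlation
shows both platforms ordering stations the same way along the latitudinal
gradient. A single fit can be inspected directly:

```r
nights <- filter_season(w$radar_nights[w$radar_nights$station_id == "S001", ], "spring")
fit <- fit_seasonal_smooth(nights$ordinal_date, nights$passage,
                           year_labels = nights$year,
                           season_range = season_window("spring"))
summary(fit)
#> Seasonal smooth, platform radar
#>   n = 428 observations over days 60-166
#>   effective df 11.64, adjusted R^2 0.781
#>   curve maximum 232.7 on ordinal day 106
halfmax_date(fit, "spring")
#> Half-max estimate (radar, spring): day 89 (rising edge; peak day 106; retention pending)
```

`run_all(pipeline_config(seed = 1), "out/")` executes the whole chain
(simulate → radar phenology → buffer aggregation → abundance phenology →
comparison) and writes every intermediate as CSV plus a manifest.

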