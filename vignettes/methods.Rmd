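---
title: "Half-max migration phenology from radar and community-science abundance: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Half-max migration phenology from radar and community-science abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomatch)
```

## The measurement model

`phenomatch` compares two measurements of the same phenomenon — the timing
of bird migration past a fixed location — taken by instruments with almost
nothing else in common.

**Radar.** An S-band weather surveillance radar measures reflectivity
factor (dBZ) in volumes of airspace. For biological scatterers this is
converted to reflectivity

$$\eta = 10^{\mathrm{dBZ}/10}\cdot 10^{3}\,\pi^{5}\,|K_m|^{2}\,/\,\lambda^{4}
\quad [\mathrm{cm^2\,km^{-3}}],$$

which is proportional to bird density under an assumed per-bird radar
cross-section $\sigma_{\mathrm{bird}}$. Multiplying the implied density
$\eta/\sigma_{\mathrm{bird}}$ by groundspeed and the 100-m height-bin
depth gives a migration traffic rate (birds km$^{-1}$ h$^{-1}$) per bin;
summing over the 30 bins (0–3,000 m AGL) and over a night's 30-min scans,
weighted by the scan interval, gives nightly passage (birds km$^{-1}$).
The default constants are the community-standard S-band values
($\lambda = 10.7$ cm, $|K_m|^2 = 0.93$, $\sigma_{\mathrm{bird}} = 11$
cm$^2$), all overridable through `radar_constants()`. Scans are assumed
uniformly spaced; missing scans are not imputed — passage is the sum over
available scans, with `n_scans` reported for quality control.

**Relative abundance.** The species-level input is a weekly relative
abundance surface: one value per species, week midpoint and grid cell
(nominally 2.96 × 2.96 km). For each station, all cells whose centroids
fall within a 37.5-km great-circle buffer (haversine on a sphere of
radius 6,371.0088 km; the sub-100-m ellipsoidal error is immaterial at
this radius) are averaged per week with equal weights — no area weighting
and no zero-exclusion. A species whose 52 weekly means are all zero is
flagged absent at that station.

## The phenology statistic

Both nightly passage and weekly mean abundance are reduced to the same
statistic. A penalized cubic B-spline smooth of ordinal date (basis
dimension 20, second-order difference penalty, smoothness selected by
generalized cross-validation, with an additional null-space shrinkage
penalty so that structureless series collapse to a constant) is fit via
`mgcv`; for the multi-year radar series, year enters as a random intercept
so that between-year amplitude differences do not distort the seasonal
shape. Predictions are taken on the integer-date grid with year effects
marginalized to zero and clipped at zero.

The **half-max date** is the first date at or before the curve maximum on
which the prediction reaches half of the maximum. Ties at the maximum are
broken toward the earliest date — "first date prior to the maximum"
presumes a unique reference point and earliest is the conservative choice.
The date is resolved at day resolution without interpolation, because the
statistic is reported as a whole ordinal date.

For abundance curves only, a curve that peaks at the very start of the
season (before ordinal day 10 in spring, day 185 in autumn) has an
uninformative rising edge — typically a wintering population departing —
so the statistic switches to the first date *after* the maximum on which
the curve falls to half-max. Radar curves never use the falling edge. Note
that the autumn threshold (day 185) lies below the autumn fitting window
(6 July = day 187), so in practice the fallback can only fire in spring;
we keep the autumn threshold for fidelity to the method's definition.

An estimate is **retained** only if the fit's adjusted
$R^2 = 1-(1-R^2)(n-1)/(n-\mathrm{edf})$ strictly exceeds 0.25 and the
half-max date lies inside the seasonal window (1 March–15 June, ordinal
60–166; 1 August–15 November, ordinal 213–319, on a fixed 365-day
calendar). Every unretained estimate carries a reason code (`low-r2`,
`out-of-window`, `no-crossing`, `flat-curve`); the pipeline logs all
drops because these filters silently discard data otherwise.

Fitting windows differ by platform: radar smooths are fit over the
seasonal windows themselves, while weekly abundance is fit over wider
windows anchored to week midpoints (4 January–28 June; 6 July–28
December) so the smoother sees the rise and fall around the window.
Weekly observations are fit as-is (26 and 25 points respectively) and
predicted daily from the smooth, rather than interpolated to daily before
fitting.

## Comparison

One radar half-max and one species-averaged abundance half-max per station
and season are paired. The offset is radar minus abundance, so negative
values mean radar dated migration earlier. Species are averaged within
stations first, mirroring the one-metric-per-platform-per-station design
of the correlation; a per-species pooling variant would weight stations
by richness and is deliberately not the default. Correlations are Pearson
product-moment with two-sided p from the t transform and 95% intervals
from the Fisher z transform. Group contrasts (flyways at 103°W and 90°W,
boundary longitudes assigned to the central band as the closed reading of
"between") use one-way ANOVA with Tukey HSD post-hoc tests
(Tukey–Kramer standard errors for unbalanced groups — the only adjusted
procedure; no correction is applied across correlation groups). Richness
is compared between seasons with a paired t test, and the offset is
regressed on latitude by ordinary least squares (slope in days per
degree).

## The synthetic world

Because the real inputs (17 years of radar volumes; request-gated
abundance products) are not desk-reproducible, the package ships a seeded
generator whose defaults encode the study conditions: 143 stations
spanning the three flyways and ≥ 15° of latitude, 293 species in a
57/16/13/14 per-cent mix of Passeriformes, Charadriiformes, Anseriformes
and other orders, and years 2002–2018.

Seasonal shapes are chosen so every ground truth has a closed form:

- *passage* species and the station-level radar pulse are Gaussians in
  ordinal date, whose rising-edge half-max is exactly
  $\mu - \sigma\sqrt{2\ln 2}$;
- *breeders* rise logistically at the spring date and fall at the autumn
  date, so the spring half-max is the logistic midpoint itself;
- *winterers* are the mirrored shape; *residents* are constant with an
  optional seasonal ripple and have no defined phenology.

Species timing moves with latitude at ~1–1.3 days per degree — later
spring and earlier autumn at higher latitude — with waterfowl configured
earlier in spring and later in autumn than songbirds. The slope is stored
as a nonnegative magnitude and applied with positive sign in spring and
negative in autumn. Noise is multiplicative: lognormal per night for radar
(sd 0.3 on the log scale) with a lognormal per-year amplitude intercept
(sd 0.25), and zero-truncated Gaussian per cell-week for abundance (CV
0.1) — both platforms are positive and heteroscedastic, and amplitude
(not timing) year effects keep truth dates well-defined. A timing-jitter
option exists but defaults to 0. Cells are points on a regular 2.96-km
grid in a local tangent plane around each station, avoiding projection
machinery while honoring the product resolution. Per-order archetype
mixtures and detectability (lognormal, sd 0.4) are documented constants,
not calibrated values — no empirical distribution for them is available.

Randomness derives from one root seed through stable string hashing of
(seed, station, species, year), so outputs are reproducible under
reordering and shifting all abundance truths (`ebird_shift_days`) provably
leaves radar output byte-identical.

**What the generator does not emulate:** precipitation contamination and
its screening, beam geometry and range-dependent biases, observer effort
and detection differences across habitats, spatial autocorrelation among
stations, and between-year timing trends. Passing tests therefore show
that the pipeline recovers phenology and its cross-platform structure
when the measurement model holds — not that the real platforms are free
of these biases.

## Numerical choices and degenerate inputs

- Fits with fewer than 10 observations, or with singular designs, are
  refused with a classed condition rather than returning garbage.
- The basis dimension is reduced to (number of distinct dates − 1) when
  data are sparse, with a floor of 5.
- A constant series fits to effective df ≈ 1 and adjusted R² ≤ 0, hence
  is never retained.
- All-zero curves and no-crossing falling edges yield unretained
  estimates with explicit reasons.
- An all-identical-observations ANOVA reports F = 0, p = 1 instead of
  0/0; zero-variance paired differences report t = 0 with a flag.
- GCV's optimum depends (weakly) on sample size, so duplicating every
  observation can move predictions by ~1% of the curve maximum; the
  extracted half-max *date* is invariant under duplication and that is
  the invariance the tests assert.
- Retention uses a strict inequality at R² = 0.25, and window boundaries
  are inclusive, matching the stated filters exactly.

## Problem sizes used in tests and the acceptance script

The test suite and `scripts/acceptance.R` exercise the pipeline at
reduced scale as the package's own choice of experimental design:
smoother-recovery replicates use one station × 17 years × 100 seeds;
cross-platform recovery uses 143 stations × 8 species × 6 years (spring);
the acceptance script runs 60 stations × 10 species × 6 years over both
seasons. These sizes keep full runs in minutes while leaving all method
parameters (windows, buffers, thresholds, noise levels) at their
study-condition defaults.

## Known limitations

- Night definition is delegated to the input: synthetic data label nights
  explicitly, and scan tables are integrated per labelled night; no solar
  geometry is computed.
- The half-max date carries no uncertainty interval; it is a point
  statistic by construction.
- The abundance smooth treats the 52 weekly values as exchangeable
  observations; no annual replicates exist on that side, so year effects
  apply to radar only.
- The flyway classification is purely longitudinal; real flyway
  boundaries are ecological, not meridional.
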