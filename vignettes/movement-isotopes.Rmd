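---
title: "Inferring whale movement from baleen carbon isotope profiles: models and methods"
author: "baleenIso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring whale movement from baleen carbon isotope profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baleenIso)
```

## The inference problem

Baleen grows continuously at the gum (gingival) end and is metabolically
inert once formed, so a baleen plate carries a multi-year chemical time
series of the whale's diet.  Because the carbon isotope composition
(δ¹³C) of phytoplankton — and hence of the krill a blue whale eats —
varies systematically with latitude and season, a sequence of δ¹³C
measurements along a plate encodes information about where the whale was
feeding through time.  Decoding that record directly is ill-posed:
baseline variation, movement, diet integration and tissue growth all
interact.  `baleenIso` takes the simulation route instead: encode each
candidate movement behaviour (year-round residency in a named region, or
seasonal latitudinal migration) as an agent-based model, push simulated
whales through a gridded monthly isoscape, synthesize the baleen δ¹³C
profile each simulated whale would have recorded, and score each
simulated profile against the measured one by linear regression.  The
hypothesis whose ensemble best reproduces the measured record is the
best-supported movement history.

The package implements the full chain:

1. `generateSyntheticEnvironment()` / `loadEnvironment()` — the
   environment the whales move through;
2. `simulateTrack()` — daily probabilistic movement;
3. `trackToDiet()` + `dietToProfile()` — diet integration and the
   time-to-distance mapping onto the plate;
4. `estimatePeriod()` / `peakSpacing()` / `assignDates()` — time
   calibration of a measured profile from its δ¹⁵N cyclicity;
5. `runEnsemble()` / `selectTop()` / `occupancyByMonth()` — ensemble
   scoring and ranking of hypotheses.

## The synthetic environment

Real applications use output of an isotope-enabled ocean biogeochemistry
model; such output cannot be redistributed with a package, and the
scientific content of the method depends only on the large-scale
structure of the fields.  `syntheticEnvConfig()` therefore generates a
parametric North Atlantic with that structure, on a 1°, 12-month
climatological lattice (no interannual axis):

* **δ¹³C baseline.**  With the latitude ramp
  `L(φ) = clamp((φ − φS)/(φN − φS), 0, 1)` (defaults 20–70 °N), the
  annual mean declines poleward, `cBase − cGrad·L(φ)` (defaults −20.5,
  3.5 ‰), and a zero-mean bloom-skewed seasonal cycle is superimposed
  with half-amplitude `a(φ) = aSub + (aMax − aSub)·L(φ)` (defaults 0.2
  and 1.5 ‰).  The cycle rises steeply over three months to its peak
  and declines slowly to a late-winter minimum — the shape of a
  plankton bloom's isotopic expression.  Its peak month shifts from
  February in the subtropics (the weak winter deep-mixing bloom) to
  June at high latitude, the familiar poleward bloom progression.  The
  peak month is snapped to integers so that the sampled monthly cycle
  is exactly zero-mean and the seasonal range is exactly `2a(φ)`,
  monotone in latitude.  Subtropical waters are thus "relatively high
  and constant" in δ¹³C but not literally flat — the weak winter cycle
  is what allows residency hypotheses to be distinguished from one
  another at all, since regression scoring is scale-invariant and can
  only latch onto shared deterministic seasonal structure, never onto
  amplitude.
* **SST** declines linearly poleward (27 °C at the equator,
  0.28 °C per degree) with a seasonal cycle of amplitude 2.5 °C peaking
  in August.  These values leave the Norwegian Sea marginally habitable
  (≥ 3 °C) in winter and push the equatorward limit of the 25 °C
  ceiling seasonally — both needed for the residency scenarios the
  method is meant to test.
* **Biomass** has a floor of 0.4 mmol N m⁻³ and a bloom term
  `3·L(φ)` co-peaking with the local δ¹³C cycle.
* **Bathymetry** is a 4000 m basin with a shelf ramp (80 m at the
  coast, 3° wide) along a 2°-wide land strip at each meridional edge.

Every constant is exposed in the configuration and documented as a
synthetic choice.  What the emulation deliberately omits: zonal
structure (gulf-stream asymmetry), eddies and fronts, interannual
variability, and any secular δ¹³C decline (the Suess effect) — the
method never interprets absolute δ¹³C values, only relative variation,
so a secular offset is irrelevant to the ranking.  Tests passing on
this environment demonstrate that the machinery is correct and that the
inference logic discriminates the intended behaviours under the stated
structure; they cannot certify performance on a specific real isoscape.

## The movement model

One whale per track, one step per day.  Each day, in fixed order:

1. **Behavioural state** comes from the operator's month schedule
   (default: migrate north March–May, south September–November, forage
   otherwise), overridden to foraging wherever local biomass reaches
   the trigger (2 mmol N m⁻³).
2. **Move or stay** is a Bernoulli draw.  The base probability per
   state (0.95 migrating, 0.5 foraging) is reduced while foraging in
   proportion to local biomass (factor `1 − 0.8·bio/bioMax`), so whales
   sit in rich patches.  A whale whose cell has drifted outside the
   3–25 °C envelope always attempts to move.
3. **Direction** is a draw over the 8 compass headings, weighted by a
   multiplicative utility of each cell one grid step away:
   zero for land, out-of-grid, out-of-envelope or (for confined
   residents) out-of-region cells; a linear depth penalty below 400 m;
   a logistic SST preference `plogis(±wSst·ΔT)` (colder preferred when
   migrating north, warmer when south, `wSst = 6 °C⁻¹`); and a biomass
   attraction `1 + wBio·bio/bioMax`, tripled while foraging.
4. **Distance** is drawn from a per-state Gaussian truncated at zero
   (inverse-CDF draw; migrating 120 ± 30 km day⁻¹, foraging
   25 ± 10 km day⁻¹) and applied along the heading with
   equirectangular geometry (per-latitude longitude scaling — at 1°
   grid resolution, geodesic precision would be false precision).
   Diagonal headings travel the same sampled distance as cardinal
   ones.  If the sampled displacement would land on an illegal cell
   the move is aborted rather than clipped, so a realised displacement
   never exceeds its drawn distance.

Between-individual variation enters once per track: each whale draws
its personal mean step length from a Gaussian around the configured
mean (SD 15 km for migratory ensembles, 5 km for residents, 0 for
reference individuals).  The migration speed and temperature-taxis
defaults make migrants strongly directed, consistent with observed
blue-whale transit speeds in excess of 100 km day⁻¹; weakly directed
migrants fail to express the full latitudinal isotope amplitude and
would blur the contrast the method relies on.

A whale with no admissible candidate cell on 10 consecutive days is
declared trapped and its run marked failed.  Failures are counted and
excluded from scoring, as failed runs are excluded in this kind of
ensemble experiment.  Two failure modes occur: coastal trapping, and
heat-trapping of far-southern residents when the monthly climatology
steps the 25 °C isotherm north at a month boundary.  Roughly one in
ten Cape Verde residency runs fails this way.

Residency hypotheses confine movement to their hotspot box.  Without
confinement a two-year foraging walk leaves any subtropical box, and
the scenario would no longer be the hypothesis it claims to be.  The
four shipped hotspots (`hotspotRegions()`) are documented approximate
boxes for the Norwegian/Barents Sea, west of Ireland, the
Canaries/Azores/Mid-Atlantic-Ridge region and the Cape
Verde/Mauritanian upwelling.

All randomness flows through R's RNG: a track seeded with
`simulateTrack(..., seed =)` replays byte-identically, and ensembles
seed run *r* with `baseSeed + r`, so failure exclusion can never alter
the surviving runs' scores.

## From track to baleen profile

Keratin records the krill eaten in the weeks to months before growth,
not same-day phytoplankton, and krill integrate their phytoplankton
diet over their tissue turnover.  `trackToDiet()` models this as a
trailing biomass-weighted average: for each day, the δ¹³C baseline at
the whale's cell for the `windowMonths` most recent mid-month
climatology values (default 2 months; the caption convention of
six-month averaging is available by setting `windowMonths = 6`),
weighted by the cell's monthly biomass, plus a constant trophic offset
(default 0 ‰ — the ranking is invariant to it anyway).  Monthly values
are attributed to the 15th; sub-monthly interpolation of a monthly
climatology would add false precision.

`dietToProfile()` then maps time to distance assuming constant baleen
growth at `g` cm yr⁻¹: the sample at distance `d` from the gingival end
averages the diet signal over the bin
`[end − (d + Δ)/g, end − d/g)` years, giving
`floor(spanYears·g/Δ)` samples at spacing `Δ`.  Averaging over the bin
(rather than point sampling) reflects that each centimetre of baleen
integrates about 27 days of growth at 13.5 cm yr⁻¹.

## Time calibration

Seasonal behaviour imprints a strong annual cycle on baleen δ¹⁵N; the
dominant periodicity of the δ¹⁵N profile in cm therefore estimates the
annual growth increment, and one cycle is assumed to equal one year.
`estimatePeriod()` linearly detrends the series (raw trends leak power
into low frequencies) and takes the periodogram on an 8× zero-padded
FFT grid, rounded up to a power of two; for 97 samples at 1 cm the
resulting period resolution near 13.5 cm is about 0.18 cm, and the
reported period is grid-quantised at that scale.  Periods longer than
half the record are excluded, and exact ties go to the lowest
frequency.  A Fisher g-test p-value on the unpadded periodogram
accompanies every estimate; the package's detection convention is
α = 0.001, demanding strong evidence, as befits an argmax search over
frequencies.  `peakSpacing()` provides the complementary estimator —
the mean distance between successive local maxima above a prominence
threshold (default half the series SD; flat-topped peaks sampled as
two equal values are collapsed to their centre).  Both estimators are
reported side by side by `calibrateProfile()`; the periodogram drives
the date assignment because it uses the whole record rather than a
handful of peaks.

`assignDates()` dates the sample at distance `d` as
`anchor − round(365.25·d/g)` days (365.25-day years, proleptic
Gregorian dates).  With a 97-sample, 1 cm record at 13.5 cm yr⁻¹
anchored at 1 March 1891 — 24 days before a 25 March 1891 stranding —
the record spans seven full years back to January 1884.

`crossCorrelation()` (per-lag Pearson correlation of the overlapping
segments, guaranteed in [−1, 1]) and `segmentPhases()`
(operator-supplied phase boundaries with per-phase summaries) support
the descriptive analysis of measured records.  Phase boundaries are
deliberately operator inputs: behavioural phases in such records are
identified by inspection, and automated changepoint detection is out
of scope.

## Ensemble scoring

`runEnsemble()` simulates `nRuns` whales under a hypothesis, each track
ending at the measured record's anchor date so that simulation and
specimen share their most recent tissue in time.  Each complete track
becomes a simulated profile at the measured sample spacing, is aligned
at the gingival end (`alignProfiles()` interpolates the simulated
record onto the measured distance grid over the overlapping span — a
two-year residency run is scored against the most recent two years of
a seven-year record), and scored by `fitR2()`: ordinary least squares
of measured on simulated, reporting r² as the squared Pearson
correlation.  r² is invariant to affine transformation of either
series, which is exactly why absolute δ¹³C levels, the Suess offset
and the trophic offset never matter to the ranking — and why constant
(degenerate) simulated profiles are scored 0 by convention with a
warning rather than being dropped.  `selectTop()` keeps the best
`ceiling(fraction·n)` runs (default 10 %), ties broken by run id so the
ranking is reproducible, and `occupancyByMonth()` pools the daily
positions of that subset by calendar month — the basis for mapping
where the best-fitting whales were in each month.

The discrimination logic that the acceptance experiment exercises: a
"measured" profile generated by a known migratory whale must be best
matched by the migratory ensemble, and a subtropical-resident truth by
the subtropical residency ensembles.  The two subtropical hotspots
share the same weak winter cycle and are not mutually resolvable at
30 runs; the experiment therefore compares subtropical residency as a
class against migration and against the high-latitude hotspots, where
the contrast is decisive.

## Synthetic fixtures and what passing means

`makeFixture()` builds the test data by running the forward model under
a recorded truth: a small environment file, a 97-sample "measured"
migratory profile (2625 days ≈ 7.19 years at 13.5 cm yr⁻¹, matching the
length of a real multi-year record) and a two-year subtropical-resident
profile.  Truth tracks use a representative individual (no
between-individual step variation) so the stand-in record is typical
rather than an extreme draw.  δ¹³C comes from the forward model plus
0.1 ‰ Gaussian noise (typical EA-IRMS analytical precision); δ¹⁵N is
synthesized as an annual cycle consistent with the same growth rate
plus noise, since δ¹⁵N physiology is outside the model's scope and the
nitrogen record's only role here is time calibration; elemental
composition is drawn inside the keratin quality band (C:N mass ratio
3.3–3.7; `cnRatio()` reports the mass convention, × 14/12 for atomic).
Every fixture is deterministic in its seed and ships its generating
truth in a manifest.  A copy of the migratory stand-in is installed at
`inst/extdata/synthetic_baleen_record.csv`; it is synthetic, and
labelled as such in its filename and manifest — it stands in for a
measured museum record, which is not redistributable here.

Problem sizes used by the test suite and the acceptance script — 100
seven-year migratory runs, 30 two-year runs per hotspot, 200-replicate
noise studies, 10⁴-step symmetry checks — are the package's chosen
experiment scale: large enough that the max-r² statistics and
Monte-Carlo calibrations are stable across seeds, small enough to run
interactively.

## Numerical conventions and degenerate inputs

Month indexing is 1-based; coordinates are °N in [−90, 90] and °E in
[−180, 180] with no antimeridian wraparound (the default basin never
crosses it).  Field lookup is nearest-cell (values belong to 1° cells;
bilinear interpolation is available behind a flag).  Constant series
are rejected by the period estimator and the correlation functions
rather than returning NaN; all-zero diet weights fall back to the
unweighted mean with a warning; a grid whose month axis is not exactly
12 long is a format error.  The stochastic draw order within a day is
fixed (move → heading → distance) so seeds reproduce exactly.

## Known limitations

The constant-growth assumption is structural: `assignDates()` exposes
the growth rate as a parameter but no varying-growth model is
implemented.  The environment is a climatology — no interannual
anomalies, no fronts or eddies, and a purely zonal baseline.  δ¹⁵N is
synthesized, not modelled: nothing here constrains nitrogen isotope
physiology.  Movement has no memory, energetics or sociality, and the
behaviour calendar is operator-fixed rather than emergent.  Regression
ranking by max r² is deliberately simple — it is a hypothesis screen,
not a likelihood-based geolocation method, and formal model selection
is out of scope.
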