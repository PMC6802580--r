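# baleenIso

Simulation-based inference of multi-year whale movement behaviour from
stable carbon isotope profiles in baleen.

## The problem

Baleen plates grow continuously from the gum and are metabolically
inert once formed, so sequential samples along a plate form a
multi-year record of the whale's diet chemistry.  Phytoplankton δ¹³C
varies with latitude (lower polewards) and season (bloom-driven
cycles, stronger at high latitude), so that record also encodes where
the whale fed — but baseline variation, movement, diet integration and
growth all interact, and no closed-form inversion exists.  `baleenIso`
is for movement ecologists and stable-isotope researchers who want to
test movement hypotheses against such records by *simulation*: encode
each candidate behaviour (year-round residency in a named hotspot, or
seasonal latitudinal migration) as an agent-based movement model, push
ensembles of simulated whales through a gridded monthly δ¹³C isoscape,
synthesize the baleen profile each would have recorded, and rank
hypotheses by how well their simulated profiles reproduce the measured
one.

The core pieces, in the field's standard terms:

* **Isoscape**: monthly 1° climatological fields of δ¹³C-POM (‰ VPDB),
  SST (°C), plankton biomass (mmol N m⁻³) and depth (m), either read
  from netCDF or generated parametrically
  (`generateSyntheticEnvironment()`), with the canonical structure:
  δ¹³C(φ, m) = c₀ − Δc·L(φ) + a(φ)·B(m; p(φ)), where L is a latitude
  ramp, a(φ) the seasonal half-amplitude and B a zero-mean bloom-skewed
  annual cycle whose peak month shifts poleward.
* **Movement model**: daily state-dependent kinesis — move/stay
  Bernoulli, an 8-direction multinomial over candidate-cell utilities
  (thermal envelope 3–25 °C, depth penalty below 400 m, logistic SST
  taxis, biomass attraction), and a zero-truncated Gaussian step length
  (`simulateTrack()`).
* **Diet transfer**: trailing biomass-weighted mean of the baseline
  over the preceding months plus a constant trophic offset, then
  binned onto the plate's distance axis at constant growth
  (`trackToDiet()`, `dietToProfile()`).
* **Time calibration**: the dominant periodicity of the δ¹⁵N record
  (zero-padded periodogram with a Fisher g-test, plus mean peak
  spacing) gives the growth rate in cm yr⁻¹, one cycle = one year;
  dates follow as anchor − 365.25·d/g (`calibrateProfile()`).
* **Scoring**: per run, OLS of measured on simulated with r² = squared
  Pearson correlation; per hypothesis, ensemble summaries, top-10%
  selection and monthly occupancy maps (`runEnsemble()`,
  `selectTop()`, `occupancyByMonth()`).

## Worked example

The package ships a synthetic 97-sample baleen record
(`inst/extdata/synthetic_baleen_record.csv`) generated by the forward
model under a known migratory truth — it stands in for a measured
museum specimen record, and its manifest records the generating truth.

```r
library(baleenIso)

rec <- readProfile(system.file("extdata", "synthetic_baleen_record.csv",
                                package = "baleenIso"))
rec
#> BaleenProfile: 97 samples at 1 cm spacing, 0.0..96.0 cm from gingival end
#>   d13C -22.47..-20.16 permil  d15N 11.99..13.91  dated 1884-01-20..1891-03-01

cal <- calibrateProfile(rec, anchorDate = "1891-03-01")
cal
#> CalibrationResult: period 13.47 cm (+/- 0.18, Fisher g p = 5.54e-41)
#>   mean peak spacing 13.67 cm; growth rate 13.47 cm/yr; anchor 1891-03-01
```

The δ¹⁵N record carries a strong annual cycle with a ~13.5 cm period,
so the plate grew ~13.5 cm yr⁻¹ and the 97 cm record spans seven full
years.  Now score two competing movement hypotheses against the δ¹³C
record:

```r
env  <- generateSyntheticEnvironment()
meas <- assignDates(rec, 13.5, "1891-03-01")

runEnsemble(migratoryHypothesis(), env, meas,
            nRuns = 20, baseSeed = 42, growthRate = 13.5)
#> EnsembleSummary 'migratory' (MIGRATORY): 20 runs, 20 completed, 0 failed
#>   r2 median 0.770  max 0.888  (top 2 runs retained)

runEnsemble(residencyHypothesis("cape_verde_mauritania"), env, meas,
            nRuns = 10, baseSeed = 42, growthRate = 13.5)
#> EnsembleSummary 'resident_cape_verde_mauritania' (RESIDENT): 10 runs, 8 completed, 2 failed
#>   r2 median 0.017  max 0.044  (top 1 runs retained)
```

The migratory ensemble reproduces the record (max r² ≈ 0.89) while
subtropical residency cannot (max r² ≈ 0.04) — the correct call, since
this record's generating truth was migratory.  Failed runs are whales
trapped by coastline or by seasonally warming water; they are counted
and excluded from scoring.  `runPipeline()` chains all stages from a
single YAML/list configuration and writes a manifest and report;
`inst/cli/baleeniso.R` exposes the same stages as shell subcommands
(`synth-env`, `simulate`, `profile`, `calibrate`, `compare`,
`fixture`, `pipeline`).

## Vignette

`vignettes/movement-isotopes.Rmd` documents the models, parameter
choices, numerical conventions and limitations in detail.
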