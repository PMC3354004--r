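# pelagitrack

Travel-speed modality and ocean co-location analysis for satellite-tracked
marine megafauna.

## What it is for

Foraging success in pelagic predators leaves a signature in their horizontal
movement: animals that regularly find dense prey alternate slow, tortuous
area-restricted search (ARS) with fast directed transit, so their
travel-speed distribution is **bimodal**; animals that rarely achieve high
foraging success spend nearly all their time searching at transit pace, and
their speed distribution is **unimodal**. Comparing populations on this axis
requires a reproducible chain from raw Argos satellite fixes to a defensible
test of unimodality, which is what this package provides:

* **Track processing** — location-class and apparent-speed (10 km/h)
  filtering of Argos fixes, running-mean smoothing, great-circle
  regularization to 6-h positions, masking of >3-day transmission gaps, and
  travel speeds (km/d) by first differencing.
* **Modality analysis** — an exact, from-scratch implementation of the
  Hartigan dip statistic `D = min over unimodal CDFs G of sup_x |F_n(x) - G(x)|`
  with uniform-bootstrap calibration; histogram mode identification; the
  *modal transiting speed* (the mode holding most of the distribution); and
  classification of putative foraging locations at ≤ 40% of it.
* **Current correction** — geostrophic surface currents from sea-surface
  height with an equatorial beta-plane solution inside ±4°, a two-parameter
  Ekman layer from wind stress, bilinear sampling along tracks, and exact
  removal of currents to recover swimming velocities.
* **Environmental co-location** — thermocline depth (maximum temperature
  gradient) and nutricline depth (2 µmol nitrate isocline) from a 1°
  profile climatology, chlorophyll-a sampling from 8-day 0.05° composites
  with bounded cloud-gap search, and dive-depth-by-latitude summaries.
* **Synthetic data** — a regime-switching correlated random walk with
  bout-persistent paces, an Argos observation model (class mix,
  class-dependent position error, transmission gaps), and synthetic ocean
  fields, so the entire pipeline runs and is tested without any download.

The statistics are classical movement-ecology quantities; see the vignette
(`vignettes/movement-analysis.Rmd`) for the model details, parameter
defaults, and the design decisions behind the synthetic generator.

## Worked example

Simulate a bimodal-style population track, push it through the full chain,
and test modality:

```r
library(pelagitrack)

sc     <- scenario_na(duration_days = 150, seed = 7)   # two-mode preset
fixes  <- degrade_to_argos(simulate_true_track(sc), sc)
chain  <- process_track(fixes, drop_classes = character(0))
result <- analyze_modality(chain$speeds, bin_width = 5, n_boot = 2000, seed = 1)
result
#> Travel-speed modality analysis
#>   n = 598 steps; dip = 0.0564, bootstrap p = 0.0004998 (2000 resamples)
#>   modes at 12.5, 37.5 km/d
#>   modal transiting speed 37.5 km/d; foraging threshold 15.0 km/d
```

The simulated animal spends 29% of its time below 15 km/d and 42% between
20 and 45 km/d; the chain recovers both speed modes (12.5 and 37.5 km/d),
identifies 37.5 km/d as the modal transiting speed because its histogram
band holds the larger mass, rejects unimodality (bootstrap dip test,
p ≈ 0.0005), and sets the foraging threshold at 40% of the modal speed
(15 km/d). A single-regime preset (`scenario_ep()`, modal speed 21 km/d)
instead yields one mode, p near 1, and a 8.4 km/d threshold.

`run_population_analysis()` wires the stages into a two-population
comparison (filtering → regularization → speeds → modality → current
correction → chlorophyll co-location → dive/latitude table) and serializes a
deterministic JSON report via `write_report()`.

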