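# shortcutflux

Storm drainage inlets along farm tracks and roads act as *hydraulic
shortcuts*: they collect surface runoff from fields and roads and pipe it
straight to the stream, bypassing any buffer the landscape would otherwise
provide. During rain events this pathway can carry substantial pesticide
loads from recently sprayed fields into surface waters. `shortcutflux` is an
R package for analysing this transport pathway in small agricultural
catchments. It is aimed at environmental scientists working with
event-based monitoring data from inlets, collector shafts and streams.

The package implements the full analysis chain:

* **Rain-event segmentation** — a rainfall episode becomes an event if its
  depth exceeds 1 mm within an 8-h window; episodes separated by at least
  8 h of dry record are distinct events. Sampling flags reproduce the field
  trigger logic (per-inlet stage thresholds of 2/3 cm; collector shaft and
  stream samplers start when at least two inlets trigger).
* **Surface-runoff connectivity** — D-infinity flow routing (Tarboton) on a
  conditioned DEM (road carving, depth-capped sink filling) delineates the
  contributing area of every inlet, the stream and infiltration sinks, with
  Monte Carlo propagation of the conditioning parameters (default 100
  runs).
* **Inlet hydrology** — stage records are converted to discharge through a
  power-law rating curve calibrated up to ~0.5 L/s; above the calibrated
  range three continuation scenarios give a (Q_min, Q_mod, Q_high) bound
  triple. Fast flow in the stream is separated with the three-pass
  Lyne–Hollick recursive filter at α ∈ {0.9, 0.925, 0.95}, and inlet/stream
  discharge ratios r_Q and r_Q,fast are formed with conservative pairing.
* **Transport-pathway attribution** — each (sample, substance) is assigned
  a category from the spatio-temporal relation between applications and the
  site: **D** surface runoff possible (application in the contributing
  area), **C** spray drift possible (within 100 m of the site or of a road
  draining to it), **B** applied without either potential, **A** no prior
  application.
* **Censored load ratios** — per (site, event, substance) the load triple
  is `f = (Q_min·c_min, Q_mod·c_min, Q_high·c_max)` with
  `c_min = 0, c_max = LOQ` for values below the limit of quantification.
  Inlet/stream ratios use cross-pairing (`Σf_inl,min / f_stream,high`, …),
  aggregated both as the mean per-substance ratio (r_f,μ,subst) and as the
  ratio of load sums (r_f,μ,sum), with attribution of the min–max spread to
  LOQ censoring vs discharge uncertainty and extrapolation from the sampled
  inlets to the whole catchment (road-area, agricultural-area and count
  weighting).
* **Concentration model** — a random-intercept linear model of log10 inlet
  concentrations with application, substance-property and event covariates;
  the collinear sorption pair (log10 K_foc, log10 K_ow) is reduced by
  single-variable-deletion AIC.
* **Synthetic study system** — a generator that builds a catchment (DEM,
  roads, inlets, plots), rainfall, plot-resolved applications and fully
  simulated observations with recorded ground truth, so every stage is
  testable end to end without any external data.

## Worked example

```r
library(shortcutflux)

report <- run_pipeline(pipeline_config(seed = 1))
report
#> <pipeline_report>
#>   events: 36 (20 sampling)
#>   samples: 3160 rows at 6 sites
#>   r_f_mu_subst mod: 0.00316; r_f_mu_sum mod: 0.00398
#>   manifest hash: 422e851c
```

For seed 1 the synthetic record contains 36 rain events, 20 of which
triggered sampling somewhere. The moderate estimate of the mean
inlet/stream load ratio per substance (r_f,μ,subst) is ≈ 0.32% and the
load-sum ratio (r_f,μ,sum) ≈ 0.40%: the four sampled inlets carry well
under a percent of the stream's pesticide load. Individual stages are
available too:

```r
d <- report$discharge_ratios
mean(d$r_q_fast_mod[d$total_mm > 10], na.rm = TRUE)
#> [1] 0.01018861   # ~1% of the stream's fast flow for large events

report$load_extrapolation$span
#>      aggregate        lo        hi
#> 1 r_f_mu_subst 0.1247263 0.1583962
#> 2   r_f_mu_sum 0.1572455 0.1996941
```

Extrapolated to all 158 inlets, the load-sum ratio rises to roughly 16–20%
across the three weighting methods — the same order as the catchment-scale
relevance reported for real systems of this type.

A thin command-line launcher over the same functions is installed at
`inst/cli/shortcutflux.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/shortcutflux.R", package="shortcutflux"))')" all --seed 1 --out out/
```

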