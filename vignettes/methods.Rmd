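---
title: "Methods: pesticide transport through storm drainage inlets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pesticide transport through storm drainage inlets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shortcutflux)
```

## The problem

In many intensively farmed landscapes, fields and farm tracks drain not to
ditches but to gridded storm drainage inlets whose pipes discharge directly
into the receiving stream. These *hydraulic shortcuts* connect remote
fields to surface waters within minutes. Event-based monitoring at such
inlets produces three linked data streams — rainfall, water-level (stage)
records, and per-event composite-sample concentrations with a substantial
fraction of values below the limit of quantification (LOQ) — and the
scientific questions are (i) how much of the stream's storm response passes
through inlets, (ii) how much of the pesticide load does, and (iii) which
application and substance factors drive inlet concentrations.
`shortcutflux` implements this analysis chain with explicit uncertainty
bounds, plus a synthetic study system with recorded ground truth that makes
every stage testable.

## Rain events and sampling triggers

An episode of recorded rainfall becomes a *rain event* when its cumulative
depth strictly exceeds 1 mm within some 8-h window; later rainfall joins
the same event unless separated by a dry gap of at least 8 h. Design
choices that the rule alone does not fix, resolved here once:

* the 1-mm test uses a *sliding* 8-h window (an anchored window would make
  event existence depend on arbitrary alignment);
* "dry" means strictly zero recorded depth at the 0.1-mm gauge resolution;
* a gap of exactly 8.0 h terminates an event; a depth of exactly 1.0 mm
  does not qualify ("exceeds" is strict);
* event boundaries are the first and last wet minute of the merged episode.

A composite sample exists at an inlet for an event iff its stage threshold
(0.02 m for small, 0.03 m for larger inlets — equivalent to roughly 1.7 and
4.7 L/min through the default rating) was exceeded during the event window.
Collector-shaft and stream samplers start only when at least two inlets
triggered. Missing stage data yields "unknown" (`NA`), never "not
sampled", so data gaps cannot masquerade as quiet events.

## Surface-runoff connectivity

Contributing areas are delineated on a conditioned DEM:

1. cells under the road network are lowered by the *road carving depth*
   (default 0.1 m) — the sub-grid effect of roads concentrating runoff;
2. depressions are filled to their pour level with a small epsilon
   gradient, but only if their maximum depth does not exceed the *sink
   filling depth* (default 0.1 m); deeper depressions are retained as
   infiltration sinks. Filling uses an iterative Planchon–Darboux-style
   sweep; depressions are identified as 8-connected components of raised
   cells.

Flow directions follow the D-infinity construction: per cell the steepest
descent over eight triangular facets, with flow split between the facet's
two neighbours in proportion to the angular position of the steepest
direction. Cells without a downslope facet (including grid-edge cells with
no in-grid descent) are sinks. Each cell's unit area is routed until
absorbed by an inlet cell, a stream cell, a WWTP-mask cell, or a sink; the
cell is labelled by the destination receiving the largest share (majority
rule, ties broken by destination order), while fractional shares are kept
for area accounting. The propagation is a single sweep in increasing
elevation order, exact because every receiver with positive proportion is
strictly lower; the test suite checks it against exhaustive fractional path
enumeration on small grids at 1e-9.

Parameter uncertainty is propagated by re-running the full
conditioning–routing–delineation chain with carving and filling depths
drawn from uniform ranges (100 runs by default, mirroring the scale of the
study design this package follows).

The exposure table intersects contributing areas with plot-resolved
application records. The spray-drift radius is 100 m, measured from the
*plot polygon boundary* to the site point (the boundary, not the centroid,
because drift originates at the sprayed edge nearest the site); indirect
drift requires a road cell draining to the site within 100 m of the plot.

## Discharge and fast flow

Inlet stage converts to discharge through `Q = a·h^b` with defaults
`a = 500 L s⁻¹ m⁻²·⁵`, `b = 2.5` — a sharp-crested V-notch-like law chosen
so that the documented trigger stages of 2 and 3 cm correspond to ≈1.7 and
≈4.7 L/min. The curve is treated as calibrated up to the stage at 0.5 L/s
(≈6.3 cm). Above that, the truth is unknown, so three continuation
scenarios bound it: the exponent is multiplied by 0.8 / 1.0 / 1.2
(min/mod/high), all continuous at the calibration limit. These multipliers
are a configurable stand-in for a rating-specific extrapolation analysis;
any monotone, ordered scenario family can be substituted.

Event volumes integrate the discharge series trapezoidally over the event
window extended by a 2-h recession tail (inlets keep draining after the
last wet minute; the tail length is configurable).

Stream fast flow uses the Lyne–Hollick recursive filter,
`f_t = α·f_{t−1} + (1+α)/2·(Q_t − Q_{t−1})`, clamped to `[0, Q_t]`, with
the standard three passes (forward, backward, forward; each pass filters
the previous pass's baseflow; the first filtered value of each pass is 0).
α ∈ {0.9, 0.925, 0.95} gives low/moderate/high fast-flow estimates — on
storm-shaped hydrographs the fast volume is increasing in α, which the
tests verify. Discharge ratios pair conservatively: the minimal inlet
estimate is divided by the *high* fast-flow estimate and vice versa, so the
reported triple brackets the truth. Stream discharge itself carries no
uncertainty here (its relative error is far below the inlet rating
uncertainty).

## Censored loads and their algebra

For a measured concentration `c` with substance LOQ:

* `c_min = c` if quantified, else 0; `c_max = c` if quantified, else LOQ;
* the load triple is `f = (Q_min·c_min, Q_mod·c_min, Q_high·c_max)` — the
  moderate slot deliberately uses `c_min`, so a censored record contributes
  nothing to the minimum and moderate loads and `Q_high·LOQ` to the high
  load;
* the inlet/stream ratio triple cross-pairs numerator and denominator
  (`Σf_inl,min / f_stream,high`, `Σf_inl,mod / f_stream,mod`,
  `Σf_inl,high / f_stream,min`);
* two aggregates: the arithmetic mean of the per-cell ratio triples, and
  the ratio of load sums with the same pairing. Cells whose stream load is
  fully censored have an undefined high ratio; they are excluded from the
  mean *with the exclusion count reported* — silently dropping them would
  bias the aggregate, and substituting anything would fabricate
  information. The mean's denominator is the number of included cells.

The spread between high and low aggregate estimates is attributed to its
two sources by recomputation: holding discharge at its moderate value
isolates the LOQ share; replacing censored values by their moderate
substitution (zero) isolates the discharge share. Catchment extrapolation
scales the summed inlet loads by road-area, agricultural-area and
inlet-count factors before ratio formation and reports the span across
methods.

Unit discipline is ng, L and ng/L throughout; constructors reject negative
and unordered inputs.

## The concentration model

The response is log10 of the inlet concentration (censored values
substituted by the LOQ before the transform — the same convention used in
the category-wise concentration comparisons; LOQ/2 is available as an
option). Covariates: days since the most recent *relevant* application
(one with runoff or drift potential to that inlet, falling back to the most
recent in-catchment application), log10 cumulative mass applied, log10
K_foc, log10 K_ow, the soil and water half-lives, log10 of the moderate
event discharge, and the transport category as a 4-level factor with A as
reference. The inlet is a random intercept; estimation is REML with
Satterthwaite degrees of freedom for the fixed-effect p-values
(`lmerTest`). Rows are restricted to substances with properties available
and at least one application inside an inlet's contributing area.

If the two sorption covariates correlate beyond |r| = 0.7, the model is
fitted twice deleting one of them each time and the deletion with the lower
AIC wins (with K_foc causal and K_ow a noisy copy, the simulation tests
show the copy is removed in ≥95% of runs). A singular fit is flagged and
its random-intercept variance reported as 0.

## Transport categories

Precedence D > C > B > A; an application counts as "before the event" if
its calendar date is on or before the event's start date (applications are
day-resolved, so a same-day application cannot be excluded and is treated
as prior). D requires an application inside the site's contributing area;
C requires drift potential without runoff potential; B any prior
in-catchment application; A none. For collector shaft and stream, D
carries a tile-drainage annotation, since those sites also receive tile
drainage. The generator computes its ground-truth labels from the same
geometric predicates through an independent code path, and the test suite
requires 100% agreement — this checks that the attribution logic is a
faithful function of the exposure geometry, not that the geometry is
correct in nature.

## The synthetic study system

The generator emulates the *structure* of an instrumented small agricultural
catchment, not any particular landscape:

* terrain: a valley trend with 5% mean down-valley slope plus smoothed
  Gaussian noise and optional dug-in depressions; the stream runs along the
  valley bottom;
* infrastructure: east-west farm tracks every 100 m, one concrete road,
  158 inlets placed on road cells (the census of the system the package
  emulates), rectangular crop plots between roads;
* rainfall: Poisson storm arrivals over a 1 April–20 August window,
  lognormal totals and durations, gamma-shaped within-storm profiles,
  quantised to 0.1 mm conserving totals. The default storm rate (0.30/day)
  was chosen once so that a season yields a few dozen events spanning
  ~1–40 mm;
* applications: spring-weighted dates, lognormal masses, 96% of mass
  inside the window by construction;
* observations: per-inlet activation totals drawn from 1.3–3.6 mm; runoff
  volume = effective depth × runoff-coefficient-weighted contributing area
  (concrete 0.8 > farm track 0.45 > field 0.12 — only this ordinal
  structure matters); concentrations are load/volume with multiplicative
  lognormal noise (σ_log10 = 0.2), constant within an event per site. Load
  sources: wash-off of prior in-CA applications decaying at ln2/DT50_soil,
  spray-drift deposits spent at the first event after application, random
  background/spill pulses, a stagnant-water reservoir carrying a fraction
  (0.25) of each event's load into the next, and a diffuse tile-drainage
  export term feeding the stream (and, at half share, the collector
  shaft). Source coefficients were set once so that simulated
  concentrations span the tens-to-thousands of ng/L with a realistic
  censoring fraction;
* the four "instrumented" inlets are drawn from the mid-to-upper range of
  the contributing-area distribution — instrumentable, but not the
  extremes — and carry a few percent of the inlet-connected area, as in
  a realistic four-of-158 design;
* the stream's fast flow is dominated by non-inlet sources (urban
  surfaces, tile drainage, pre-event water), represented by an additional
  fast-responding area fraction (0.35 of the catchment).

What the generator does **not** emulate: within-event chemograph dynamics
(concentrations are constant per event, following evidence that road-runoff
concentrations vary little within events), wind-driven drift physics, soil
erosion and particulate-phase transport, snow processes (snowmelt is only a
flag that boosts road runoff for one event), and real GIS geometry
(plots are rectangles; roads are straight). Passing tests therefore show
that the *analysis* is correct and internally consistent under known ground
truth — not that any particular real catchment behaves like the default
configuration.

## Numerical choices and problem sizes

* Depression filling: epsilon 1e-5 m per step ensures strict descent off
  filled areas; the filled/unfilled decision threshold is 1e-12 m.
* Majority labels break ties by destination order (inlets, stream, WWTP,
  sink); fractional shares are exact to the propagation order.
* Cells whose routed mass does not fully resolve (possible only with
  degenerate direction fields) are assigned to sink and counted in a
  warning.
* The default grid is 250×250 cells at 2 m (0.125 km²) with all 158
  inlets: large enough that contributing areas, drift radii and road
  topology interact as in a full-size system, small enough that the whole
  pipeline runs in seconds. The Monte Carlo stage runs on a 60×60
  companion catchment with proportionally fewer inlets; parameter-recovery
  simulations use 30×30 systems over shorter windows. These sizes are the
  package's choices for its own test design.
* Degenerate inputs: grids below 20×20 are rejected (too small for
  routing); empty application sets, zero storm rates, zero plots and
  single-level random factors all have defined behaviour covered by tests.

## Known limitations

* The contributing-area model is purely topographic; infiltration
  heterogeneity, antecedent moisture and crusting are outside scope.
* The rating-curve extrapolation scenarios are a parametric stand-in; if a
  site-specific hydraulic analysis exists, its scenario family should be
  substituted.
* The mean-of-ratios aggregate excludes fully censored stream cells, which
  biases it toward cells with detectable stream load; the exclusion count
  is reported so users can judge the severity.
* Grab samples of stagnant water substitute composite samples when an
  inlet did not trigger; a flag preserves the sample type, but the two are
  treated as exchangeable concentrations downstream.
* The concentration model is observational; its coefficients describe the
  synthetic (or supplied) data, not causal effects.
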