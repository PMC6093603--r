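---
title: "Methods: simulating and valuing marsh adaptation under sea-level rise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and valuing marsh adaptation under sea-level rise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marshplan)
```

`marshplan` couples three models — a stochastic marsh-fate simulator, a
multi-criteria ecosystem-service valuation, and a strategy cost model —
into a single ranking of marsh-adaptation strategies by expected benefit
per million dollars. This vignette records the modelling assumptions,
the defaults and why they were chosen, and the limits of what the
package's tests can demonstrate.

## The marsh-fate simulator

Full marsh-fate models (SLAMM and kin) track dozens of wetland
categories with site-calibrated transition rules. `marshplan`
deliberately replaces that machinery with an *elevation-band*
classifier over six aggregated categories — open water, tidal flat,
saltmarsh (regularly flooded), transitional (irregularly flooded)
marsh, and dry undeveloped/developed land — anchored at three tidal
datums: mean tide level (MTL, the elevation origin), mean higher high
water (MHHW), and the salt boundary (the upper limit of tidal
vegetation). The simplification keeps the mechanisms that drive the
decision problem while making every transition auditable:

* **Band classification.** A cell's category is read off its elevation
  relative to the *current local* MTL. Categories only move seaward
  over time (a cell that drowns does not spontaneously recover), unless
  an intervention explicitly raises its elevation.
* **Accretion feedback.** Marsh cells gain elevation at
  `a_max − (a_max − a_min)·z/z_bound` (mm/yr), maximal at MTL and
  minimal at the salt boundary. This is the standard negative feedback
  by which low marsh traps sediment fastest; it also means artificially
  raised marsh (thin-layer deposition) accretes more slowly afterwards,
  so deposition benefits fade over decades.
* **Marsh collapse.** Conversions to a wetter marsh class carry a loss
  of elevation capital from rapid decomposition of sub-surface biomass:
  0.07 m (transitional to saltmarsh) and 0.19 m (saltmarsh to tidal
  flat) at the default central values, drawn per realization from
  truncated normals (sd 0.03 m, truncated at 0). The sd is our choice:
  field estimates of collapse magnitudes are sparse, and a wide
  distribution represents that honestly without admitting negative
  losses.
* **Armoring.** Strategy semantics are expressed through which dry
  cells are armored during reclassification: no-action (`PROTECT`)
  armors all dry land; the undeveloped-migration strategy armors only
  developed land; the developed-migration strategy armors nothing.
  The restoration and deposition strategies armor all dry land so that
  each strategy's measured benefit is attributable to its single
  intervention. Armored cells never convert, however deep the
  inundation — armoring is read as permanent defence (a configurable
  reading; the alternative, eventual conversion to open water, changes
  no ranking on our fixtures).

Time stepping works directly on the output years (default every 5 years,
2016–2100). Collapse is detected between consecutive output years, so a
cell that skips a band within one interval incurs the loss for the
transition actually observed.

## Uncertainty propagation

All uncertain inputs are described as distributions (`point`, `uniform`,
`triangular`, `truncated-normal`) and sampled jointly by Latin-Hypercube
sampling: for each parameter the n draws occupy its n equal-probability
strata exactly once, with strata permuted independently across
parameters. The SLR-by-2100 default is uniform on [0.47 m, 2.01 m] —
the bounds span the plausible scenario range and nothing in between is
privileged. The within-century trajectory is the anchored quadratic
`offset(t) = slr_2100·τ²`, the simplest accelerating curve passing
through both endpoints; the shape only matters through the relative
weighting of mid-century versus late-century states, and is
configurable.

Elevation data error is a spatially autocorrelated field: white
Gaussian noise smoothed by a separable Gaussian kernel of scale
`corr_length` (default 30 m, typical of lidar DEM error correlation),
recentred and rescaled to the target sd (default 0.05 m). Any
stationary construction with the right mean, sd and increasing lag-1
autocorrelation would serve; this one is cheap and exact at the grid
scale we use.

Realization *j* of every strategy shares the same parameter draw and
error field (common random numbers), so strategy contrasts are
differences in dynamics, not sampling noise. Sub-seeds are derived
deterministically from the master seed, so individual realizations are
reproducible in isolation.

## Valuation

Service values are linear in landscape metrics
(S = (Σᵢ sᵢAᵢ + s_edge·E + s_width·D)·V). The edge and width terms
extend the pure-area form because habitat and flood-protection services
demonstrably depend on the marsh/open-water interface and on marsh
width; nonlinear and threshold forms are out of scope. The marsh width
metric itself is defined as marsh area divided by interface length
("hydraulic width") — rotation-invariant, cheap, and exact for
rectangular fringes; a transect-based width would need a shoreline
model we do not have. The interface uses 4-connectivity (diagonal
adjacency double-counts ambiguously).

Normalisation divides each service by its initial cross-site mean
computed **on the no-action initial condition and reused for every
strategy** — otherwise strategies would be scored on different scales
and their Z values would not be comparable. The shipped stakeholder
weights are the eleven-service survey shares (7.6% carbon … 8.7%
general preservation); they sum to 99.9% as printed and are
renormalised to 1 at load. The shipped per-service coefficients are
**illustrative**: the survey-derived originals are not public, so the
defaults merely key each service to sensible metrics (sequestration to
marsh area, nekton to edge, flood protection to width, recreation to
dry undeveloped area). Any real application must supply its own
`services.csv` and site multipliers.

Time weights q default to uniform (no discounting; a geometric option
exists), and realization weights z default to equal — restricting the
analysis to an SLR band is done by zeroing z outside the band and
renormalising.

## Costs

Migration strategies are charged the *expected* conversion footprint:
per cell, the realization fraction that starts dry and ends as marsh in
2100, times cell area, grouped by ownership class and priced at the
midpoint of the class's low/high $/ha estimates with a 20% markup
(parkland free). We monetise the expectation rather than a fixed
quantile mask because the ranking statistic is itself an expectation; a
`P ≥ q` mask option is available. The developed-migration strategy adds
a physical-restoration charge on converted developed land at the
edge-restoration unit — a stand-in, as no separate unit is published.
The intervention units ($550,000/acre thin-layer, $624,000/acre edge
restoration, 1 acre = 0.4047 ha) are published engineering estimates.
The ownership-class dollar ranges shipped in `costs.csv` are
illustrative placeholders. Costs are nominal dollars; acquisition
timing and appreciation are ignored.

## The synthetic estuary

The fixture generator emulates the geometry that makes the decision
problem non-trivial: a west-east shore gradient from subtidal (−2 m) to
upland (+3 m), a meandering steep-banked channel (so marsh touches open
water directly and the interface metric is exercised), smooth correlated
topographic noise (sd 0.15 m), randomly blocked ownership in the four
cost classes, alongshore site bands, and a "1974 footprint" strip of
current flat/open water adjacent to today's marsh. It does **not**
emulate: real channel networks, erosion or overwash, salinity gradients,
parcel-scale ownership geometry, or calibrated accretion fields. Tests
passing on this fixture demonstrate the machinery — band dynamics,
stratified sampling, aggregation identities, cost arithmetic — not the
fidelity of any specific coastal forecast.

## Numerical choices and degenerate inputs

* ASCII grids are written with 17 significant digits so doubles
  round-trip bit-exactly.
* Thin-layer eligibility (Euclidean distance ≤ 60 m, threshold
  inclusive, cell centre to cell centre) is computed by exact
  integer-offset dilation — identical to the all-pairs computation.
* A zero-sd error field, an empty 1974 footprint (warned no-op), a site
  without marsh (zero interface → width defined as 0), and a service
  with zero initial mean (dropped with a warning, division undefined)
  are all handled explicitly.
* `accretion_max < accretion_min` in a joint draw is repaired by
  swapping, preserving the rate law's orientation.
* Ties in the ranking break by lower cost, then site name; zero-cost
  positive-benefit rows are flagged `UNBOUNDED` and listed first rather
  than given infinite ratios.

## Problem sizes

The default configuration (64×64 cells at 5 m, 50 realizations, five
strategies, 5-year steps 2016–2100) runs in well under a minute on one
CPU; the test suite uses 16–32-cell grids with 1–2 realizations for
unit checks and exercises the full default size once. These sizes were
chosen so the full Monte-Carlo design remains interactive; the engine
is linear in cells × realizations × strategies × years.

## Known limitations

* The simulator is a reduced-form stand-in: no 26-category transition
  tree, no erosion, no salinity, no storm events, no flood-frequency
  module for infrastructure.
* Thin-layer deposition is applied once at the start year;
  re-application schedules are not modelled.
* Utility is ordinal across strategies but has no monetary
  interpretation; the package ranks, it does not solve a budget-
  constrained portfolio problem.
* All shipped coefficients and land-cost ranges are illustrative; the
  published engineering units (collapse losses, deposition geometry,
  intervention unit costs, weight shares) are the only quantities
  carried over as-is.
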