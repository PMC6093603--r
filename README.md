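# marshplan

Decision support for tidal-marsh conservation under uncertain sea-level
rise (SLR).

Coastal managers facing accelerating SLR must decide, parcel by parcel,
whether to armor shorelines, buy upland so marshes can migrate, restore
historical marsh footprints, or spray dredged sediment onto drowning
marsh surfaces — all with a limited budget and deep uncertainty about
how much the sea will actually rise. `marshplan` ranks such adaptation
strategies by *expected ecosystem benefit per million dollars spent*,
propagating uncertainty end to end: from stochastic marsh-fate
projections, through stakeholder-weighted ecosystem-service valuation,
to per-strategy cost models.

## The model

**Marsh fate.** Land cover is classified from elevation relative to the
local tidal datums: open water below −MHHW, tidal flat on [−MHHW, 0),
regularly-flooded saltmarsh on [0, MHHW), irregularly-flooded
transitional marsh on [MHHW, salt boundary), dry land above. Each
Monte-Carlo realization draws a joint parameter set (SLR by 2100, tidal
datums, accretion rates, collapse losses, elevation-error field) by
Latin-Hypercube sampling and steps the landscape forward: marsh accretes
at a rate decreasing with platform elevation; rising water reclassifies
cells seaward unless armoring blocks conversion; marsh-collapse
transitions remove elevation capital (7 cm for transitional→saltmarsh,
19 cm for saltmarsh→tidal flat). Strategy interventions act on the
initial state — e.g. thin-layer deposition adds 20 cm to low marsh
within 60 m of open water or dry land, and edge restoration regrades the
1974 marsh footprint to mean tide level.

**Valuation.** Each ecosystem service *i* at a site is a linear function
of landscape metrics times a site-quality multiplier,
S = (Σᵢ sᵢAᵢ + s_edge·E + s_width·D)·V, normalised by its initial
cross-site mean so services are non-dimensional (S̃ᵢ = Sᵢ/⟨Sᵢ(0)⟩).
Aggregation is a chain of weighted sums: over services
(W = Σ wᵢ S̃ᵢ, stakeholder weights), over years (Q = Σ qₖ Wₖ), and over
realizations (Z = Σ zⱼ Qⱼ). With Σwᵢ = 1 the cross-site start-year mean
of W is exactly 1 (reported as 100 utility units).

**Costing and ranking.** Migration strategies pay the midpoint of
low/high land-cost estimates per ownership class (+20% markup; parkland
free) on the expected dry→marsh conversion footprint; thin-layer and
edge restoration pay $550,000 and $624,000 per acre (0.4047 ha) on the
treated area. Strategies are ranked by
(Z_strategy − Z_no-action) per million dollars.

## Worked example

```r
library(marshplan)
cfg <- default_config()
cfg$seed <- 42L; cfg$n_realizations <- 10L; cfg$years <- seq(2016, 2096, 10)
cfg$fixture$n_rows <- 32; cfg$fixture$n_cols <- 32
res <- run_analysis(cfg)
res$ranking[, c("site","strategy","benefit","persistent_ha","cost",
                "benefit_per_musd","rank")]
```

```
   site            strategy benefit persistent_ha   cost benefit_per_musd rank
1     2 MIGRATE_UNDEVELOPED  0.0643       0.02529  34080            1.887    1
2     1   EDGE_RESTORE_1974  0.1987       0.10371 254411            0.781    2
3     1 MIGRATE_UNDEVELOPED  0.1392       0.04276 244800            0.568    3
4     2   EDGE_RESTORE_1974  0.0964       0.09586 235137            0.410    4
5     1          THIN_LAYER  0.0527       0.00738 169879            0.310    5
6     1   MIGRATE_DEVELOPED  0.2192       0.08232 764942            0.287    6
7     2   MIGRATE_DEVELOPED  0.1388       0.06172 641641            0.216    7
8     2          THIN_LAYER  0.0518       0.01815 411107            0.126    8
9     1             PROTECT  0.0000       0.00000      0            0.000    9
10    2             PROTECT  0.0000       0.00000      0            0.000   10
```

`benefit` is the utility gain over no-action (Z units; the cross-site
start-year utility is 1 by construction), `persistent_ha` the
duration-weighted marsh area gained (a marsh lasting 10 of 80 years
counts 1/8 of its area), `cost` total dollars, and `benefit_per_musd`
the ranking statistic. On this synthetic estuary, letting marsh migrate
onto cheap undeveloped land at site 2 buys the most benefit per dollar;
buying out developed parcels delivers the largest absolute benefit at
the worst price; no-action sits at the bottom with zero benefit and
zero cost.

A shell interface wraps the same pipeline:

```sh
exec/marshplan report --seed 42 --outdir out/
# writes ranking.csv, ranking_windowed.csv, metrics.csv, costs.csv,
# utility_timeseries.csv, constituents.csv, landcover_expected.csv,
# per-year land-cover grids (.asc) and probability maps
```

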