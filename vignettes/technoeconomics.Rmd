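---
title: "Methods: the seaweed-farming technoeconomic model"
author: "seafarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the seaweed-farming technoeconomic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seafarm)
```

## The model

`seafarm` prices open-ocean seaweed farming cell by cell on a
latitude/longitude raster and converts the harvest into one of two climate
services: carbon dioxide removal (CDR) by sinking the biomass to the deep
sea, or avoided greenhouse-gas emissions by substituting the biomass for
conventional food, feed or fuel. Everything downstream hangs off four
spatial inputs — annual harvest yield $s_{dw}$ (tDW km$^{-2}$ yr$^{-1}$),
ocean depth, significant wave height, over-water distance to the nearest
port — plus the spatially varying fraction $f_{seq}$ of carbon deposited on
the seafloor that stays out of the atmosphere for at least 100 years.

**Farm-gate production.** Annualized capital cost per km$^2$ is a base rate
marked up multiplicatively in exposed water,

$$c_{cap} = c_{capbase}\,(1 + k_d\,[\text{depth}>500\,\mathrm{m}]
          + k_w\,[\mathrm{swh}>3\,\mathrm{m}]) + c_{slbase}\,p_{sline},$$

where $p_{sline}$ is metres of seeded line per km$^2$ implied by the line
spacing of the seaweed type grown in the cell. Operating cost sums
insurance, licence, labour and other recurring costs; harvest cost is a
per-harvest rate times the number of annual harvests; equipment reaches the
farm on a one-way barge leg charged per ton-km over the port distance.
Production cost per ton dry weight divides the per-km$^2$ total by
$s_{dw}$, and production emissions mirror the transport terms plus
round-trip maintenance traffic,

$$e_{mnt} = 2\,d_{port}\,e_{mntbase}\,\frac{n_{mnt}}{a_{mnt}}
          + e_{mntbase}\,d_{mnt}.$$

The maintenance term is implemented exactly as written: the per-km$^2$
patrol distance $d_{mnt}$ is not scaled by the trip count. Whether it
should be is genuinely ambiguous; we follow the printed form and note the
choice here.

**Sinking.** Wet mass is ten times dry mass. The harvest barge tows
biomass and used equipment to the assigned sinking site ($d_{sink}$), sinks
the load, returns to the farm and then to port, so seaweed transport is
charged over one $d_{sink}$ leg on wet tons while equipment is charged over
$2\,d_{sink}$ plus the port leg. Gross removal per km$^2$ is

$$e_{seqsink} = k_{atm}\,k_{fseq}\times 0.30 \times \tfrac{44}{12}\times
s_{dw},$$

with $k_{atm}$ the atmospheric removal fraction (air–sea disequilibrium and
phytoplankton nutrient competition folded into one scalar, sampled on
[0.4, 1]) and 0.30 the carbon fraction of dry weight. The removal equation
is stated per ton but summed per km$^2$ before the final normalisation; we
adopt the per-km$^2$ reading, which is the dimensionally consistent one,
and normalise once at the end. Net removal subtracts the transport
emissions; cells whose net removal is not positive are excluded from every
aggregate — we use a strict threshold of $10^{-9}$ tCO$_2$ tDW$^{-1}$
rather than exactly zero purely as division hygiene. With no carbon price
(the default) the sinking value is a pure cost, and the headline quantity
is $c_{pertonsink} = (c_{prod} - v_{sink})/(e_{remsink} - e_{prod})$ in $
per tCO$_2$ removed.

**Products.** Harvest returns straight to port; transport is charged on wet
tons plus equipment mass, normalised per dry ton. Product value is a
globally uniform market price minus transport and conversion costs.
Avoided emissions start from the category's substituted-emissions intensity
(food 1–6, feed 1–3.1, fuel 0.7–1 tCO$_2$-eq tDW$^{-1}$, all GWP$_{100}$;
the fuel range is consistent with 3.2–3.5 tCO$_2$ per ton fossil fuel at a
0.25 t-biofuel-per-tDW yield) and subtract the chain's own transport and
conversion emissions. Cells with no net avoided emissions are excluded; a
product worth more than it costs shows up as a negative cost, i.e. profit
per tCO$_2$-eq.

## Parameter ranges and sampling

Monte Carlo ranges follow two conventions: parameters with several
literature values take [min, max] as the 5th/95th percentile bounds;
single-value parameters take value ± 50%. Bounds are then rounded per
parameter class (capital/operating/harvest to \$10,000, labour/insurance to
\$1,000, line cost and transport cost to \$0.05, transport emissions to
5e-6, maintenance emissions to 5e-4, avoided emissions to 0.1, conversion
cost outward to \$10, conversion emissions to 0.01), and two floors are
extended to reflect possible innovation: capital cost down to \$10,000
km$^{-2}$ (autonomous farm) and transport emissions to 0 (net-zero
vessels). `build_ranges()` implements these rules; rows whose full
literature support is not reproduced in this package (capital, seeded line,
harvest, $k_{atm}$ and the placeholder rows below) carry their model ranges
as explicit bounds with the provenance noted per row.

Draws are independent uniforms within each rounded range — by design, no
correlation structure. Each simulation also draws which yield-uncertainty
percentile map (5/25/50/75/95) to use: a standard-normal draw is binned
with cut points at the normal quantiles of 0.15, 0.375, 0.625 and 0.85
(midpoints between the percentile levels), giving bin probabilities
0.15/0.225/0.25/0.225/0.15. The mapping from a "normal distribution over
five maps" to bins is not uniquely determined; midpoint bins are the
symmetric choice and the cut points are configurable in code.

The sinking-site optimisation uses a separate *mean parameter set*: the
midpoint of each *unrounded* literature range, except transport and
maintenance emissions whose minima are first extended to zero (giving e.g.
2.25e-5 tCO$_2$ t$^{-1}$ km$^{-1}$ for transport and 1.77e-3 tCO$_2$
km$^{-1}$ for maintenance).

Several scalars live only in supplementary material we do not reproduce:
annualized equipment mass $m_{eq}$, maintenance trip counts and areas,
insurance, licence, labour, other operating costs, and conversion
costs/emissions. Their shipped defaults are plausible placeholder ranges,
flagged as such in `default_parameter_table()$note`, and should be replaced
with sourced values for any substantive application.

## The sinking-site optimisation

Seaweed need not sink where it grew: towing to water with a higher
$f_{seq}$ trades transport cost and emissions against better permanence.
For each candidate fraction $q \in \{0.01, \dots, 1.00\}$ we build the set
of cells with $f_{seq} \ge q$, run one multi-source weighted distance
transform to get every cell's over-water distance to that set, evaluate the
sinking chain with mean parameters, $d_{sink}$ set to that distance and
$k_{fseq} = q$, and keep per cell the $q$ minimising the cost per ton
removed. Ties break to the smaller distance, then the larger $q$. Because
the local cell's own $f_{seq}$, snapped down to the 0.01 grid, is always a
candidate, the optimised cost can never exceed the sink-in-place cost; when
the winner is the home cell the unmodified local $f_{seq}$ is kept.
Candidate fractions above the field maximum have empty source sets and are
skipped; cells the mean-parameter sweep cannot validate at any $q$ (zero
yield, or net emissions everywhere) fall back to sinking in place. The
assignment is computed once and shared by all Monte Carlo draws — per-draw
reoptimisation would be a different, far costlier design.

The distance transform itself is a multi-source Dijkstra over the
8-connected ocean graph (compiled code, binary heap), with land impassable,
great-circle centre-to-centre edge weights (east–west pitches shrink with
cosine of latitude; diagonals follow the spherical geometry) and longitude
wrap-around on global grids. Connectivity and metric are not dictated by
the problem statement; 8-connectivity with geodesic weights is the standard
choice for ocean rasters, and the transform is oracle-tested against an
independent graph library on dozens of random land configurations.

## The synthetic world

The package ships a generator in place of a biophysical growth model and
real rasters, so the full pipeline is testable end to end.

* **Grid.** Equal-angle lat/lon raster; land from thresholded smoothed
  noise (contiguous blobs); per-cell spherical areas. Default 1 degree —
  coarse enough for minutes-scale ensembles, fine enough that the sinking
  optimisation actually moves biomass (about a quarter of ocean cells get
  $d_{sink} > 0$ at 1 degree).
* **Environment.** Smooth random fields within plausible ranges (depth
  0–6,000 m, wave height 0–6 m with a poleward trend, $f_{seq}$ in
  (0, 1)); ports on random coastal cells; $d_{port}$ from the same distance
  transform the sinking module uses; 5%-area shipping and MPA masks.
* **Yields.** Four types with distinct latitude affinities: tropical types
  peak near the equator, temperate near 45 degrees. Peak median yields
  (6,500 / 4,500 / 2,600 / 2,200 tDW km$^{-2}$ yr$^{-1}$) anchor tropical
  reds above 6,000 and temperate browns above 2,000 in productive water.
  Percentile maps multiply the median by ordered factors
  {0.5, 0.8, 1.0, 1.2, 1.5}, smoothly perturbed in space with cell-wise
  ordering enforced; the true inter-percentile spread of yield uncertainty
  is unknown to us, so this spread is an explicit free parameter. The
  nutrient-limited scenario damps the ambient fields by a smooth factor in
  (0, 1], guaranteeing limited ≤ ambient cell-wise.
* **Farm design per type.** Line spacing 0.75 m for tropical reds (dense
  raft/off-bottom culture), 1.0 m for tropical browns and temperate-red
  nets, 1.5 m for temperate-brown longlines; harvests consolidated into
  two annual campaigns for the fast-turnover tropical types and one for
  temperate types. These choices make seeded line the dominant average
  cost component, matching the reported structure of farming costs this
  model family is known for; they were set once alongside the cost ranges
  and are not fitted quantities.

What the generator does **not** emulate: real coastline geometry and
bathymetry correlation, seasonality, inter-annual variability, nutrient
fields (the limited scenario is a damping factor, not a nitrate budget),
and any spatial correlation between yield and environmental drivers beyond
latitude. Tests passing on this world therefore validate the *machinery* —
equations, optimisation, sampling, aggregation — not the geography of any
real cost map.

## Numerical choices

* Per-cell cost quantiles across simulations use the nearest-rank empirical
  inverse CDF (deterministic, oracle-testable against a plain sort);
  simulations in which a cell's pathway is invalid contribute nothing to
  that cell rather than an infinity.
* `cheapest_fraction()` sorts valid cells by cost with ties broken by cell
  index, and accumulates area until the target fraction of total ocean
  area; average costs over a mask are area-weighted for \$ per tDW and
  benefit-weighted (total dollars over total tons of benefit) for \$ per
  tCO$_2$(-eq), the natural reading of an average cost per ton of climate
  benefit.
* Reproducibility: every generator takes a seed and restores the caller's
  RNG state; ensembles derive one child seed per simulation index from the
  root seed, so results are independent of evaluation order; boosting runs
  single-threaded with a fixed seed.
* Parameter importance is gain-based from gradient-boosted regression
  trees (modest, fixed hyperparameters: depth 4, 300 trees, learning rate
  0.1), normalised to sum to one; split-count and SHAP-style attributions
  would be defensible alternatives, and a permutation-importance method on
  a held-out third of simulations is provided as a robustness check. The
  per-simulation outcome for importance ranking is the benefit-weighted
  average cost within that simulation's own cheapest 1% or 2% area — the
  scalar "cost where costs are lowest" is not uniquely defined, and this
  choice is configurable.

## Problem sizes

The shipped test-suite and acceptance runs use a 16 x 32 fixture world for
unit and oracle tests, 50 random grids up to 20 x 20 against the Dijkstra
oracle, a 36 x 72 world for the scenario comparison, and the full 1-degree
(180 x 360) globe with a 500-draw ensemble for the quantile-ordering and
sensitivity properties — sizes chosen so the whole suite completes in a few
minutes on a single core while still exercising every code path at the
default resolution.

## Known limitations

Placeholder parameter rows (above) bound what the absolute dollar values
mean; the synthetic world bounds what spatial patterns mean. Sequestration
permanence enters only through the scalar map $f_{seq}$ and the scalar
$k_{atm}$ — no ocean circulation, no time dimension, no multi-century
accounting. Market values are globally uniform and demand is unlimited; no
price response, discounting or financing structure beyond annualized costs.
The equation chain is linear in each cost parameter, so Monte Carlo spread
is driven entirely by the input ranges, not by model nonlinearity.
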