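---
title: "Methods: coupled sea-level-rise and migration simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled sea-level-rise and migration simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slrmig)
```

## The joint model

`slrmig` couples a climate-impacts step with a migration step over a list
of spatial zones (county equivalents). For a scenario year with sea-level
rise $x$, the climate step partitions each zone $i$ into an affected
portion $\theta_i^A$ (population on flooded land, summed from sub-zone
exposure records at increment $x$) and an unaffected portion
$\theta_i^U$. The migration step computes two flow matrices and their sum
$T = T' + T''$:

$$T'_{ij} = g_C(m_i^A)\,P'_{ij}, \qquad T''_{ij} = g_S(m_i^U)\,P''_{ij},$$

where the production functions are linear, $g(m) = \alpha m$, with
$\alpha_C = 1$ (forced displacement: everyone on flooded land moves) and
$\alpha_S = 0.03$ (the long-run annual inter-county migration fraction).
Climate flows run from affected portions to habitable portions, including
the origin zone's own habitable half; business-as-usual flows run between
habitable portions, excluding same-zone pairs. Fully flooded zones stay
origins but are removed from every destination set. A matched baseline —
the same zones with no flooding, business-as-usual flows only — is run at
every step; it never reads the exposure table, which gives the structural
identity that zero exposure reproduces the baseline exactly.

A county is *directly affected* by the population on its flooded land and
*indirectly affected* at level $d$ when its extra incoming migrants
(scenario minus baseline) exceed $d\%$ of its population, with strict
inequality. Incoming counts exclude intra-county relocation by default:
people moving from a county's flooded half to its habitable half are
existing residents, and counting them would flag every flooded county as
indirectly affected, erasing the direct/indirect distinction the
framework exists to draw (a switch restores them). Flag sets nest across
thresholds by construction.

## Destination-choice models

All models share the four spatial-interaction features per ordered pair:
origin population $m_i$, destination population $m_j$, great-circle
distance $d_{ij}$ (haversine, Earth radius 6371.0 km, parent-zone
centroids), and intervening opportunities $s_{ij}$ — the habitable
population strictly closer to the origin than the destination, excluding
both endpoints. Ties exactly on the circle boundary are excluded; this
strict-interior convention makes small worked examples deterministic.
Opportunity mass uses post-flooding ($\theta^U$) populations: flooded
portions are not opportunities.

The radiation model uses
$w_{ij} = m_i m_j / [(m_i+s_{ij})(m_i+m_j+s_{ij})]$; the extended
radiation model generalises it with an exponent $\alpha$ (default 0.5)
controlling scale sensitivity. Weights are normalised *within each
origin's offered destination set* rather than by the open-system
correction $1/(1-m_i/M)$: the framework needs $P_{ij}$ to be a
distribution over where a leaving migrant goes, and the offered set
changes per origin (own-zone pair included for climate origins, excluded
for baseline origins, flooded zones removed).

The neural scorer is the trainable counterpart: same features, free
functional form. We fit a single-hidden-layer network (`nnet`, default 24
units, logistic output) to per-origin flow *shares* by cross-entropy,
with inputs $\log m_i, \log m_j, \log d_{ij}, \log(1+s_{ij})$
standardised internally; raw scores are renormalised per origin at
prediction time, so predicted rows are probability distributions
regardless of output scale. Weight decay ($10^{-4}$) regularises; across
restarts the fit with the best held-out-origin cross-entropy is kept; all
randomness (initial weights, origin split) derives from one seed, making
refits bitwise reproducible. A deeper architecture would be defensible —
we kept the single hidden layer because it already recovers the
generating models in the package's fixtures at held-out CPC above 0.95
and keeps fitting fast and dependency-light; the size, decay and
iteration budget are arguments, not constants.

Model agreement is scored by the common part of commuters,
$\mathrm{CPC} = 2\sum\min(T_a,T_b)/(\sum T_a + \sum T_b)$.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `rate_C` | 1 | fraction | forced displacement claims the whole affected population |
| `rate_S` | 0.03 | fraction/yr | observed normal-conditions county out-migration rate |
| `d` | 0.5, 1, 3, 6, 9 | % of county pop | indirect-effect intensities; 3% means doubling of normal in-migration |
| `intra_km` | 1 | km | distance for the own-zone pair; strictly positive so distance-decay kernels stay finite (the two halves share a centroid, so no geometric distance exists) |
| `alpha` | 0.5 | — | extended-radiation scale exponent |
| timelines | medium, high | m, yr | medium reaches 0.3/0.6/0.9 m in 2055/2080/2100; high reaches 0.3–1.8 m in 2042/2059/2071/2082/2091/2100; custom schedules via JSON |

Populations are carried as nonnegative reals (projections are often
fractional); rounding to whole persons happens only on request
(round-half-even) or when sampling synthetic flows.

## Population modes

`run_scenario(mode = "exogenous")` (default) re-reads populations and
per-increment exposure from the inputs at each step: each step is a
self-contained snapshot, appropriate when population projections already
exist per increment. `mode = "compounded"` carries populations forward by
net migration; the displaced population at step $t$ is the
increment-over-previous-step affected population (nobody is displaced
twice), climate arrivals join the destination's habitable pool and are
eligible for later business-as-usual migration, and total population is
conserved exactly. Exogenous is the default because coupling migration
back into projections is conceptually attractive but empirically
uncalibrated; compounded mode exists to explore that feedback. Whether
headline numbers should be per-increment snapshots or accumulated is a
reporting choice; both are computable from the returned object.

The `d`% threshold uses the step-year population (sum of both partition
halves per county), not a fixed base year — the flag is about strain on
the county as it stands at that step.

## The synthetic generator

`synthetic_region()` emulates the three data products the simulator
consumes: a census-style zone table, per-sub-zone flooded-population
exposure at 0.3–1.8 m increments, and (via `generate_flows()`)
county-to-county annual flow tables, plus `inject_shock()` for a
hurricane-year signal. Defaults — 200 zones, 30% coastal, log-normal
populations with $\mu = 9, \sigma = 1$ (median $\approx$ 8,100, heavy
right tail, like US county populations), flooding fraction growing with
the increment and decaying inland with a 60 km e-folding length,
heterogeneous sub-zone vulnerability, extended radiation ($\alpha=0.5$)
as the business-as-usual generator and a distance-tilted kernel for
displacement — give the dual-model machinery a real signal to separate.
Flows are multinomial draws of size $\mathrm{round}(\alpha m_i)$ over a
model's probability row; a shock multiplies listed counties' outflow
totals and redistributes them by the distance-tilted kernel, reproducing
the coastal, >100%-increase, >1,000-migrant fingerprint the filter
detects.

What it does *not* emulate: real geography and bathymetry, correlated
hurricane damage across neighbours, economic push/pull covariates,
reporting artefacts of administrative flow data (suppression of small
flows, methodology breaks), and population projection uncertainty.
Passing tests on this generator therefore demonstrate that the machinery
is internally consistent and can recover known generating processes from
sampled data — not that any particular empirical forecast is right.

## Numerical and design choices

- Partition halves always sum to the parent population; equality is
  enforced to $10^{-9}$ for real-valued populations.
- Exposure validation rejects affected > total and de-nested flooding
  (affected decreasing in the increment) at read time, so downstream
  monotonicity is a property of inputs, not a hope.
- The shock filter applies the 1,000-migrant floor to the *current*
  (shock) year, where the elevated outflow lives; manual exclusions are
  configuration, not computation. Zero previous outflow is treated as an
  infinite increase with a warning.
- Rows whose total weight is zero (e.g. all destination masses zero) fall
  back to a uniform distribution with a warning rather than NaN.
- Training pairs with shocked destinations belong to neither training
  set: inflows to a disaster county mix both regimes.
- Neural model persistence is JSON at full precision (hyperparameters,
  standardisation, weight vector); restored models predict identically.

## Problem sizes

The test-suite and acceptance fixtures use 40–200 zones: 200 zones
($\approx$ 40,000 ordered pairs) for the conservation, shock-recovery and
neural-recovery checks, smaller regions elsewhere. These sizes make every
check a complete, from-scratch computation — region generation, flow
sampling, model fitting, full scenario run — while keeping the whole
suite fast enough to run routinely; the machinery itself is $O(n^2)$ in
zones and has no fixed size limits.

## Limitations

Within-year dynamics, return migration and destination capacity are out
of scope; distances are centroid great-circles, not travel costs; the
climate production function assumes permanent inundation is the only
displacement channel; and the neural model inherits the usual caveat of
black-box fits — good interpolation over the feature distribution it was
trained on, unquantified extrapolation outside it.
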