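---
title: "Dynamic stochastic patch occupancy modelling in fluctuating wetlandscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic stochastic patch occupancy modelling in fluctuating wetlandscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dspom)
```

## The model

Many wetland-dependent species live as metapopulations on mosaics of
geographically isolated wetlands. Classical stochastic patch occupancy models
(SPOMs) treat the patch mosaic as static; this package implements the dynamic
variant (D-SPOM), in which stochastic hydroclimatic forcing drives the daily
suitability of every patch and the distances between them, and the occupancy
chain, metapopulation capacity and dispersal-network topology all become
time-resolved.

The occupancy state is a binary vector $p_i(t)$ over patches, advanced as a
discrete-time Markov chain with synchronous updates. An unoccupied patch $i$
is colonized with probability $1 - \exp(-C_i(t)\,\Delta t)$, where

$$C_i(t) = c \sum_{j \ne i} e^{-d_{ij}(t)/D}\, S_j(t)\, p_j(t),$$

and an occupied patch goes extinct with probability
$1 - \exp(-E_i(t)\,\Delta t)$ with $E_i(t) = e / S_i(t)$. Here $S_i(t)$ is the
patch suitability (wetted area, or one depth-zone area, normalized), and
$d_{ij}(t)$ the perimeter-to-perimeter gap distance. Both fluctuate with the
water balance. The landscape matrix
$m_{ij} = e^{-d_{ij}/D} S_i S_j$ (zero diagonal) yields the metapopulation
capacity $\lambda_{\max}(t)$, its leading eigenvalue; the mean-field
persistence condition is $\lambda_{\max} > e/c$. Because
$\lambda_{\max}$ depends only on the hydrological state, it is deterministic
given the forcing, while occupancy is Monte-Carlo sampled.

All stochastic events in one day are computed from the state at the start of
that day (a first-order, synchronous chain). A patch with $S_i = 0$ cannot be
colonized and, if occupied, goes extinct with probability one at the next
step; the globally extinct state is absorbing.

## Hydrologic driver

Each wetland follows a power-law bathymetry
$A(h) = A_{\max}\,\min(1, h/h_{\max})^{2/p}$ with the stored volume its exact
integral, so area, volume and stage interconvert in closed form and
$\mathrm{d}V/\mathrm{d}h = A(h)$. The daily volume update is

$$V' = V + P\,(A + c_a A_{\max}) - k_{ET}\,\mathrm{PET}\,A - k_{leak}\,A,$$

with precipitation $P$ captured by the wetted surface plus a contributing
area $c_a A_{\max}$, and evapotranspiration and linear groundwater leakage
acting on the wetted surface (depths in cm, areas in m²). When losses would
overdraw storage in a single day both loss terms are curtailed
proportionally, so the flux ledger closes to machine precision over any
horizon; excess above the full volume spills and leaves the system (wetlands
are hydrologically independent, as appropriate for geographically isolated
wetlands). Stages are therefore always in $[0, h_{\max}]$ and areas in
$[0, A_{\max}]$.

Parameters that matter, with defaults:

* `k_leak` (cm d⁻¹, default 0.1): linear groundwater loss over the wetted
  area. The leakage law of the underlying hydrologic lineage is configurable
  only through this coefficient; an area-proportional law was adopted and is
  isolated behind `hydro_params()`.
* `pet_coeff` (default 1): multiplier on PET over the wetted area.
* `ca_ratio` (default 3): contributing-area-to-maximum-area ratio; typical
  upland catchments of depressional wetlands are a few times the wetland
  footprint.
* `h0` (default `"full"`): initial stages. The initial condition is not
  constrained by theory; simulations meant to be initial-condition-free
  should discard a spin-up period.

Rainfall is a marked Poisson process aggregated daily — event counts
Poisson($\lambda$), event depths exponential with mean $\alpha$ — giving a
compound-Poisson daily depth with mean $\alpha\lambda$ and variance
$2\alpha^2\lambda$. Daily aggregation (counts per day rather than a
wet/dry Bernoulli) keeps $\lambda > 1\,$d⁻¹ meaningful. Exponential marks are
the convention of the ecohydrological lineage this model builds on. PET comes
either from a fixed constant (sensitivity analyses conventionally use
0.50 cm d⁻¹) or from Thornthwaite's monthly formula with a mid-month
day-length correction, spread uniformly over each month.

## Suitability normalization

The model's $c$ and $e$ are calibrated against a dimensionless suitability,
but no absolute unit convention exists for "suitability = area". The package
normalizes $S_i(t) = A_i(t) / \bar A_{\max}$ with $\bar A_{\max}$ the
landscape mean maximum area (configurable via `s_ref`). Every qualitative
property of the model — the persistence threshold expressed relative to
$\lambda_{\max}$, monotonicities, correlation signs — is covariant under this
normalization; only the absolute numerical values of $c$, $e$ and
$\lambda_{\max}$ depend on it.

## Depth zones and the metacommunity

`zone_areas()` splits the wetted area into concentric annuli by local water
depth: shallow (< 30 cm), intermediate (30–80 cm), deep (> 80 cm). The area
with depth exceeding $d$ is exactly $A(h - d)$, so the three zones telescope
to the total area with no residual. "Deep" means strictly greater than
80 cm: at $h = 0.8$ m the deep zone has zero area. `run_metacommunity()`
runs fully independent chains for species preferring each zone; each species
draws from its own RNG stream derived from the master seed by the zone index
(seed + 1000·zone), so results do not depend on the order species are
listed. A realization's extinction day is the first day with no occupied
patch.

## Dispersal networks

At any day, the emergent dispersal network has the occupied patches as nodes
and links wherever the gap distance is at most the threshold distance $D$
(the boundary `gap == D` is linked). Degree and betweenness are computed on
the unweighted graph (betweenness with even splitting among equally short
paths, endpoints excluded); the network length $L$ is the gap-length-weighted
shortest-path diameter. The published definition of $L$ ("the two most
distant nodes") is ambiguous on fragmented graphs; the package takes the
maximum over connected components of their weighted diameters, since $L$ is
tracked through fragmentation episodes, with the largest-component diameter
available as an alternative (`fragmented = "largest"`). The network length
duration curve (NLDC) is the empirical exceedance curve of $L(t)$ using the
Weibull plotting position $k/(n+1)$.

Dry patches keep their coordinates and enter the gap matrix with radius
zero; they are excluded from the dynamics by $S = 0$ rather than removed
from the matrix, so all matrices keep a constant shape over time. The mean
nearest-neighbour distance (NND) averages over wet patches by default;
`wet_only = FALSE` keeps all patches, which is the stabler choice for
correlation analyses on landscapes that dry out episodically. Statistics
that are undefined on a given day (fewer than two wet patches) are reported
as missing, never as zero.

## Synthetic landscapes: what they emulate and what they do not

`archetype_params()` encodes two contrasting wetlandscape archetypes at the
landscape-statistics level: a dense, heterogeneous prairie-pothole-like type
(≈30 wetlands km⁻², mean maximum area ≈12,700 m² so that a 10 × 10 km domain
carries ≈38 km² of maximum wetted area, lognormal areas with sdlog = 1) and
a sparse, homogeneous playa-like type (≈1 km⁻², mean 50,000 m², sdlog = 0.3,
near-parabolic bathymetry). Centres are uniform with a hard minimum
separation (rejection sampling). Real inventories have spatially clustered,
non-circular wetlands with correlated area–depth relationships; none of that
is emulated. Tests passing on these synthetic landscapes therefore validate
the model mechanics and its qualitative response structure, not any
site-specific prediction. Per-wetland attributes of the real case-study
landscapes are not published, so only landscape-level statistics are
emulated.

## Study conditions used by the test suite and acceptance script

Problem sizes were chosen as the smallest at which each property is
cleanly measurable:

* **Persistence-threshold recovery** uses a homogeneous (sdlog = 0.3),
  well-connected ($D/\mathrm{NND} = 1.5$) 20-patch landscape with
  $c = 0.1/\lambda_{\max}$ and $e/c \in \{0.1, 0.2, 5, 10\}\,\lambda_{\max}$
  over 10⁴ days × 100 realizations. The homogeneous choice is deliberate: on
  strongly heterogeneous landscapes the capacity is carried by a few large
  patches, and at 20 patches demographic stochasticity extinguishes chains
  well below the deterministic threshold — a real finite-size effect of the
  theory, not a property of the implementation. The homogeneous landscape is
  the canonical setting in which the mean-field criterion is informative at
  this size.
* **Correlation structure** uses the dense archetype scaled to
  1.414 × 1.414 km (60 patches at the archetype density) under strongly
  seasonal forcing (wet season $\lambda = 0.30$ d⁻¹ days 1–180, dry season
  0.02 d⁻¹; $\alpha = 0.9$ cm; ET 0.5 cm d⁻¹; `k_leak` 0.2 cm d⁻¹), a 3-year
  horizon, $e = 0.002$, $c = 1.5$, $D/\mathrm{NND} = 1.5$, 30 realizations.
  The elevated extinction coefficient makes occupancy responsive to habitat
  fluctuations within a short horizon.
* Mass balance is verified over 10 years × 50 wetlands at 10⁻⁹ relative
  tolerance; rainfall moments at $T = 10^5$ days within 3 standard errors;
  eigenvalue, degree, betweenness and shortest-path computations against
  independent oracles (general eigendecomposition and power iteration,
  exhaustive path enumeration over every graph on ≤ 6 nodes,
  Floyd–Warshall).

## Numerical choices

* Synchronous chain update; $\Delta t = 1$ d, matching daily forcing.
* Colonization and extinction probabilities via `-expm1(-rate)` for
  accuracy at small rates; infinite extinction rate maps to probability 1.
* `metapopulation_capacity()` uses the symmetric eigensolver after an
  explicit symmetry check (tolerance 10⁻⁸ relative); the leading eigenvalue
  of a non-negative symmetric matrix with zero diagonal is non-negative.
* Volume inversion is closed-form; stage is clamped to $[0, h_{\max}]$ and
  volumes to $[0, V_{\max}]$ before inversion, so no root finding occurs.
* Landscape tables are written with 15 significant digits; round-trips are
  exact to decimal-text precision.
* The initial occupancy default (`p0 = "all"`) occupies every patch with
  positive suitability; a Bernoulli fraction is available.
* Survival ($f_S$) is defined as at least one occupied patch on the final
  simulated day.

## Known limitations

* Patches are equivalent circles; perimeter-based suitability proxies and
  polygon-resolved gap distances are out of scope.
* No upland-matrix resistance or anisotropic dispersal; the kernel is
  isotropic $e^{-d/D}$ only.
* No inter-wetland surface connectivity (fill-and-spill routing); spill is
  lost.
* Species traits are fixed; no evolution, rescue effects or interactions.
* The static engine freezes areas at their simulated time means; other
  averaging conventions (median, stage mean) would give slightly different
  static baselines.

## A worked run

```{r example, eval = FALSE}
L <- do.call(generate_wetlandscape,
             archetype_params("dense", extent = c(1414, 1414), seed = 1))
rain <- generate_rainfall(alpha = 0.9, lambda_freq = 0.2,
                          t_days = 730, seed = 2)
hydro <- simulate_hydrology(L, forcing_series(rain, pet = 0.5),
                            hydro_params(k_leak = 0.2))
traits <- species_traits(e = 2e-4, c = 1.5, D = resolve_dispersal(L, 1.5))
run <- run_dspom(L, hydro, traits, n_realizations = 100, seed = 3)
run
plot(run$omega, type = "l", xlab = "day", ylab = expression(Omega(t)))
```
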