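---
title: "Grid-filter geolocation for pop-up archival tags: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-filter geolocation for pop-up archival tags: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridtag)
```

## The problem

Pop-up satellite archival tags (PSATs) record depth, temperature and light
while attached to a fish, then release, surface, and report a single
accurately-known pop-up position. Between the known release and pop-up
positions the animal's daily locations must be inferred from weak, indirect
measurements: the universal times of sunrise and sunset (which constrain
longitude strongly and latitude weakly) and daily sea-surface temperature
(SST) estimates (which constrain position through the ocean's SST field).
For deep-dwelling species most days carry *no* usable observation at all —
in the deployment programme this package is modelled on, only about 7% of
tag-days had solar event times and about 41% had SST. Pointwise track
estimation is hopeless in that regime; instead the package estimates, for
every day, a full probability surface over a discretized ocean, and pools
those surfaces into Utilization Distributions (UDs).

## State-space model

**State.** The fish's daily position on a regular lon/lat grid (nominal 9 km
cells; tests run at 30-40 km). Land cells are excluded by a mask; each water
cell carries bathymetry.

**Dynamics.** Between days the position density follows an
advection-diffusion equation with diffusivity $D$ (km²/day) and optional
advection $(u, v)$, solved by an explicit flux-form finite-volume scheme
(centred diffusion, first-order upwind advection). Faces that touch land or
the domain edge carry exactly zero flux, so probability mass can pile
against a coastline but never crosses it and is conserved to machine
precision. The explicit scheme is automatically sub-stepped so that the
fraction of a cell drained per sub-step,
$\Delta t\,(2D/\Delta x^2 + 2D/\Delta y^2 + |u|/\Delta x + |v|/\Delta y)$,
stays below 0.9, which also guarantees nonnegativity. Cell widths scale with
$\cos(\text{lat})$ per row, so the kernel is metrically correct on a lon/lat
grid.

**Observations.** Each day's likelihood over cells is a product of
independent Gaussian terms:

* SST: `dnorm(obs, refSST(cell), sigma_sst)` with `sigma_sst = 1` °C;
* sunrise and sunset times: `dnorm(obs, predicted(cell), sigma_event)`
  with `sigma_event = 20` min, residuals taken circularly on the
  1440-minute clock;
* a hard bathymetry gate: zero likelihood where the water is shallower than
  the day's maximum measured depth (optional, on by default);
* days with no observations contribute a uniform likelihood over water.

Solar event times per cell are predicted from a low-precision solar
ephemeris (mean elements plus equation of centre, ~0.01°), via the standard
twilight condition
$\cos\omega = (\sin h_0 - \sin\phi\,\sin\delta)/(\cos\phi\,\cos\delta)$
and the sidereal-time relation between the local hour angle and UT, with the
solar position refreshed at the provisional event time (three fixed-point
passes; a fourth moves the answer by well under half a minute). The twilight
altitude defaults to $h_0 = -0.833°$ (geometric rise/set with standard
refraction) and is configurable, since tag manufacturers differ in what
"sunrise" means operationally. Cells in polar day or night receive a finite
floor likelihood $e^{-8}$ of the Gaussian mode rather than zero, so a single
bad observation cannot create an absorbing impossibility.

**Filtering and smoothing.** The forward filter starts from a point mass at
the release position, alternates prediction and Bayes update, and finally
updates with a point mass at the pop-up position (treated as exact; a small
Gaussian kernel can be substituted). The backward filter mirrors it from the
pop-up, propagating with the exact transpose of the forward mass kernel
(`P^T x = P(A x)/A` for cell areas $A$ — the diffusion operator is
self-adjoint under area weighting; advection is negated). The two-filter
smoother multiplies the forward *updated* field by the backward *predicted*
field, so every observation enters exactly once; on a finite grid this is
the exact hidden-Markov-model smoothing marginal, which the test suite
verifies against a dense transition-matrix forward-backward recursion to
1e-10 on small worlds. Per-day normalizers accumulate to the data
log-likelihood, identical (to rounding) whether accumulated forward or
backward.

## Set-membership preprocessing

Before filtering, solar event times are screened by a feasibility argument:
starting from the release cell, each day's feasible set is the previous
day's set dilated by the maximum sustainable speed (`vmax`, default 150
km/day) *through water*, intersected with the bathymetry and SST gates
(3-sigma bands); an analogous backward pass runs from the pop-up cell, and
the day's set is the intersection. The dilation is a chamfer (8-neighbour,
metric-weighted) distance transform with land impassable — expansion must go
around coastlines, not across them. An observed event time whose circular
distance to the set of predicted event times over the feasible cells exceeds
`k_reject * sigma_event` (default 3 sigma = 60 min) is discarded. If a day's
observation gates empty its set, the SST/depth constraints are dropped for
that day (sensor error being more plausible than teleportation), never the
speed/land constraints.

## The synthetic world

`make_environment()` builds a western-boundary landmass with a wiggly
coastline, a shelf that deepens to abyssal depths away from the coast, and a
daily SST field = latitudinal gradient + seasonal cycle (amplitude growing
poleward, peak late August) + a static smooth spatial anomaly (sd 0.8 °C),
clamped to 4-31 °C — mirroring the 5-30 °C span of the northwest Atlantic.
`simulate_track()` draws each day's position from the *filter's own*
prediction kernel applied to a point mass at the current cell: simulation
and inference share a single transition-kernel implementation, so the
calibration experiment probes the estimator, not a reimplementation.
`simulate_tag_records()` emits SST with probability 0.41/day and
sunrise+sunset pairs with probability 0.07/day (the observed sparsity of the
real programme), with 1 °C / 20 min Gaussian noise, plus a daily maximum
depth drawn uniformly below 90% of the local bathymetry (capped at 900 m).

What the generator does *not* emulate: oceanographic fronts and eddies
(the SST anomaly is static and smooth), blocked missingness from
deep-dwelling episodes (a config hook exists but the default is independent
missingness), vertical behaviour beyond the max-depth draw, and reference-SST
error (the same field drives simulation and filtering — the well-specified
regime). A green calibration therefore establishes internal consistency of
the machinery at the stated noise levels, not robustness to a mis-specified
ocean.

## Numerical and design choices

* **Depth gate in the HMM update.** The max-depth constraint is applied both
  in preprocessing and as a hard gate in the likelihood (a flag disables the
  latter). The gate is deliberately a plain indicator: the full generative
  density of "max depth given position" is unknown for real tags. Under the
  synthetic world this omission measurably over-concentrates posteriors —
  daily 95% HPD coverage is ~0.933 with the gate versus ~0.945 without —
  both inside the acceptance band.
* **Backward prior.** The two-filter combination uses the backward filter's
  predicted field, whose day-T element is the pop-up point mass itself;
  normalization per day makes the product exact on the finite grid.
* **Ties and determinism.** HPD regions rank cells by density with ties
  broken by cell index; all simulators are seeded; reruns are bit-identical.
* **Degenerate inputs.** All-gated-out days fall back to the predicted field
  (flagged); zero two-filter products fall back to the forward posterior
  (flagged); on-land endpoints snap to the nearest water cell within two
  cells, else error.
* **Diffusivity.** The movement model's $D$ is not stated by the programme
  this package models; the default 300 km²/day is a plausible large-pelagic
  scale and `fit_diffusion()` profiles the filter likelihood over a
  candidate grid per tag.

## Known limitations

**Single-track diffusivity estimation is weakly identified.** With SST-only
position information of ~1 °C noise against ~0.8 °C/degree gradients, a
daily fix is uncertain by ~140 km, far above the ~25 km daily step scale at
$D = 300$ km²/day. Most of the likelihood's information about $D$ then comes
from the release-to-pop-up bridge, which contributes only about two degrees
of freedom (the maximizer behaves like $D\,\chi^2_2/2$). The package's
recovery experiment at 250-day deployments places the true $D$ within one
100 km²/day grid step in ~76% of replicates — real, but below the 80%
aspiration; pooling tags, or SST fields with sharper fronts, would be needed
to do better. The corresponding acceptance test is left failing at its
stated threshold rather than weakened.

**Coverage percentages depend on pooling scale.** Total-variation distances
between pooled UDs (e.g. the sigma-event sensitivity check) shrink as more
fish-days are pooled; single-tag UDs are far more sensitive than pooled ones.

**No NetCDF/GeoTIFF I/O.** Gridded inputs and outputs use plain-text
formats (lon/lat/matrix lists, long-format CSV, GeoJSON) because no R
NetCDF/raster stack is assumed at build time.

## A worked micro-example

```{r example, eval = FALSE}
env <- make_environment(seed = 1, resolution_km = 40)
cfg <- sim_config(D = 300, n_days = 60, seed = 1)
track <- simulate_track(env, cfg)
sim <- simulate_tag_records(track, env, cfg)

fs <- propagate_feasible_sets(sim$dep, sim$records, env)
sc <- screen_event_times(sim$records, fs, env$grid)
mp <- movement_params(D = 300)
fwd <- forward_filter(sim$dep, sc$records, env, mp)
bwd <- backward_filter(sim$dep, sc$records, env, mp)
st <- two_filter_smooth(fwd, bwd)
track_summary(st)[1:5, ]
```
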