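---
title: "Simulating phosphorus-dependent maize architecture and root system conductance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating phosphorus-dependent maize architecture and root system conductance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizoconduct)
```

## The scientific question

Soil phosphorus (P) availability reorganizes the architecture of young
*Zea mays* plants: with decreasing P, axial root radii shrink, crown
roots elongate more slowly and leaves extend more slowly. Because the
root system's capacity to take up water — its conductance
$K_{rs}$ (cm$^2$ d$^{-1}$) — emerges from the sizes, ages and hydraulic
properties of all its segments, architectural reorganization translates
into functional change. This package couples a stochastic
functional–structural plant simulator, parameterized per soil-P
treatment from rhizotron measurements, to a xylem hydraulic-architecture
solver, so that $K_{rs}$ of a growing plant can be computed through time
under each P regime.

Four treatments span severe deficiency to sufficiency, with
plant-available soil P of 1.8 (P0), 3.3 (P1), 4.6 (P2) and 7.7 (P3)
mg P per 100 g soil.

## Organ growth model

Every organ (root axis, lateral, stem, leaf) elongates along the
negative-exponential law

$$ l(t) = l_{max}\left(1 - e^{-r t / l_{max}}\right), $$

where $r$ (cm d$^{-1}$) is the initial elongation rate — the slope at
emergence — and $l_{max}$ the asymptotic maximal length. Its inverse,

$$ t(l) = -\frac{l_{max}}{r}\,\log\!\left(1 - \frac{l}{l_{max}}\right), $$

maps a position along an axis to the age at which the axis reached it.
This inverse does double duty: it converts distance-indexed conductivity
profiles to age-indexed ones, and it assigns exact creation times to
simulated segments. `fit_elongation()` estimates $r$ from traced length
time series by bounded 1-D least squares with $l_{max}$ held fixed
(139 cm for axial roots, a literature value; tabulated values for
laterals and leaves). For leaves, points after the daily elongation rate
starts declining carry no information about the initial rate;
`trim_declining_phase()` drops trailing points once the daily increment
falls below 20 % of the maximum observed increment — the cutoff fraction
operationalizes a qualitative rule and is exposed as an argument.

## Stochastic architecture

A plant is a rooted tree of cylindrical segments. The parameter tables
(one per treatment, shipped as plain CSV under `inst/extdata/` and
checksummed cell-for-cell by the test suite) give each organ type its
radius $a$, basal-zone length $l_b$, apical unbranched zone $l_{delay}$,
inter-branch distance $l_n$, elongation parameters and insertion angle
as (mean, s.d.) pairs; every simulated organ draws its own realization
(normal, truncated below at $10^{-4}$ of the mean so radii and rates
stay positive).

The axial schedule is deterministic in time and stochastic in count: the
primary root starts at sowing; seminal roots appear from `first_B`
onward spaced `delay_B` with a total count realized from `max_B` by
mean-preserving stochastic rounding (3.5 becomes 3 or 4 with equal
probability); crown whorls appear at `first_SB` + k·`delay_RC`, each
whorl carrying `n_C` roots (same rounding) spaced `delay_SB`. Laterals
branch beyond the basal zone at spacing $l_n$, leaving the apical
$l_{delay}$ unbranched, with the lateral type (long/short) drawn from
the tabulated successor probabilities. $l_{delay}$ is treated as a
length in cm: the tabulated magnitudes (0.19–2.6) are only readable as
an apical-zone length, although the parameter catalogue prints rate
units — an assumption we document rather than hide.

Headings follow a gravitropism-biased random walk: per growth step of at
most `dx` = 0.25 cm, `N` candidate headings are drawn (unit heading plus
Gaussian noise of 0.2 rad per $\sqrt{\text{cm}}$) and the most downward
one kept. `N` is 1.5 for axial roots and 1 for laterals. The tables
print no values for tropism, axial insertion angles, `dx` or the stem
maximal length, so the package fixes documented defaults once (primary
vertical; seminal 0.9 rad; crown 1.2 rad; stem $l_{max}$ 80 cm; first
leaf at day 5); these were not revisited afterwards.

One design choice departs from the obvious time-stepping loop: the
simulator builds each organ's full polyline once and assigns each
segment the exact creation time implied by the inverse growth law, so
`network_at_time()` recovers the architecture at *any* earlier time with
no discretization error in the growth dynamics, and a single simulation
serves every evaluation time. Identical (parameters, horizon, seed)
reproduce the network bit-for-bit.

Of note: the stem inter-node distance printed for P1 (0.153 cm) is an
order of magnitude below the other treatments (≈1.5–1.7 cm) and is
implemented exactly as tabulated.

## Hydraulic architecture and $K_{rs}$

Water enters a root segment radially across its surface,
$J_r = K_r(\psi_{sr} - \psi_{xyl})$ with
$K_r = 2\pi\,a\,dl\,k_r(\text{age})$, and travels axially through the
xylem, $J_x = K_x(\text{age})\,\partial\psi_{xyl}/\partial l$.
Potentials are water heads (cm). At steady state the radial inflow
balances the axial flow divergence, which on the segmented tree becomes
a sparse symmetric positive-definite linear system in the nodal xylem
potentials. The discretization places the radial exchange at the segment
midpoint and eliminates the midpoint unknown analytically (a star–delta
reduction), which keeps the assembly second-order accurate: a single
uniform root converges to the closed form
$K_{rs} = \sqrt{2\pi a k_r K_x}\,\tanh(L\sqrt{2\pi a k_r/K_x})$ within
0.1 % at `dx` = 0.1 cm, and the production solver is cross-checked
against an independently assembled dense system on random trees to
$10^{-8}$ relative.

The stem takes up no water ($k_r = 0$) and conducts axially with the
Hagen–Poiseuille conductance $K_x = \pi a_{xyl}^4 / (8\mu)$ of an
equivalent xylem cylinder. The head-based viscosity of water at 20 °C is
$\mu = \eta/\rho g = 1.002\times 10^{-3}\,\text{Pa s} / 98.1\,\text{Pa
cm}^{-1} = 1.18\times 10^{-10}$ cm d. The equivalent xylem radius
defaults to one tenth of the stem radius, which makes the stem a
negligible resistance ($K_x \approx 95$ cm$^3$ d$^{-1}$, three orders
above root axial conductances); $K_{rs}$ is insensitive to this default
at well below 1 %. The collar — where the plant potential boundary
condition applies — is the most distal stem node; above-ground stem
segments carry no flow and do not distort $K_{rs}$.

From the solution, the actual transpiration is $T_{act} = \sum_i J_{r,i}$,
the standard uptake fraction $SUF_i = J_{r,i}/T_{act}$ (computed under
uniform soil potential; it sums to one), the effective soil–root
potential is $\psi_{sr,eff} = SUF^\top \psi_{sr}$, and

$$ K_{rs} = \frac{T_{act}}{\psi_{sr,eff} - \psi_{collar}}. $$

By linearity, $K_{rs}$ is independent of the soil and collar potentials
chosen (the defaults are −300 and −1000 cm; the tests verify invariance
to $10^{-10}$).

### Hydraulic property profiles

$k_r$ and $K_x$ are age- and root-type-dependent, supplied as
piecewise-linear knot tables with constant extrapolation, and treated as
treatment-independent: P treatments differ hydraulically only through
architecture (radii enter $K_r$ directly). The packaged default profile
(`inst/extdata/hydraulic_profile_synthetic.csv`) is a **synthetic
stand-in**, not a transcription of any measured conductivity atlas: per
type, $k_r$ decreases with age and $K_x$ increases, with magnitudes in
the range of the classic published maize profiles, globally calibrated
once so that a single simulated P-sufficient 28-d plant falls inside the
published young-maize range of $7.0\times10^{-5}$ to
$2.37\times10^{-2}$ cm$^2$ d$^{-1}$. Absolute $K_{rs}$ levels therefore
inherit the stand-in's uncertainty; treatment *contrasts* are driven by
the measured architecture tables. Users with measured profiles can load
them via `hydraulic_profile()` (or convert distance-indexed data with
`distance_profile_to_age_profile()`).

## Phosphorus response functions

Three dose–response functions, fitted to the tabulated per-treatment
means, convert the treatment-averaged "general" parameter set plus a
soil P level into a treatment-specific set:

* axial radius, linear in P: $a_{ax} = \alpha_a P + a_{P0}$, fitted by
  OLS pooling the three axial types, applied by scaling each type's mean
  by the line's ratio at $P$ versus the fit centroid (preserving
  per-type offsets);
* crown elongation, capped-linear through the origin in
  $PB = P/DM_{plant}$: $r_c = \alpha_{rc}\min(PB, PB_{max})$, with the
  changepoint profiled over observed PB values and applied as an
  absolute rate;
* leaf elongation, linear in P: $r_l = \alpha_{rl} P + r_{P0}$, applied
  as an absolute rate.

All fits record their validity bounds and refuse extrapolation. The
plant dry-matter values needed for PB are published only graphically, so
the package ships documented synthetic stand-ins (1.0, 1.8, 2.2, 2.8 g
for P0–P3) and takes DM as an argument everywhere. With these stand-ins
the response-driven parameter sets reproduce the tabulated ensembles'
mean total root volume within about 10 % for P0/P1 but overshoot by
18–27 % for P2/P3 — dominated by the crown-elongation response, whose PB
covariate is exactly where the stand-in dry matter enters. This is a
known limitation: with measured dry matter the agreement would be
tighter.

## What the synthetic generators emulate — and what they do not

`gen_root_length_series()` produces rhizotron-style cumulative length
series (daily to day 21, every other day to 28) with Gaussian tracing
noise (default s.d. 0.5 cm), clipped non-decreasing.
`gen_synthetic_rhizotron()` writes per-day RSML files of a simulated
plant projected to the rhizotron plane, primary root first, ids stable
across days, with a JSON truth record. `gen_response_dataset()` draws
dose–response data around known coefficients (default 5 % relative
noise). None of these emulate image segmentation errors, root occlusion
at the rhizotron wall, or tracing topology mistakes — so green tests
demonstrate correctness of the estimation machinery under the stated
noise model, not robustness to real imaging artefacts.

## Numerical choices and problem sizes

* Elongation fits: Brent search on $r \in (0, 50]$, tolerance
  $10^{-12}$; exact recovery from noiseless series to $10^{-6}$.
* Segment length `dx` 0.25 cm in simulations (0.1 cm in closed-form
  solver checks); a 28-d P3 plant has roughly 10,000 segments and
  solves in well under a second.
* Ensembles default to 100 runs; the packaged acceptance checks use 25
  runs per treatment with ±2 s.e. tolerances,
  which keeps a full four-treatment evaluation near a minute.
* Laterals attach at the nearest parent node ($\le$ `dx`/2 arc-length
  rounding); a lateral whose scheduled emergence precedes its attachment
  node's creation is deferred to that node's creation time (a sub-`dx`
  distortion).
* Degenerate inputs: all-zero radial conductances, zero-gradient
  boundary conditions, lengths at the growth asymptote and out-of-bounds
  response inputs all raise informative errors rather than returning
  NaN.

## Known limitations

* The hydraulic profile is a calibrated synthetic stand-in (above);
  absolute conductances should not be over-interpreted.
* The shoot is simplified: vertical stem, leaves carry no hydraulic
  segments; leaf area only caps blade growth.
* No root decay/lifetime, no soil water flow or perirhizal resistance
  ($K_{rs}$ is an intrinsic property; soil potential is an input), no
  rhizotron wall confinement in 3D growth.
* The crown-elongation response depends on dry matter that the package
  can only approximate by default.
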