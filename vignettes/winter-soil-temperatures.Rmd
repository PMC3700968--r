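---
title: "Modelling winter 10 cm soil temperatures under snow and crop residue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling winter 10 cm soil temperatures under snow and crop residue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frosthatch)
```

## The problem

Miscanthus rhizomes overwinter at about 10 cm depth and are killed by cold
soil: the temperature at which half of them die is about −3.5 °C for
*M. × giganteus* and *M. sacchariflorus*, and about −6 °C for the hardiest
*M. sinensis* hybrids. Air temperature is a poor guide to that risk in
continental winters, because snow and any prostrate residue layer decouple
the shallow soil from the atmosphere. `frosthatch` simulates one field
column through many winters and asks: how often does the 3-day running mean
of the daily-mean 10 cm temperature reach a lethal threshold, and how much
does a residue layer of a given thickness change that?

This vignette documents the model, its parameters, the synthetic weather
that drives it, the numerical choices, and the limits of what the shipped
tests demonstrate.

## Model structure

### Conduction stack

The column is an ordered stack of horizontal slabs: an optional snow slab,
an optional residue slab, and 11 mineral soil layers with fixed
thicknesses 5, 5, 10, 10, 10, 20, 20, 20, 50, 50, 50 cm (250 cm total,
nodes at layer midpoints: 2.5, 7.5, 15, 25, … 225 cm). Heat flows
vertically; interface conductances are series combinations of the half-slab
resistances. The lower boundary is zero-flux at 250 cm — geothermal flux is
negligible at this depth and duration. The 10 cm output temperature is
linearly interpolated between the 7.5 and 15 cm nodes.

Each hour the solver (a) computes the surface energy balance, (b) advances
conduction implicitly, and (c) updates snow mass. Soil water is updated
daily by a bucket model. The default time step is 60 min; a
`dt_hours = 0.5` option halves it, and a test asserts the annual extreme
minimum moves by less than 0.1 °C when it does.

### Surface energy balance

The skin temperature solves

  (1−α)·S + ε·(L↓ − σT⁴) − H − LE − G = 0

by bisection on a bounded interval, to a residual far below the 0.1 W m⁻²
contract. Sensible heat uses a neutral bulk transfer coefficient
k²/ln(z/z₀)² with z = 10 m and the roughness length of the exposed surface
(snow 0.002 m, residue per its spec, bare soil 0.01 m). Latent heat is
winter-minimal by design: it is suppressed entirely over snow, residue, or
a frozen surface, and otherwise scaled by a soil-moisture beta
(liquid − wilting)/(field capacity − wilting) of the top layer.
Atmospheric stability corrections are deliberately omitted: the extreme
minima this package targets are radiation- and conduction-dominated, and a
neutral bulk formulation keeps the balance monotone in skin temperature,
which makes the bisection unconditionally safe. The ground heat flux G
couples the skin to the top slab through its half-slab conductance and is
the upper boundary condition of the conduction step.

Surface albedo is an area-weighted composition: the snow-covered fraction
(depth/5 cm, capped at 1) takes the snow albedo 0.75; the remainder takes
the residue albedo where residue is present, else the bare-soil albedo
0.15.

### Conduction with freezing

Conduction is backward-Euler implicit (tridiagonal), unconditionally
stable. Soil freezing uses an apparent-heat-capacity regularisation: the
liquid fraction of a layer's water falls linearly from 1 at 0 °C to 0 at
−0.5 °C, so each layer has a single-valued enthalpy function E(T) that
folds in the 334 kJ kg⁻¹ latent heat. The nonlinear system is solved by
Picard iteration with secant (chord) capacities, then — the key numerical
choice — the final state is set by *inverting the enthalpy actually moved
by the solved fluxes*. Because the tridiagonal solve telescopes exactly to
its boundary fluxes, this conservative projection closes the energy budget
to machine precision regardless of how well the Picard iteration converged
near a phase boundary. The ledger carried through a run (stored enthalpy
change vs. time-integrated ground heat flux plus advected snowfall and
soil-water enthalpy) is asserted in tests at 0.5 % of the cumulative
absolute surface flux and in practice closes ~10 orders of magnitude
tighter.

The same enthalpy inversion backs `freeze_thaw_partition()`: applying an
energy residual to a layer conserves total water mass exactly, exchanges
latent heat, and holds the temperature inside the freezing range while
both phases coexist — which is what produces the zero-curtain plateau the
solver tests assert.

### Snowpack

A single bulk slab of constant density: depth = SWE/ρ, fractional cover
ramps to 1 at 5 cm depth. Precipitation falls as snow at or below 1.1 °C
(the boundary value itself is frozen — a stated tie-break). New snow
arrives at min(air temperature, 0) and mixes into the bulk temperature by
mass. Energy reaching a 0 °C pack melts it at 334 kJ kg⁻¹; melt and rain
pass through to infiltration. Conductivity comes from density via Yen's
(1981) power law k = 2.22362 (ρ/1000)^1.885.

The density default is **250 kg m⁻³**. A constant density is an explicit
simplification (real packs densify from ~100 to ~400 kg m⁻³ over a
season); 250 is a representative bulk value for a mid-winter continental
pack. A fresh-snow value like 150 kg m⁻³ systematically over-insulates:
with it, the cold-continental preset's bare-soil annual extreme minima sit
near −2 °C, far from the −8…−11 °C climatology such regions actually show,
whereas 250 kg m⁻³ reproduces that climatology (see the acceptance
script's `bare_mean_extreme_min_C`). A pack shallower than 5 mm is tracked
as mass but omitted from the conduction stack (its thermal mass is
negligible); the tiny bookkeeping energy of that regime is carried in the
ledger's `external` term.

Three-layer snow physics, metamorphism, wind redistribution, and stubble
snow-trapping are out of scope; the stack discretisation would admit a
multi-layer upgrade.

### Residue layer

A residue layer is a slab with conductivity taken directly from its spec
and volumetric heat capacity = bulk density × specific heat. Presets
(every field overridable):

| quantity | maize stover | miscanthus straw |
|---|---|---|
| thickness (m, scenario-set) | 0.05 | 0.01 / 0.025 / 0.05 |
| roughness length (m) | 0.012 | 0.0065 |
| bulk density (kg m⁻³) | 36.4 | 22.0 |
| cellulose density (kg m⁻³) | 1450 | 1350 |
| thermal conductivity (W m⁻¹ K⁻¹) | 0.126 | 0.08 |
| specific heat (J kg⁻¹ K⁻¹) | 1900 | 1335 |
| porosity | 0.975 | 0.96 |
| albedo | 0.25 | 0.32 |
| fractional cover | 0.95 | 0.90 |

Two interpretation points were genuinely open:

* **Fractional cover.** Field residue covers 90–95 % of the ground. A
  single column with area-averaged slab properties would let the bare
  10 % short-circuit the slab resistance and destroy most of the
  insulation — physically wrong for patchy mulch over a laterally
  non-conducting metre of soil. We therefore run *parallel two-column
  averaging*: a fully covered column and a bare column on identical
  forcing, area-weighted by the cover fraction. Sweeps inherit this.
* **Bulk density vs. porosity.** The tabulated miscanthus porosity (0.96)
  is not consistent with 1 − bulk/cellulose density (≈0.984). Both values
  are exposed; the tabulated porosity is used where porosity is required,
  and `residue_porosity_check()` reports the discrepancy. Porosity sweeps
  vary bulk density at fixed cellulose density, which changes the slab's
  heat capacity but not its tabulated conductivity — hence their effect on
  extreme minima is much smaller than the albedo sweeps', as the tests
  assert.

The residue persists year-round (no decay, no wind loss). Snow sits on top
of residue; the stack order snow → residue → soil is physically forced.

### Soil properties and water

Texture parameters for the 11 USDA classes ship as a CSV
(`inst/extdata/soil_textures.csv`) built from the standard
Clapp–Hornberger/Campbell set: porosity, Campbell *b*, air-entry potential
and saturated conductivity tabulated; field capacity and wilting point
evaluated from the Campbell retention curve at −33 and −1500 kPa; dry
conductivity from Johansen's bulk-density relation; solids conductivity
graded from quartz-rich sand (5.0) to clay (2.5 W m⁻¹ K⁻¹); solids heat
capacity 2.13 MJ m⁻³ K⁻¹. Users can substitute their own table.

Thermal conductivity mixes Johansen-style: geometric-mean saturated
conductivity over solids/water/ice, interpolated from the dry value by a
Kersten number (log₁₀ form for liquid, linear for ice, blended by phase
ratio). This makes conductivity monotone in total water and larger for ice
than for the same content of liquid — both property-tested. Heat capacity
is the volume-weighted sum of solids, liquid (4.18), ice (1.9) and air
(0.0012 MJ m⁻³ K⁻¹).

Hydrology is deliberately a field-capacity cascade bucket, not Richards
flow: winter extreme minima respond to antecedent moisture (through heat
capacity and conductivity), not to infiltration dynamics. Infiltration
fills layers to field capacity and cascades; frozen layers accept none
(water becomes runoff); evaporation draws the top layer down to wilting
point; column mass closes exactly every step. This is the package's main
fidelity trade-off and is stated as such.

## The synthetic weather generator

The generator is the stand-in for multi-decade station forcing. Daily mean
temperature = annual mean − amplitude·cos(2π(d−d_cold)/365) + AR(1)
anomalies (stationary SD `anomaly_sd`, lag-1 `anomaly_autocorr`) − outbreak
pulses + optional linear trend. Cold outbreaks arrive as a Poisson process
(`outbreak_rate` per November–March window); each is a half-sine pulse of
gamma-distributed peak magnitude (mean `outbreak_drop`, shape 2) lasting
`outbreak_duration_days`. Years are 365 days — leap days would complicate
year-over-year statistics for no analytical gain. Precipitation occurrence
is Bernoulli; amounts are gamma (shape 0.75) with the seasonal mean scaled
so the November–March share equals `winter_precip_fraction`. Humidity,
wind, and solar (extraterrestrial radiation × wet/dry transmissivity)
close the forcing set.

Eight site presets span a cold/dry "north-plains" (annual mean 4 °C,
amplitude 17.5 °C, 3 outbreaks per winter) through snowy "upper-lakes" and
"lakeshore" variants to a mild "south" (13.5 °C). The preset values were
chosen once so that, e.g., north-plains January means sit near −13 °C with
outbreak minima reaching −25…−40 °C air temperature, and its simulated
bare-soil 10 cm climatology lands in the −8…−11 °C range with the −3.5 °C
threshold reached in most winters — the regime the package is meant to
probe. The generator's hourly disaggregation uses a piecewise cosine with
the minimum at (rounded) sunrise and the maximum at 14:00, clamped into
[tmin, tmax] so daily extremes are reproduced exactly even when adjacent
days differ sharply (the cost is a small possible jump at midnight after a
strong warm-to-cold transition); shortwave follows the zenith-angle shape
normalised to conserve the daily total exactly; precipitation falls in a
contiguous 6-hour morning block; longwave down uses Brutsaert clear-sky
emissivity with a wet-day cloud correction.

What the generator does **not** emulate: correlation between outbreaks and
antecedent snowfall, multi-day storm structure, wind–snow interactions,
observed spatial gradients. Passing tests therefore demonstrate the
physics and statistics of the pipeline under a realistic *statistical*
winter, not agreement with any particular station record.

## Statistical conventions

* **Winter year**: July 1 – June 30, labelled by the ending year, so one
  cold season is never split; incomplete boundary years are dropped. A
  calendar-year mode exists behind a flag.
* **Running mean**: centred, 3-day default; boundary days are excluded
  rather than padded. The smoothed extreme is deliberately conservative
  relative to the raw daily minimum.
* **Exceedance**: "at or below", ties count.
* **Bias correction**: obs regressed on sim (quadratic), evaluated at sim;
  extrapolation beyond the fitted range (plus a 10 % margin) is refused.
* **Trends**: OLS slope rescaled to °C/decade, two-sided t-test, P<0.05;
  an AR(1) effective-sample-size correction is available but off by
  default since the convention being mirrored states only the plain test.

## Design choices where the design was open

* Residue warms the *mean* annual extreme monotonically in thickness under
  paired weather, and that is what the tests assert. Individual winters
  can buck the direction: a residue layer warms the surface, which can
  thin an early snowpack and leave the column more exposed to a later
  outbreak. This snow-timing feedback is physical, visible in paired runs
  on snowy presets, and the reason the monotonicity claims are made of
  means and exceedance fractions rather than of every winter.
* Spin-up default is 1 year (configurable): a point column started at the
  site annual-mean temperature and field capacity reaches thermal
  equilibrium quickly; multi-year hydrologic spin-up matters for regional
  water balance, which is out of scope.
* Crop growth is not simulated. Management scenarios are represented by
  their post-harvest winter surface states (bare vs. residue-covered),
  because every analysed statistic is a wintertime extreme.
* The Dirichlet boundary mode of the conduction solver exists solely so
  the analytic oracles (series-resistance steady state, damping-depth
  decay) are expressible as tests.

## Problem sizes

The shipped tests and the acceptance script use: 30 complete winters
(31 calendar years + 1 spin-up year) for the thickness experiment and
exceedance fractions; 6 thickness members (0–20 cm) on common random
numbers, two columns per fractional-cover member; 125 pseudo-sites × 500
replicates for bias-correction recovery; 27-year series for trend
recovery; 16-day periods over a 50-slab column for the damping-depth
oracle. A 30-year, two-column scenario takes a few seconds on one core.

## Known limitations

No canopy or standing stubble (hence no preferential snow trapping), no
snow densification, neutral-only turbulent exchange, bucket hydrology, a
single bulk snow layer, clamped diurnal interpolation, and a weather
generator with independent daily draws beyond AR(1) temperature memory.
These bound the realism of absolute site predictions; the package's claims
are about the *structure* of the residue–snow–soil response and the exact
arithmetic of its risk statistics.
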