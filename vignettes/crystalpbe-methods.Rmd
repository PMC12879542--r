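---
title: "Methods: discrete-method population balance modelling of batch cooling crystallization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discrete-method population balance modelling of batch cooling crystallization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crystalpbe)
```

## Model

`crystalpbe` simulates unseeded or seeded batch cooling crystallization of
α-L-glutamic acid (α-LGA) from water. The state of the slurry is the solute
amount in solution plus a discretized crystal size distribution; the vessel
is either a single well-mixed zone or a small network of exchanging
well-mixed zones.

**Solubility.** The equilibrium mole fraction is the quadratic
$C^*(T') = a_0 - a_1 T' + a_2 T'^2$ with $a_0 = 0.08131$,
$a_1 = 5.95783\times10^{-4}$, $a_2 = 1.10258\times10^{-6}$. Published
versions of this polynomial state the temperature in degrees Celsius, but
with Celsius the curve *decreases* over 10–80 °C, which is physically wrong
for LGA (solubility rises steeply with temperature) and inconsistent with
the supersaturation levels the same sources report (S ≈ 1.5 for the
reference composition at 45 °C). Evaluated with $T'$ in kelvin the curve is
strictly increasing on the operating range and reproduces those
supersaturation levels, so `absolute_kelvin` is the default convention;
`celsius_as_printed` remains selectable for literal reproduction. A related
inconsistency is inherited from the source data: the reference loading of
43 g LGA per 1000 g water is commonly described as saturated at 70 °C, yet
the kelvin-convention polynomial puts its saturation temperature at
60.3 °C (`saturation_temperature(0.0052374)`). The package treats the
polynomial as authoritative and keeps 70 °C only as the *nominal*
saturation point used in metastable-zone-width reporting.

**Driving force and kinetics.** $S = C/C^*(T)$ and $\sigma = S - 1$, both
on the mole-fraction basis. Primary nucleation and growth are power laws,
$\dot n_0 = k_N \sigma^n$ and $G = k_G \sigma^g$, zero for $\sigma \le 0$
(no dissolution — the growth term of the discretization is one-directional,
so undersaturated excursions simply freeze the population). Two literature
parameter sets are built in:

| set | $k_N$ (#/m³·s) | $n$ | $k_G$ (m/s) | $g$ | origin |
|---|---|---|---|---|---|
| `kinetics_tai_shei()` | 4.02×10⁶ | 1.87 | 9.76×10⁻⁸ | 2.34 | 6 L vessel, 600 rpm, crash cooling |
| `kinetics_penchev()`  | 4.02×10⁶ | 1.87 | 2.80×10⁻⁷ | 1.43 | 20 L vessel, 100 rpm, slow cooling |

The Penchev growth constants are what `fit_growth_power_law()` returns on
that study's (σ, G) data: ordinary least squares of $\log G$ on
$\log\sigma$, with $k_G = e^{\text{intercept}}$, $g$ the slope, and the
standard error of $k_G$ by the delta method. OLS on logs is the simplest
estimator consistent with multiplicative measurement error; weighted
alternatives are out of scope. $G$ is interpreted as the rate of change of
the volume-equivalent *diameter*: the convention is not stated with the
published constants, and the diameter reading is the one consistent with
the Sauter-mean-diameter definition used for reporting. Note that the
power laws carry no temperature or agitation dependence: a well-mixed run
at "150 rpm" is physically identical to one at "100 rpm" unless the
kinetic constants differ, and the report says so.

**Size grid and discrete method.** Crystal volumes live on a geometric
(ratio-factor) grid $V_{i+1}/V_i = 2^q$ with
$d_i = (6V_i/\pi)^{1/3}$ (spherical volume-equivalent sizes; a fixed π/6
shape factor). $q$ is real-valued, fixed by the requested
$(d_{\min}, d_{\max}, n_{\text{bins}})$; the classical integer-$q$ grids
are a special case, but integer $q$ would limit resolution to factor-2
volume steps. The default grid is 40 bins from 1 to 1000 μm
($q \approx 0.767$, diameter ratio ≈ 1.19 per bin) — fine enough that
doubling the bin count moves the final Sauter mean diameter by under 5 %
(checked in the test suite), coarse enough that a full batch integrates in
well under a second. Growth is the upwind two-term transfer written above;
its telescoping structure conserves total particle number exactly, with
nucleation the only number source. The largest bin has no outflow (closed
top); a warning is raised if more than 1 % of crystal volume accumulates
there, which signals that $d_{\max}$ was chosen too small. Upwind transfer
on a geometric grid is numerically diffusive: a monodisperse pulse spreads
as it grows. On an 80-bin grid the volume-weighted mean diameter of a
growing pulse advances within 15 % of the imposed $G$ over a decade of
growth (property-tested); sharper flux-limited schemes are deliberately
out of scope.

**Mass balance and energy.** The solute balance is written in moles of
LGA on a fixed water mass (default 1 kg, $n_w = 55.51$ mol):
$\dot n_{LGA} = -(\rho_s V_{sol}/M_{LGA})\,\dot\phi_T$ where
$\phi_T = \sum_i \alpha_i$ is the total crystal volume fraction. The
crystal density defaults to $\rho_s = 1540$ kg/m³ (literature value for
α-LGA) and the solution volume is constant at (solution mass)/(1000
kg/m³) — the slurry never exceeds ~3 % solids, so volume shrinkage and the
concentration dependence of solution density are second-order. The energy
balance is reduced to an imposed temperature ramp (default 0.6 K/min from
70 to 20 °C, then hold); crystallization enthalpy and impeller heat input
are neglected. A `jacket_flux` mode derives the ramp rate from
$q''A/C_{th}$ for users who prefer to state a wall flux, but it requires
the wetted area and lumped thermal mass explicitly because the
flux-to-ramp equivalence depends on fill level and heat capacity.

## Numerical choices

The coupled ODE system (solute moles + one $\alpha_i$ per bin, per zone)
is stiff near nucleation onset; it is integrated with `deSolve::ode`
(lsoda) at relative tolerance $10^{-8}$ and absolute tolerances
$10^{-12}$ mol on the solute state and $10^{-16}$ per volume-fraction bin.
Number densities are clamped at zero inside the right-hand side, so the
tiny negative undershoots lsoda can produce never feed back into the
rates; outputs are clipped at zero and any clipped mass shows up honestly
in the mass-balance audit. The audit —
$|\Delta n_{LGA} + \rho_s V_{sol} \Delta\phi_T / M_{LGA}| / n_{LGA}(0)$ —
closes to ~10⁻¹⁵ on the reference batch and is asserted below 10⁻⁶ on
every simulation in the test suite. Refining the solver tolerance tenfold
moves the peak supersaturation by less than 10⁻³ (tolerance-convergence
test). The output grid (default every 10 s) only controls sampling, not
the integration step.

Event detection works on the sampled trajectory: the crystallization
onset is the first 1 % relative drop of $C$ below $C_0$, linearly
interpolated between samples (1 % is a pragmatic stand-in for the
qualitative "concentration starts to decrease"; the metastable zone width
is monotone in this threshold, which is property-tested). The
supersaturation peak is refined by parabolic interpolation through the
peak sample and its neighbours. The desupersaturation time is the first
crossing of the S threshold *after* the peak — the solution starts
undersaturated ($S_0 = 0.78$ at 70 °C for the reference composition), so
"first time below threshold" without the after-the-peak qualifier would
trivially return zero. CSD percentiles interpolate the cumulative volume
curve in log-diameter against geometric bin edges, matching the grid's
geometry; the CSD mode is refined log-parabolically over the peak bin and
its neighbours.

## The multizonal reduction

`simulate_zonal()` integrates the same local model in each of a few
well-mixed zones connected by user-specified volumetric flows.
Solute moves between zones as $Q \times$ donor molar concentration,
crystals as $Q \times$ donor $\alpha_i$ (every size class advected alike —
no inter-zone settling or slip, since no transport law for it is
available at this level of reduction), and heat as
$Q \times$ donor temperature. The imposed cooling duty is split between
zones by heat weights; weights proportional to zone volume reproduce a
uniform (algebraic) temperature, and in that case a single zone is
*exactly* the well-mixed integrator — the equivalence is asserted to
10⁻¹⁰ in the tests. Zone volumes are constant, which requires balanced
flows (`validate_network()` names offending zones). As exchange flows grow
large the zonal solution collapses to the well-mixed one, and the averaged
solids become insensitive to how the heat duty is split — both limits are
tested at 100× and 10000× a reference flow. `three_zone_template()` ships
a top/bulk/wall preset in which the wall zone takes a disproportionate
share of the cooling duty: it runs colder, reaches higher peak σ and
accumulates more nucleation than the bulk (directionally tested), which is
the qualitative signature of wall-dominated cooling in real stirred
vessels. Zone topology and flow magnitudes are user inputs: deriving them
from resolved flow fields is outside this package's scope.

## Synthetic data

The fixtures module generates all test inputs in code. Growth-rate
datasets draw σ log-uniformly (default 0.05–1, the range where the power
law is actually exercised in a cooling batch) and apply multiplicative
lognormal noise of sd 0.1 on the log scale — mimicking the scatter of
growth rates estimated from desupersaturation experiments, which is
multiplicative in nature; a fixed seed makes every fixture byte-stable.
Seeded populations place a lognormal volume distribution on the grid by
differencing the CDF at geometric bin edges (deterministic; the recovered
percentiles match the generating quantiles within one bin). The
equilibrium fixture emits a configuration with $C_0 = C^*(T_0)$, an exact
fixed point of the simulator. What these fixtures do *not* emulate:
measurement bias in growth data, non-lognormal seed shapes, impurity
effects, and any agitation dependence — passing tests show the numerics
and estimators are correct, not that the power-law model captures a
particular vessel.

## Reference batch and known limitations

The reference conditions used throughout the tests and the acceptance
script are: 43 g LGA per 1000 g water ($x_0 = 0.0052374$, via
$M_{LGA} = 147.13$, $M_{H_2O} = 18.015$ g/mol), cooling 70 → 20 °C at
0.6 K/min (an 83.3 min ramp, extended by a hold at 20 °C to 333 min where
the approach to equilibrium is measured), Tai–Shei kinetics, 40 bins from
1 to 1000 μm. These sizes keep the full suite under a minute while staying
grid- and tolerance-converged as documented above.

Under these conditions the well-mixed model computes: onset at
34.7 °C (MSZW 35.3 K), supersaturation peak S = 2.30 at 64.3 min,
S = 1.58 at the end of the ramp, S < 1.10 at 148 min, final solids
fraction 0.0155, final CSD mode 213 μm. Experimental and spatially
resolved studies of this vessel class report earlier onset (around 45 °C,
MSZW ≈ 25 K), a lower peak (S ≈ 1.5 at ≈ 42 min) and a faster approach to
equilibrium (~65 min), while agreeing with the final CSD location and
solids level. The gap is a documented property of the well-mixed
assumption, not a numerical artefact — an independent moment-closure
integration of the same lumped model reproduces this package's trajectory,
and both rate laws are convex in σ, so any spatial supersaturation
heterogeneity (cold wall films especially) makes the *mean* nucleation and
growth rates exceed the rates at the mean σ. Lumped power-law kinetics
calibrated in other vessels simply cannot represent that acceleration;
the multizonal mode exists precisely to reintroduce it with a cold wall
zone, at the cost of user-supplied topology. Users comparing against
plant or CFD data should expect the well-mixed trajectory to crystallize
late and retain supersaturation longer, and should treat onset/peak
timing — not the final CSD — as the quantities most sensitive to mixing
detail.

Other limitations: no agglomeration or breakage kernels, no secondary
nucleation, no size-dependent or temperature-dependent (Arrhenius) growth
constant, constant solution volume, closed top size bin, first-order
upwind growth transfer. Each is a deliberate scope boundary; the module
surfaces are designed so that richer kernels or schemes could be added
without changing the bookkeeping types.
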