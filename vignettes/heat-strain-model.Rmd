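---
title: "Modelling physiological heat strain under low-level thermal radiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling physiological heat strain under low-level thermal radiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(firestrain)
```

## The problem

A firefighter working near a fire is heated by low-level thermal radiation
(a few to ~20 kW/m^2) through three clothing layers — outer shell, moisture
barrier, thermal liner — and the enclosed air layer between the liner and
the skin. Skin burn is only part of the risk: the combination of radiant
load, heavy clothing and hard work drives the deep-body (core) temperature
up, and heat strain can persist long after the exposure ends because the
clothing discharges its stored energy into the body. `firestrain` couples a
one-dimensional clothing/air-gap heat-transfer solver to an 81-node human
thermoregulation model and reports strain endpoints: the *safe exposure
time* (first crossing of a 38.5 °C core threshold), the *effective cooling
time* (recovery below that threshold after the exposure), the *dangerous
time zone* between them, and a 44 °C skin-burn flag.

## Clothing and air-gap model

Within each fabric layer the temperature obeys a transient conduction
equation with an in-depth radiative source,

$$(\rho C_p)_{fab}\,\partial_t T = \partial_x\!\big(k_{fab}(T)\,\partial_x T\big)
  - \partial_x q_{rad},$$

where the penetrating source radiation decays by Beer's law,
$q_{rad}(x) = q_0\, e^{-\kappa x}$, with a per-layer extinction coefficient
$\kappa = \ln((1-r)/\tau)/L$ built from the layer's reflectivity and
transmissivity. Fabric conductivity uses the porous-fabric mixing rule
$0.8\,k_{air}(T) + 0.2\,k_{fiber}(T)$ with $k_{fiber} = 0.13 +
0.0018\,(T-300)$ and $k_{air} = 0.026 + 0.000068\,(T-300)$ W/(m K). Because
the mixing rule's room-temperature value (0.0468 W/(m K)) disagrees with
the measured conductivities of the inner layers, each layer is anchored to
its measured value at 300 K and the mixture's slope is applied
multiplicatively — this preserves both the measurements and the temperature
dependence.

The outer surface receives the net source flux

$$q_0 = F_{hs\text{-}shell}\,\sigma\big(\varepsilon_{hs}T_{hs}^4 -
  \varepsilon_1 T_{shell}^4\big)\frac{A_{hs}}{A_{fab}}
  - \sigma\varepsilon_1 F_{shell\text{-}amb}(1-\varepsilon_g)
    \big(T_{shell}^4 - T_{amb}^4\big)$$

and loses heat by free convection (vertical-plate correlation; the
turbulent branch is implemented in its squared, dimensionally consistent
form, with the un-squared variant available behind `squared = FALSE`) plus
surface radiation; during cooling the source term vanishes and the
radiative loss is no longer veiled by the hot-gas emissivity
($\varepsilon_g = 0.02$). The source-side view factor is never measured
directly: `calibrate_view_factor()` recovers it by bisection so that the
flux on the initially ambient shell equals the scenario's nominal flux
(0.378 for 8.5 kW/m^2 with the packaged bench geometry). Nominal fluxes
beyond the source's reach at $F = 1$ (above ~22.5 kW/m^2 for the 733.15 K
source) pin $F = 1$ and calibrate the source temperature instead.

The air gap is a radiation-participating enclosure: the liner and skin
exchange parallel-plate radiation
$\sigma(T_{liner}^4 - T_{skin}^4)/(1/\varepsilon_l + 1/\varepsilon_s - 1)$,
attenuated across the gap with $\kappa_{air} = 5\ \mathrm{m^{-1}}$ (the
absorbed ~3% is deposited in the gap air), while conduction/convection is
modelled by multiplying the gap air conductivity by the enclosure Nusselt
number

$$Nu = \begin{cases}
 1, & Ra \le 10^3\\
 0.22\big(\tfrac{Pr}{0.2+Pr}Ra\big)^{0.28}\big(\tfrac{H}{L}\big)^{-1/4},
   & 10^3 < Ra \le 10^{10},
\end{cases}$$

floored at 1. This $k_{eff} = Nu\,k_{air}$ treatment equals the lumped film
exchange $h = Nu\,k_{air}/L$ in quasi-steady state (the lumped view is
exposed as `gap_interface_fluxes()`) but remains conservative in
transients. Convection is gated at $Ra > 1000$ for a vertical gap (1708
horizontal). Two conventions matter here and are deliberate:

* **Rayleigh property state.** The gap Rayleigh number uses dry-air
  properties at the *ambient reference state* rather than the film mean.
  At film-state properties a ~6 mm gap under the nominal exposure peaks
  near $Ra \approx 700\text{–}900$ and convection could never start there,
  which contradicts the documented onset behaviour of garment gaps at
  about 6 mm; the ambient-state convention reproduces it
  (onset at 6 mm, none at 3 mm).
* **Cavity height.** Garment air layers are pinched into closed cells by
  fabric–skin contact, so the enclosure height defaults to the gap size
  (roughly cubical cells); a fixed height is configurable.

A gap of size zero means perfect thermal contact between liner and skin. A
run's innermost boundary is the current mean skin temperature (Dirichlet),
and `skin_surface_flux()` — conduction across the last interval plus the
attenuated radiation — is what the body model (or a skin-simulant sensor)
receives.

## Numerical scheme

The PDE is discretized by vertex-centred finite volumes (interfaces fall on
nodes, so steady two-material stacks reproduce series resistance exactly)
and advanced by Crank–Nicolson steps of 0.1 s with 5 µm fabric spacing —
the gap uses 0.1 mm because its field is near-linear; the grid-halving test
bounds the error of that choice below 1%. Nonlinear terms (conductivities,
the $T^4$ boundary and gap radiation, the Beer source) are lagged and the
tridiagonal system is solved exactly by the Thomas algorithm inside a
point-iteration loop swept until the largest temperature change falls below
10^-6 K (cap 100 sweeps, warning on cap). A plain point-by-point iteration
without the exact tridiagonal kernel stalls at this mesh's diffusion number
(~780) and would silently corrupt the solution, which the energy audit
(closure to 0.1% per step) and the analytic transient-slab comparison
(< 0.5%) would expose. Temperatures outside (200, 1500) K abort the run
with diagnostics. The kernel is compiled (Rcpp): a full 2800 s coupled run
(~28,000 steps over ~800 implicit unknowns plus the 81-node body) takes
roughly half a minute, and the two parameter sweeps (7 flux runs, 9 gap
runs) together about 8 minutes on one CPU.

## The 81-node body model

Twenty segments (face, head, chest, stomach, back, hips, and paired
shoulders, upper arms, forearms, hands, thighs, calves, feet) each carry
core, muscle, fat and skin nodes; an 81st node is the central blood pool.
Each tissue node balances metabolic heat, convective exchange with the
blood ($B = 1.067\,\dot V\,(T - T_{81})$ W per L/h), conduction to its
neighbours, and — for skin — the clothing boundary flux and sweat
evaporation; respiration (8% of the metabolic rate) is charged to the chest
core. The blood pool integrates $\sum B$, so its discrete balance is
conservative to rounding. The ordinary differential equations advance by
explicit 0.1 s steps (time constants of the stiffest nodes are tens of
seconds; halving the step moves the 300 s core temperature by < 0.01 K).

The active system turns node errors $Err = T - T_{set}$ into warm/cold
signals and drives four controllers (vasodilatation, vasoconstriction,
sweating, shivering) from the head-core signal and the area-weighted skin
signals, with the canonical coefficient set ($C_{dl} = 117$, $S_{dl} =
7.5$; $C_{st} = 5$, $S_{st} = 0.5$; $C_{sw} = 371.2$, $S_{sw} = 33.6$;
$P_{ch} = 24.4$) and the local $2^{Err/10}$ factor on skin perfusion and
sweating. Skin perfusion is `(basal + w·DL)/(1 + w·ST)`, capped at 40 L/h
whole-body: with a single well-mixed blood pool and no countercurrent
exchange, an unbounded vasodilated skin loop slaves the blood node to the
skin temperature (core excursions several kelvin beyond the model family's
validity); the ceiling keeps the skin–core partition of stored heat
physiological. Sweat commands are bounded at 670 W (~1 L/h) and evaporation
is capped by the environmental maximum
$h_e (P_{sat}(T_{skin}) - P_a) A$, $h_e = 49.5$ W/(m^2 kPa), scaled by a
clothing evaporative efficiency. That efficiency defaults to 1
(free-surface evaporation): with strongly impeded evaporation (~0.3) the
clothed body at 30 °C cannot return below the 38.5 °C threshold within the
simulated cooling at moderate fluxes, i.e. the recovery behaviour this
model is built to quantify would not exist; the knob remains configurable
for drier formulations.

**Dataset provenance.** The published multi-node datasets use 16 segments;
the 20-segment table packaged here (`build_body()`) is a *reconstruction*:
areas and masses re-aggregated by surface-area/mass proportionality,
physiologically plausible capacities, set points, basal rates and
perfusions, and — following the original calibration principle of this
model family — inter-layer conductances (and, where needed, basal
perfusion) solved in code so that the set-point state is an *exact*
thermoneutral steady state. The free parameters that the published sources
do not determine (basal skin perfusion 7 L/h, its 40 L/h ceiling, the
evaporative efficiency) were fixed once against the nominal
8.5 kW/m^2 bench condition and not revisited for other fluxes or gap
sizes.

## Scenario driver and endpoints

`run_scenario()` advances clothing and body in lock-step at 0.1 s: the
clothing solver receives the area-weighted mean skin temperature, the body
receives the skin surface flux on all 20 (covered) segments. The phase
switches at `exposure_s` (default 300 s; cooling 2500 s; ambient 30 °C and
65% RH). The metabolic rate is 290 W/m^2 during the exposure — hard work —
and drops to a resting 58.2 W/m^2 during cooling: recovery happens at rest,
and with the work rate sustained the heat balance at 30 °C never turns
negative and no recovery threshold would ever be re-crossed. Threshold
crossings are linearly interpolated between 0.1 s samples; the effective
cooling time reports an infinite sentinel when the core is still above
threshold at the end of the simulated cooling. `sweep_scenarios()` runs the
flux axis (default 5–23 kW/m^2) or the gap axis (0–24 mm) serially and
deterministically.

## Synthetic bench-top traces

`synthetic_flux_trace()` emulates what a water-cooled skin-simulant sensor
records behind a clothing sample: a saturating exponential rise during the
exposure (default time constant 40 s) toward `plateau_fraction × nominal`,
then an exponential storage-discharge decay (default 120 s), with optional
seeded Gaussian noise (tests use none). These taus are fixture parameters
chosen for shape realism, not measured values. `bench_top_run()` replays
any trace — synthetic or measured — through the body model alone, which is
the same computational pathway as a coupled run with the clothing solver
replaced by the record; replaying a coupled run's own flux through it
reproduces the coupled core trajectory to < 0.05 K. What the generator does
*not* emulate: sensor dynamics, lateral losses, moisture effects, or
run-to-run variability of a real bench; passing tests on these fixtures
validates the body model's pathway, not the fidelity of any laboratory
trace.

## Known limitations

* One-dimensional heat transfer; no lateral conduction or edge losses.
* Dry fabric: no moisture storage, transport or evaporation inside the
  clothing (the evaporative-efficiency knob is the only coupling).
* Optical properties of the layers are constants and largely
  unmeasured — the shell's $\tau = 0.044$, $r = 0.09$ (giving
  $\kappa \approx 4.8\times 10^3\ \mathrm{m^{-1}}$) are calibration knobs.
* The enclosure correlation with its Nusselt floor of 1 makes small-gap
  convection a weak effect: the total gap conductance at 6 mm
  (convection + radiation) cannot exceed the 3 mm pure-conduction value
  for any attainable Rayleigh number, so peak strain decreases
  monotonically with gap size over 3–24 mm in this implementation.
* The body dataset is a reconstruction; absolute times carry an
  engineering uncertainty we treat as ±15%.
* No cardiovascular strain, dehydration or burn-depth integration; the
  44 °C skin flag is a threshold, not a damage integral.
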