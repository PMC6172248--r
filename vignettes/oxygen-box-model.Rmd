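---
title: "A forward carbon-sulphur-oxygen box model of Phanerozoic atmospheric O2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A forward carbon-sulphur-oxygen box model of Phanerozoic atmospheric O2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(phanox)
```

## The problem

Atmospheric oxygen over the Phanerozoic is set by the long-term balance
between the burial of reduced species in sediments — photosynthetic organic
carbon and microbially produced pyrite sulphur — and their oxidative
weathering and metamorphic recycling:

$$\mathrm{CO_2 + H_2O \rightleftharpoons CH_2O + O_2}$$
$$\mathrm{2Fe_2O_3 + 16Ca^{2+} + 16HCO_3^- + 8SO_4^{2-} \rightleftharpoons
  4FeS_2 + 16CaCO_3 + 8H_2O + 15O_2}$$

so each mole of buried organic carbon is worth one mole of O2 and each mole
of buried pyrite sulphur 15/8 moles.

GEOCARBSULF-style box models estimate both burial fluxes by inverting
seawater isotope records (delta13C of carbonate, delta34S of sulphate)
through isotope mass balance (IMB). Inverting the sulphur record requires a
fractionation factor between sulphate and buried pyrite, and the classic
choice — a fractionation that shrinks as oxygen falls, here
$\alpha_s = \alpha_{s,0}\,\mathrm{O_2mr}^{n}$ — creates a pathological
feedback: at low O2 the fractionation becomes implausibly small (below the
envelope of the geologic record) and the burial flux demanded by the
inversion diverges as $1/\alpha_s$, locking modelled oxygen near the
present value.

This package implements the *forward* alternative: pyrite and gypsum
burial and weathering are computed from model state (ocean sulphate,
organic-matter supply, normalized O2, COPSE-style laws), no sulphur isotope
inversion is performed, and the delta34S record is instead a validation
target for the model's synthetic sulphate composition. The legacy inverted
scheme is retained as a diagnostic (`legacy_alpha_s()`,
`legacy_pyrite_burial_imb()`, `legacy_sulphur_diagnostic()`) so the
contrast between the two formulations can be reproduced directly.

## Model structure

The state comprises ten reservoir masses — ocean+atmosphere carbon
$\mathrm{OA_C}$ and sulphate $\mathrm{OA_S}$, young/ancient crustal organic
carbon, carbonate, pyrite and gypsum (the GEOCARB "rapid recycling" split)
— their isotope compositions, and ocean-atmosphere O2. Masses are carried
in units of $10^{18}$ mol and fluxes in $10^{18}$ mol/Myr; time runs
forward in Myr from the start age (default 570 Ma), with all I/O in Ma.

### Carbon side

Organic burial is inverted from the driving carbonate delta13C record
$\delta(t)$ by IMB over the ocean-atmosphere pool:

$$F_{bg} = \frac{M_{OA}\,\dot\delta -
  \sum_i F_i\,(\delta_i - \delta)}{\Delta^{13}C},$$

where the $F_i$ are the carbon inputs (carbonate and organic weathering,
degassing) at their reservoirs' compositions and the burial fractionation
carries a linear oxygen dependence
$\Delta^{13}C = \Delta_0 + J\,(\mathrm{O_2mr}-1)$ with $\Delta_0 = 25$
permil and $J = 4$ by default. A demand for negative burial is clipped to
zero and counted in the run's health flags. Carbonate burial closes the
surface carbon budget (see *Numerical choices*).

Silicate weathering is
$F_{ws} = F_{ws,0}\, f_{AW}\, f_A^{0.5} f_D^{0.65}\,
 f_{plant}\, g_{sil}(R_{CO_2}, GEOG)$
and carbonate weathering scales with carbonate land area ($f_L f_A f_D$),
its climate factor and the young reservoir mass; ancient weathering and
degassing are rate constants times reservoir mass times erosion
($f_A f_D$) or spreading ($f_{SR}$) forcings, with an
$\mathrm{O_2mr}^{\beta}$ ($\beta = 0.5$) oxidative feedback on organic
carbon. The climate factors use the documented GEOCARB-family forms
($\Delta T = \gamma \ln R_{CO_2} + GEOG$;
$g_{sil} = e^{0.09\Delta T}(1+0.045\Delta T)^{0.65}
 (2R_{CO_2}/(1+R_{CO_2}))^{0.4}$;
$g_{carb} = 1 + 0.087\Delta T$), all equal to 1 at present and increasing
in CO2. CO2 is internal state only ($R_{CO_2} = \mathrm{OA_C/OA_{C,0}}$);
reconstructing the Phanerozoic CO2 curve is a non-goal.

### Sulphur side (the forward scheme)

$$F_{wp,y} = \frac{F_{ws}}{F_{ws,0}}\cdot k_{wp}\cdot
  \frac{\mathrm{Pyr}_y}{\mathrm{Pyr}_0}\cdot \mathrm{O_2mr}^{0.5}
\qquad
F_{wgyp,y} = \frac{F_{wc,y}}{F_{wc,y0}}\cdot k_{wgyp}\cdot
  \frac{\mathrm{Gyp}_y}{\mathrm{Gyp}_0}$$

$$F_{bp} = k_{bp}\cdot\frac{\mathrm{OA_S}}{\mathrm{OA_{S,0}}}\cdot
  \frac{F_{bg}}{F_{bg,0}}\cdot\frac{1}{\mathrm{O_2mr}}
\qquad
F_{bgyp} = k_{bgyp}\cdot\frac{\mathrm{OA_S}}{\mathrm{OA_{S,0}}}\cdot
  \mathrm{Calc}$$

Young pyrite weathers with silicates and young gypsum with carbonates
(hence the flux-ratio prefactors); pyrite burial increases with ocean
sulphate and organic-matter supply and decreases with dissolved oxygen —
an O2 feedback with no fractionation term; gypsum burial follows sulphate
and the normalized seawater calcium reservoir (supplied as the `calc`
forcing, default 1). Ancient weathering keeps the GEOCARB form with an
added $\mathrm{O_2mr}^{0.5}$ feedback on ancient pyrite only; degassing is
linear in ancient reservoir mass and spreading rate, with degassed sulphur
returned to the sulphate pool (oxidized on emission, the O2 cost charged
at 15/8 per mole of pyrite sulphur); young-to-ancient transfer is linear
in the young mass. Every flux moves mass between modelled reservoirs, so
total carbon and total sulphur are conserved identically.

The sulphate delta34S evolves with pyrite buried at
$\delta_{sulphate} - \alpha_{s,fwd}$ ($\alpha_{s,fwd} = 35$ permil,
constant) and gypsum at $\delta_{sulphate}$; this synthetic record is an
*output* for comparison against data (`validate_d34s()`), never an input.

### Initialization

Total sulphur is $418\times10^{18}$ mol — ocean sulphate 38, pyrite 280,
gypsum 100 (pyrite:gypsum 2.8:1, reflecting a Proterozoic dominated by
pyrite burial with low gypsum deposition across the Ediacaran-Cambrian
boundary). The legacy configuration ($638\times10^{18}$ mol total, pyrite
= gypsum = 300) is available via `model_config(sulphur_init = "legacy")`.
The paper trail for the young/ancient split of those totals is silent, so
the split is a configurable parameter defaulting to 50:50.

Present-day fluxes are round literature-scale magnitudes chosen so that
*every* reservoir budget closes exactly at the anchor (all forcings 1,
$R_{CO_2} = \mathrm{O_2mr} = 1$): organic burial 5, carbonate burial 20,
silicate weathering 6, organic weathering 3 + 1.5, carbonate weathering
12 + 6, carbon degassing 0.5 + 2, pyrite and gypsum burial 1 each, young
pyrite/gypsum weathering 0.6 each, ancient 0.3 each, sulphur degassing 0.1
each (all $\times 10^{18}$ mol/Myr). Closure makes the present state an
exact fixed point of the derivative field, which anchors the conservation,
stability and convergence tests.

```{r anchor}
cfg <- model_config()
fx <- make_fixture("steady")
st <- initialize_state(cfg, fx$record)
max(abs(model_derivatives(st, 570, cfg, fx$forcings, fx$record)$deriv))
```

## Tunable parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `J` | O2 dependence of carbon fractionation | 4 (sweep 2.5-7.5) | - |
| `delta0_frac` | present carbonate-organic fractionation | 25 | permil |
| `beta_ox` | oxidative-weathering exponent | 0.5 | - |
| `alpha_s_forward` | sulphate-pyrite burial fractionation (output only) | 35 | permil |
| `legacy_delta_s0`, `legacy_n` | legacy fractionation law | 35, 1.5 | permil, - |
| `gcm` | temperature per ln CO2 | 4.33 | K |
| `o2mr_floor` | O2 floor guarding 1/O2mr | 1e-3 | - |
| `rtol`, `atol` | solver tolerances | 1e-8 | - |
| `start_age` | run start | 570 | Ma |

## Synthetic data

No driving compilation is redistributed with the package, so all inputs
can be generated in code:

* `synthetic_forcings()` — smooth sums of low-frequency sines, pinned to 1
  (or 0 K for GEOG) at 0 Ma and bounded by a stated amplitude.
* `synthetic_delta13c()` — baseline drift plus a few localized Gaussian
  excursions with constant 1-permil reported SD, pinned at 0 Ma to the
  steady-state composition implied by the flux configuration
  (`steady_delta13c()`, computed, not hard-coded).
* `make_fixture()` — three scenarios: `steady` (exact balance; holds 21%
  atm O2), `excursion` (a +3 permil, ~20-Myr carbon-isotope excursion at
  497 Ma in the style of the late-Cambrian Steptoean event; oxygen rises
  during and after), and `stress` (a sustained -8 permil excursion that
  drives the IMB burial demand negative and collapses oxygen to the floor,
  exercising the structured-failure path).

These fixtures emulate the *statistical structure* of real inputs — not
their values. Real compilations carry lithology- and basin-dependent
scatter, uneven sampling, and excursions whose shapes are not Gaussian;
passing tests on fixtures therefore demonstrates correctness of the
machinery (conservation, anchors, feedback signs, solver accuracy), not
fidelity of any particular Phanerozoic oxygen curve. Curve-level
comparison requires user-supplied digitized records
(`check_landmarks()`).

## Numerical choices

* **Solver.** Default `lsodar` (adaptive variable-step, variable-order,
  stiff-capable, with root finding used to terminate cleanly at the O2
  floor or an exhausted reservoir); `radau` (implicit Runge-Kutta) is
  supported and agrees to well under 0.1% on the fixtures. The
  requirement placed on the solver is accuracy (self-convergence under
  tolerance halving, agreement with brute-force explicit Euler), not a
  particular named scheme.
* **Isotope state.** Compositions are integrated directly
  ($\dot\delta = \sum F_{in}(\delta_{in}-\delta)/M$); together with the
  mass equations this conserves isotope-weighted mass exactly in the
  continuous system, and to solver tolerance in the discrete one.
* **Record interpolation and slope.** Records and forcings are piecewise
  linear (higher order would invent structure between coarse nodes); the
  record slope uses a central difference of the interpolant with a
  0.25-Myr half-step, clamped at the span edges. An optional second-pass
  cubic smoothing spline (`smooth_spline = TRUE`) exists behind a flag;
  the documented 10-Myr moving average is canonical.
* **Carbonate closure.** `carbonate_closure = "restoring"` (default) sets
  $F_{bc} = F_{bc,0}\,\mathrm{OA_C/OA_{C,0}}$ — a carbonate-saturation
  restoring term that keeps $\mathrm{OA_C}$ (hence $R_{CO_2}$) prognostic
  and equals exact closure at steady state; `"exact"` closes the surface
  budget instantaneously, which freezes $R_{CO_2}$ at 1. Both conserve
  total carbon identically.
* **Guards.** Negative IMB burial is clipped (counted, warned); O2mr has
  a 1e-3 floor at which integration terminates with a structured failure
  (`run$failed`, `run$failure$age_ma`, `run$failure$reason`) rather than
  continuing silently; assembled fluxes are checked finite and
  non-negative every call.
* **Problem sizes.** Tests integrate full 570-Myr runs at 1-Myr reporting
  (each well under a second) and check the solver against explicit Euler
  at 1-kyr steps over a 10-Myr window spanning the excursion onset.

## Design decisions on open points

* The envelope runs perturb the record *pointwise* by $k\cdot sd(t)$; a
  single global SD would understate uncertainty where the compilation is
  sparse.
* Sulphur degassing is routed to ocean sulphate as oxidized S with the
  corresponding O2 cost; partial reduced emission would need an extra
  free parameter the sources do not constrain.
* `Calc` is a forcing series (default 1), not dynamic state: no governing
  equation is available for it at this model's level of description.
* The solar-luminosity contribution to surface temperature is not a
  separate term; the additive `GEOG` forcing carries any combined
  paleogeography/insolation offset. This keeps the present-value anchor
  property exact and leaves the choice of offset history to the forcing
  tables.
* The legacy fractionation constants (35 permil at present, exponent 1.5)
  are the GEOCARB-family defaults and are configurable; they reproduce
  the documented behaviour (fractionation < 10 permil at 10% atm O2,
  inverted burial demand more than an order of magnitude above present at
  low O2).

## Worked example

```{r example}
fx <- make_fixture("excursion")
run <- run_model(fx$config, fx$forcings, fx$record)
run
plot(run)
```

```{r sweep}
sw <- j_sweep(fx$config, fx$forcings, fx$record, j_values = c(2.5, 4, 7.5))
sw
```

```{r legacy}
d <- legacy_sulphur_diagnostic(c(5, 10, 21), model_config())
d
```

## Limitations

* The package ships no observational data; headline Phanerozoic oxygen
  curves require externally digitized delta13C and forcing tables.
* CO2 is a diagnostic internal state, not a calibrated reconstruction.
* The legacy diagnostic holds the carbon/sulphur background at the
  present-day anchor; it illustrates the flux relationship, not a
  transient legacy run.
* Biological C:P stoichiometry shifts, coal-basin forcings and other
  late-Paleozoic refinements of COPSE-lineage models are out of scope.
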