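---
title: "Sizing and simulating distal resistance in 3D-printed coronary phantoms"
author: "coroflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sizing and simulating distal resistance in 3D-printed coronary phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coroflow)
```

## The problem

Benchtop flow loops built around 3D-printed patient-specific coronary
phantoms can reproduce epicardial geometry down to sub-millimeter plaque
detail, but no printer can reproduce the arterioles and capillary bed that
set most of the coronary circulation's resistance. The standard workaround
is hardware: each coronary tree (LAD, LCX, RCA) drains into its own sealed
outflow chamber, and a catheter of chosen lumen and length is spliced
downstream of each chamber to impose the missing distal resistance. The
chamber doubles as a compliance element; the catheter is a pure resistor.
`coroflow` covers the quantitative side of that workflow:

1. **Catheter sizing** — what length of which French size realizes a target
   resistance;
2. **Chamber characterization** — estimating each chamber's own (small)
   hydraulic resistance from constant-flow pressure sweeps, and reporting it
   as a percentage of the coronary resistance it perturbs;
3. **Circuit prediction** — a lumped-parameter (0D) solution of the
   three-branch network, at steady state and as an RC transient.

All internal computation is in CGS units (cm, g, s): resistance in
dynes·s/cm⁵, pressure in dynes/cm², flow in cm³/s. Constructors and file
readers accept clinical units (mmHg, mL/min) and convert with fixed
constants (1 mmHg = 1333.22 dynes/cm²; 1 mL/min = 1/60 cm³/s).

## Catheter sizing by the Hagen–Poiseuille law

For fully developed laminar flow in a cylinder of inner radius $r$ and
length $L$, the hydraulic resistance is

$$R \;=\; \frac{8\,\mu\,L}{\pi r^4},$$

with $\mu$ the dynamic viscosity. `poiseuille_length()` inverts this
exactly, $L = R\pi r^4 / 8\mu$, so sizing a catheter for a target
resistance is closed-form; `poiseuille_resistance()` and
`poiseuille_length()` are exact inverses to machine precision. Entrance and
exit losses and turbulence corrections are deliberately ignored: at
coronary phantom flows (a few cm³/s split across three branches and driven
through sub-millimeter lumens) the flow is comfortably laminar, and the
reference sizing table the package ships is itself Poiseuille-consistent
(below).

### The viscosity default, and why it is 0.037 poise

The sizing table shipped as `reference_length_table()` — 9 vessel × activity
conditions × 3 radii = 27 lengths — does not state the working fluid.
Viscosity is, however, identifiable from the table, because $L \propto
\mu^{-1}$ at fixed $R, r$: `fit_viscosity()` minimizes the mean relative
error between predicted and tabulated lengths over $\mu \in (0.005, 0.10)$
poise and lands at:

```{r}
fit_viscosity()
```

3.7 cP is a typical blood-analog (e.g. glycerol–water) viscosity, so the
package defaults to `fluid_properties(0.037)`. With that default all 27
tabulated lengths reproduce within 2.5 % relative error (worst cell ~2.3 %,
a length printed as 3.9 cm where the formula gives 3.99 — a rounding
artifact of the source table). The default is overridable everywhere a
fluid enters.

A viscosity-free consistency check is the fourth-power ratio law: at fixed
target, $L(r_2)/L(r_1) = (r_2/r_1)^4$ for *any* $\mu$. The tabulated
ratios obey it within 2.5 % across all conditions.

### Catalogs, feasibility, and the chamber correction

`catheter_catalog()` models available stock: 4/5/6 Fr with inner radii
0.06/0.071/0.09 cm and a 112 cm maximum stock length. The default minimum
length is 0 because stock can always be cut shorter; only over-length
designs are infeasible, which matches how the reference table flags its
own cells (129.1, 176.95 and 333.3 cm marked "use a smaller French size").
A positive `min_length_cm` models rigid stock and activates the
complementary "use a larger Fr" flag.

`design_for_target()` returns one option per catalog radius, with the
achieved resistance recomputed from geometry (hence exact), a relative
error, and feasibility flags; options sort by |relative error| with
feasible options winning ties. Because the chamber adds its own series
resistance, `required_distal_resistance(coronary, chamber)` subtracts the
measured chamber resistance first; asking the catheter for a non-positive
resistance is rejected as non-physical.

`build_quantized_set()` reproduces the bench practice of stocking
resistances in round multiples — by default every multiple of 10,000
between 50,000 and 300,000 dynes·s/cm⁵ (26 catheters). (The source
material quotes 50,000–300,000 in its methods text and 50,000–500,000 in a
figure caption; the methods value is the default and the range is a
parameter.) Rounding a true target to the nearest stocked multiple induces
the error reported by `quantization_error()` — about 1.7 % for the rest-LAD
target, consistent with the ~2 % the protocol itself cites; the bound is
`step / (2 * target)`.

## Chamber characterization

The chamber experiment drives a constant flow through each chamber alone
and records the pressure drop: the default `sweep_protocol()` is 80–160
mL/min in 20 mL/min steps (1.33–2.67 cm³/s). `characterize()` reports two
estimators:

- `mean_resistance` — the arithmetic mean of the per-point ratios
  $\Delta P_i / Q_i$ (the headline figure, matching how mean chamber
  resistances are conventionally quoted);
- `slope_resistance` — the through-origin least-squares slope
  $\sum \Delta P_i Q_i / \sum Q_i^2$.

For noiseless linear data the two coincide exactly with the true
resistance. It is not knowable from a published mean alone which of the
two a given source used; reporting both makes the choice explicit. Pressure
drop is taken as inlet minus outlet with the outlet at atmosphere unless
the caller differences the channels themselves.

`percent_of_coronary()` and `percent_table()` express a chamber resistance
as a percentage of each vessel's coronary resistance per activity state
(columns R, E1, E2 for rest, light and moderate exercise). With the
reference chamber means (LAD 1671, LCX 1820, RCA 591 dynes·s/cm⁵):

```{r}
percent_table(c(LAD = 1671, LCX = 1820, RCA = 591))
```

well under 7 % everywhere — the chamber is a small, correctable
perturbation. Percentages are rounded half-up to two decimals at render
time only; internal values keep full precision. Per-flow resistances (a
data.frame of chamber/flow/resistance) produce the per-flow table shape
instead, since measured chamber resistance can vary with flow; only the
mean-based row is recoverable from a published mean.

## The lumped circuit

`phantom_network()` assembles an inlet (pressure- or flow-driven), three
parallel branches — each artery resistance → chamber (series resistance
$R_{ch}$, compliance $C$ at the chamber node) → catheter resistance → an
atmospheric outlet — and an optional aortic outflow path.

**Steady state** is series–parallel resistor reduction:
$Q_i = (P_{in} - P_{out,i}) / R_{series,i}$, with $P_{in}$ solved from the
inlet nodal balance in flow-driven mode. Compliances carry no steady flow.
The test suite checks the solver against an independent brute-force nodal
solve (full conductance matrix, base `solve()`) and verifies flow
conservation to 1e-9 relative in both drive modes.

**Transients** integrate one compartment per branch,

$$C_i \frac{dP_i}{dt} = Q_{in,i} - \frac{P_i - P_{out,i}}{R_{ch,i} + R_{cath,i}},$$

so the time constant per branch is $\tau_i = (R_{ch,i}+R_{cath,i})\,C_i$
and a constant-inflow run converges to the steady solution. The inlet ball
valve (the aortic-valve surrogate of the hardware) is modeled as an ideal
check valve in flow-driven transients: negative source flow is clipped to
zero, after which the inlet node floats on the branch balance.
Pressure-driven transients, and flow-driven transients with more than one
branch, require positive artery resistances so the inflow split is
defined; the single-branch flow-driven case needs none.

The integrator is classical fixed-step RK4, written in the package rather
than delegated, because the solver (with its valve clipping and stability
contract) is part of what the package promises to make testable: every
transient behavior is checked against a closed form — exponential decay
($P(\tau)/P(0) = e^{-1}$ to 1e-6), the first-order low-pass gain
$1/\sqrt{1+(\omega R C)^2}$ (within 2 % at two frequencies), fourth-order
step-size convergence, and an independent `deSolve` integration of the same
ODEs on a two-branch network. The step must satisfy
$dt < 2\min_i(\tau_i)/s$ with safety factor $s \ge 1$ (default 5);
violating it is an error, not a warning, because an unstable explicit run
is silently wrong.

Compliance values are hardware-specific and not shipped as science:
`1e-4` cm⁵/dyne appears in examples and tests purely as a placeholder of
plausible magnitude (it gives $\tau \approx 25$ s against a rest-state
distal resistance), and transient simulation refuses to run without an
explicit compliance per branch.

`apply_activity()` retargets a network to an activity state: per branch it
subtracts the chamber resistance from the preset coronary resistance and
realizes the remainder through the catalog, warning when only an
infeasible (over-length) option exists. Preset resistances decrease with
activity (hyperemia), so moderate-exercise flows strictly exceed rest
flows at equal inlet pressure — a property the tests verify through the
steady-state solver.

## Synthetic data: what it emulates and what it does not

`generate_chamber_experiment()` emulates the chamber sweep with known
ground truth: $\Delta P = R_{true} Q$ over the sweep, perturbed by the
`noise_model()`. Noise is applied to the pressure channel only — the
programmable pump is treated as calibrated, so flow setpoints are exact
(switch to absolute noise or zero noise as needed). The default noise in
validation studies is 2 % relative Gaussian, chosen as a bench-realistic
sensor scale that exercises the estimators without swamping them; no
sensor specification was available to pin it down. All randomness flows
from the explicit seed in the noise model — there is no hidden global
state, the caller's RNG stream is restored, and a provenance record (truth,
sweep, noise, seed) regenerates any experiment bit-for-bit.

`recovery_suite()` is the validation harness: at each noise level it
replicates the sweep, re-estimates, and reports bias and SD per estimator.
At 2 % noise and 1000 replicates the mean estimator's bias is far below
1 % of truth, and its SD matches the theoretical $\sigma R/\sqrt{n}$
within Monte-Carlo slack; SD doubles from 2 % to 4 % noise.

What the generator does **not** emulate: flow-dependent chamber resistance
(real chambers show mild $R(Q)$ trends, plausibly minor-loss effects — no
model for it is assumed, so none is generated), sensor drift or
quantization, pulsatile pressure waveforms, or any geometric/printing
error. Passing recovery tests therefore demonstrate estimator correctness
under the stated noise model, not robustness to those effects.

## Numerical and design choices

- **Rounding**: percentages half-up to 2 decimals, resistances to whole units,
  applied at render time only (`render_report()`); all internal artifacts
  keep full precision.
- **Tie-breaks in design**: relative errors below 1e-12 are treated as
  exact ties, resolved in favor of feasible options, then smaller French
  size (shorter catheter, less dead volume).
- **Quantization ties**: a target exactly half-way between stocked
  multiples rounds up.
- **Degenerate inputs**: zero-length catheters have zero resistance;
  zero-flow points are rejected by index in `characterize()`; empty
  catalogs, empty sweeps, incomplete preset maps, and chamber ≥ coronary
  corrections are all errors with named causes.
- **Problem sizes** used by the validation suite and the acceptance
  script: the full 27-cell sizing table, 5-point sweeps, 1000-replicate
  Monte-Carlo recovery, transient grids of ~1000–4000 RK4 steps. The whole
  suite runs in a few seconds on one core.

## Known limitations

- The 0D model has one RC compartment per branch; multi-element Windkessel
  variants, intramyocardial pressure coupling and systolic time-varying
  resistance are out of scope — the benchtop phantom has no contracting
  myocardium.
- No stenosis pressure-loss terms (quadratic/Bernoulli) and no FFR
  computation; branches are linear resistors.
- Non-Newtonian or temperature-dependent viscosity is not modeled; the
  fluid is a single constant-viscosity Newtonian analog.
- The reference sizing table carries its source's own rounding (one cell
  at ~2.3 % deviation); tests use a 2.5 % tolerance against it rather than
  asserting exact table equality.
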