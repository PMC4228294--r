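---
title: "A Starling-force network model of CSF production and reabsorption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Starling-force network model of CSF production and reabsorption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfnet)
```

## The model

`csfnet` implements a lumped-parameter ("well-mixed compartment") model of
water and solute exchange in the cranium.  Eight compartments — arteries,
arterioles, capillaries, veins, ventricles, extracellular space (ECS),
perivascular space (PVS) and subarachnoid space (SAS) — are connected by
twelve directed arcs, each carrying one constitutive law:

* **Luminal arcs** (`Q1`–`Q6`, `Q11`): Hagen–Poiseuille flow
  `Q = ΔP/α`, with `α = 8µL/(πR⁴)` when derived from lumen geometry.
  `Q1`/`Q5` connect the arterial inlet and venous outlet to fixed boundary
  pressures.  `Q11` is the aqueduct from the ventricles to the SAS.
* **Starling arcs** (`J7` choroid plexus epithelium, `J8` blood–brain
  barrier, `J10` ventricular ependyma, `J12` arachnoid granulations):
  transmembrane water flux by the *amended* Starling law
  `J = L_pA (ΔP − Σᵢ σᵢ Δπᵢ)`, where the osmotic sum runs over **all**
  solutes — proteins, ions, glucose and loading osmolytes — not only
  colloids.  Osmotic pressures come from the van't Hoff relation
  `π = RT·φ·n·C` (≈19.34 mmHg per mOsm at 310.15 K).  The arachnoid
  granulations are a one-way valve (`J12 ≥ 0`).
* **Darcy arc** (`Q9`, PVS–ECS interface): porous-media flow
  `Q = kAΔP/(µL)`, algebraically identical to a luminal arc with
  `α = µL/(kA)`.

Water balances (`dV/dt`) are written per compartment with the canonical
signs (e.g. ventricles: `J7 + J10 − Q11` plus any protocol source; ECS:
`Q9 + G − J10`, where `G` is metabolic water).  Solute balances track molar
amounts per (compartment, species): luminal and Darcy arcs convect the
donor-side concentration (upwind rule, which keeps amounts nonnegative);
Starling arcs carry convective solvent drag `(1−σ)·J·C_donor` plus an
optional zero-order active-transport ("pump") term per (arc, species) that
represents carrier-mediated secretion, e.g. choroidal ion transport.
Glucose is additionally consumed in the ECS at a first-order rate
`k_gluc·C·V`, producing metabolic water at 6 × 18.015 µL per mmol of
glucose (`G` may instead be fixed directly; the adult-human value is
34 µL/min).

**Pressure closure.**  The flux laws need `P(V)`.  Compliant compartments
follow a linear compliance `P = P0 + (V − V0)/κ`.  The vascular
compartments default to *rigid*: their pressures are solved at every
right-hand-side evaluation from the instantaneous flow balance (a small
linear system, since every law is affine in pressure at fixed composition;
one-way arcs enter via an active-set iteration).  This reflects that the
vascular tree is boundary-driven on the time scales of interest.  The
Monro–Kellie constraint (constant total intracranial volume) is monitored
through the trajectory diagnostics, not enforced.

**Numerics.**  The coupled system (8 volumes + 8 × species amounts) is
stiff; it is integrated with `deSolve::lsoda` (defaults `rtol = 1e-8`,
`atol = 1e-10`).  Bolus events are applied as instantaneous state
increments with a stop-and-restart of the integrator — injection durations
(seconds) are far below the model's time scales (minutes), so smoothing
them would only add stiffness.  Inside the right-hand side the one-way
clamp is smoothed by `½(J + √(J² + ε²))` with ε = 10⁻⁶ µL/min: the hard
kink of `max(J, 0)` collapses the stiff solver's step size when an
operating point sits near the valve's closing point, while the smoothed
form differs from it by at most 5·10⁻⁷ µL/min.  Steady states are found by
a damped Newton iteration (finite-difference Jacobian over the free
coordinates; Levenberg–Marquardt retries on stall) bracketed by transient
integration, and verified by the residual norm and optionally by a
confirmation integration over 100 min.

**Units** are fixed throughout: µL, µL/min, mmHg, mmol/L (≡ mOsm for
species with `φ·n = 1`), minutes, K.  Species are listed post-dissociation
(Na⁺ and Cl⁻ separately, `n = 1`); the osmotic coefficients default to 1
and are configurable per species.

## The virtual experiments

**Ventriculo-cisternal perfusion (VCP).**  `run_vcp()` adds a continuous
intraventricular infusion of tracer-laden perfusate (`Q_inj`, default
77 µL/min) and an open collection drain at the SAS node (a cannula at a
reference pressure), solves to steady state, and applies the classical
tracer-dilution estimator `Q_f = Q_inj (C_inj − C_out)/C_out`.  Because
the eight-node network has no separate cisterna magna, the collected
concentration is sampled from the aqueduct effluent — the stream arriving
at the collection site before it mixes into the wider SAS — as in the
experimental preparation, where collection sits directly at the aqueduct
outlet.  With an impermeant tracer this makes the estimator exact up to
the steady-state tolerance, which the test suite verifies across
randomized parameterizations (the estimator-validity property).  The
experimental steady-state criterion (successive 15-min samples within
±2%) is available as `method = "sampled"`.

Perfusates are modeled as an ionic mock-CSF base (up to 250 mOsm) plus
sucrose carrying any surplus osmolarity, diluted below the base — matching
the experiments' sucrose solutions.  Serum osmolarity is perturbed by
adding an impermeant mannitol-class osmolyte to the arterial boundary
(hyperosmolar loading) or by proportional dilution (hypo-osmolar).

**Dose–response and sensitivities.**  `dose_response()` sweeps the
perfusate (ventricular site) or arterial (serum site) osmolarity and
reports the local sensitivity of nascent flow by central finite difference
(±10 mOsm) around the control point.

**Intravenous tracer bolus.**  `run_tracer_bolus()` emulates the
radiolabeled-water experiments: an inert, freely permeating tracer (σ = 0
on every membrane) appears in arterial blood, and a hyperosmolar sucrose
bolus is applied to a ventricle; the ventricular accumulation curves of
the two arms (bolus vs isomolar control) and the post-bolus plateau of
nascent flow are returned.

**Chronic intraventricular loading.**  `run_chronic_infusion()` infuses an
isotonic vehicle plus an impermeant macromolecule (dextran-class, mapped
to the mannitol species; FGF2 is a separate species whose ependymal
reflection coefficient is fitted) for days and tracks the ventricular
volume.

## Calibration

Most membrane parameters are not directly measurable; `calibrate()` fits
them by weighted least squares on log-transformed parameters
(Levenberg–Marquardt via `minpack.lm`, box bounds, σ capped at 1), with a
seed-controlled Latin-hypercube multi-start.  Anchors are the published
operating points transcribed into the packaged fixture tables; residuals
are scaled by `max(|target|, floor)` so that near-zero anchors (flow
arrest) do not dominate.  A profile-style probe flags parameters whose
±20% perturbation moves the objective by less than 1% as non-identifiable.
Pathological parameter regions can make the stiff integrations arbitrarily
slow, so each objective evaluation runs under a wall-clock limit and is
treated as infeasible if exceeded.

Four parameter sets ship with the package, each with its own anchor set:

* `human_baseline` — calibrated to 580 mL/day CSF production, 150 mL CSF
  (25 mL ventricular / 125 mL SAS), 34 µL/min metabolic water.
* `feline_vcp` — calibrated to the feline VCP operating points
  (6/320/780 mOsm ventricular rows, the serum rows, and the regression
  sensitivities 0.231 and 0.835 µL/min per mOsm).  The printed
  sensitivities come from regressions over many animals rather than the
  sparse table rows (whose secants differ), so they enter as independent
  anchors with their own weights.
* `canine_bolus` — the intravenous-tracer scenario (control 12.6 µL/min,
  950 mOsm bolus response 24.8 µL/min).
* `chronic_infusion` — the rodent-scale chronic loading scenario.

The validation data mix species and preparations; no single parameter set
can satisfy the human and feline scales simultaneously, which is why the
sets are separate.  Anchor weights are fixed design choices reflecting
provenance: the ventricular series (29 animals) and the regression
sensitivities carry the most weight in the feline set; in the chronic set
the 15-day dextran row — the protocol the simulation actually replicates —
carries the calibration, with the other-study rows (different agents,
molecular weights and imaging) as weak shape constraints.

## Design choices where the source material is open

* **Arc endpoints.**  The eight compartments and the labels of the twelve
  arcs are stated, but endpoints are not listed arc-by-arc; the assignment
  used here (see `build_canonical_network()`) follows the network figure's
  caption prose and is fixed as the reference topology.  Alternative
  topologies load via configuration.
* **Temperature** is fixed at 310.15 K (body temperature; not stated in
  the source material), and the gas constant is expressed in
  L·mmHg·mmol⁻¹·K⁻¹.  The Henry's-law constant is taken as
  0.03 mmol·L⁻¹·mmHg⁻¹, the standard physiological value (a printed unit
  of mmol/mL/mmHg appears to be a typo).
* **Membrane solute transport** is purely convective ((1−σ) solvent drag)
  plus the optional pump terms; no separate diffusive permeability is
  modeled because no such parameter is given.  Tracers are species like
  any other: the perfusion dye (iodinated albumin) has σ = 1 on membranes,
  tritiated water σ = 0.
* **Rectified choroidal secretion.**  In the feline and canine
  configurations the choroid-plexus arc is one-way (secretion only).  The
  choroid plexus is a secretory epithelium driven by active transport, and
  the slow-perfusion serum series shows flow pinned near zero (0.9 µL/min
  at 1110 mOsm serum) rather than reversing — a two-way Starling arc at a
  fitted conductance would instead predict large absorption.  The
  canonical topology leaves `J7` two-way by default; rectification is a
  per-configuration choice.
* **Per-species reflection coefficients at the choroidal barrier.**  The
  feline calibration requires the effective osmotic coupling of the
  choroidal epithelium to differ by species: near-blind to small ions
  (σ ≈ 0.01; carrier-mediated equilibration), intermediate for sucrose
  (σ ≈ 0.2, fitted), full for the impermeant mannitol/dextran class.
  This is what reconciles, within one parameter set, the ventricular
  sensitivity (0.231 µL/min per mOsm), the serum sensitivity (0.835), the
  flow arrests at 6 mOsm (ventricular) and 360 mOsm (serum), and the
  780 mOsm response: with uniform σ the ventricular mixing feedback
  mathematically caps the serum sensitivity near 0.3 µL/min per mOsm.
  A corollary is that the simulated serum response is asymmetric — strong
  for impermeant loading, weak for dilution — so the hypo-osmolar serum
  rows are fitted only loosely.
* **Chronic-infusion mechanics.**  Ventricular enlargement in a
  pressure-closure model requires a sustained pressure rise.  In the
  chronic configuration the infused dextran (reflected at the ependyma)
  drives an osmotic recirculation loop ventricle → SAS → PVS → ECS →
  ventricle whose extra aqueduct throughput raises ventricular pressure,
  and the volume follows the compliance.  The model therefore equilibrates
  within hours at the enlarged volume; the slow month-scale creep seen in
  vivo involves tissue mechanics outside this model's scope (poroelastic
  parenchyma is a non-goal), so rows at different durations are fitted by
  the same equilibrium value.
* **Problem sizes.**  Tests and the reproduction script run the shipped
  calibrations at modest optimizer settings (single damped descent from
  the curated configurations, ≤ 12–15 iterations) and grids of 3–5
  osmolarities; the estimator-validity property uses 50 randomized
  parameterizations.  These sizes were chosen to characterize the model
  well while keeping a full reproduction run in the minutes range on one
  CPU.

## What the synthetic scenarios do and do not show

The shipped configurations emulate the published *operating points* —
flows, sensitivities, arrests, volume changes — under idealized well-mixed
compartments, fixed boundary compositions, and steady perfusion.  They do
not emulate pulsatile hemodynamics, spatial gradients within compartments,
anesthesia or preparation artifacts, measurement noise, or inter-animal
variability.  Passing the acceptance properties therefore shows that the
network model plus calibration can *jointly realize* the published values
and that the tracer-dilution estimator is internally consistent; it does
not validate the model against raw animal data, which are not
independently reproducible from the published summaries.

## Known limitations

* The serum dose–response is asymmetric around control (see above); the
  hypo-osmolar serum anchors (290 mOsm → 49.9 µL/min; the 60 mOsm row)
  are underpredicted.
* The slow-perfusion control row (12.6 µL/min perfusion → 12.6 µL/min
  nascent flow) is overpredicted by the feline set; it comes from a
  different preparation and carries low weight.
* Chronic-infusion rows at 12 days are overpredicted because the model
  equilibrates fast (no tissue creep).
* Electro-diffusion, carrier kinetics (Michaelis–Menten transport),
  temperature dependence of φ, spinal absorption, and spatially resolved
  transport are out of scope.

## A quick example

```{r example, eval = FALSE}
model <- csf_config("feline_vcp")
ctrl <- run_vcp(model, perfusate_osm = 320, perfusion_rate = 77)
ctrl

dr <- dose_response(model, "ventricle", osm_grid = c(6, 150, 320, 500, 780))
attr(dr, "local_sensitivity")
autoplot(dr)
```
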