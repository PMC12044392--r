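---
title: "Modelling the circulatory life cycle of irreversibly sickled cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the circulatory life cycle of irreversibly sickled cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iscsim)
```

## The model

`iscsim` simulates the ion and water homeostasis of a single red blood
cell driven through a stochastic sequence of oxygenated (arterial) and
deoxygenated (venous) inter-capillary transits. It is built for one
question: how does an ISC-destined stress reticulocyte carrying HbS
evolve, over a 4–7 day circulatory lifespan, through the three-phase
pattern of hyperdense collapse, volume-stable pathogenic state, and
terminal rehydration?

The cell is described by its water volume `Vw` (liters of cell water per
liter of original cells; relative volume 1 is the reference cell) and the
contents of Na⁺, K⁺, the lumped diffusible anion A⁻ = Cl⁻ + HCO₃⁻, total
calcium and total magnesium (all in mmol/Loc). Hemoglobin and an
impermeant pool X (the organic and inorganic phosphates, including the
ATP and 2,3-BPG that buffer magnesium) are conserved. Plasma is an
infinite reservoir. Fluxes are in mmol/Loch (influx positive);
permeabilities in h⁻¹, where 1 h⁻¹ ≈ 2×10⁻⁸ cm/s for the standardized
cell; RT/F = 26.73 mV at 37 °C.

### Operator splitting: slow fluxes, fast equilibria

Membrane transport changes contents over minutes to days; water, proton
and charge relaxation complete in seconds. The integrator therefore
splits the two: contents are advanced explicitly (default 1 s steps,
halved on positivity failure), and after every step the fast equilibria
are re-solved algebraically:

1. **Jacobs–Stewart condition.** The anion exchanger plus the CO₂ shunt
   rapidly equalize the proton and anion concentration ratios across the
   membrane, rH = rA with rA = CAo/CAi and rH = [H⁺]i/[H⁺]o. We treat
   this as instantaneous, which ties the cell pH to the anion
   concentration: pHi = pHo − log₁₀(rA).
2. **Hemoglobin titration (Dalmark line).** nHb = α(pHi − pI) with
   α = −8 Eq/(mol·pH) for HbS, so hemoglobin charge is negative above the
   isoelectric point and slightly positive in the acidified ISC.
   Deoxygenation raises the pI (7.4 for deoxy-HbS at 37 °C), which is the
   physiological link between oxygen transitions and the whole cascade.
3. **Electroneutrality** with the fixed charge `nX` on the impermeant
   pool, and **osmotic equality** including the hemoglobin osmotic
   coefficient fHb = 1 + b1·CHb + b2·CHb², the colloid-osmotic
   nonlinearity that ultimately floors the collapse.

These three conditions determine (pHi, Vw, QA) jointly at fixed cation
and divalent contents; the solver nests two monotone scalar root solves
(Brent) and is idempotent to 1e−10. The membrane potential is then
solved from zero net current over the Goldman leak currents plus the
electrogenic pumps, with warm-started brackets. With the anion
permeability dominant, Em tracks the anion Nernst potential EA within
~1 mV, the familiar anion-dominated limit.

### Transport pathways

* **Ground leaks**: constant-field (Goldman) electrodiffusion for Na⁺,
  K⁺, A⁻ and Ca²⁺. The Na⁺/K⁺/Ca²⁺ ground permeabilities are not free:
  they are back-computed at construction so that leaks exactly cancel the
  configured pump fluxes in the reference state (pump-leak construction).
  This guarantees a true steady start, so everything that happens
  afterwards is attributable to PIEZO1.
* **PIEZO1**: deoxygenation of HbS is treated as necessary and
  sufficient to open the channel and to block its spontaneous
  inactivation; reoxygenation restores it instantly. The open channel
  adds poorly selective Goldman permeabilities for Ca²⁺, Mg²⁺, Na⁺, K⁺
  and A⁻, scaled by a per-transit random amplitude factor.
* **Na/K pump**: 3:2 stoichiometry (electrogenic), cubic intracellular
  Na site whose apparent affinity is competitively inhibited by
  intracellular K (`KmNa·(1 + CK/KiK)`), and a Mg²⁺ activation factor
  with half-activation at 50 µmol/Lcw. The K-inhibition term is the
  load-bearing choice: phase 2 requires pump activity to *rise* as the
  cell loses K, and the pump to be maximally responsive to Na once the
  cell is K-depleted.
* **PMCA**: Michaelis extrusion, capacity 36 mmol/Loch. We treat the
  pump as fully electrogenic, i.e. its 2+ charge flux enters the
  zero-current equation. This is a deliberate simplification: with an
  electroneutral Ca pump the reference state cannot satisfy per-species
  zero flux and zero membrane current simultaneously without explicit
  proton bookkeeping; the electrogenic form closes the system exactly
  (Em_ref = EA) and its steady-state current is small.
* **Gardos channel (KCNN4)**: Hill-activated K⁺ permeability
  (coefficient 2), driving KCl and water loss whenever deoxy-PIEZO1
  calcium influx raises [Ca²⁺]i above the resting trace level.
* **K:Cl cotransport** (off by default): electroneutral product-gradient
  form. It cannot be pump-leak balanced at the reference state (the
  anion permeability is a fixed configuration entry), so it is enabled
  as a runtime pathway change. At a reticulocyte-scale rate (0.02 h⁻¹,
  ~1.5 mmol/Loch at reference) it moves the collapse time by less than
  the seed-to-seed spread (under 10%) and leaves the phase-2 state
  unchanged, which is why it is excluded from the default ISC model.

Free calcium uses a linear buffer (`ca_buffer_ratio`), free magnesium a
1:1 mass-action system against ATP and 2,3-BPG whose effective
dissociation constants rise on deoxygenation (deoxy-Hb sequesters both
buffers, releasing Mg²⁺ during venous transits).

## The circulation generator

The synthetic input is a seeded, alternating schedule of transits:
durations uniform on [30, 60] s (oxy) and [30, 90] s (deoxy), and
per-deoxy-transit PIEZO1 amplitude factors uniform on [0.25, 1.75]
(mean 1, so amplitudes scale the configured mean permeabilities). These
bounds are not experimental measurements — the experimental record
establishes that the deoxy response varies stochastically over wide
bounds, not any particular distribution family — so they are
configuration, chosen bounded and mean-preserving. Lingering episodes (cells trapped in venules) are
40-minute deoxy stays replacing the deoxy transit in progress at their
scheduled times (0.5, ~1.1 and 3.5 days in the typical protocol). A
single global seed feeds two substreams (durations, amplitudes) so
either randomness source can be frozen independently. What the generator
does *not* emulate: oxygen-tension continua (transits are binary
oxy/deoxy), spatial vascular structure, and cell-to-cell variation in
channel density — so a passing suite says the *mechanism* reproduces the
reported trajectories under the stated circulation statistics, not that
these statistics describe any particular patient.

## The reference state and its calibration knobs

The reference is a macrocytic stress reticulocyte in an oxygenated
steady state: plasma 140/5/125 mmol/L Na/K/A at pHo 7.40 and
290 mOsm/L; cell Na 10, K 130 mmol/Lcw at pHi 7.2; water volume
0.85 Lcw/Loc; hemoglobin 3.5 mmol/Loc (about 70% of a normal MCH — ISCs
carry the lowest Hb contents among sickle subtypes), giving a reference
hemoglobin osmotic contribution of ~7 mOsmol/Lcw with the standard
virial coefficients b1 = 0.0645 Lcw/mmol, b2 = 0.0258 (Lcw/mmol)². Pump
turnovers are reticulocyte-grade: Na pump flux 26 mmol/Loch (~10× mature
cells) and PMCA capacity 36 mmol/Loch (~40× mature). The amount and
fixed charge of X close the osmotic and charge balances (nX ≈ −0.65 per
mmol), and the mean deoxy-PIEZO1 Ca²⁺ permeability is set to 10× the
reference PMCA flux — the pump-leak ratio below which no hyperdense
collapse materializes within ~1.5 days.

Constants that the published record does not pin down numerically were
calibrated once, by simulation, against the reported trajectory
signatures, and then frozen as package defaults:

* `pI_oxy = 6.7`. The deoxy pI is printed (7.4); the oxy value is not.
  6.7 jointly reproduces the pH trajectory (dip ~6.3–6.4, phase-2 mean
  ~6.7–6.8, oscillation span ~6.45–6.98) and a slightly positive mean Hb
  charge in phase 2. The implied initial Hb charge concentration
  (~−17 mEq/Lcw) is somewhat smaller in magnitude than the reported
  ~−20: the linear titration line cannot satisfy every reported anchor
  at once, and we prioritized the pH trajectory.
* `KmCa = 0.7 µmol/Lcw`, resting [Ca²⁺]i 0.05 µmol/Lcw: reference PMCA
  flux 2.4 mmol/Loch with a 15-fold capacity reserve, so calcium loaded
  during a deoxy transit is cleared within a couple of minutes of
  reoxygenation.
* `ca_buffer_ratio = 8e−4`: the effective free fraction of cytosolic
  calcium. It sets the relaxation time of [Ca²⁺]i (~1 min) and thereby
  paces the cumulative calcium loading of phase 1; the hyperdense
  collapse completes in ~0.5–0.8 days, within the day-scale window in
  which circulating ISCs are observed to reach the hyperdense state.
* Gardos `PKmax = 1.8 h⁻¹`, `K05Ca = 2 µmol/Lcw` (hill 2): per-transit
  free-calcium excursions sweep through the activation range, so
  dehydration accelerates as hyperpolarization builds instead of
  saturating at the first transit. The half-activation sits in the
  flux-measurement range for KCNN4 rather than the lower patch-clamp
  range; with a sub-µM midpoint the channel saturates immediately and
  the cell collapses in minutes, which the circulatory record excludes.
* Na pump `KmNa = 4`, `KiK = 70 mmol/Lcw`: reference flux 26 at
  Na 10/K 130, and a phase-2 oscillation envelope reaching about
  −50 mmol/Loch.
* Inhibition step: factor 0.04 at day 4. Neither the time nor the
  kinetics of the terminal Na-pump decline is experimentally known, so
  a single sudden step at a configurable time is the simplest
  representation; both are protocol knobs, and the default factor is
  calibrated so the settled phase-3 pump flux is
  ~−10 mmol/Loch, against measured phase-3 fluxes of −7 to −9.

## Phase detection and summary statistics

All statistics are computed on per-transit summaries (duration-weighted
means and extrema accumulated during integration), smoothed over one
full oxy+deoxy cycle to suppress oscillation aliasing.

* **Trough**: phase 2 is a nearly flat 3-day plateau, so a global argmin
  of the smoothed volume is ill-posed (it lands anywhere in the
  plateau's stochastic wander). The trough is instead the *knee* ending
  the steep phase-1 descent: the first entry of a 9-cycle rolling median
  of the cycle-mean volume into a band 20% (of the total drop) above the
  plateau floor. This makes the trough time insensitive (<10%) to
  inserting lingering episodes, matching their observed near-invariance
  of the overall dehydration trend.
* **Phase-2 drift** is the systematic trend (regression slope times
  phase length) of the smoothed volume, excluding a 3 h settling window
  after the trough; stochastic wander is reported separately as the
  5–95% spread of cycle means. The trend is the quantity that phase-2
  stability constrains (<2%); the wander reflects amplitude clustering
  in the random schedule and is several percent.
* **Pump envelope**: 5th percentile of per-transit minima (deoxy
  transits) and 95th percentile of per-transit maxima of the Na-pump
  flux over phase 2, matching how oscillation bounds read off a plotted
  trace.
* **Hemoglobin osmotic contribution at the trough**: the maximum of the
  instantaneous fHb·CHb trace before the inhibition event — i.e. its
  value at the deepest momentary dehydration, which is what the peak of
  a plotted trace shows; cycle-averaging would smooth the oscillation
  peaks away.
* **pH dip**: minimum transit-averaged pHi over the first 1.5 days.
* **ATP turnover**: time-averaged |JNa_pump|/3 + |JCa_pump| (one ATP per
  pump cycle) over phase 2, relative to a mature red cell baseline
  defined by the nominal reference rates divided by 10 (Na) and 40 (Ca).

## Numerical choices and degenerate inputs

Explicit first-order stepping at dt = 1 s during transits (the fast
equilibria being re-solved exactly each step), with a Heun
(trapezoidal) corrector for the calcium content alone — free calcium
relaxes on a ~1 min timescale, the one stiff species at this step size —
converges to well under 0.1% per simulated minute against a 10× finer
step; steps are halved (to
dt/1024) when an update would drive a content negative, then abort with
a time-stamped error. The pHi root is bracketed adaptively around the
previous solution and widened on failure; anion depletion (CA → 0) and
osmotically infeasible configurations (CA approaching total osmolarity)
produce explicit diagnostics rather than silent clamping. Output is
thinned to one record per minute plus every transit boundary, keeping a
5-day CSV under ~20k rows while per-transit extrema are accumulated at
full resolution inside the integrator. A 5-day run covers ~8,000
transits (~430,000 steps) and takes on the order of 15 s on one CPU;
scans and the acceptance script run three to ten such simulations.

## Known limitations

* HbS polymerization kinetics, delay times, and any polymer-permeability
  coupling are outside the model: deoxygenation is the sole PIEZO1
  trigger, regardless of HbS concentration or state.
* Vacuolar/organelle calcium accumulation is neglected; total cell
  calcium here is cytosolic-buffered only, so long-run total-Ca
  trajectories underestimate the accumulation seen in ISC vacuoles.
* Cl⁻ and HCO₃⁻ are lumped into one diffusible anion; no explicit
  carbonic anhydrase or CO₂ kinetics.
* The X pool's charge is pH-independent (fitted at reference);
  titratable phosphates would soften the pH excursions slightly.
* The linear Dalmark titration with a single oxy/deoxy pI pair cannot
  reproduce every reported charge anchor simultaneously (see the pI_oxy
  note above).
* ATP is assumed adequate throughout (the stress-reticulocyte condition
  persists); the terminal pump decline is imposed, not emergent from a
  metabolic model.
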