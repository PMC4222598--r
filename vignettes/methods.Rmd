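---
title: "Models and methods: ventricular fibrillation under global ischemia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: ventricular fibrillation under global ischemia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ischvf)
```

## Scope

`ischvf` simulates human ventricular electrophysiology under the three
electrophysiological components of acute global ischemia — hyperkalemia,
acidosis and hypoxia — and analyses what they do to fibrillation: action
potential duration (APD) and conduction velocity (CV) restitution, the
stability of re-entrant spiral waves, the dominant frequency (DF) of
fibrillatory activity, and, in the inverse direction, the estimation of
extracellular potassium and ATP-sensitive channel activation from clinical
style DF recordings. Everything runs at desk scale on one CPU; the
synthetic-data generators produce every input the pipeline needs, with
ground truth attached.

## The cell model

Membrane kinetics follow the ten Tusscher–Panfilov 2006 (TP06) human
ventricular epicardial model: 12 Hodgkin–Huxley gates, intracellular
sodium/potassium/calcium dynamics with subspace and sarcoplasmic-reticulum
compartments, and the standard current set (fast sodium, L-type calcium,
transient outward, rapid and slow delayed rectifiers, inward rectifier,
sodium–calcium exchanger, sodium–potassium pump, plateau and background
currents). The transcription was validated against the model's canonical
fingerprints: resting potential −86.2 mV, APD90 ≈ 306 ms at 1 Hz, peak
upstroke velocity ≈ 290 mV/ms, and a plane-wave CV of ≈ 71 cm/s at the
standard diffusion settings (see below).

### Restitution-slope presets

`tp06_params(slope = )` exposes the base model's three named parameter
sets, labelled by the maximal S1S2 APD-restitution slope they produce
under normal conditions. The five varied parameters are `GKr`, `GKs`,
`GpCa`, `GpK` and the plateau scaling of the f-gate time constant. The
published default values (`GKr` 0.153, `GKs` 0.392, `GpCa` 0.1238, `GpK`
0.0146) are the steep, breakup-capable set (label 1.8); the flatter
variants raise the sarcolemmal calcium pump and reduce the plateau
potassium current (`1.4`: `GpCa` 0.3714, `GpK` 0.0073; `1.1`: `GpCa`
0.8666, `GpK` 0.00219 with the f-gate time constant halved for V > 0).
Measured in this package's S1S2 harness (with the 5 ms refinement
resolving both sides of conduction block) the three presets give maximal
slopes of 0.98, 1.43 and 1.80 — strictly ordered and on their nominal
labels; slope measurements remain protocol-sensitive (conditioning
length, stimulus geometry, measurement position, foot sampling).

### The ATP-sensitive potassium current

Hypoxia opens ATP-sensitive potassium channels. The package models the
resulting current with a conductance formulation of the Shaw–Rudy /
Ferrero lineage — a power dependence on extracellular potassium, an
exponential voltage factor, and a driving term referenced to the
potassium Nernst potential:

$$ I_{KATP} \;=\; g_0\, f_{ATP}\, \left(\frac{[K^+]_o}{5.4}\right)^{0.3}
   \frac{V - E_K}{40 + 3.5\,e^{0.025 V}} $$

with `f_atp` in percent of open channels. The scaling coefficient $g_0$
is calibrated, not copied: `calibrate_g0()` solves (by bracketed root
finding on re-simulated APDs, relative tolerance $10^{-3}$) for the $g_0$
at which 0.05 % open channels exactly halve the steady-state APD90 at
1 Hz. The shipped default, $g_0 = 16.713$ per percent, is the output of
that calibration for the base parameter set; the calibration is itself
re-run and re-checked in the acceptance suite. With this calibration the
estimated open fractions in inverse fits come out in the 0.01–0.15 %
range, matching the scale on which such fits are reported.

### Ischemia parameterization

`ischemia(Ko, acidosis, f_atp)` carries the three knobs: extracellular
potassium in 5–12 mM (hyperkalemia; enters the Nernst potentials, the
$\sqrt{K_o}$ scaling of the inward and rapid delayed rectifiers, the
pump, and $I_{KATP}$); a 0.2–1.0 multiplier on `GNa` and `GCaL`
(acidosis); and the open percentage of ATP channels (hypoxia). Values
outside the modeled ranges warn but are retained — clamping is never
silent. In tissue runs the three parameters can be ramped linearly over a
configurable window (default 500 ms, within the 200–800 ms range typical
for gradual-onset protocols).

## Tissue model and numerics

Tissue is the isotropic monodomain equation on 1D cables and 2D sheets,
$\partial_t V = D \nabla^2 V - I_{ion}/C_m$, discretized with the 3-point
(1D) or 5-point (2D) Laplacian at `dx` = 0.25 mm and explicit Euler time
stepping at `dt` = 0.02 ms. Gating variables integrate with the
Rush–Larsen exponential scheme; voltage-only rate functions are served
from pre-computed look-up tables (0.01 mV step, linear interpolation,
verified to reproduce direct evaluation to better than $10^{-6}$
relative). No-flux boundaries are realized by cell-centred mirror ghost
nodes, the choice that makes the discrete operator exactly conservative
(its sum over nodes is zero to machine precision). An instability guard
aborts if any node's voltage moves more than 10 mV in one step — above
the fastest physiological upstroke (≈ 6 mV per step at `dt` = 0.02 ms)
but triggered immediately by numerical blow-up. The diffusion stability
bound `dt < dx²/(2 d D)` is enforced as a precondition.

With `D` = 1.54 cm²/s this discretization propagates a 1 Hz plane wave
at 70.6 cm/s (the continuum value for the model is ≈ 75 cm/s; a
5 % discretization slowdown at 0.25 mm is expected, and refining `dx`
recovers it). CV measurements use the maximum-upstroke-velocity time at
two probes, with parabolic refinement of the discrete derivative peak.

## Protocols

**S1S2 restitution** (`s1s2_apd_restitution()`, `cv_dispersion()`): ten
S1 stimuli at BCL 1000 ms along one short edge of a thin strip, one S2 at
a coupling interval decremented from 1000 ms in 20 ms steps with 5 ms
refinement near conduction block; APD90 and the diastolic interval are
measured 2.5 cm from the stimulated edge, CV between probes bracketing
that site. The conditioning train runs once and is checkpointed right
after the last S1, so each S2 replays from the same state. The strip is
pseudo-1D (1–3 nodes wide) — exactly equivalent to a wider sheet for
plane waves, which the tests verify.

**Spiral initiation** (`init_spiral_crossfield()`): S1 plane wave from
the left edge; after `s2_delay` an S2 covering the quarter of the sheet
behind the front and below the midline. Inside the vulnerable window the
broken S2 end curls into a single spiral (verified by a phase-singularity
count of one); `scan_s2_delay()` automates the window search.

## Desk-scale fibrillation surrogate

The human-heart wavelength of this model (CV × APD ≈ 14 cm) means
sustained re-entry simply does not fit on a centimetre-scale sheet at the
full diffusion coefficient — re-entry initiated on such sheets
extinguishes within a rotation. The package's fibrillation surrogate
(`gen_vf_fixture()`) therefore compresses the wavelength by reducing the
diffusion coefficient to `D` = 0.25 cm²/s (wavelength scales as
$\sqrt{D}$, giving ≈ 5.6 cm) on a 4.5 × 4.5 cm sheet with the steep
(slope-1.8) preset. A cross-field S1S2 at `s2_delay` = 360 ms initiates
one spiral which breaks into a multi-wave state (3+ phase singularities)
within ~2 s; the developed state at ~2.8 s is the saved initial
condition for fibrillation studies, and its own development-phase probe
recording doubles as the normal-conditions dominant-period reference
(~218 ms, stable across analysis windows). All single-cell and restitution
quantities keep the full `D` = 1.54 cm²/s; only the 2D fibrillation
surrogate is wavelength-compressed, and its comparisons (period shifts
under ischemia components) are relative, within the same scaled system.

Dominant periods are measured from 100 probe nodes on a regular
sublattice, sampled every 2 ms, over the last 1.5–2 s of each run:
per-probe periodogram (linear detrend, split-cosine taper, 8× zero
padding) via `stats::spec.pgram`, median across probes, largest peak in
0.5–15 Hz. Quiescence (all probes below a 10 mV peak-to-peak floor) is
signalled as `NA` with an attribute, never guessed.

## Phase analysis

Activation phase uses delay embedding,
$\theta = \mathrm{atan2}(V(t-\tau) - V^*,\; V(t) - V^*)$ with $\tau$ =
10 ms and $V^*$ = −40 mV (the phase computation itself is a
package-level choice; delay embedding is the standard optical-mapping
practice). Phase singularities are plaquette winding numbers: the sum of
wrapped phase differences around each 2 × 2 loop, ±2π marking a
singularity of that chirality, merged within 2 grid units. The detector
is verified against a brute-force contour-integration oracle and against
planted-vortex fields whose ground truth the generator carries.
Wavefronts are 8-connected components of the depolarizing excited set
(V > −40 mV and rising).

## The period surface and the inverse problem

`build_period_surface()` maps (K_o, f_ATP) to the fibrillation period by
direct simulation from the saved fixture (ramp, run, periodogram), with
terminated runs recorded as missing and the result projected onto the
monotone cone (non-decreasing in K_o, non-increasing in f_ATP) by
alternating isotonic regression — the monotone contract that the inverse
procedure needs. Because a full simulated surface is a cluster-scale
object, the package also ships `reference_period_surface()`: a synthetic
parametric surface (baseline 185 ms; period rising ~60 ms across the
hyperkalemic range; hypoxia shortening saturating and attenuated at high
K_o) used as the invertible forward model in tests and inverse-fit
studies. It emulates the direction and magnitude of the simulated
surface, not any particular simulation — it is labelled synthetic in its
metadata.

The inverse procedure takes a DF recording with landmarks A (30 s,
ischemia onset), B (180 s, ischemia end) and C (210 s, end of
reperfusion recording):

1. **Scaling.** All surface periods are multiplied by
   $s = T_{patient}(\text{anchor}) / T_{surface}(K_o = 5.4, f = 0)$. The
   regular fit anchors at point A; the alternative fit anchors at the
   start of the recording, attributing the perfused-phase DF rise to ATP
   channels already opening (`f_A` solved from the DF at A).
2. **Three-point fit.** Assuming potassium has washed out by C while the
   ATP channels have recovered only a fraction $r \in \{0, 0.25, 0.5\}$:
   solve $T_s(5.4, f_C) = 1/DF_C$ for $f_C$ by monotone bisection, set
   $f_B = f_C/(1-r)$, then solve $T_s(K_B, f_B) = 1/DF_B$. Landmark DFs
   average a ±2 s window. Out-of-range targets clamp to the surface
   boundary with a warning flag.
3. **Trajectory fit.** On [A, B] the chain rule
   $dT/dt = \partial_K T\,\dot K + \partial_f T\,\dot f$ is closed with
   the equal-relative-approach constraint
   $\dot K/(K_B - K + \epsilon) = \dot f/(f_B - f + \epsilon)$
   ($\epsilon = 10^{-3}$), which drives both components monotonically
   toward their point-B values. Rates are clamped at zero (monotonicity);
   clamped steps are counted and more than 10 % of them raises a quality
   flag. The closure is an interpretation — it satisfies the stated
   purpose (reach the point-B values monotonically) but has no
   mechanistic basis, and the implementation keeps it isolated so other
   closures can be substituted.

Surface interpolation is monotone piecewise-cubic (Fritsch–Carlson) per
axis, tensored in two stages; partial derivatives are central differences
of the interpolant (step $10^{-4}$ of the axis range), numerically
indistinguishable from analytic derivatives at the fit's tolerances.

## Synthetic patients

`synthetic_patient_spec()` / `gen_df_recording()` emulate the clinical
recording structure: 30 s perfused fibrillation, 150 s ischemia with
saturating-exponential monotone rises normalized to hit $(K_B, f_B)$
exactly at 180 s (default time constants 60 s, consistent with reported
potassium accumulation rates of 0.5–1 mM/min), then 30 s reperfusion
with fast potassium washout (τ = 8 s) and slow, possibly partial ATP
channel recovery. DF samples at 1 Hz carry i.i.d. Gaussian noise
(default sd 0.1 Hz) standing in for inter-electrode spread; every
recording carries its ground truth. What the generator does *not*
emulate: electrogram waveforms, electrode geometry, spatially correlated
noise, or non-monotone ischemia time courses — so passing inverse-fit
tests shows the estimator is correct *given the model class*, not that
the model class captures every clinical recording.

## Numerical and design choices, compactly

- `dt` = 0.02 ms (halving it moves APD90 by < 1 %), `dx` = 0.25 mm,
  look-up table step 0.01 mV.
- Stimulus convention −52 pA/pF for 1 ms (≈ 2× threshold); S1 edge strip
  1 mm deep.
- APD measured to 90 % repolarization (level exposed), upstroke at
  maximum dV/dt, resting potential taken just before the upstroke.
- S2 decrement schedule 20 ms coarse / 5 ms fine near block — chosen for
  curve resolution, not prescribed by any source.
- Nernst/reversal potentials refreshed every 10 steps (0.2 ms) — the
  concentrations they depend on drift far more slowly.
- Problem sizes for the shipped studies: 5–6 cm cables/strips for CV and
  restitution; 4.5 cm sheet, 2.2 s continuation runs, last 1.5 s
  analysed for the fibrillation surrogate; 20-patient synthetic cohorts
  for inverse-fit validation. These are the package's desk-scale study
  conditions, chosen once so the full suite runs on a single CPU.

## Known limitations

- Epicardial cell type only; no transmural heterogeneity, no Purkinje
  system, no bidomain effects, no mechanics, no gap-junction uncoupling —
  consistent with the first-minutes-of-ischemia regime the model targets.
- `f_atp` is an exogenous knob; ATP/ADP metabolism is not modeled.
- The fibrillation surrogate is wavelength-compressed 2D, not an
  anatomical ventricle: phase-singularity counts stand in for 3D filament
  counts qualitatively, and absolute periods at desk scale differ from
  organ-scale values (relative comparisons are the meaningful output).
- At desk scale the re-entry period is *circulation-limited* — set by
  pathlength over conduction velocity in a domain of about one wavelength
  — rather than refractoriness-limited as at organ scale. Interventions
  that mostly change CV therefore move the desk-scale period more than
  they would the organ-scale one: severe acidosis (conductances at 20 %,
  roughly halving CV) either extinguishes the surrogate's activity within
  about a second or leaves a single slow crawling wave whose period is
  several times the normal one, where the organ-scale expectation is
  near-invariance. The package measures such runs honestly
  over the window in which activity existed
  (`dominant_period(end_at_quiescence = TRUE)`) and records terminations
  as missing values, never silently interpolated.
- Under severe acidosis the site-measured restitution curve develops a
  steep electrotonic foot: near block, the decrementally conducting
  premature wave's upstroke and APD recover with diastolic interval
  faster than the cell-intrinsic restitution, so the maximal measured
  slope is conduction-coupled rather than cellular. The curve as a whole
  is still compressed (flattened in the large), and reversed-branch
  points (site DI not decreasing with the coupling interval) are
  excluded from curves and counted in their metadata.
- The model does not reproduce supernormal conduction (a CV rise at
  mildly elevated potassium before the decline): measured CV here falls
  monotonically with K_o at 1 Hz and across the S1S2 dispersion range.
  The supernormality reported for this class of models appears to be
  protocol- and formulation-sensitive; the package documents the
  discrepancy rather than tuning for it.
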