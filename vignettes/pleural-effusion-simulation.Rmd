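---
title: "Simulating large pleural effusion and therapeutic thoracentesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating large pleural effusion and therapeutic thoracentesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleurasim)
```

## The problem

A large unilateral pleural effusion compresses the lung above it, pushes
the hemidiaphragm into the abdomen (sometimes inverting it), shifts the
mediastinum toward the healthy side and stresses the rib cage.  During
stepwise therapeutic drainage, pleural manometry and spirometry show a
family of behaviours that are hard to explain from measurements alone:
pressure-volume (Ppl-V) loops that lean left or right or cross themselves
in a figure of eight, pleural pressure amplitudes that *fall* before they
rise, and arterial blood gases that barely react to the removal of litres
of fluid.  `pleurasim` implements a lumped-parameter virtual patient in
which every internal variable is observable, so such mechanisms can be
isolated and probed.

## Mechanical model

Each lung is a stack of `n_layers` horizontal layers (default 100) in a
prismatic hemithorax of capacity `hemithorax_cap` and height
`lung_height`.  Pleural fluid of volume $V_{pf}$ fills the dependent part
of the ipsilateral pleural space; its surface lies at
$V_{pf}/A$ cm above the base ($A$ the prism cross-section).  Pleural
pressure is referenced at the lung apex and rises hydrostatically below
the fluid surface, 0.0981 kPa per cm of fluid of density 1 kg/L.

Gas moves from the mouth through a tracheal resistance, per-side main
bronchi, and per-layer peripheral airways into the layers.  Node pressures
are eliminated algebraically, so flow continuity at the carina and at each
bronchial node holds to machine precision at every solver evaluation.
Mid-order bronchi are collapsible: when the local pleural pressure exceeds
the feeding bronchial pressure the peripheral resistance rises linearly
with the compression (gain `beta_aw`, capped at `beta_cap`-fold).

Constitutive laws:

* **Lung layer recoil** $P_{el}(V) = -\frac{1}{k}\log(1 - V/V_{max})$ per
  layer, i.e. an exponential pressure-volume characteristic that stiffens
  toward capacity.  This nonlinearity is what forces the contralateral
  lung onto a flat part of its compliance curve when it must accommodate
  the whole tidal volume, one of the two amplitude mechanisms below.
* **Rib cage**: Kelvin-Voigt (spring `C_rc` + dashpot `R_rc`), driven by
  the mean of the two mid-thorax pleural pressures plus the rib-cage
  share of the muscle drive.  A compliance below `1e-4` L/kPa is treated
  as rigid (the state is pinned to zero rather than integrating a
  microsecond time constant).
* **Mediastinum**: purely elastic, $V_{med} = C_{med}\,(P_{pl,i} -
  P_{pl,c})$, displacement positive toward the contralateral side.  This
  single parameter controls how much of a breathing swing in one
  hemithorax is transmitted to the other.
* **Hemidiaphragms**: massless elastic membranes
  ($C_{di}$ each) loaded by the pleural pressure at diaphragm level
  (including the full fluid column on the effusion side), the abdominal
  pressure, and the active muscle pressure.
* **Abdomen**: a purely elastic shared compartment; its pressure rises
  with the summed caudal diaphragm displacements,
  $P_{ab} = (x_i + x_c)/C_{ab}$.  The dashpot parameter `R_ab` is
  retained in the interface but does not enter the quasi-static chain —
  its contribution at breathing rates is of order 0.01 kPa and would turn
  the chest-wall algebra into an implicit DAE.

At every evaluation the chest-wall unknowns (two apical pleural
pressures, abdominal pressure, diaphragm displacements, mediastinal
shift) are solved from a linear 3-by-3 system under the hemithorax
content constraints; the diaphragm force-length factor is refreshed by
two Picard passes, which suffices because displacement changes per solver
step are tiny.

### Muscle driver and paradoxical diaphragm action

Breathing is driven by a half-sinusoid active pressure over the
inspiratory fraction `Ti_frac` of each cycle (expiration is passive), a
standard respiratory-mechanics driver.  The neural amplitude is shared by
both hemidiaphragms; rib-cage muscles contribute the fraction
`rc_mus_frac`.  The pressure each hemidiaphragm actually transmits is
scaled by a *signed* effectiveness, linear in its caudal displacement:
+1 at or above resting length, zero at `di_eps_zero` L of caudal
displacement, saturating at `di_eps_floor` (default −0.3) when fully
inverted.  The negative branch matters: a flattened, inverted
hemidiaphragm that contracts pulls itself *up*, raising rather than
lowering ipsilateral pleural pressure.  That paradoxical action — weakly
opposed through a stiff mediastinum, easily overridden through a
compliant one — is what makes loop lean depend on mediastinal compliance,
and a magnitude-only force-length factor cannot produce functional
inversion.  The floor is deliberately moderate: the figure-eight loop
requires the early-inspiratory pressure *dip* (rib-cage muscles plus the
transmitted contralateral action) to be overtaken mid-breath by the
lagged abdominal push of contralateral lung filling together with the
paradoxical pull; a strong floor (−0.6 and beyond) turns the loop into a
simple left-leaning lens with no crossing, and the crossing that a 25 Hz
grid then still reports is a chord-sampling artifact — which is why loop
geometry inside the package is classified on a 10 ms grid.

The drive controller (`adapt_drive_to_vt()`) rescales the amplitude by
the damped ratio of target to achieved tidal volume until the simulated
VT is within 2% of `VT_target`, mimicking chemoreflex defence of
alveolar ventilation.  It is a deterministic fixed-point iteration; with
an effusion in place the converged amplitude is always larger than at
baseline.

### Recruitment and derecruitment

A layer collapses when its feeding bronchial pressure falls below the
local pleural pressure (beyond `P_close`) *and* its gas has actually been
squeezed down to the trapped volume (`trapped_frac` of layer capacity);
it reopens when the feeding pressure exceeds local pleural pressure by
`P_open`.  The interval `P_open > P_close` is a genuine hysteresis, so
flags cannot chatter.  The volume gate matters: without it, a wash-in
transient can close an apical layer that still holds most of its gas and
the hysteresis then keeps it closed forever.  Closed layers hold their
trapped gas, are excluded from the airflow network, and re-enter it at
the trapped volume when recruited.

### Numerics

The state (per-layer gas volumes plus the rib-cage volume) is integrated
with fixed-step classical RK4.  The default step is 5 ms: the fastest
network time constants (peripheral resistance times local layer
compliance) are tens to hundreds of ms, and halving the step to 1 ms
changes FRC, VT and pressure amplitude by well under 0.1%.  Fixed-step
integration makes every run bit-reproducible, which the session-level
determinism tests rely on.  Recruitment flags, the lagged bronchial
pressures used by the collapsible-airway law, and the force-length state
are updated once per accepted step.  Simulations discard wash-in breaths
and verify periodicity (tidal volume and end-expiratory volume changing
by <0.5% between the last two breaths), extending the wash-in when
recruitment is still settling.

The initial condition is a relaxed static equilibrium found by damped
fixed-point iteration between layer volumes and the chest-wall balance;
layer volumes are relaxed continuously so that discrete recruitment flips
cannot cycle the iteration.

## Parameters

The defaults describe a generic resting adult: per-lung FRC ≈ 1.18 L
(total ≈ 2.4 L), VT 0.5 L at 12 breaths/min, cardiac output 5 L/min,
room air at 101.3 kPa.  Chest-wall values are the package's own
calibration within textbook ranges: `C_rc` 2 L/kPa (≈0.2 L/cmH2O),
`C_ab` 3 L/kPa, `C_di` 1.2 L/kPa per hemidiaphragm, hemithorax capacity
4 L.  They were chosen once so that a 3 L effusion reproduces the
clinically observed regime this package is built around: dependent
collapse with a *spared, ventilated apical cap*, a hemidiaphragm pushed
about 1 L into the abdomen, and pre-drainage pleural pressures of a few
tenths of a kPa to a couple of kPa.  Stiffer textbook-style chest walls
collapse the whole lung at 3 L, which contradicts that regime.  All
values are config-overridable (`write_patient_config()` /
`read_patient_config()`), so calibration to an individual is data, not
code.

Two named presets bracket the mediastinal behaviour:
`stiff_mediastinum` (`C_med`/5) and `compliant_mediastinum`
(`C_med`×5).

## Gas exchange and perfusion

Gas exchange uses one well-mixed alveolar compartment per lung (layers
contribute through their summed open-layer ventilation and end-expiratory
volume; per-layer gas states would add cost without an observable
counterpart).  Each lung balances fresh-gas delivery at humidified
inspired pressures against perfusion-weighted equilibration with blood;
oxygen is carried by a Hill saturation curve (`P50` 3.55 kPa, exponent
2.7) plus dissolved O2, CO2 by a curve linearised around 40 mmHg.
Arterial blood is mixed in *content* space (contents are conserved;
partial pressures are not) and converted back by inverting the content
curves; the venous return closes the loop through a Fick constraint with
fixed tissue VO2/VCO2.  STPD/BTPS volume corrections are ignored
throughout (a few percent, immaterial for the mechanisms studied).

Perfusion per side falls with the local mid-lung pleural pressure through
a smooth logistic conductance, halving at `perf_P_half` = 0.5 kPa with
width `perf_w` = 0.3 kPa; flow reaching unventilated tissue is shunt.
The three flows always sum exactly to cardiac output.

The "atmospheric" reference for the baseline alveolar O2 offset is the
dry partial pressure FiO2 × P_atm (21.3 kPa); inspired gas inside the
model is humidified (FiO2 × (P_atm − 6.27 kPa)).  Both are reported by
`gas_exchange_steady()`.

## The analysis pipeline

The measurement side mirrors clinical drainage recordings: 25 Hz pleural
pressure and mouth flow in one-minute intervals between aliquots (200 mL
aliquots to 1 L, then 100 mL).  Breaths are delimited at inspiratory
zero-crossings of mouth flow with a ±2%-of-peak hysteresis band; flow is
integrated trapezoidally and re-zeroed per breath; loops are classified
by their end-inspiratory minus end-expiratory pressure (dead band
`epsilon` = 0.05 kPa, configurable — the boundary between "leaning" and
"vertical" is not defined sharply by the physiology) and tested for
self-intersection by exact segment-pair geometry.  End-inspiration is
the volume peak of the breath, not the end of the neural inspiratory
phase: with a half-sinusoid driver the active pressure returns to zero
before the volume peaks, and clinical loop reading uses the volume
extremes.  Pendelluft is quantified as the fraction of samples with
opposite-signed main-bronchial flows beyond a 1%-of-peak dead band (the
dead band suppresses numerical zero chatter).  Trend statistics use OLS
slopes split at 1.9 L withdrawn (the boundary observed between the two
drainage stages); a stage with fewer than two points reports `NA` rather
than failing.

For simulated sessions, loops are built from one representative
steady-state breath per interval; for recorded or synthetic sessions,
per-breath metrics are median-aggregated within each interval.

## The synthetic-signal generator

`synth_spec()`/`gen_session()` emulate the *format and statistics* of the
clinical recordings, not their physiology: a flow fundamental scaled to
VT, a two-harmonic pleural pressure whose phase offset sets the lean and
whose second-harmonic weight induces (or not) a figure-eight, linear
trajectories of interval mean pressure and amplitude in withdrawn volume,
and additive Gaussian noise from a private seeded RNG stream (the global
RNG state is never touched).  The two-harmonic family is the minimal one
producing every loop class the analyzer must distinguish.  What passing
round-trip tests show is that the analyzer recovers known ground truth
under realistic sampling and noise; they say nothing about breath-to-
breath variability, drift, coughs or sensor artefacts, which real
recordings contain and the generator deliberately omits.

## What the standard experiments show

* Mediastinal compliance sweep at 3 L: loop lean moves monotonically from
  left (functional inversion behind a stiff mediastinum) to right
  (contralateral swings transmitted through a compliant one).
* The stiff-mediastinum loop self-intersects: ipsilateral outflow during
  inspiration (paradoxical pressure rise) and inflow during early
  expiration cross the inspiratory and expiratory limbs.
* Gases along drainage: before drainage the ventilated contralateral lung
  runs a roughly doubled fresh-gas ratio and an elevated alveolar O2;
  early aliquots restore ipsilateral perfusion before recruitment
  restores ipsilateral ventilation, so shunt can transiently depress
  arterial O2 — the blunted, non-uniform blood-gas response.
* Amplitude trajectories differ between the presets; under a compliant
  mediastinum the large contralateral swings required to hold VT are
  transmitted to the ipsilateral side and the amplitude falls as
  recruitment proceeds.

## Known limitations

* The four-phase interlung flow sequence is reproduced from its second
  phase on: in this implementation the inverted hemidiaphragm's
  paradoxical action is proportional to the common drive from inspiration
  onset, so the brief initial both-lungs-inflow phase is essentially
  absent under a stiff mediastinum.  The testable consequences (no
  pendelluft in late expiration, figure-eight, left lean) are unaffected.
* No posture dependence, no gravitational pleural gradient in the
  fluid-free hemithorax (a deliberate simplification: the phenomena of
  interest need only the fluid-side gradient), no airway inertance, no
  acid-base chemistry, no transcutaneous electrode physics, and dyspnea —
  a subjective symptom — is out of scope.
* Closed layers keep their trapped gas indefinitely; absorption
  atelectasis is not modelled.
* The abdomen has no internal structure (the liver's support of the right
  hemidiaphragm can only be emulated by lowering `C_ab`).

## Problem sizes used by the test-suite

Unit and property tests run the full 100-layer patient where the result
depends on it (morphology, convergence, gases) and a 25-layer patient for
plumbing checks; drainage-session tests use a 1 L effusion (7 intervals).
The layer-convergence check compares 100 against 200 layers in both the
baseline and the 3 L case; convergence (<1% in FRC, VT, amplitude under
count doubling) in fact already holds at 25 layers.
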