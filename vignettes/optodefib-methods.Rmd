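---
title: "Models and numerical methods in optodefib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in optodefib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`optodefib` simulates optogenetic termination of reentrant arrhythmias in
synthetic three-dimensional cardiac tissue. This vignette documents the
models it implements, the parameters that matter, the numerical choices,
and — importantly — what the synthetic desk-scale study conditions do and
do not represent.

## The opsin photocurrent models

### GtACR1: a two-state Markov chain

The *Guillardia theta* anion channelrhodopsin GtACR1 conducts chloride
when illuminated with green (515 nm) light. Because no dark/light-adapted
current branches have been reported for ACRs, the channel is represented
by a single open state O and a single closed state C with
`P(O) + P(C) = 1` and master equation

$$\frac{dP(O)}{dt} = k_{CO}\,(1 - P(O)) - k_{OC}\,P(O).$$

(The two-state scheme makes a one-variable master equation the only form
consistent with the conservation law; the package integrates it with the
exact exponential update toward
`P_ss = k_CO/(k_CO + k_OC)`, so probabilities cannot leave `[0, 1]`
regardless of step size.)

The closing rate is light-independent, `k_OC = 1/tau_off` with
`tau_off = 119` ms; the opening rate follows a logarithmic
irradiance dependence fitted to steady-state photocurrent plateaus,

$$k_{CO}(E_e) = \frac{1}{\tau_{on}}\,
  \frac{5.878134701 + \ln(E_e + 0.0028)}
       {0.369864 - 0.1072\,\ln(E_e + 0.0028)},$$

with `tau_on = 1110` ms and irradiance `E_e` in mW/mm².  The constants
are constructed so that `ln(0.0028) = -5.8781347...`: the numerator
vanishes exactly in darkness, and the rate is clamped below at zero.  The
denominator is positive throughout the protocol range (it would change
sign only above ~31 mW/mm², three times the largest irradiance any
protocol here uses; the formula should not be extrapolated there).

The photocurrent is Ohmic, `I = P(O) g_max (V - E_rev)` with
`g_max = 1.4` mS/cm² and `E_rev = -40` mV, the chloride reversal
potential in adult cardiomyocytes under physiologic chloride.  (Some
experimental preparations report −90 mV because of low-chloride pipette
solutions; `E_rev` is an ordinary parameter and can be overridden via
`opsin_params("GtACR1", E_rev = -90)`.)  Because −40 mV sits *above* the
resting potential and *below* the plateau, strong GtACR1 activation does
not simply silence the membrane: it clamps it near −40 mV —
"optogenetic voltage forcing" — which inactivates sodium channels and
makes propagation through forced tissue impossible.

A useful working point: at 0.001 mW/mm² and −80 mV the steady-state
current magnitude is ≈2 pA/pF, a current ChR2 needs several hundred times
more light to produce.  That asymmetry, not the optics, is why green
light wins despite its shallow penetration.

### ChR2-H134R: a four-state chain, and the red-shifted variant

ChR2-H134R is modelled with the established four-state scheme (closed
states C1, C2; open states O1, O2; O2 conducts with relative conductance
γ = 0.1), a first-order light-adaptation variable `p`, voltage-dependent
deactivation `Gd1(V)` and recovery `Gr(V)`, light-dependent inter-open
transitions `e12`, `e21`, and the empirical inward rectification
`G(V) = (10.6408 - 14.6408 e^{-V/42.7671})/V`, which places the
effective reversal near +13 mV.  Two calibration decisions matter:

* the conductance is **not** taken from the source formulation but
  recalibrated so that the steady-state photocurrent at 5 mW/mm² and
  −80 mV is 2.2 pA/pF, giving `g_max = 0.11` mS/cm²;
* the photon-flux conversion factor (the product of retinal cross
  section, quantum efficiency and an optical loss factor) is not
  separately identifiable from whole-cell current data, so it is fixed
  (`flux_factor = 0.03799` ms⁻¹ per mW/mm²) such that the published
  conductance and the published current jointly hold.  Both anchors are
  enforced by tests.

`ChR2-RED` is a hypothetical red-shifted variant: identical kinetics and
conductance, peak absorption moved to 669 nm.  It isolates the effect of
deeper optical penetration from channel properties.

The four-state chain is advanced by forward Euler with per-step
renormalization of the probability vector; `p` uses an exact exponential
update.  At protocol time steps (≤ 0.05 ms) the rates are ≤ ~0.3 ms⁻¹,
so the scheme is well inside its stability region; agreement with a
stiff ODE solver on the same right-hand side is verified in the tests.

## Light transport

Illumination is uniform on the endocardial surface.  Attenuation in the
wall uses the steady-state photon diffusion approximation
`D ∇²Φ − μ_a Φ = 0` with

$$a = 1 - \frac{4}{5}\,\frac{\mu_s' + \mu_a}{\mu_s'(1+g) + \mu_a},
\qquad D = \frac{1}{3(\mu_s' + \mu_a a)}.$$

Green light uses `μ_a = 0.7 /mm`, `μ_s' = 1.42 /mm`, `g = 0.9`
(giving `a = 0.5`, `D = 0.189` mm); blue and red use literature values
`(μ_a, D) = (0.52, 0.183)` and `(0.1, 0.34)`.  The penetration depth is
`δ = sqrt(D/μ_a)` — 520 μm (green), 593 μm (blue), 1.84 mm (red).
Note the square root: the printed values above are consistent only with
`sqrt(D/μ_a)`, not with the ratio itself.

Boundary conditions are `Φ = 1` (Dirichlet) on the illuminated surface
and zero flux elsewhere; this reproduces the exponential bulk decay that
the penetration-depth picture assumes.  (A partial-flux Robin surface
condition would change the near-surface profile by a modest factor; the
Dirichlet choice is the simplest one consistent with normalizing the
surface to the applied irradiance.)  Optical properties are treated as
homogeneous across normal, fibrotic and scar tissue, since no
region-specific optics are available.  The field is solved once per
(geometry, wavelength) with a sparse direct solve and cached; local
irradiance during a pulse is `E_e` times the per-node factor.  The
solver matches the closed-form solution of its own discrete recurrence
to 1e−6 and the continuum exponential to ~2% at `h = 0.1` mm; at the
production spacings (0.4–0.5 mm) the discrete decay length is 2–4%
longer than δ, a known property of the second-order stencil.

## Myocyte electrophysiology

Atrial membrane kinetics use the Courtemanche–Ramirez–Nattel human
atrial formulation (21 state variables); ventricular kinetics use the
ten Tusscher–Panfilov 2006 human ventricular formulation in its
epicardial parameterization (19 state variables).  A single cell type is
used across the wall — no endo/mid/epi gradient — because transmural
heterogeneity is orthogonal to the questions asked here.  Both are
implemented in C++ from the original publications: Rush–Larsen
exponential updates for Hodgkin–Huxley gates (rates tabulated on a
0.05 mV grid with linear interpolation), forward Euler for
concentrations and voltage, and the original algebraic rapid-buffering
updates for the calcium subsystem.  Nernst potentials are refreshed
every 8 steps in tissue runs (concentrations drift by less than 1e−4
relative over that interval).  Published initial conditions are
equilibrated for 10 s of quiescence at run time and cached; resting
potentials land near −86 mV (ventricular) and −81 mV (atrial), and APD90
changes by <1% under time-step halving.

Diseased tissue is represented by node labels with conductance
multipliers: ventricular border zone `g_Na ×0.38`, `g_CaL ×0.69`,
`g_Kr ×0.30`, `g_Ks ×0.20` (slow, long-APD peri-infarct tissue); atrial
fibrotic remodeling `g_Na ×0.6`, `g_CaL ×0.5`, `g_K1 ×0.5` plus halved
tissue conductivity.  These multipliers are conventions from the
infarct/fibrosis modeling literature, are config-exposed, and should be
read as stand-ins rather than measurements.  Scar is a non-excitable
void: scar nodes carry no state and no coupling.

## Tissue: the opsin-coupled monodomain model

Propagation follows the monodomain reaction–diffusion equation with an
anisotropic diffusivity tensor `D_T I + (D_L − D_T) f fᵀ`; fibers lie in
the wall plane and rotate linearly endo→epi by 120° total.  The spatial
discretization is second-order finite differences on a structured grid
(0.40 mm ventricular / 0.45 mm atrial by default, matching realistic
element sizes); in-plane cross-derivatives use the four-corner stencil,
and the assembled operator is exactly symmetric with zero row sums
(no-flux boundaries, discrete charge conservation).  Time integration is
operator-split: per-node ionics (plus the opsin current at expressing
nodes, using the node's cached attenuated irradiance) followed every
second ionic step by a Crank–Nicolson diffusion solve via
Jacobi-preconditioned conjugate gradients on the constant system matrix
(relative tolerance 1e−8; 2–4 iterations in practice).  Default ionic
steps are 25 μs (ventricular) and 50 μs (atrial).

Monodomain diffusivities are not printed in the source literature for
these cohorts; the defaults (`D_L = 0.13` mm²/ms ventricular, `0.243`
atrial, 4:1 anisotropy) were calibrated once so that planar conduction
velocity at the default spacing is ≈0.6 mm/ms longitudinally
(ventricular) and ≈0.7 mm/ms (atrial).  At 0.4–0.5 mm spacing the
transverse velocity is lattice-limited (ratio ≈3 rather than the
continuum 2), and the sodium upstroke foot is only marginally resolved,
so spatial refinement still moves CV appreciably (on the order of 15%
per spacing halving, always upward) while time-step halving moves it by
under 5%; the convergence tests quantify both.

Opsin expression is node-level binary — 58.2% of excitable nodes chosen
uniformly at random (the transduction level reported in mouse hearts one
year after systemic AAV delivery), full single-cell conductance at
expressing nodes, one map per geometry reused across opsins.  In
darkness the opsin current is exactly zero, so dark runs are bitwise
identical with and without an expression map (a tested invariant).

Activation detection uses an upward crossing of −20 mV with a 50 ms
lockout; the arrhythmia-activity metric is the fraction of excitable
nodes above −50 mV.  These detection constants are package conventions
(config-exposed), not literature values.

## Synthetic geometry: what it emulates, and what it does not

Patient-specific atrial and ventricular models reconstructed from
clinical imaging cannot be redistributed, so the generator builds
structured slabs that reproduce the *mechanisms* those models exhibit:

* an illuminated endocardial face opposing an epicardial face, with the
  atrial wall (2.5 mm) thin relative to several green penetration depths
  and the ventricular wall (8 mm default) much thicker;
* diffuse fibrosis (random patches with remodeled currents and reduced
  conductivity) for the atrial substrate;
* a transmural scar with border-zone rim for the ischemic ventricular
  substrate, with two variants: an annular excitable channel around the
  scar (anatomical reentry, the synthetic analogue of VT circling an
  infarct), and a "protected circuit" in which an endocardial scar cap
  shields an epicardial-side channel both optically (≥ 4 mm ≈ 8 δ_green
  from the illuminated surface) and electrotonically.

Everything is a pure function of the spec and its seed.

**Desk-scale study conditions.** A human reentrant wavelength
(CV × APD ≈ 0.6 mm/ms × 300 ms ≈ 180 mm) cannot fit any bench-sized
slab.  The desk presets used by the protocol tests therefore (i) reduce
diffusivities to 35% of the organ-scale defaults and (ii) triple the
delayed-rectifier conductances (APD90 ≈ 190 ms at slow rate), shrinking
the wavelength to ~30–40 mm so that a sustained circuit fits a
23 × 23 × 2 mm slab (sweep preset, ~5–6 × 10³ excitable nodes) and a
22 × 22 × 5 mm slab (protected-circuit preset, ~10⁴ nodes), at 0.5 mm
spacing and a 50 μs step.  Induced cycle lengths land in the clinical VT
range (150–350 ms).  Consequences to keep in mind: absolute
defibrillation threshold irradiances on these slabs are *not* the
patient-geometry thresholds (those depend on wall thickness, scar
architecture and total illuminated area); only orderings and mechanisms
transfer.  The passing tests demonstrate the mechanism — voltage forcing
of illuminated tissue to −40 mV, failure modes from protected circuits —
not patient-level dosimetry.

## Protocols

Reentry induction offers the clinical-style rapid-pacing trains (atrial:
twelve 5 ms pulses, coupling interval 300 ms decremented by 20 ms to
200 ms and held; ventricular: eight pulses at 600 ms plus two
extrastimuli at configurable intervals) and a cross-field S1–S2 method,
which is the default at desk scale because pacing-train inducibility
depends on substrate geometry unavailable here.  The S2 coupling
interval is scanned; candidates are screened with an early-exit run and
verified by ≥2 s of stimulus-free persistence.  Non-inducibility is a
reported outcome, not an error.

A defibrillation attempt applies one 1000 ms endocardial light pulse at
a given surface irradiance, starting at one of three onsets spanning the
reentrant cycle (ventricular: +0/+100/+200 ms; atrial protocol:
+0/+70/+140 ms), measured from the predicted next activation of the
induction reference probe (phase anchoring inside the cycle is a
convention; only the spanning matters).  Success requires no reentrant
activity within 800 ms after light offset; termination during light and
"indirect" termination after light offset are distinguished.  The
quiescence rule — activity below 0.5% of excitable nodes sustained for
200 ms and through the window — is a package convention layered on the
800 ms window.  Runs whose tissue is fully quiescent after light may
stop early: with no stimulus, a quiescent monodomain state cannot
re-excite, so this is an exact optimization, and it is why successful
attempts finish faster than failures.

The sweep driver runs every (opsin × irradiance × onset) combination
from the identical induced snapshot with the identical expression map,
classifies outcomes, tabulates successes out of the number of onsets
(the published table format), and records the mean end-of-light voltage
of illuminated expressing endocardial nodes — the quantity that exposes
the voltage-forcing mechanism (within ±5 mV of −40 mV in successful
GtACR1 attempts).  The test-suite sweep uses three irradiances per
decade boundary (0.05, 0.5, 5 mW/mm²) inside the ventricular protocol
range 0.001–10; the full decade grid is configuration.

## Numerical and design notes

* The two-state GtACR1 update is exact for constant irradiance; light
  pulses are rectangular, so per-node rates are precomputed at each
  on/off transition.
* Degenerate inputs: zero-irradiance pulses are legal and exactly
  equivalent to darkness; empty sweeps produce empty but valid tables;
  non-inducible substrates report `inducible = FALSE`.
* The Crank–Nicolson matrix is constant per run; CG warm-starts from the
  previous voltage, and the discrete maximum principle of the diffusion
  half-step is exercised directly in the tests.
* Fibrotic conductivity scaling enters edges by the geometric mean of
  the node factors, which preserves symmetry.
* Determinism: every stochastic element (expression maps, fibrosis
  patches) draws from an isolated RNG seeded by the spec, restoring the
  caller's RNG state; identical configurations give bitwise-identical
  recordings.
* The single-cell suppression verdict evaluates the membrane *after*
  the 5 ms stimulus has dissipated (3 ms margin): a 30 pA/pF pulse
  displaces any membrane passively above −20 mV while it flows, so the
  meaningful question is whether a regenerative response outlasts the
  stimulus.

## Known limitations

* Structured-grid finite differences replace unstructured FEM; wall
  geometry is a slab, not a chamber.
* Monodomain only: no extracellular potentials, no shock electrotherapy.
* Single ventricular cell type; no Purkinje system; no mechanical
  deformation.
* Optical homogeneity across scar/fibrosis; no Monte-Carlo photon
  transport, no specular interfaces.
* Desk-scale conductivity/repolarization scaling (above) means absolute
  irradiance thresholds are not comparable to organ-scale values.
* ChR2 four-state kinetic constants follow the established H134R
  formulation with a calibrated flux factor; they are not refit to raw
  data here.
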