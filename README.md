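# optodefib

Simulation of optogenetic defibrillation in synthetic human cardiac
tissue.

Conventional defibrillation interrupts reentrant arrhythmias with painful
high-energy shocks. An optogenetic alternative light-sensitizes the
myocardium with microbial opsins and terminates reentry with light. Most
prior work used depolarizing cation channels (ChR2-H134R), whose efficacy
is limited by light attenuation in tissue and by the weak photocurrents
available at safe irradiances. Anion channelrhodopsins such as GtACR1
conduct chloride instead: in adult cardiomyocytes (chloride reversal
≈ −40 mV) strong green-light activation *clamps* the membrane near
−40 mV — depolarized enough to inactivate sodium channels, so forced
tissue becomes an unexcitable wall and reentrant wavefronts die on it.
This package exists to study that mechanism quantitatively.

`optodefib` implements, as a tested R package with compiled cores:

* **Opsin photocurrents** — a two-state Markov model of GtACR1 with
  opening rate `k_CO(E_e) = (1/τ_on)·(5.8781347 + ln(E_e + 0.0028)) /
  (0.369864 − 0.1072·ln(E_e + 0.0028))`, closing rate `1/τ_off`
  (τ_on = 1110 ms, τ_off = 119 ms), current
  `I = P(O)·g·(V + 40)` with g = 1.4 mS/cm²; and the four-state
  ChR2-H134R model (γ = 0.1, voltage-dependent rectification, effective
  reversal ≈ +13 mV) recalibrated to g = 0.11 mS/cm², plus a red-shifted
  variant with identical kinetics.
* **Light transport** — the steady-state photon diffusion equation
  `D∇²Φ = μ_a Φ` on the tissue grid, with
  `a = 1 − (4/5)(μ_s'+μ_a)/(μ_s'(1+g)+μ_a)`, `D = 1/(3(μ_s'+μ_a a))`
  and penetration depth `δ = √(D/μ_a)`: 519.6 μm (green), 593.2 μm
  (blue), 1.844 mm (red).
* **Membrane kinetics** — Courtemanche human atrial and ten
  Tusscher–Panfilov 2006 human ventricular (epi) myocyte models in C++
  with Rush–Larsen gating, plus border-zone / fibrotic remodeling
  variants.
* **Tissue** — an opsin-coupled anisotropic monodomain solver
  (structured grids, transmural fiber rotation, Crank–Nicolson
  diffusion, 58.2% diffuse opsin expression), with a synthetic-geometry
  generator producing atrial-like sheets and ventricular-like slabs with
  fibrosis, infarct scar + border zone, and a "protected epicardial
  circuit" preset.
* **Protocols** — voltage-clamp characterization, conductance
  calibration by bisection, single-cell AP suppression, cross-field and
  rapid-pacing reentry induction, and the irradiance × onset-time
  defibrillation sweep with the 1000 ms light pulse and 800 ms success
  window, reported as n-out-of-3 success tables.

## A worked example

```r
library(optodefib)

# photocurrent working points
p <- opsin_params("GtACR1")
tr <- run_voltage_clamp(p, v_hold = -80, e_e = 0.001)
plateau_current(tr)
#> [1] -1.809571          # ~2 pA/pF inward from 1 uW/mm^2 of green light

calibrate_conductance("ChR2", target_current = 2.2, e_e = 5, v_hold = -80)
#> [1] 0.1100003          # mS/cm^2, the recalibrated ChR2 conductance

# optics
op <- light_preset("green")
c(a = op$a_param, D = op$D, delta_um = 1000 * op$delta)
#>           a           D    delta_um
#>   0.5008829   0.1890000 519.6152423

# single-cell voltage forcing: stimulate, illuminate, stimulate again
res <- run_single_cell_suppression("ventricular", e_e = 1.0)
c(res$suppressed, res$peak_before, res$peak_during, res$plateau)
#> [1]   1.00000  48.22101 -30.80439 -40.39667
```

The last line says: the pre-light stimulus fires a full action potential
(still at +48 mV when the stimulus artifact window closes); during
illumination the same stimulus cannot (the response stays at −31 mV)
because the membrane is held at the −40.4 mV plateau — the chloride
reversal.

At tissue scale, `slab_preset("ventricular-desk")` builds a scarred
ventricular-like slab, `induce_reentry()` starts an anatomical reentrant
wave around the infarct (cycle length ≈ 340 ms), and `run_defib_sweep()`
reproduces the protocol's success tables; `min_full_success()` then
returns the weakest irradiance that terminated every attempt — on this
slab 0.5 mW/mm^2 for GtACR1, while neither ChR2 variant reaches full
success anywhere on the tested grid.
See the methods vignette (`vignettes/optodefib-methods.Rmd`) for why the
desk-scale slabs use scaled conductivities and what does and does not
transfer to organ scale.

A thin CLI wrapping these stages (subcommands `characterize-opsin`,
`attenuation`, `single-cell`, `make-geometry`, `induce`, `defib-sweep`,
`report`) is installed at `inst/cli/optodefib.R`.

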