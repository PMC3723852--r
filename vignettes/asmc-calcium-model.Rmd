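---
title: "Methods: a whole-cell model of ASMC Ca2+ dynamics with store-operated entry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a whole-cell model of ASMC Ca2+ dynamics with store-operated entry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmca)
```

## The model and its assumptions

`asmca` treats an airway smooth muscle cell (ASMC) as two well-mixed Ca²⁺
pools — cytosol (`c`) and sarcoplasmic reticulum (`c_s`), both in μM of
*free* Ca²⁺ — exchanging through three release pathways and one uptake
pathway, with the plasma membrane carrying influx and PMCA extrusion:

$$\frac{dc}{dt} = \underbrace{(k_{IPR}P_{IPR} + \lambda_{RyR} + J_{SR})(c_s-c)}_{\text{SR release}}
 - \underbrace{\epsilon\,\frac{V_e c}{K_e+c}}_{\text{SERCA}}
 + \underbrace{\alpha_0 + \alpha_1 p + V_s s}_{\text{membrane influx}}
 - \underbrace{\frac{V_p c}{K_p+c}}_{\text{PMCA}}$$

$$\frac{dc_s}{dt} = \gamma\left(\epsilon\,\frac{V_e c}{K_e+c} -
 (k_{IPR}P_{IPR} + \lambda_{RyR} + J_{SR})(c_s-c)\right)$$

The factor `gamma = 5.405` is the cytosol/SR volume ratio folded together
with the relative strength of fast linear buffering in each compartment;
with membrane fluxes disabled the model conserves `c + c_s/gamma` exactly,
which the test suite verifies along integrated trajectories.

**IP₃ receptor.** The open probability is the three-subunit reduction of the
classical eight-state binding scheme:
`P_IPR = [p/(p+K1) · c/(c+K5) · (1−phi)]³` — each identical subunit must
bind IP₃, bind activating Ca²⁺ and escape Ca²⁺ inhibition. The inhibited
fraction `phi` relaxes as `dphi/dt = beta(c,p)(1−phi) − alpha(p)·phi`, with
binding rate `beta = c(a₂p + a₄K₁)/(p+K₁)` (the inhibitory affinity depends
on whether IP₃ is bound; `a₂ = k₋₂/K₂`, `a₄ = k₋₄/K₄`) and unbinding
`alpha = (k₋₂p + k₋₄K₃)/(p+K₃)`. Because the equilibrium constants satisfy
the detailed-balance relation `K₁K₂ ≈ K₃K₄`, this is algebraically the
familiar single-gate form with `Q₂ = K₂(p+K₁)/(p+K₃)`. The side of this
equivalence matters: assigning the slow no-IP₃ rate `k₋₄` to the IP₃-bound
branch instead produces an equilibrium fold and no restabilization at high
agonist, contradicting the intended bifurcation structure, and was rejected
during development.

**Store-operated entry.** SOCE is the essential nonstandard ingredient: the
membrane influx depends on the *store* through the slowly adapting SOCC
activation `s`, with `ds/dt = (s_inf(c_s) − s)/tau_s`,
`s_inf = K_s⁴/(K_s⁴+c_s⁴)`. `s_inf` is the fraction of STIM sensors
dissociated from SR Ca²⁺ and free to couple to Orai/TRP; `tau_s = 30` s
represents slow STIM translocation. The SOCE current is `V_s·s` with no
explicit external-Ca²⁺ driving force; removing external Ca²⁺ in a protocol
zeroes every influx term while `s` keeps gating (open channels carrying no
current).

**Drug kinetics.** Three first-order states encode pharmacology: `p_eff`
(effective agonist/IP₃, timescale `tau_p`), `serca_eff` (CPA reduces the
operating SERCA fraction toward `1 − cpa_block_fraction`, timescale
`tau_e`), and the Rya-Caf-evoked RyR leak `lambda_RyR`, which rises with a
saturating first-order law of timescale `tau_SR` toward the ceiling
`K_RYR·tau_SR²` and never decays afterwards — ryanodine locks RyR open
irreversibly. The leak's ceiling (19 s⁻¹, ~28× the maximal IPR rate) empties
the SR within seconds, which is the clamping mechanism of the
ryanodine–caffeine protocol.

## Parameters

Defaults (see `?asm_parameters` for the full annotated list) are the
reference hand-calibrated values: `V_p = 7.5`, `K_p = 1.5`, `V_s = 1.57`,
`K_s = 50`, `n_s = 4`, `tau_s = 30`, `alpha_0 = 0`, `alpha_1 = 0.00105`,
`gamma = 5.405`, `V_e = 5`, `K_e = 0.1`, `k_IPR = 0.667`, `J_SR = 0.01`,
`K_RYR = 0.19`, `tau_SR = 10`, `tau_p = tau_e = 30`, the receptor constants
`K₁…K₅` of the original eight-state scheme, and `k₋₂ = 0.167` with
`k₋₄ = 0.138·k₋₂` fixed as a ratio. `k₋₂` is the frequency-scaling knob of
the IPR: it sets the inhibition-recovery clock that paces spiking.

Two scenario knobs are deliberately free because no reference value exists:

* `cpa_block_fraction` (default **0.15**): the fraction of SERCA capacity
  removed at full CPA effect. The defining observation of the partial-block
  scenario is that cytosolic Ca²⁺ returns close to its resting level once
  agonist is washed out in the continued presence of CPA, with SOCE
  deactivating as the store refills. In this calibration that behaviour
  requires a modest block — at 0.15 the washout level is ~117 % of rest and
  oscillations still damp into an elevated plateau while CPA and agonist are
  both present; at 0.5 the washout level would stay ~2× rest, which is the
  full-block phenotype, not the partial one. The default was therefore
  chosen, in the same spirit as the original hand-fit, to reproduce the
  qualitative experiment; it is exposed in every config.
* `dye_Kd` (default 0.17 μM): affinity of the fluorescence emulation
  (`fluorescence_transform()`), used only for qualitative comparison with
  high-affinity indicator recordings. Dye saturation is why simulated spike
  amplitudes should not be compared linearly with fluorescence traces; the
  emulation never feeds back into the dynamics.

## Protocols

`build_protocol()` encodes the lung-slice experiments as pure data (timed
piecewise-constant target changes): the three-step Rya-Caf clamp
(`fig3_threestep`), the three competing CPA hypotheses (`cpa_fast_full`,
`cpa_slow_full` with `tau_e = 600` s, `cpa_partial`), the long-exposure
variant (`cpa_long`: 5 min agonist+CPA, 10 min CPA alone) and the
zero-external-Ca²⁺ test (`cpa_zero_ca`). Default phase durations (agonist
400 s, washouts 200 s, Rya-Caf 200 s) are plausible placeholders for the
experimental timings, which are not printed anywhere; all are overridable.
In `cpa_zero_ca` the external solution is switched 10 s before the final
agonist application: the store drains passively once influx stops, so a
longer delay erases the residual-release transient this protocol is designed
to expose. Even at 10 s the transient is small (a few nM rebound carried by
a clear burst of IPR flux) — consistent with the fact that the corresponding
experimental deflection needs magnification to be seen — because the slow
agonist ramp (`tau_p = 30` s) lets the store leak out quasi-statically
instead of firing a regenerative spike.

## Numerical choices

* **Integration**: `lsoda` (stiff-capable) with `rtol = 1e-8`,
  `atol = 1e-10`, `hmax = 1` s, restarted at every protocol event; the
  right-hand side is compiled C for speed, with the R implementation kept as
  the validated reference (the suite checks both integrate identically).
  Transient negative excursions below 1e-12 are clipped; anything below
  −1e-6 is treated as an integrator failure.
* **Equilibria**: damped Newton on the 4-variable core (drug states frozen
  at targets) with the analytic Jacobian, residual tolerance 1e-11, over a
  deterministic multi-start grid `c ∈ {0.05, 0.2, 1} × c_s ∈ {10, 100, 300}`;
  branch continuation reuses the previous root (continuity).
* **Stability / Hopf**: dense eigenvalues of the analytic 4×4 Jacobian;
  stability-boundary crossings are refined by bisection to 1e-4 in the swept
  parameter and classified Hopf (complex leading pair) vs fold (real). The
  left Hopf here is delicate: the crossing pair's real part moves from −0.6
  to 0 within ~0.01 in agonist and the pair splits into two real eigenvalues
  immediately after, so tracking only complex pairs on a coarse grid
  mislocates it — hence the boundary-based detector.
* **Periodic branches**: direct simulation with state inheritance in both
  sweep directions (no boundary-value continuation; period-doubled branches
  are not tracked). Fresh starts are nudged 2 % off the equilibrium so
  unstable roots are escaped; bistability is the set of grid values where
  the two directions settle on different attractors, and the cycle fold is
  bracketed by the last oscillating grid value of the cycle-carrying sweep.
  Near the subcritical onset the cycle state must be inherited from an
  oscillating neighbour — a nudged equilibrium start below the Hopf falls
  back to rest.
* **Oscillation metrics**: peaks are local maxima with prominence ≥ 5 % of
  the window range; oscillation requires ≥ 3 peaks and ≥ 0.01 μM range;
  frequency is 60/mean inter-peak interval; default transient discard 200 s
  (several `tau_s`, `tau_p`). Sweep windows are 1000 s per grid point
  (~15–150 periods), extended to 3000 s near onset so slow cycles retain
  ≥ 3 peaks; these sizes keep the full acceptance sweep under a minute on
  one CPU while leaving frequency estimates grid-limited rather than
  window-limited.

## Design decisions where the form was open

* **Pump kinetics**: PMCA and SERCA are first-order saturating pumps
  (`Vc/(K+c)`). With the reference parameter set, Hill exponent 1 for both
  is the only choice consistent with the calibration note that the STIM
  affinity sits at half the resting SR load (`c_s* = 94.4 ≈ 2K_s` here;
  exponent-2 variants put `c_s*` at 158–177 μM), and the only one that
  yields a monotone steady state in agonist, exactly two Hopf points below
  twice the default agonist concentration, and sustained oscillations at the
  default agonist — so it is adopted despite quadratic pumps being equally
  common in this literature.
* **RyR leak law**: the ramp constant `K_RYR` has units s⁻², which fixes the
  saturating first-order law above (initial slope `K_RYR·tau_SR`, ceiling
  `K_RYR·tau_SR²`) as the dimensionally consistent reading.
* **Equilibrium eigenvalues** are reported for the drug-frozen 4×4 core;
  including the drug rows only appends `−1/tau` eigenvalues (and an
  uninformative zero for the frozen RyR leak) that obscure stability labels.

## What the model does and does not capture

The deterministic whole-cell description reproduces the signature behaviours
this package is built around: agonist-frequency coding across the
experimentally observed band, the Rya-Caf plateau whose level is set purely
by membrane fluxes (so a persistent elevation implies persistent SOCE), the
insensitivity of that plateau to further agonist, CPA's failure to clamp
Ca²⁺ unless its block is complete, and loss of oscillations when SOCE is
pushed down (Hopf) or up (cycle fold). It does not represent stochastic
Ca²⁺ puffs and microdomains (relevant exactly at the low-agonist onset,
where the deterministic slow cycles live), explicit buffer species, IP₃
metabolism, receptor desensitization, mitochondria, membrane potential, or
contraction itself. Passing tests therefore certify the dynamical-systems
behaviour of this formulation, not quantitative agreement with any
individual cell.

**Known limitation — the frequency axis.** All structural anchors of the
reference calibration are reproduced (resting `c_s* ≈ 2K_s`, two Hopf
points, right-hand bistability, monotone steady state, SOCE-dependent
frequency modulation), but the oscillation-frequency *range* on the stable
branch computes to ≈ 1.8–16.4 min⁻¹, stretched relative to the
0.5–11 min⁻¹ band reported for human lung slices that the original
calibration targeted. The original equations admit more than one reading,
and no reading we tested
of the ambiguous pieces — pump exponents, gating-power placement,
inhibitory-site assignment — matches the band without breaking the
structural anchors above. The acceptance artifacts report the computed
values honestly; treat absolute frequencies from this implementation as
~1.5× high at the top of the band and correspondingly compressed at the
onset.

## Determinism

The model has no stochastic component: identical parameters and protocol
give bit-identical output tables (asserted in the test suite). Random states
appear only in property-style tests, under fixed seeds.
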