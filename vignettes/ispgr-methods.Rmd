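---
title: "Signal model, simulation design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal model, simulation design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ispgr)
```

This vignette is the package's account of the science it implements: the
semi-steady-state signal model for preparation-interleaved spoiled
gradient-echo (I-SPGR) imaging, the Bloch simulator used as its oracle, the
joint T1/T2/M0 fit, the pseudo-spiral phase-encode ordering, the synthetic
phantom the whole package is tested on, and the evaluation statistics — with
the assumptions, units, defaults, and numerical decisions stated explicitly.

## The sequence and its signal model

One **shot** of the sequence consists of a preparation block followed by a
readout block of `k` RF excitations with flip angle $\alpha$ spaced `TR`
apart. The preparation block contributes three intervals, each acting on the
longitudinal magnetization $M_z$ only:

* $T_{FS}$ (ms): a temporal gap plus an off-resonance fat-suppression pulse.
  On-resonance spins experience pure T1 relaxation.
* $T_{BS}$ (ms): a motion-sensitized driven-equilibrium blood-suppression
  block that tips the magnetization into the transverse plane and back, so
  the stored magnetization decays with T2 ($M_z \mapsto M_z e^{-T_{BS}/T_2}$,
  with no recovery term).
* $T_{Sp}$ (ms): a spoiling interval; pure T1 relaxation.

Under perfect spoiling, transverse magnetization never survives between
pulses and a recursion over $M_z$ just before each pulse closes in one shot.
After enough shots the evolution becomes *shot-periodic* (a semi steady
state), and summing the geometric within-shot recursion yields the
closed-form signal after pulse $n$ implemented by `ispgr_signal()`
(see the README for the expression). Two structural properties anchor the
test suite:

* **Collapse**: with $T_{FS} = T_{BS} = T_{Sp} = 0$ the expression reduces
  algebraically to the Ernst equation for every $n$, tested to machine
  precision over random parameters.
* **Within-shot convergence**: the gap between $S_n$ and the Ernst signal
  decays geometrically with ratio $E_1\cos\alpha$ — the signal relaxes
  toward the steady state inside each shot and the preparation resets it.

**Assumptions.** Instantaneous RF pulses; perfect spoiling in the closed
form; the fat compartment is not modeled (fat suppression is assumed to act
only off-resonance); flow and motion effects of the blood-suppression block
are not modeled — static tissue simply accrues T2 decay. All times are in
milliseconds internally; flip angles are accepted in degrees at every
interface and converted to radians internally.

**Degenerate inputs.** The geometric-series factor
$(1 - C^m)/(1 - C)$ is evaluated with an explicit $C \to 1$ branch
returning its limit $m$, so the model stays finite as
$\alpha \to 0, TR/T_1 \to 0$ during optimizer exploration. A tissue with
$M_0 = 0$ returns exactly 0.

## The Bloch simulator as an independent oracle

`simulate_ispgr()` is event-driven: rotations are instantaneous and
relaxation over every interval is applied in closed form, so the simulator
has no time-discretization error and is an *independent* check on the
algebra of the signal model (it implements the recursion, never the summed
expression). Simulations start from thermal equilibrium and play the readout
block first, so the recorded time axis starts at the first RF pulse.

In perfect-spoiling mode the transverse magnetization is zeroed after each
readout. The four validation tissues (T1 ∈ {500, 1500} ms × T2 ∈ {25, 50}
ms, with TR = 5 ms, α = 15°, k = 20, T_FS = 50 ms, T_BS = 12 ms, T_Sp = 6
ms) match the analytical model to better than $10^{-10}$ relative once the
transient has died out.

**Burn-in.** `time_to_steady_state()` reports the earliest sequence time
after which every readout matches the same-index readout of the final
simulated shot within a relative tolerance (default $10^{-3}$), with an
explicit "not converged" sentinel. For oracle-equivalence comparisons at the
$10^{-6}$ level this burn-in is insufficient by construction — the per-shot
transient decay factor is $E_{Sp}E_{BS}E_{FS}(E_1\cos\alpha)^k \approx
0.28\text{–}0.35$ here, so one shot past a $10^{-3}$ deviation roughly
$3\times10^{-4}$ remains. Equivalence tests therefore compare the final shot
of a 30-shot (~5 s) train. Measured with the $10^{-3}$ criterion against the
analytical model, the four validation tissues converge at 0.94, 1.07, 1.24,
and 1.51 s of sequence time — the time grows with T1 and T2, since both
slow the decay of the shot-to-shot transient.

In **rf_gradient** mode an ensemble of isochromats (default 500,
convergence-checked: doubling changes steady-state deviations well under 1%)
carries full 3-vector magnetization. Intra-voxel gradient spoiling is
modeled as a per-TR precession phase spread uniformly over $[0, 2\pi)$
across the ensemble (and pro-rated by duration for the preparation
intervals); RF spoiling uses quadratic phase cycling
$\phi_j = \Delta\phi \cdot j(j-1)/2$ with the increment in degrees as
configuration, and the recorded signal is the demodulated complex ensemble
mean. `spoiling_deviation()` contrasts the prepared sequence with a plain
SPGR train of the same TR and flip angle: deviations from the
perfect-spoiling prediction grow with flip angle, and the prepared sequence
is measured at the first readout of a late shot (the sample that acquires
central k-space). The preparation itself is treated as in perfect mode for
$M_z$; residual transverse magnetization is additionally T2-decayed and
dephased. Flowing spins, off-resonance, and slice profiles are not
simulated.

## Joint T1/T2/M0 fitting

`fit_voxel()` minimizes ordinary (Gaussian) least squares between the
measured magnitudes and the forward model evaluated at readout index
`n = 1` — the readout that samples the center of k-space and therefore
determines image contrast. Magnitude noise is not Rician-corrected; the
default synthetic noise is additive Gaussian on the magnitude, matching
that assumption.

Numerical design:

* **Variable projection.** The model is linear in $M_0$, so $M_0$ is solved
  in closed form at every candidate $(T_1, T_2)$ and bounded
  Levenberg–Marquardt (minpack.lm) runs on the profiled residuals over
  $(T_1, T_2)$ only. The full 3-parameter problem has a long, curved,
  ill-conditioned $T_1$–$M_0$ valley in which LM stalls far from the
  optimum; profiling removes it. Noiseless recovery is then exact to
  ~$10^{-14}$ across the T1 × T2 grid.
* **Multi-start.** The profiled surface still has local minima at short T2,
  so the fit evaluates a fixed coarse grid (T1 ∈ {300, 800, 1500, 2500} ms ×
  T2 ∈ {30, 60, 150} ms, clipped to the bounds) and refines the best three
  starts. The grid is fixed, so the fit is deterministic without any seed.
* **Bounds.** Defaults T1 ∈ [100, 3000] ms and T2 ∈ [20, 300] ms — the
  in-vivo choices; they are arguments, and analyses whose ground truth lies
  outside (the 8-vial phantom spans T2 15–328 ms) must widen them, as the
  closure tests do. A solution on a T1/T2 bound is reported converged with a
  distinct `at_bound` flag.
* **M0 bound.** $[0, 1000 \times \max|signal|]$. A tighter signal-based
  bound is a trap here: under strong suppression the unit-$M_0$ signal peaks
  at only ~0.09 for the in-vivo preset, so e.g. $10\times\max$ would exclude
  the true $M_0$ and pin fits to a spurious constrained optimum. $M_0$ is in
  arbitrary units; the bound exists only for numerical containment.
* **SPGR misfit model.** `model = "spgr"` fits the Ernst equation (T1 and
  M0 only) — the comparison that quantifies the bias of ignoring the
  preparation. On noiseless phantom data it underestimates T1 on every vial
  (fits collapse toward the lower T1 bound), while the semi-steady-state
  model recovers the truth.
* **Degenerate voxels.** Non-finite or all-zero signal vectors return
  `converged = FALSE` with `NA` parameters and are excluded from summaries.

B1+ transmit-field correction is the linear actual-flip-angle convention
$\alpha_{actual} = r_{B1} \alpha_{nominal}$, with the ratio map smoothed by
a separable 3-D Gaussian (`smooth_b1_map`, default σ = 1 voxel; kernels are
truncated at 3σ and renormalized at borders, so constant maps are preserved
exactly — at the cost that impulse mass near borders is not).

`fit_regions()` provides the alternative analysis path (average the signals
over a labeled region, then fit once); both region-averaged and
voxel-then-average estimates are available because printed phantom analyses
are ambiguous between them.

## Pseudo-spiral phase-encode ordering

`spiral_arm()` samples the parametric curve $r = -x^2 + 2x$,
$\varphi = 2\pi x + \text{rotation}$ at `points_per_arm` values of $x$
uniform on $[0, 1]$ (the simplest reading of a fixed number of samples along
a curve parameterized on the unit interval; one full turn per arm). The unit
disc maps anisotropically onto the rectangular grid so $r = 1$ touches both
extents of the default 178 × 30 matrix; indices are 0-based with DC at
$\lfloor n/2 \rfloor$, rounded to nearest and clipped. Duplicates after
rounding are retained — the scanner plays all `k` readouts regardless.
Successive arms rotate by the golden angle (137° default); plans are fully
deterministic.

Because $r$ is monotone in $x$, every arm starts exactly at the grid center:
the readout immediately after the preparation — where the suppression
contrast is strongest and the model is evaluated (`n = 1`) — acquires
central k-space.

**Sampling-density caveat.** At 178 shots the plan places 5340 samples on a
5340-point grid; the center is visited ~8× per grid point while peripheral
visit density falls below 1 (`sampling_report()`). *Unique* coverage inside
the inscribed ellipse is comparatively flat, with a pile-up ring at
$r = 1$ where every arm ends. The genuinely unreachable periphery is the
rectangle's outer radial band including its corners, which the
inscribed-ellipse spiral never touches; `center_density()` therefore
contrasts the central 10%-radius disc (unique coverage 0.63) with the
$r > 0.9$ outer band (0.40) rather than with the disc's entire complement.

## The digital phantom and the synthetic acquisition

`make_phantom()` builds an 8-vial cylindrical phantom emulating a MnCl2
calibration object: T1 spans 236–2013 ms and T2 spans 15–328 ms, with the
intermediate vial values **log-spaced between those endpoints** — the
per-vial manufacturer values are not public, so the intermediate ground
truth is synthetic by construction. The default grid is 40 × 40 × 3 voxels
at 0.98 × 0.98 × 4 mm (the reconstructed resolution of the emulated
protocol, at a desk-scale matrix); vials sit on a ring and are validated
non-overlapping.

`simulate_stack()` composes the forward model per voxel (flip angles scaled
by a supplied B1+ field) and adds noise per `noise_model()`:
`gaussian_magnitude` (default) adds Gaussian noise directly to the
magnitudes; `rician` builds the magnitude of a complex signal with Gaussian
noise on both channels. The SNR convention: noise SD equals the noiseless
reference-measurement signal *averaged over the object* divided by `snr`;
the reference measurement defaults to FA 10° at T_BS 13 ms, the measurement
closest to the Ernst angle for mid-range T1. The empirical SNR of generated
stacks matches the request within 5%.

What the generator does *not* emulate: k-space undersampling artifacts and
streaking, respiratory motion, fat compartments, coil sensitivities, and
spatially correlated noise. Passing tests on this phantom therefore
demonstrate correctness of the signal model, the fit, and the statistics
under the model's own assumptions — not robustness to reconstruction or
motion effects in real data.

## Evaluation statistics

* `bias_table()` — region-mean fitted vs reference values, error strictly
  `fitted − reference`, per model; converged voxels only.
* `sensitivity_analysis()` — Monte-Carlo precision maps over a ground-truth
  T1 × T2 grid. Defaults: T1 ∈ {300…2500} ms (6 values), T2 ∈ {20…200} ms
  (7 values), SNR 30, 100 repetitions per cell, seeded and reproducible.
  One noise SD is used for the whole map (`snr_scope = "grid"`), derived
  from the grid-averaged reference signal: noise is a property of the
  acquisition, not of the tissue, so short-T2 cells — whose signals decay
  most during blood suppression — see a lower effective SNR, exactly as on a
  scanner. The per-cell summary is the **median** absolute relative error
  (robust to fit-boundary pile-up; `summary = "mean"` is available).
  Boundary-valued fits count as estimates rather than being dropped —
  dropping them would flatter the reported precision. Under these defaults
  the maximum median T1 error over cells with T2 < 40 ms is ~50%: the
  short-T2 region is where joint estimation degrades sharply, with errors
  capped in part by the fitting bounds themselves.
* `repeatability()` — Bland–Altman mean difference and ±1.96 SD limits of
  agreement, and the within-subject coefficient of variation
  $wCV = \sqrt{\overline{d^2}/2} / \text{grand mean}$, verified against a
  hand-enumerated two-pair oracle and exactly scale-invariant.
* `roi_summary()` — median and IQR per parameter with the
  linear-interpolation quantile convention (`type = 7`), stated because
  medians/IQRs are convention-sensitive.
* `correlate_with_diameter()` — Shapiro–Wilk on *both* variables
  (p < 0.05 flags non-normality); Pearson if both pass, Spearman otherwise.
  The both-must-pass gate is the adopted reading of "depending on the
  distribution" of either variable.

## Problem sizes used by the shipped analyses

Chosen as desk-scale defaults: phantom closure and misfit analyses run the
40 × 40 × 3 phantom (~1200 vial voxels) through `fit_volume()`; the
sensitivity map uses the 6 × 7 default grid at 100 repetitions per cell
(4200 fits); Bloch validations use 30-shot (~5 s) trains; ensemble spoiling
sweeps use 300–500 isochromats. Every randomized analysis takes an explicit
integer seed and is bit-reproducible from it.

## Known limitations

* The closed form assumes perfect spoiling; the ensemble simulator
  quantifies, but the fit does not correct, RF-spoiling imperfections.
* Magnitude noise is fitted under a Gaussian assumption; at very low SNR a
  Rician likelihood would be more faithful (the generator can produce Rician
  data for such studies).
* The blood-suppression block is modeled as pure T2 decay of stored
  magnetization; efficiency losses from motion or B1+ inhomogeneity in the
  preparation itself are out of scope.
* The trajectory generator emits phase-encode orderings and masks, not
  gradient waveforms or timing.
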