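# ispgr

Signal modeling and joint T1/T2 mapping for blood- and fat-suppressed
interleaved spoiled gradient-echo (I-SPGR) MRI.

## The problem

Variable-flip-angle (VFA) relaxometry estimates T1 from spoiled
gradient-echo (SPGR) images acquired at several flip angles, using the Ernst
steady-state signal

```
S = M0 · sin(α) · (1 − E1) / (1 − cos(α) · E1),   E1 = exp(−TR/T1).
```

Imaging the wall of an abdominal aortic aneurysm additionally requires
suppressing the signal of flowing blood (iMSDE preparation) and of
surrounding fat (SPIR preparation). Interleaving these preparation blocks
with the readout breaks the steady state: each shot consists of a
preparation block — a T1-weighting gap of duration `T_FS`, a
blood-suppression interval `T_BS` during which the magnetization is stored
transverse and decays with T2, and a spoiling interval `T_Sp` — followed by
`k` RF excitations. The longitudinal magnetization then evolves *within*
each shot while repeating identically *across* shots (a semi steady state).
Fitting such data with the Ernst equation produces large systematic T1
errors.

This package implements the closed-form semi-steady-state signal model for
that sequence. With `E_FS = exp(−T_FS/T1)`, `E_BS = exp(−T_BS/T2)`,
`E_Sp = exp(−T_Sp/T1)` and `C = E1·cos(α)`, the signal after RF pulse
`n ∈ [1, k]` is

```
S_n = sin(α) · M0 · [ (1 − E1)(1 − C^(n−1))/(1 − C)
      + ((1 − E_Sp) + (1 − E_FS)·E_Sp·E_BS
         + E_Sp·E_BS·E_FS·(1 − E1)(1 − C^k)/(1 − C)) / (1 − E_Sp·E_BS·E_FS·C^k)
        · C^(n−1) ].
```

Because the preparation imposes both T1 and T2 weighting, varying the flip
angle *and* the blood-suppression duration makes a joint voxel-wise
T1/T2/M0 fit possible. With all preparation durations zero the expression
collapses algebraically to the Ernst equation.

Around the model the package provides, in matched module surfaces:

* **Bloch simulator** (`simulate_ispgr`) — event-driven, exact interval
  exponentials; perfect-spoiling mode as an independent oracle for the
  closed form, plus an RF/gradient-spoiled isochromat-ensemble mode
  (`spoiling_deviation`) to quantify imperfect spoiling.
* **Parameter fitting** (`fit_voxel`, `fit_volume`, `fit_regions`) —
  bounded least squares with variable projection (M0 profiled out) and a
  deterministic multi-start over T1 × T2; B1+ flip-angle correction
  (`actual_flip_angle`, `smooth_b1_map`); NIfTI input/output.
* **k-space trajectory** (`generate_trajectory`) — golden-angle
  pseudo-spiral phase-encode ordering on a Cartesian grid, with sampling
  density reports.
* **Synthetic data** (`make_phantom`, `simulate_stack`,
  `paired_replicates`) — a digital 8-vial relaxometry phantom (T1
  236–2013 ms, T2 15–328 ms) imaged through the forward model with
  configurable B1+ fields and noise.
* **Evaluation statistics** (`bias_table`, `sensitivity_analysis`,
  `repeatability`, `roi_summary`, `correlate_with_diameter`) — accuracy
  tables, Monte-Carlo noise-sensitivity maps, within-subject coefficient of
  variation with Bland–Altman limits, and normality-gated correlation.

## Worked example

```r
library(ispgr)

p <- protocol_preset("invivo_ispgr")     # TR 3.5 ms, k = 30, T_FS = 202 ms,
p$measurements                           # FAs 25/20/10/4° at T_BS 13 ms,
                                         # FA 10° also at T_BS 20 and 35 ms

tissue <- tissue_params(T1 = 800, T2 = 50)   # vessel-wall-like tissue
round(model_vector(tissue, p), 4)
#> [1] 0.0902 0.0807 0.0624 0.0340 0.0522 0.0376
```

These are the six model intensities (arbitrary units, M0 = 1) the fit
inverts. Note the strong attenuation — the FA 10° signal drops from 0.0624
to 0.0376 as `T_BS` grows from 13 to 35 ms; that decay encodes T2.

```r
# the event-driven Bloch simulation converges to the closed form
train <- simulate_ispgr(tissue, seq_params(TR = 5, alpha = 15, k = 20,
                                           T_FS = 50, T_BS = 12, T_Sp = 6),
                        n_shots = 30)
convergence_time_to_model(train, rel_tol = 1e-3)
#> [1] 1251        # ms of sequence time

# joint T1/T2/M0 fit of one noisy voxel
set.seed(1)
y <- model_vector(tissue, p)
fit <- fit_voxel(y + rnorm(6, sd = y[3] / 30), p)
unlist(fit[c("T1", "T2", "M0", "converged")])
#>         T1         T2         M0  converged
#> 970.688050  46.422486   1.187433   1.000000

# digital 8-vial phantom, forward-simulated at SNR 30, fitted voxel-wise
ph <- make_phantom()
st <- simulate_stack(ph, p, noise = noise_model(snr = 30, seed = 1))
maps <- fit_volume(st, p, t2_bounds = c(10, 400))
bias_summary(bias_table(maps, ph$label,
                        data.frame(label = 1:8, T1 = ph$vials$T1,
                                   T2 = ph$vials$T2)))
#>   model parameter mean_error
#> 1   fit        T1  26.405134
#> 2   fit        T2   1.394914
```

The single noisy voxel illustrates the method's noise sensitivity (one
draw at SNR 30 moved T1 from 800 to 971 ms); averaging over a vial brings
the mean T1 bias down to ~26 ms here. Fitting the same prepared data with
the naive SPGR model instead (`model = "spgr"`) underestimates T1 on every
vial — the bias the semi-steady-state model exists to remove.

A thin command-line front end over the same functions ships in
`inst/cli/ispgr.R` with subcommands `trajectory`, `bloch`, `simulate`, and
`fit`.

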