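# cryopa

Simulation of how **cooling the intermediate medium improves
photoacoustic imaging depth**.

In photoacoustic (PA) imaging, the tissue between the light source and a
deep target absorbs light too and emits its own ultrasound transient —
a background that sets the noise floor for the target echo. The PA
amplitude at a point is

```
p0 = Γ · μa · F,        Γ = β v_s² / C_p
```

where `Γ` is the Grueneisen parameter, `μa` the optical absorption and
`F` the fluence. `Γ` of soft tissue falls by ~1.5 %/°C on cooling while a
target held at body temperature keeps its `Γ`; cooling the medium
therefore lowers the background but not the signal, improving SNR by

```
ΔSNR = 10 log10 | Γ(T_warm) / Γ(T_cold) |     (≈ 1.99 dB for 35 → 5 °C)
```

A smaller second mechanism helps: the reduced scattering `μs'` of
protein-rich tissue drops ~0.4 %/°C on cooling, so more fluence reaches a
deep target. `cryopa` simulates both mechanisms end to end:

* voxel **Monte-Carlo light transport** (Rcpp core; continuous
  absorption weighting, Henyey–Greenstein scattering, Russian roulette
  with exact energy bookkeeping),
* **temperature scaling** of `Γ`, `μs'` and the speed of sound,
* two **acoustic forward models** — velocity-potential shell
  decomposition for trace-domain SNR, and spherical-wave superposition
  for linear-array RF synthesis,
* **DAS / DMAS / double-stage DMAS beamforming** and image-domain SNR,
* an **experiment runner** sweeping scenario × depth × temperature into
  reproducible CSV/JSON tables.

## Worked example

```r
library(cryopa)

# Grueneisen-only scenario: one fluence realization per depth, cooling
# enters only through Γ of the medium; target pinned at 37 °C.
sw <- run_scenario_sweep("gamma_only", depths = c(10, 30),
                         temperatures = c(5, 20, 35),
                         n_photons = 2e4, seed = 3)
sw[, c("depth", "temperature", "pa_signal", "pa_noise", "snr_db")]
#>   depth temperature    pa_signal     pa_noise     snr_db
#> 1    10           5 5.662444e-04 2.316927e-03  -6.119085
#> 2    30           5 2.799769e-07 1.449362e-05 -17.140546
#> 3    10          20 5.662444e-04 2.989584e-03  -7.226068
#> 4    30          20 2.799769e-07 1.870144e-05 -18.247529
#> 5    10          35 5.662444e-04 3.662240e-03  -8.107429
#> 6    30          35 2.799769e-07 2.290927e-05 -19.128890

delta_snr_from_sweep(sw, t_warm = 35, t_cold = 5)
#>   depth delta_snr_db
#> 1    10     1.988344
#> 2    30     1.988344
delta_snr_analytic(35, 5, thermo_model())
#> [1] 1.988344
```

Reading this: `pa_signal` (the target's contribution at its arrival time
`t = z/v_s`) is *identical* across temperatures — the target's Γ never
changes — while `pa_noise` (the medium's shell emission at the same
arrival time) shrinks as the medium cools, so the SNR improves by exactly
the analytic Γ-ratio, 1.988 dB from 35 °C to 5 °C, at every depth.
Amplitudes are arbitrary units per unit launched pulse energy; only
ratios are meaningful.

The `analysis/` scripts run the study workflow in order and write tables
under `results/`:

```sh
Rscript analysis/01_temperature_models.R    # scaling laws + analytic ΔSNR
Rscript analysis/02_light_transport_checks.R  # Beer–Lambert & diffusion oracles
Rscript analysis/03_scenario_sweeps.R       # Γ-only / μs'-only / combined sweeps
Rscript analysis/04_imaging_experiment.R    # RF synthesis, DS-DMAS, image SNR
```

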