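---
title: "Simulating photoacoustic SNR enhancement by cooling the intermediate medium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating photoacoustic SNR enhancement by cooling the intermediate medium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In photoacoustic imaging a nanosecond laser pulse deposits optical energy
in tissue; thermoelastic expansion converts it into an ultrasound
transient detected at the surface. The amplitude generated at a point is

$$ p_0(\mathbf r) = \Gamma(\mathbf r)\,\mu_a(\mathbf r)\,F(\mathbf r), $$

with $\Gamma = \beta v_s^2 / C_p$ the (dimensionless, strongly
temperature-dependent) Grueneisen parameter, $\mu_a$ the absorption
coefficient and $F$ the local fluence. Deep targets are hard to image not
only because little light reaches them, but because the *intermediate
medium* between source and target emits its own photoacoustic transient —
a structured background that arrives at the detector at the same times as
the target echo and sets the noise floor.

Because $\Gamma$ of soft tissue falls by roughly 1.5 % per degree Celsius
of cooling while the target can be held at body temperature, cooling the
medium suppresses the background without touching the signal. A second,
smaller effect helps too: the reduced scattering coefficient $\mu_s'$ of
protein-rich tissue falls by about 0.4 %/degC on cooling, so more fluence
reaches a deep target. `cryopa` simulates both mechanisms end to end and
quantifies the resulting SNR gain.

## Pipeline

1. **Phantom** (`phantom_recipe()`, `build_slab_rod_phantom()`): a
   homogeneous slab with chicken-breast-like optics
   ($\mu_a = 0.3\,\mathrm{cm^{-1}}$, $\mu_s' = 10\,\mathrm{cm^{-1}}$,
   $g = 0.9$) containing a 1 mm square-section rod with
   $\mu_a = 30\,\mathrm{cm^{-1}}$ at a chosen depth (5–30 mm), lit by a
   uniform 1 cm beam.
2. **Thermal state** (`thermo_model()`, `apply_temperature()`): anchored
   linear scaling of $\Gamma$ and $\mu_s'$; three scenarios
   (`gamma_only`, `mus_only`, `both`) freeze one or neither property.
3. **Light transport** (`run_mc()`): voxel Monte Carlo.
4. **Acoustics** (`shell_decompose()`/`pa_trace_shell()` for trace-domain
   analysis; `pa_trace_superposition()` for array RF).
5. **Metrics** (`snr_db()`, `delta_snr_analytic()`, `image_snr()`) and
   orchestration (`run_scenario_sweep()`, `run_imaging_experiment()`).

A minimal trace-domain example:

```{r, eval = FALSE}
library(cryopa)
sw <- run_scenario_sweep("gamma_only", depths = 30,
                         temperatures = c(5, 35), n_photons = 1e5, seed = 1)
delta_snr_from_sweep(sw, t_warm = 35, t_cold = 5)   # ~1.988 dB
delta_snr_analytic(35, 5, thermo_model())            # identical
```

## The thermal model and its conventions

The literature quotes *percentage rates*: 1.5 %/degC for $\Gamma$,
0.4 %/degC for $\mu_s'$, without stating an anchor temperature or whether
the rate compounds. We adopt a **linear anchor convention**
$s(T) = 1 + r\,(T - T_{\mathrm{ref}})$ with $T_{\mathrm{ref}} = 20$ degC
(the midpoint of the 5–35 degC sweep); a per-degree compounding variant
$(1+r)^{T-T_{\mathrm{ref}}}$ is available via
`thermo_model(compounding = TRUE)` and every result table records which
convention produced it. The choice matters little — the 35→5 degC SNR
gain is 1.988 dB linear vs 1.940 dB compounded — and the anchor cancels
entirely from within-convention SNR differences. Supported range is
0–45 degC: above ~55 degC protein coagulation changes tissue optics
irreversibly and neither rate is trustworthy. Acoustic attenuation enters
only as the optional scalar `xi` (default 1, i.e. ignored): the evidence
for its low-temperature behaviour is inconclusive and the SNR ratio is
unaffected by any common factor.

The target is pinned at 37 degC in every standard sweep, so its
$\Gamma$ — and hence `pa_signal` — is *identical* across a sweep in which
only the medium temperature changes. That is not approximately true but
exactly true in the code, and the test suite asserts it at machine
precision.

## Monte-Carlo transport choices

Weighted photons take scattering-limited steps: the free path is sampled
from the local $\mu_s$ alone, directions from the Henyey–Greenstein
inverse CDF with the local $g$, and absorption is handled by
*continuous path-length weighting*: while a photon traverses a voxel over
length $\ell$, it deposits $w(1 - e^{-\mu_a \ell})$ there. Compared with
interaction-site deposition ($w\,\mu_a/\mu_t$ per collision) this
estimator has lower variance and is *exact* for non-scattering media,
which turns the Beer–Lambert check into a sharp test (observed error
$\sim 10^{-4}$, dominated by voxel-centre vs. voxel-average evaluation)
rather than a statistical one. Russian roulette (threshold $10^{-4}$,
survival 0.1) terminates low-weight photons unbiasedly; its kills and
survival boosts are tallied so that

```
deposited + escaped + roulette_lost - roulette_gained = launched
```

holds to floating-point accuracy on every run — the packaged tests
require $10^{-9}$ relative. Boundaries are matched (no Fresnel
reflection; the refractive indices are not part of the study) and
escaping photons are tallied. Randomness is counter-based: photon $i$ of
a run with seed $s$ draws from a splitmix64 substream keyed by $(s, i)$,
so a fixed seed gives bit-identical maps on any platform and two runs
with equal seeds share their randomness photon by photon (common random
numbers for paired temperature contrasts).

**Grid.** The default slab is $64 \times 64 \times 32$ mm at 0.5 mm
voxels. The lateral extent is deliberately twice the deepest target
depth: the shell noise model (below) integrates over hemispherical shells
centred on the detector, and with a slab only as wide as the deepest
shell radius every shell voxel is roughly equidistant from the co-located
source and detector, which suppresses the scattering-scenario SNR effect
by construction. With full hemispheres the cooled-scattering improvement
at 30 mm is positive (~1.5 dB for 35→5 degC) and smaller than the
Grueneisen-only gain, the expected qualitative ordering.

## Acoustic forward models

**Shell model (trace domain).** All voxels whose distance to the detector
falls in $[r - \mathrm dr/2, r + \mathrm dr/2)$, $\mathrm dr = v_s\,
\mathrm dt$, contribute at arrival time $t = r/v_s$. Binning the
deposited energy by shell, separately for background- and
target-labelled voxels, gives the background trace
$\Gamma_{\mathrm{out}} E_{\mathrm{shell,bg}}(t)$ and target trace
$\Gamma_{\mathrm{in}} E_{\mathrm{shell,target}}(t)$. Each trace is
exactly linear in its own region's $\Gamma$ — this is the mechanism that
makes the analytic prediction
$\Delta\mathrm{SNR} = 10\log_{10}|\Gamma(T_1)/\Gamma(T_2)|$ an exact
oracle under the shared-fluence protocol. Sweeps use $\mathrm dt =
0.4\,\mu s$ (shell thickness 0.6 mm, comparable to the rod), which keeps
the per-shell Monte-Carlo variance low; amplitudes are read at the
arrival gate $t = z/v_s \pm 3$ samples (discrete sampling makes a point
evaluation ill-defined; the gate width is configurable).

**Spherical-wave superposition (array RF).** For beamforming we need
per-element time series. Every voxel is treated as an impulsive uniform
spherical source of the voxel's volume in a homogeneous lossless medium;
its exact bipolar far-field waveform $p_0 (r - v_s t)/(2r)$ over
$|r - v_s t| \le a$, convolved in closed form with a box over the voxel's
radial footprint, is evaluated at the sample times and accumulated. This
is algebraically the time derivative of the velocity potential
($p = -\rho\,\partial\varphi/\partial t$) but avoids numerically
differencing a voxel-quantized arrival histogram, which we measured to
amplify lattice quantization noise far above the signal. Against the
textbook uniform-sphere N-wave (radius 1 mm, observer 10.05 mm,
partial-volume voxelization at 25 µm, 20 samples across the N-wave) the
relative $L_2$ error is 2.4 %. Two numerical caveats are deliberate:
the source radius is inflated to $0.55\,v_s\,\mathrm dt$ (with
charge-conserving amplitude rescaling) when the sampling is coarser than
the voxel, and a *single isolated* voxel whose arrival aligns exactly
with a sample can be underrepresented when $v_s \mathrm dt$ exceeds its
waveform width — dense source distributions are unaffected, but
point-target fixtures should use $v_s\,\mathrm dt$ no larger than about
the voxel size. The transducer's band-pass response and element
directivity are not modelled; frequency-dependent acoustic attenuation
and heterogeneous sound speed are out of scope.

**Protocols.** The subtraction protocol `PA_signal = PA_true -
PA_noise` is implemented in `signal_noise_split()`; the signal is gated
on the *difference trace* so that, when the target-present and
target-free traces share one fluence realization, the result is exactly
the target's own contribution. In the Grueneisen-only scenario one
Monte-Carlo realization per depth is reused across all temperatures
(temperature enters only through $\Gamma$), making Monte-Carlo noise a
common factor; scattering scenarios genuinely change the fluence and are
re-simulated per temperature with per-condition seeds.

## Beamforming and the image metric

`das()` sums delayed element samples; `dmas()` computes the pairwise
delay-multiply-and-sum $\sum_{i<j}\mathrm{sign}(s_i s_j)\sqrt{|s_i
s_j|}$ via the signed-root identity (making it $O(N)$ per pixel);
`ds_dmas()` applies DMAS within subapertures (default 8 of 128 elements)
and again across the subaperture outputs. The exact double-stage variant
in the literature differs in details that are not specified consistently;
since only the image-domain SNR of the result is consumed downstream, any
pairwise-DMAS-squared scheme with the same localization behaviour serves.
No apodization; an optional Hilbert-envelope step (`envelope_image()`)
exists behind a flag and is off by default. Delays are one-way times of
flight with linear interpolation between samples; pixels whose delay
exceeds the record are zeroed.

Image SNR is $10\log_{10}(\max I^2 / \sigma_b^2)$ with $\sigma_b^2$ the
pixel variance over the background: all pixels farther than 3 mm from the
detected peak, excluding a 1 mm border. In the full-field synthetic
images the brightest pixels are shallow clutter directly under the beam
entry, not the target, so the peak search is restricted to ±1.5 mm around
the known rod position ("peak intensity of the imaging target") and the
image starts at 5 mm depth. Before beamforming, the RF is high-pass filtered
(`highpass_rf()`: moving-average subtraction, ~1 µs window). The medium's
bulk emission is spatially smooth and hence temporally slow at the array;
without this standard slow-clutter rejection it buries the deep rod in
every image. No band-pass or directivity is imposed — the transducer's
5 MHz response remains unmodelled. The default sensor noise (standard
deviation $6\times10^{-8}$, about 10 % of the high-passed clutter RMS of
the standard phantom over the imaged depth band, per unit launched
energy) is a fixture choice, not a measured value: it keeps the
background dominated by the medium's own emission — the mechanism under
study — while making repeated frames distinct.

## What the synthetic data do and do not emulate

The generator reproduces the study conditions: slab-with-rod geometry,
the 5–30 mm × 5–35 degC condition grid with the target pinned at 37 degC,
uniform 1 cm illumination, a 128-element 0.3 mm-pitch linear array, and
i.i.d. Gaussian sensor noise across samples, elements and frames. It does
not emulate: heterogeneous real tissue, the transducer's 5 MHz band-pass
and directivity, laser pulse-to-pulse energy fluctuation, acoustic
attenuation or reflection, thermometer drift, or temperature-dependent
*absorption* (deliberately excluded from the study's scope). Passing
tests therefore demonstrate the internal consistency of the model chain
and the sign and rough size of the cooling effect — not calibrated
absolute SNRs for any real system.

## Problem sizes and determinism

Default runs use $10^5$ photons for tests and quick sweeps and $10^6$ for
the scattering-scenario comparisons (whose effect sizes must clear their
Monte-Carlo standard errors; these are estimated by photon batching, 20
batches per run). Everything downstream of a seed is deterministic:
photon `i` of a run draws from a counter-based substream keyed by
`(seed, i)`, so maps are bit-identical across platforms; sweeps
re-exported from the same inputs are byte-identical; and a per-condition
cache (`cache_dir`) lets interrupted sweeps resume without recomputation.
Scattering-scenario conditions at the same depth share their seed across
temperatures (common random numbers), which pairs the runs and tightens
temperature contrasts. The analysis scripts under `analysis/` run the condensed
condition grid (depths 10/20/30 mm, three temperatures) in a few minutes
each; `analysis/03_scenario_sweeps.R --full` runs the full 6 × 7 grid.

## Known limitations

* The shell noise model ignores acoustic diffraction and treats the
  detector as a point; the superposition model adds aperture averaging
  but not element directivity.
* Absolute amplitudes are in arbitrary units per unit launched energy;
  only ratios (SNR, gains) are meaningful.
* The scattering-scenario SNR gain depends on the slab being much wider
  than the deepest shell radius (see above); narrow phantoms suppress it.
* Image-domain SNR at 30 mm is strongly negative in these units because
  the deep target is far dimmer than mid-depth clutter; the cooling
  *gain* is still positive and is what the experiment measures.
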