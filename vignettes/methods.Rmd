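---
title: "Methods: coupled broadband-NIRS and EEG analysis of the infant brain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled broadband-NIRS and EEG analysis of the infant brain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnirseeg)
```

## The scientific problem

Functional specialisation of the infant cortex is usually probed with one
modality at a time: haemodynamics (fNIRS/fMRI) or electrical activity (EEG).
`bnirseeg` implements a multimodal pipeline that couples *three* signals
measured simultaneously in awake infants: oxygenated and deoxygenated
haemoglobin changes (Δ[HbO₂], Δ[HHb]) and the oxidation state of cytochrome-c
-oxidase (Δ[oxCCO]) — a direct optical marker of mitochondrial energy
metabolism, resolvable only with *broadband* NIRS — together with
band-limited EEG power. The scientific question is whether specific cortical
sites (the temporo-parietal junction in particular) show coordinated neural,
haemodynamic and metabolic responses that are selective for social versus
non-social stimulation.

Because infant recordings of this kind are not openly shareable, the package
ships a synthetic-data generator that emulates the study design and plants
known coupling structure, so every stage of the pipeline is testable from
scratch.

## The experimental design being emulated

Sessions open with a ≥10 s rest, then alternate 8 s baseline blocks (static
images shown 1–3 s each) with social / non-social video blocks of 8–12 s,
conditions strictly alternating. `generate_schedule()` reproduces this
design. bNIRS samples on a 1.4 s grid (the source time-multiplexing period —
the only acquisition timing stated for the instrument; see *Numerical
choices*), over a 4-source × 14-detector probe forming 19 channels at 2.5 cm
separation. EEG uses 32 labelled 10/20 electrodes at 500 Hz.

## Forward model and chromophore resolution

Attenuation changes follow the modified Beer–Lambert law,

$$\Delta A(\lambda, t) = \sum_{i} \varepsilon_i(\lambda)\,\Delta c_i(t)\, d\,
\mathrm{DPF},$$

with $d$ the source–detector separation and DPF the differential pathlength
factor, fixed at the age-appropriate 5.13 (a DPF(λ) vector is accepted).
`ucln_invert()` solves the least-squares multiwavelength system over the
wavelengths in 780–900 nm, yielding the three chromophores simultaneously;
`forward_attenuation()` is its exact forward counterpart, so noise-free
round trips recover concentrations to ≤1e-9 µM (a property the tests
enforce). Adding wavelengths strictly reduces the noise sensitivity of the
inversion; the tests check the 3 → 120 wavelength error monotonicity.

The bundled extinction asset (`extinction_synthetic.csv`) is a **synthetic**
smooth approximation of the compiled literature spectra (Hb isosbestic point
near 798 nm, broad oxCCO band near 830 nm), and is clearly labelled as such;
every quantitative test instead uses `synthetic_extinction()`, a
deterministic full-rank spectral triple, so no numerical claim rests on the
asset. Attenuation is treated in natural-log OD; a log₁₀-convention table
would only rescale the recovered concentrations.

## Motion correction

`wavelet_motion_correct()` applies, per channel and wavelength, a periodic
Daubechies-5 discrete wavelet transform (implemented in the package;
orthonormality and perfect reconstruction are tested) at the conventional
maximum useful depth, zeroing detail coefficients outside the interquartile
fence $[Q_1 - \alpha\,\mathrm{IQR},\; Q_3 + \alpha\,\mathrm{IQR}]$ at each
level, with the tuning parameter α = 0.8. Motion artifacts are sparse,
large detail coefficients and are strongly attenuated (≥50 % peak reduction
in tests); smooth physiology, concentrated in the approximation band and
within the per-level fences, passes through with interior distortion below
5 %. Two numerical caveats are deliberate: signals are reflect-padded to a
power of two, so the first/last ~30 s carry boundary transients; and zeroing
a coarse-level coefficient spreads over that coefficient's support (~±30
samples around a spike). Both are documented rather than hidden, and the
tests evaluate fidelity away from these regions.

## Filtering

All filters are zero-phase (forward–backward) Butterworth designs, chosen so
block averages are not phase-shifted; the stated orders follow the
MATLAB-style convention in which `butter(n, [lo hi])` yields a band-pass of
order 2n. Chromophore series use a fourth-order 0.01–0.4 Hz band-pass. At
the 1.4 s sampling period the Nyquist frequency is ≈0.357 Hz, below the
stated 0.4 Hz upper edge; the package clamps the edge just below Nyquist
with a warning instead of guessing an unstated faster acquisition rate. EEG
uses a 0.1–100 Hz band-pass plus a 48–52 Hz notch.

## EEG processing

After filtering, channels are re-referenced to the average; channels whose
1 s segments exceed 200 µV more than 30 % of the time are flagged and
rebuilt by inverse-distance-weighted interpolation of their three nearest
good neighbours on the bundled montage (a simple, stated replacement for
toolbox-specific interpolation). Blocks (baseline + following stimulus) are
cut into 1 s segments of exactly `fs` samples — the last 200 ms of the
previous second plus 800 ms of the current one — and the leading 200 ms
mean is subtracted (*within-segment baseline correction*). The first
stimulus segment's carryover therefore comes from the final 200 ms of the
baseline. Segments overlapping inattention (a Bernoulli mask in the
generator, standing in for video-coded attention) or exceeding 200 µV are
rejected.

Band RMS power is computed per segment, channel and band — theta 3–6,
alpha 8–12, beta 13–30, gamma 20–60, high-gamma 60–80 Hz (the beta/gamma
overlap is intentional and kept as defined) — as the RMS of the band-passed
signal over the segment's unique 800 ms. The band filter is applied to the
continuous record before windowing: the within-segment DC correction
carries no band-limited power, so this is equivalent to filtering each
segment while avoiding 1 s-window edge transients; an FFT band-power
variant was considered and rejected as it changes the metric, not just the
estimator. *Block baseline correction* subtracts the mean RMS over the
final 2 s of the baseline (interpreted as the last 2 s before onset) from
the whole block; blocks are then averaged per condition, keeping 8 baseline
seconds and the first 8 s of the stimulus period — the same 8 s window that
enters the coupling GLM, which also resolves the ambiguity of averaging
8–12 s blocks of unequal length. Group condition statistics are paired
t-tests across subjects on stimulus-averaged RMS (social−baseline,
nonsocial−baseline, social−nonsocial) with Benjamini–Hochberg FDR across
the montage channels within each band and contrast.

## Infant response functions

The canonical adult haemodynamic response function cannot be assumed for
infants, and no metabolic analogue exists at all, so both are reconstructed
from the data. The basis is a double gamma,

$$h(t) \propto g(t;\,a_r,\,1) - \tfrac{1}{r}\,g(t;\,a_u,\,1),$$

with $g$ a gamma density, unit scale (so the "delay" parameters $a_r, a_u$
are the gamma shapes — the convention under which the adult canonical basis
is (6, 16, 6)), peak-normalised to 1 with $h(0)=0$. `grid_search_hrf()`
evaluates every combination of response delay 5–15 s, undershoot delay
5–20 s and response:undershoot ratio 2–6 in steps of 1 (880 models) against
a grand-average response: OLS on an intercept plus the boxcar-convolved,
**standardised** kernel regressor. Standardising the regressor makes the
fitted β equal to $\mathrm{cor}(x, y)\,\mathrm{sd}(y)$, so "highest
significant β" is a genuine best-fit criterion, invariant to the
kernel-dependent regressor norm — without it the selection would depend on
arbitrary scale and noise-free self-recovery would not hold. Significance
uses p < 0.05 (uncorrected; no threshold is otherwise specified), ties
resolve lexicographically on (response delay, undershoot delay, ratio) —
real ties exist: when both delays coincide the ratio cancels out of the
normalised kernel. If nothing is significant the best fit is returned
flagged.

Two behaviours of this estimator are worth knowing. First, the maximum-β
rule is polarity-sensitive: HHb responses are negative-going, and fitting
them directly selects the basis whose *undershoot* mirrors the response
rather than the basis generating it — the demonstration workflow shows
this. Second, the 0.01 Hz high-pass applied before block averaging shifts
the apparent response timing (a noise-free planted (8, 7, 2) basis is
recovered as roughly (9–11, ·, ·) after filtering); grid-search results on
filtered pipeline data describe the *filtered* response, which is exactly
what then enters the coupling GLM built from the same filtered data.

Self-consistency is the key property: noise-free grand averages generated
from any grid point are recovered *exactly* (tested over a thinned
sub-grid), and in particular the infant best-fit bases — response delay 8 s
for HbO₂/HHb and 9 s for oxCCO (2 s and 3 s later than the adult 6 s, the
orientation consistent with infants' delayed haemodynamics), undershoot 7 s
(9 s earlier than the adult 16 s) and ratios 2 and 3 — are recovered by the
880-model search. White-noise grand averages are flagged non-significant at
a rate bounded well below certainty (the 880-model search inflates the
per-average false-positive rate above the nominal 5 %, which is why the
recovered flag matters).

## Coupling GLM

The analysis is restricted to the bNIRS channels that showed significant
haemodynamic–metabolic coupling in the prior analysis of this cohort; those
per-condition, per-chromophore lists are consumed as printed inputs and
their sorted union — channels 11, 12, 13, 14, 16, 18 — is used everywhere
(`select_coupling_channels()`).

For each (EEG channel, band, chromophore) cell the neural regressor follows
the stated double convolution literally: kernel ⊛ stimulus boxcar gives the
"predicted" bNIRS series on a 1 s working grid; that series is then
convolved (causal, same-length, onset-anchored — edge handling is not
otherwise specified) with the subject's stimulus-period RMS block, linearly
interpolated onto the 1.4 s bNIRS grid, and z-scored so β is comparable
across cells. A conventional alternative (RMS ⊛ kernel) is available behind
`mode = "rms_conv_kernel"` for sensitivity analysis. The subject GLM fits
the concatenated social and non-social block-averaged 8 s windows in one
design with two condition-specific regressor columns plus an intercept —
"both conditions together", while still yielding a per-condition β; fitting
block-averaged windows (rather than the continuous recording) follows the
8 s stimulus-period restriction of the averaged RMS. Group statistics are
one-sample t-tests of β against zero with BH-FDR applied across the six
bNIRS channels within each (EEG channel, band, chromophore, condition)
family — exactly the six channel-wise tests per hypothesis of the design;
EEG channels are not corrected over. The social-vs-nonsocial comparison is
a paired t-test on per-subject β differences with the same family
structure. Zero-variance cells are reported as NA rather than silently
dropped.

## What the synthetic generator emulates — and what it does not

The generator reproduces: the block design; linear time-invariant
chromophore responses (boxcar ⊛ double-gamma, the forward analogue of the
GLM); the Beer–Lambert forward model with Gaussian OD noise; brief motion
spikes shared across a channel's wavelengths (motion disturbs optode
coupling, not chromophores); synthetic detector counts for the QC rules;
1/f EEG background with condition-locked narrowband amplitude modulation;
injected >200 µV artifacts; and a Bernoulli inattention mask (video-coded
attention is not reproducible). It does **not** model vascular biophysics,
head geometry, photon transport, cardiac/respiratory physiology or real
electrode noise; passing tests therefore demonstrate the *statistical*
correctness of the pipeline (recovery, calibration, FDR control) on data
satisfying the model's assumptions, not robustness to every physiological
confound of real infant recordings.

One consequence of faithful emulation: average re-referencing spreads a
planted oscillation into every channel (−1/n of the burst), so in small
montages the "null" EEG channels of a planted band/condition carry genuine
condition-locked structure. The planted-coupling false-positive analysis
accounts for this by assessing FDR control on the families that are null by
construction.

## Problem sizes and statistical checks

The replicate studies use deliberately reduced problem sizes — e.g. the
100-cohort planted-coupling study runs 10-subject cohorts (5 trials, 3 EEG
channels, two bands, 250 Hz EEG, 16 wavelengths) — chosen so the whole
validation remains desk-scale while keeping every stage of the pipeline in
the loop; the demonstration workflow under `analysis/` uses a 14-subject
cohort, matching the joint-analysis sample of the emulated study. Per-family
BH control is what the procedure guarantees (for an all-null family the FDR
equals the family-wise error), so the acceptance property asserts that the
fraction of null families with any discovery stays within binomial error of
the nominal q = 0.05, and that the planted cell is recovered in ≥90 % of
cohorts.

## Known limitations

* The bNIRS acquisition rate is taken to be the 1.4 s multiplexing period;
  if the true instrument rate were faster, the 0.4 Hz filter edge would not
  need clamping and block averages would be better resolved.
* Wavelet correction quality is assessed in the signal interior; boundary
  seconds of a recording are less trustworthy after correction.
* The haemodynamic–metabolic coupling statistic that selected the six
  analysis channels is not re-derived; its printed channel lists are inputs.
* EDF and SNIRF containers are out of scope; the tabular dialects carry the
  same information for every operation implemented here.
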