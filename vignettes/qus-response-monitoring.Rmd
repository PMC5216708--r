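---
title: "Multi-parameter QUS monitoring of tumor response: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-parameter QUS monitoring of tumor response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Quantitative ultrasound (QUS) characterizes tissue microstructure from the
frequency content of raw radiofrequency (RF) backscatter, before envelope
detection discards it. During effective chemotherapy, tumor cell death
changes the size, concentration and organization of the acoustic scatterers
well before the tumor shrinks; QUS parameters therefore move within weeks,
while diameter-based response criteria need months. `quspred` implements a
seven-parameter QUS pipeline for predicting the response of locally
advanced breast tumors to neoadjuvant chemotherapy from serial scans
(pre-treatment and weeks 1, 4, 8), together with the classification and
survival analyses that turn the parameters into a response call, and a
point-scatterer RF simulator that makes every estimator testable by
parameter recovery.

## The measurement model

A scan of one image plane is a matrix of beamformed RF lines sampled at
40 MHz from a 6 MHz linear array. The tumor ROI is tiled with 2 x 2 mm
analysis blocks at 80% overlap in both directions (about 10 spatial pulse
lengths axially and 5.5 beamwidths laterally, the minimum for stable
spectral estimates). A block is kept when at least 90% of its area lies
inside the ROI, so border blocks are excluded rather than padded — the
ROIs this emulates are drawn in the tumor center precisely to avoid
attenuation artifacts at the margins.

Each block's power spectrum is the across-line average of Hann-windowed
periodograms, zero-padded to at least four times the block length (grid
step below 0.1 MHz). All spectral quantities are handled in the 3–8 MHz
band, the system's −6 dB bandwidth.

**Reference-phantom normalization.** Dividing (subtracting in dB) the
spectrum of a tissue-mimicking phantom with known properties — attenuation
0.15 dB/cm-MHz, sound speed 1515 m/s, 18 µm glass microspheres — cancels
the transmit pulse, receive electronics and diffraction, leaving relative
tissue backscatter in dBr. Because the phantom is static, its spectra may
be averaged over as many independent planes as desired; the pipeline pools
several phantom realizations into the per-depth reference bank so that
reference speckle does not limit downstream fits.

**dB bookkeeping.** One convention is used throughout: attenuation
`alpha` in dB/cm-MHz is a one-way amplitude coefficient, and since an
amplitude ratio expressed in dB equals the corresponding power ratio in
dB, the round-trip loss on a power spectrum at depth `z` cm is
`2 alpha f z` dB. Point attenuation compensation therefore adds
`2 A(f)` dB with `A(f) = (alpha0 x0 + alpha1 x1) f`, where `alpha0 = 1`
dB/cm-MHz is the assumed intervening-breast-tissue coefficient over the
path `x0` above the ROI (from ultrasound tomography measurements) and
`alpha1` is the tumor's own estimate over the path `x1` from ROI top to
block center.

## The seven parameters

**ACE** (attenuation coefficient estimate, dB/cm-MHz). Reference phantom
method: normalized block spectra are averaged across laterally adjacent
blocks, and the slope `s(f)` (dB/cm) of normalized magnitude versus depth
is fitted at every frequency in the band. Under the convention above the
slope is `-2 f (ACE - alpha_ref)`, so `ACE = alpha_ref - mean_f s(f)/(2f)`.
The fit needs at least three distinct block depths. On noiseless spectra
constructed from the attenuation law the estimator is exact; on simulated
speckle it recovers a planted 1.0 dB/cm-MHz within a few percent on
20-seed ensembles.

**MBF, SS, SI** (midband fit dBr, spectral slope dBr/MHz, spectral
intercept dBr). Ordinary least squares of the attenuation-corrected
normalized spectrum on frequency over 3–8 MHz. SI is the intercept at
0 MHz, SS the slope, and MBF the fitted value at the band center
(5.5 MHz), so `MBF = SI + 5.5 SS` identically. MBF tracks integrated
backscatter (energy efficiency of the scattering); SS falls as scatterers
grow; SI mixes size and acoustic concentration.

**ASD, AAC** (average scatterer diameter µm; average acoustic
concentration, dB-relative concentration). The backscatter coefficient is
estimated as `BSC(f) = BSC_ref(f) 10^(dBr(f)/10)` with the reference BSC
given analytically by the Gaussian form-factor model
`BSC = C n gamma^2 f^4 exp(-0.827 k^2 a^2)` (Insana–Hall
parameterization; `C` a fixed scale constant — only relative AAC survives
normalization, so AAC is reported as `10 log10(n gamma^2)` in dB). The
model is fitted in the log domain, where `ln(BSC/f^4)` is linear in `f^2`
with slope `-0.827 (2 pi / c)^2 a^2`; `ASD = 2a`. A non-physical positive
slope is clamped to `ASD = 0` and flagged, and fits with `ka > 1.2` at
8 MHz carry a validity warning. The fit also reports the signed,
unclamped `a^2`; ensembles should average `a^2` before the square root
(`pooled_asd_um()`), because the square root biases averages of noisy
per-fit diameters downward. ASD is the most attenuation-sensitive
parameter: a 0.04 dB/cm-MHz ACE error tilts the spectrum enough to shift
`a^2` by half its value at small radii, which is why per-tumor estimates
pool spectra over several image planes.

**SAS** (spacing among scatterers, mm). Coherent, quasi-periodic scatterer
arrangements imprint a comb of period `c/(2d)` on the power spectrum. Per
block and scan line, an autoregressive power spectrum is estimated with
Burg's recursion at order 50 (AR spectra of 2 mm gates show far more
conspicuous combs than FFT periodograms and no gate ringing; the order is
a configuration knob). The AR spectrum, evaluated on a dense 0.02 MHz
grid, is normalized in dB by a planar-reflector (Plexiglas–water) spectrum
from a pre-recorded bank at depths 1–6 cm, choosing the depth nearest the
block (ties toward the shallower). The linear-power spectrum is
mean-subtracted, its autocorrelation over frequency lag is averaged across
the block's lines, and the spacing is `SAS = c/(2 Δf*)` at the peak lag
`Δf*`. Peak selection uses a first-dominant rule: the earliest local
maximum in the 0.2–2.5 MHz search window reaching at least half the
height of the tallest in-window peak. The comb's harmonics produce
secondary autocorrelation peaks at multiples of the fundamental, and a
plain argmax locks onto them often enough to halve the median recovered
spacing; the dominance rule restores the fundamental. Blocks with no
qualifying peak report SAS as missing, never zero.

## From blocks to patients to a response call

Block maps are summarized per tumor by the mean (median for SAS, whose
per-block estimates may be missing). Classification uses baseline-
normalized features: `dX(w) = X(w) - X(0)` for each parameter at the
chosen week, which removes between-patient echogenicity differences;
optionally the week-0 absolute values ride along as `(X_wk0, dX)` pairs.

The classifier is k-nearest-neighbor with k = 2 under the Euclidean
metric. Features are z-scored on each training fold (Euclidean distance
across dBr, mm and dB/cm-MHz is meaningless otherwise), a split vote
falls back to the nearest neighbor's class, and exact distance ties break
toward the lower training index. Class imbalance (42 responders vs 16
non-responders in the study cohort) is handled by drawing the balanced
class size with replacement from the majority class, keeping every
minority patient; evaluation is leave-one-patient-out, with all resampled
copies of the held-out patient removed from the training fold — leaving
duplicates in would let the query match itself at distance zero and
inflate every metric, so the leakage-free variant is the default.
Sensitivity, specificity and accuracy are averaged over 10 resampling
repeats and reported with their across-repeat SD. Feature selection is
exhaustive over all subsets of sizes 2–7 of the seven parameters (120
subsets); accuracy is the objective, ties prefer the smaller subset, then
lexicographic order. With baseline pairs included the column count
doubles but the enumeration is unchanged.

Survival comparison is the Kaplan–Meier product-limit estimate per
predicted response group with a two-group log-rank test (hypergeometric
variance, standard tie handling), both delegated to the `survival`
package; per-parameter group comparisons use the right-tailed
pooled-variance unpaired t-test (Welch behind a flag).

## The simulator and what it does (not) show

The simulator realizes point-scatterer fields in the imaged plane:
diffuse scatterers with Poisson counts, uniform positions and zero-mean
Gaussian amplitudes, plus an optional coherent component of axial layers
at the planted spacing (position jitter SD = 5% of the spacing). Number
density is volumetric (per mm³) realized over a 2 mm elevational slice —
a typical linear-array beam width — so the phantom recipe's 2.2 g/L of
18 µm glass translates to its actual ~290 spheres/mm³. Echoes are placed
at round-trip delays with fractional-sample interpolation, attenuated
segment-wise with the exact per-depth law `10^(-2 alpha f z / 20)`
(short-time Fourier segments with constant-overlap-add Hann windows), and
filtered by a Gaussian pulse spectrum (6 MHz center, −6 dB band covering
3–9 MHz) times the square root of the same Gaussian form factor the BSC
analysis fits — so form-factor recovery is exact in the noiseless limit
by construction, and what the recovery tests measure is robustness to
speckle, attenuation and estimation error, not model mismatch. White
electronic noise enters at a configurable SNR (40 dB default).

What the simulator does not model: diffraction and elevational focusing,
nonlinear propagation, frequency-dependent scattering beyond the form
factor, spatially heterogeneous tumors, and any biophysical mechanism
linking therapy response to microstructure. The synthetic cohort plants
the observed effect *directions* — backscatter intensity (MBF/SI/AAC) and
attenuation rise in responders, flat in non-responders — with magnitudes
chosen once (responder echogenicity gain 6 ± 2.5 dB at week 4 against a
2 dB null SD; attenuation shift 0.3 ± 0.1 dB/cm-MHz) to give roughly 80%
separability, so that pipeline regressions are detectable without making
the task trivial. Passing end-to-end tests therefore demonstrates that
the chain recovers planted effects of plausible size, not that real
tumors are classifiable at any particular accuracy.

For spacing recovery the lattice amplitude is set to 6 diffuse-amplitude
units (about twice the diffuse RMS per resolution cell): a coherent
component of comparable or greater power than the diffuse background is
the regime in which mean-scatterer-spacing analysis is meaningful, and
the same conspicuity consideration motivates the AR-order default.

## Numerical choices and problem sizes

- Hann windows everywhere a window is needed; block FFT length = next
  power of two ≥ 4 × block samples.
- Reference spectra are depth-binned at the block grid and matched to
  sample blocks by nearest depth; ACE excludes nothing by default (an
  SNR-based frequency mask is a config hook, unnecessary on simulated
  data at 40 dB SNR).
- SAS: AR order 50, search window 0.2–2.5 MHz, lag-0 exclusion of two
  grid cells, dominance fraction 0.5, parabolic peak interpolation.
- The week-0 rows of delta tables are identically zero and are never fed
  to the classifier; patients missing week 0 are dropped from that
  week's analysis only, with a logged message.
- Recovery experiments use 20-seed ensembles on ~40-line frames with
  12 × 11 mm ROIs (three pooled image planes per tumor for the size
  ladder, four pooled phantom planes in the reference bank); the
  end-to-end experiment scales the cohort to 10 + 10 patients at weeks
  0 and 4. These sizes were chosen so the whole validation runs in
  minutes on a single core while leaving ensemble standard errors well
  inside the stated tolerances.

## Known limitations

- The BTS (bulk tumor shrinkage) values printed in the packaged clinical
  table are authoritative even where they cannot be reproduced exactly
  from the printed focus dimensions (rounding and unstated focal sums);
  recomputed values are kept alongside for transparency.
- Four patients in the table carry a pathology-override flag where the
  recorded response contradicts the shrinkage/cellularity rule; the
  override (pathology wins) is applied, and any further disagreement is
  listed by the loader rather than silently fixed.
- ASD below ~20 µm diameter approaches the resolution limit of a 3–8 MHz
  band: the form-factor signal spans < 1 dB across the band, so single
  fits are noise-dominated and only pooled estimates are meaningful.
- Follow-up times for the real cohort are not public; all survival
  demonstrations run on the synthetic cohort with a configurable hazard
  ratio.
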