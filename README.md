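# quspred

Multi-parameter quantitative ultrasound (QUS) analysis of raw
radiofrequency (RF) echo data for early prediction of breast-tumor
response to neoadjuvant chemotherapy.

Anatomical response criteria need months of treatment before tumor
diameters move; the frequency content of ultrasound backscatter reacts to
therapy-induced changes in tissue microstructure within weeks. `quspred`
implements the full analysis chain from raw RF frames to a response call
and survival comparison:

- **Block processing**: tumor ROIs tiled with 2 x 2 mm RF blocks at 80%
  overlap; per-block Hann-periodogram power spectra over the 3–8 MHz band.
- **Reference-phantom normalization and attenuation**: spectra normalized
  by a phantom with known properties (0.15 dB/cm-MHz, 1515 m/s, 18 µm
  glass microspheres); the tumor attenuation coefficient estimate
  (**ACE**) from the spectral-difference slope
  `ACE = α_ref − mean_f s(f)/(2f)`; point attenuation compensation
  `+2 A(f)` dB with `A(f) = (α₀x₀ + α₁x₁) f`.
- **Linear spectral fits**: midband fit (**MBF**), spectral slope
  (**SS**), spectral intercept (**SI**), with `MBF = SI + SS·f_c`
  (`f_c` = 5.5 MHz).
- **Backscatter-coefficient model fits**: Gaussian form factor
  `BSC ∝ f⁴ exp(−0.827 k²a²)` fitted in the log domain, yielding average
  scatterer diameter (**ASD** = 2a) and acoustic concentration (**AAC** =
  10 log₁₀ nγ²).
- **Spacing among scatterers** (**SAS**): Burg autoregressive (order 50)
  block spectra, planar-reflector normalized (bank at 1–6 cm), spectral
  autocorrelation, `SAS = c/(2Δf*)` at the first dominant peak lag.
- **Classification**: baseline-normalized Δ-features, 2-nearest-neighbor
  classifier with per-fold z-scoring, class balancing by resampling,
  leave-one-patient-out evaluation averaged over 10 repeats, and
  exhaustive feature-subset search (all 120 subsets of sizes 2–7).
- **Survival**: Kaplan–Meier curves per predicted response group,
  two-group log-rank test, right-tailed pooled-variance t-tests.
- **Simulator**: point-scatterer RF synthesis with known ground truth
  (attenuation, scatterer size, concentration, spacing), reference
  phantom and planar reflectors, plus a longitudinal synthetic cohort —
  so every estimator is validated by parameter recovery.

The packaged clinical table (`inst/extdata/clinical_cohort.csv`) holds the
58-patient cohort (age, tumor dimensions, bulk tumor shrinkage,
cellularity notes, response), from which the cohort summaries are
recomputed.

## Worked example

Simulate a tumor-like medium with a planted attenuation of 1.0 dB/cm-MHz
and 25 µm effective-radius scatterers, and recover the QUS parameters:

```r
library(quspred)

acq <- acq_params(n_lines = 40, n_samples = 1200)
medium <- medium_spec(attenuation = 1.0, scatterer_radius_um = 25,
                      number_density = 100)
field <- sample_field(medium, acq_volume(acq, medium$sound_speed), seed = 1)
frame <- synthesize_rf(field, pulse_spec(), acq, medium, noise_seed = 2)

ref_bank <- build_reference_bank(synthesize_reference(acq, seed = 3))
roi <- roi_from_rect(frame, lines = c(2, 39), depth_mm = c(6, 18))
res <- extract_qus_features(frame, roi, ref_bank, alpha0 = 0, x0_cm = 0)
round(res$features, 2)
#>   MBF    SS    SI   SAS   ACE   ASD   AAC
#> -6.07 -0.35 -4.12    NA  0.99 50.65 20.02
```

ACE lands on the planted 1.0 dB/cm-MHz, ASD near the true 50 µm diameter,
and AAC near `10 log10(100 · 1) = 20` dB; MBF/SS/SI are the normalized
spectrum's line fit (SAS is `NA` because no planar-reflector bank was
passed and the medium has no periodic structure). The end-to-end
classification experiment on a reduced synthetic cohort
(10 responders + 10 non-responders, weeks 0 and 4):

```r
e2e <- run_cohort_experiment(n_per_group = 10, weeks = c(0, 4), seed = 1)
e2e$perf
#> sensitivity  91.0 +/-  3.2 %
#> specificity  68.0 +/- 14.8 %
#> accuracy     79.5 +/-  8.0 %  (10 repeats)
```

The planted week-4 effect (responders gain backscatter intensity and
attenuation) is recovered well above chance (159/200 pooled correct
predictions, one-sided binomial p ≈ 7e-18).

The numbered scripts under `analysis/` run the same steps as a narrative
workflow (cohort simulation, phantom recovery, classification with subset
search, survival comparison), writing tables under `results/`.

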