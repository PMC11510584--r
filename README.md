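# sonocal

Simulation and analysis of acoustic-emissions-calibrated focused ultrasound
(FUS) exposures for microbubble (MB)-mediated blood–brain-barrier opening,
modelled on a clinical-prototype sparse hemispherical transmit/receive array
(258 kHz drive, 256 ultraharmonic receive channels for 3D passive cavitation
imaging, 4 subharmonic receivers for inertial cavitation detection).

The package is aimed at therapeutic-ultrasound researchers who want a
tested, reproducible implementation of the full exposure-calibration loop —
and a synthetic-data generator realistic enough to exercise every stage of
it — without access to hardware or raw in vivo data.

## What it implements

* **Array model** — seeded quasi-uniform hemispherical receiver layouts
  (64 modules × 4 corner elements = 256 PCI channels + 4 ICD receivers on a
  25.1 cm scaffold), uniform-medium propagation delays, JSON serialization.
* **Synthetic data** — per-burst multichannel RF (activation of a
  point-source MB emitter on a pressure sigmoid around a per-target
  threshold `P_thr`; 387 kHz ultraharmonic and 129 kHz subharmonic tones,
  wideband inertial-cavitation noise, white channel noise, channel-coherent
  clutter), synthetic post-sonication T1w/T2\*w volumes and
  immunofluorescence sections with encoded outcomes, and target-wise outcome
  tables with the published dose–response and protein/RBC couplings.
* **Signal processing** — zero-phase 8-pole Butterworth 380–400 kHz
  bandpass; burst-gated spectral band integrals over 119–139 kHz with a
  10 kHz subharmonic notch; the per-step channel-mean calibration/baseline
  ratio and its mean + 5 SD flag rule.
* **3D passive cavitation imaging** — delay-sum-integrate beamforming over
  an 11 × 11 × 21 mm, 1 mm-voxel grid (fast compiled narrowband backend +
  time-domain reference oracle), PSLR / positional-error / −3 dB ellipsoid
  axis metrics, and the coherent-activity detection gate
  (PSLR ≤ 70 %, ≤ 2 mm lateral, ≤ 4 mm axial).
* **Closed-loop controller** — MB-free baseline ramps, the calibration-phase
  pressure ramp (0.15 MPa start, 15 kPa steps) with dual PCI/ICD stopping,
  raster-interleaved scheduling at the target-wise burst repetition
  frequency, the open-loop treatment phase at
  `target level × calibration PNP`, and the four retrospective
  quality-control exclusion rules.
* **Imaging quantification** — circular-ROI (2.3 mm) relative Gd contrast
  enhancement with slice-wise normalization, max across planes and two
  jittered rater placements; T2\*w hypointensity flagging (labelled
  stand-in); relative immunofluorescence intensity on 2D sections.
* **Statistics & capacity** — summary-based Welch t test, type-II ANOVA with
  Tukey HSD, ANCOVA with Gd enhancement as covariate, linear regression, and
  the dose-limited treatment-capacity planner.

At its core is the calibration rule: ramp the burst PNP at each target,

    p_k = 0.15 MPa + (k − 1) · 15 kPa,

until coherent MB activity is detected on PCI (PSLR ≤ 70 % and SPTA
positional error ≤ 2 mm lateral / ≤ 4 mm axial) or the ICD ratio series
exceeds its baseline reference by 5 SDs; then treat at
`PNP = target level (%) × calibration PNP`.

## Worked example

A scaled-down session (16 modules, 2.5 ms captures, noiseless deterministic
emission) showing threshold recovery by the closed-loop calibration:

```r
library(sonocal)

welch_from_summary(1.43, 0.16, 8, 1.14, 0.09, 18)
#> Welch t = 4.80, df = 9.0, p = 0.00096

capacity_plan()
#> capacity_plan: 93.75 min delivery window -> 3543 targets, 75.5 cm^3

constants <- system_constants(capture_length = 2.5e-3)
geom <- build_array_geometry(seed = 7, n_modules = 16)
sub  <- sample_virtual_subject(4, seed = 1, constants = constants,
          emission = emission_model(noise_floor = 0, sigmoid_slope = Inf,
                                    clutter_n = 0))
plan <- sonication_plan(sub, burst_length = 1e-3, target_level = 75,
                        n_tx_bursts = 3, max_output = 0.8e6)
base <- run_baseline_ramps(plan, sub, geom, seed = 2, constants = constants,
                           pci_metrics = FALSE)
cal  <- run_calibration_phase(plan, sub, geom, base, seed = 3,
                              constants = constants,
                              process_min_output = FALSE)
cal$states[, c("target_id", "detection_step", "calibration_pnp", "stop_reason")]
#>   target_id detection_step calibration_pnp stop_reason
#> 1         1             23          480000         pci
#> 2         2             28          555000         pci
#> 3         3             22          465000         pci
#> 4         4             36          675000         pci

round(sub$targets$pthr)
#> [1] 473619 546528 454793 673575
```

Each calibration pressure is the first ramp step at or above that target's
true activation threshold: target 1's threshold of 0.474 MPa is crossed at
step 23 (0.480 MPa), target 4's 0.674 MPa at step 36 (0.675 MPa). The Welch
p-value reproduces the infusion-method group comparison from its printed
summaries, and the capacity plan turns the 150 µL/kg MB dose limit at
1.6 µL/kg/min into a 93.75 min delivery window, 3543 treatable targets and
about 75 cm³ at 2.2 × 2.2 × 4.4 mm cell spacing.

For a full pipeline run (baseline → calibration → treatment → synthetic
imaging → quantification → exclusions) see `run_full_session()`; for the
science and the modelling choices see the methods vignette
(`vignettes/sonocal-methods.Rmd`).

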