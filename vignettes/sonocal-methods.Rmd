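---
title: "Acoustic-emissions-calibrated focused ultrasound exposures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic-emissions-calibrated focused ultrasound exposures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sonocal)
```

## The problem

Microbubble (MB)-mediated focused ultrasound (FUS) transiently opens the
blood-brain barrier (BBB), but the pressure at which MBs begin to cavitate
varies from target to target (vasculature, skull transmission, MB supply).
Rather than prescribing a fixed pressure, the protocol modelled here
*calibrates* each target acoustically: the peak negative pressure (PNP) of
repeated bursts is ramped upward until the receive array detects either
spatially coherent MB emissions (by 3D passive cavitation imaging, PCI, at
the 387 kHz ultraharmonic of the 258 kHz drive) or an increase in wideband
emissions indicative of inertial cavitation (ICD, on dedicated subharmonic
receivers). The detection pressure is the *calibration pressure*; treatment
bursts are then delivered at a fixed fraction of it (the *target level*).
Downstream, BBB opening is quantified as relative gadolinium (Gd) contrast
enhancement in T1w MRI, and tissue effects as red-blood-cell (RBC) and
protein (albumin, IgG) extravasation in sections.

`sonocal` implements this entire loop as tested, reusable code, driven by a
synthetic-data generator that emulates the acoustic and imaging observations
of the in vivo rabbit study the pipeline is modelled on. No raw in vivo data
are available; everything the pipeline consumes is simulated with the
statistical structure of the published summaries.

## The array model

The system is a sparse hemispherical transmit/receive array: 64 modules on a
25.1 cm-diameter scaffold, each module an 8 x 8 element grid (2.5 mm pitch)
whose 4 corner elements receive at the ultraharmonic, giving 256 PCI
channels, plus 4 dedicated wideband (ICD) receivers tuned to the
subharmonic. Only the counts, scaffold radius and sparse character of the
layout are public; `build_array_geometry()` therefore places module centres
by seeded blue-noise rejection sampling on the hemisphere with a minimum
angular gap, projects the corner-element offsets back onto the sphere, and
drops the ICD receivers into the largest inter-module gaps. Layouts are
deterministic per seed and serializable to JSON.

Propagation is single-path at a uniform sound speed (default 1482 m/s,
degassed water): the modelled sonications are transcranial but uncorrected,
and the rabbit skull is thin at 258-387 kHz, so no skull layer or aberration
model is included. This choice has one visible consequence discussed under
*Limitations*.

## The synthetic-data generator

The generator is phenomenological by design: the pipeline needs inputs that
are spectrally, spatially and statistically realistic, not a bubble-dynamics
simulation.

**Per-target emission model.** Each target has a threshold pressure
`P_thr` drawn from a truncated normal (mean 0.53 MPa, SD 0.09 MPa, floor one
ramp step above the 0.15 MPa minimum output, matching the distribution of in
vivo calibration pressures). A burst at pressure `p` *activates* with
probability `sigmoid((p - P_thr) * slope)`; an activated burst radiates a
387 kHz tone to the PCI receivers and a 129 kHz tone to the ICD receivers
(amplitude scaled by the same sigmoid, spherical 1/r spreading, one
propagation delay per receiver), plus band-limited 100-200 kHz wideband
noise on the ICD receivers once `p` exceeds an inertial threshold `P_ic`.
The sigmoid slope default (2e-4 per Pa) spans the 5-95% activation range in
about two 15 kPa ramp steps, so calibration detections scatter around
`P_thr` the way they do in vivo.

Two optional structure parameters are off by default:

* `pthr_between_sd` splits the threshold variance into between- and
  within-subject components. The marginal SD of 0.09 MPa together with the
  reported intra-grid calibration-pressure range of 0.23 MPa implies a
  within-subject SD near 0.065 MPa (the expected range of 16 iid normal
  draws is 3.53 SD); the default iid mode reproduces the marginal
  distribution and gives an intra-grid range of ~0.32 MPa, while
  `pthr_between_sd = 0.062e6` reproduces the in vivo intra-grid range.
* `emission_offset_sd` displaces each target's emission site from the
  targeted coordinate (MB activity arises in nearby vasculature). A value of
  1.2 mm reproduces the reported positional-error spread of detected bursts
  (2.0 +/- 1.0 mm) and the observed fraction of targets that never satisfy
  the PCI gates and calibrate through ICD instead. It is off by default so
  the controller properties can be validated in the exact
  point-source-at-target mode.

**Noise and clutter.** Each channel carries white noise (RMS 0.7 in the
generator's arbitrary pressure units). Critically, bursts also carry
*channel-coherent clutter*: 8 burst-gated tone sources per burst at random
in-band frequencies and random positions 15-50 mm from the focus, half
drive-linked and half drive-independent, present with or without MBs. This
models transmit-linked reverberation and system pickup. Without it,
temporally-averaged noise-only PCI volumes are nearly flat, the peak
side-lobe ratio (PSLR) gate becomes vacuous, and baseline sonications
false-trigger at the positional-gate rate (~5% of bursts); with it, baseline
volumes have the peaked structure the detection gates were designed to
reject, and the simulated false-positive rate falls to ~0.1-0.5% of bursts
(the in vivo figure is 0.12%). The emission strength (9e-3 amplitude-metre)
is set so a detection burst's spatial-peak temporal-average (SPTA) intensity
spikes well above baseline levels, as in the published control traces, and
so detected-burst PSLR lands near the reported 49 +/- 13%.

**Imaging and outcome generators.** `simulate_t1w_volume()` builds
post-sonication T1w volumes (0.39 mm in-plane / 256 matrix / 1.5 mm slices)
as a uniform baseline with multiplicative Gaussian lesions (in-plane FWHM
2.5 mm, chosen near the 2.3 mm ROI diameter; configurable). Lesion
amplitudes are calibrated *jointly*, by solving a small linear system whose
entries are the expected ROI response of each target to each lesion
(jitter-averaged own response on the diagonal, neighbour cross-talk on the
3.5 mm grid off it), so that the ROI quantification stage recovers the
encoded enhancement ratios without bias. `generate_outcome_table()` draws
per-target true Gd enhancement from condition presets that encode the
reported group summaries (at 75% target level: 1.19/1.44/1.53/1.64 for
0/60/120/240 Tx bursts; 1.18 for the 50% level, where burst count had no
detectable effect), then derives albumin and IgG relative intensities as
linear functions of Gd enhancement and RBC area as a linear function with
burst-length-specific intercepts and half-normal noise floored at zero. The
link slopes come from the 50%/75% group means; the noise SDs are set so
regressions over a 66-target mixed design recover the reported explained
variance (albumin r^2 ~ 0.63, IgG ~ 0.46, RBC ~ 0.24). The burst-length
sub-means of Gd enhancement at 75% (1.36/1.43/1.48 for 1/5/10 ms) are not
separately encoded; the preset table conditions on target level and burst
count only, since both marginals cannot be satisfied by one table.

## Signal processing and PCI

The PCI band filter is an 8-pole Butterworth bandpass (380-400 kHz) applied
zero-phase. A 16-pole transfer-function design is numerically unstable in
double precision at this narrow relative band, so "8th order bandpass" is
realized as `signal::butter(4, band)` (8 poles); it attenuates the 258 kHz
drive by more than 140 dB. For matrices the filter can also be applied as
the exact `|H|^2` response in the frequency domain, which is what the fast
beamformer backend does internally.

The ICD statistic integrates the Hann-tapered magnitude spectrum of each
wideband receiver over 119-139 kHz, excluding a 10 kHz notch centred on the
subharmonic (realized as exclusion of bins in 124-134 kHz), gated to the
burst plus a 0.5 ms guard. Per pressure step, the calibration-phase integral
is divided by the microbubble-free baseline integral at the same step and
averaged over receivers; a step whose channel-mean ratio exceeds the mean of
the first 10 steps by more than 5 SDs (n-1 denominator, strictly greater, so
a zero-SD reference never flags ties) raises the ICD flag. Whether the
original analysis gated the FFT to the burst or the full capture is not
stated; gating to the burst with a guard is the default here.

Beamforming is delay-sum-integrate over an 11 x 11 x 21 mm grid of 1 mm
voxels centred on the target, with two interchangeable backends:

* a reference time-domain implementation with nearest-sample delays
  (at 10 MS/s a sample is ~0.15 mm of path), intended for small instances
  and used as the correctness oracle; and
* the default narrowband backend: one FFT per channel on the
  window-trimmed, zero-padded record, retention of the bins around the
  passband (optionally weighted by the zero-phase Butterworth response),
  and a short inverse FFT of those bins -- i.e. exact sinc decimation of
  the demodulated analytic signal -- followed by a compiled kernel applying
  per-voxel nearest-decimated-sample envelope shifts with phase-exact
  carrier rotation.

On a toy instance the two agree within 1% of the peak intensity provided the
toy is sampled finely enough (80 MS/s in the tests) that the *reference's*
nearest-sample phase quantization sits below the tolerance; against an
exact-fractional-delay spectral oracle the narrowband backend agrees to
0.1%. The decimated envelope rate floor (`fd_min`, default 150 kHz) trades
envelope-alignment granularity (~6.7 microseconds) against kernel cost; for
1-10 ms bursts the induced error is a fraction of a percent.

**Quality metrics.** The main lobe is the 26-connected region of voxels at
or above half maximum containing the maximum; PSLR is the largest intensity
outside it as a percent of the maximum; positional errors are the lateral
and axial distances from the SPTA voxel centre to the intended target;
detection requires PSLR <= 70% and errors <= 2 mm lateral / <= 4 mm axial,
all inclusive. The -3 dB ellipsoid is fit by intensity-weighted second
moments of *all* above-half-maximum voxels on a trilinearly upsampled grid
(factor 4; equivalent to the interpolation an isosurface extraction
performs), with the principal SDs scaled to -3 dB full lengths by the
half-maximum-truncated-Gaussian factor 2*sqrt(2*log 2)/0.50472 = 4.666.
Degenerate volumes (all-zero, as in noiseless baselines) report PSLR 100 and
infinite positional errors so they can never satisfy the detection gate;
lobes touching the grid boundary mark the axes unreliable.

## The controller

Baseline ramps run the full pressure ladder (0.15 MPa start, 15 kPa steps)
at every target without MBs, recording the ICD denominators and,
optionally, per-burst PCI metrics for false-positive bookkeeping. The
calibration phase interleaves targets in raster order (posterior-left
first) at the target-wise burst repetition frequency, ramping each target
until PCI detection or an ICD flag; the detection burst's pressure is the
calibration pressure, and the target's remaining calibration bursts run at
the minimum system output. The in vivo protocol had an operator end the
ramp on an ICD flag; here the stop is automatic, with a configurable
latency to mimic operator delay. If PCI and ICD fire on the same burst the
stop reason is "both". Targets that reach maximum output (default 1.0 MPa,
above the largest reported calibration pressure of 0.94 MPa; the protocol
for this case is not documented) are marked uncalibrated and excluded from
the Tx phase with a warning. The Tx phase delivers the planned number of
bursts at target level x calibration pressure, open-loop, with PCI
detections logged but not acted upon; a positive emission-model
`drift_rate` lowers the effective threshold burst by burst and manufactures
the retrospective coherent-activity events the exclusion rules screen for.

Four retrospective exclusion rules mirror the published analysis: (1) the
effective target level exceeded the intended level by more than 5
percentage points, judged by re-screening pre-detection calibration bursts
with relaxed thresholds (default PSLR <= 90, 3/6 mm); (2) coherent activity
in the Tx phase; (3) the calibration detection fails a stricter
retrospective threshold set -- a stand-in for manual re-classification of
the detection projections, with defaults (PSLR <= 60, 1.2/3 mm) set at the
separation observed between true detections (on-centre, PSLR 45-53) and
false positives (off-centre, PSLR 50-69) in the default
point-source-at-target generator mode (with `emission_offset_sd > 0` the
positional component should be relaxed accordingly); (4) an
anatomy-confound flag supplied by the caller. A target is excluded if any
rule fires.

## Statistics and capacity

The two-group infusion-method comparison uses a two-sided t test computed
from group summaries; the Welch form is the default because the reported
group SDs differ by about 2x (the pooled form is available). Factor
analyses use type-II ANOVA (`car::Anova`) on fixed-effects linear models --
the design is unbalanced -- with Tukey-HSD-adjusted pairwise comparisons of
estimated marginal means (`emmeans`), with and without relative Gd
enhancement as a covariate; no correction beyond Tukey is applied.
Correlations use ordinary least squares. Repeated sessions per animal are
treated as fixed effects, mirroring the original analysis.

`capacity_plan()` converts the regulatory MB dose limit (150 uL/kg at 1.6
uL/kg/min) into a delivery window (93.75 min), subtracts the pre-infusion
time, applies the duty cycle to get an on-time budget, and divides by the
per-target on-time ((calibration + Tx bursts) x burst length); with the
stated parameter set this yields 3543 targets and ~75 cm^3 at
2.2 x 2.2 x 4.4 mm cell spacing.

## Orchestration and reproducibility

`run_full_session()` chains geometry, subject, baseline, calibration, Tx,
outcome generation, synthetic imaging, quantification and exclusions. A
single master seed fans out into recorded stage seeds, so a rerun is
identical end-to-end and each stage is independently reproducible. All
artifacts are text or standard formats: JSON geometry, JSON-lines burst
logs, CSV outcome tables, NIfTI volumes. The package's exported functions
and this vignette are the interface; no shell wrapper is provided.

## Problem sizes used in the tests

Monte-Carlo and controller tests run at reduced sizes chosen for coverage
rather than realism: reduced module counts (4-64 receive channels for
controller logic, 128 for the noisy recovery property, the full 256 for
point-spread checks), capture windows of 2.5-6.5 ms instead of 13.1 ms, and
ramp ceilings of 0.6-0.8 MPa. The acceptance script runs the point-spread
study on the full 256-channel geometry with full 13.1 ms captures (20
bursts) and the enhancement-recovery study on 20 full-size subjects per
condition.

## Numerical choices and edge cases

* ICD ratios guard zero baselines with a floor and flag the step.
* SPTA ties break first-in-scan-order and are recorded.
* `welch_from_summary` with two zero-SD equal-mean groups returns t = 0,
  p = 1.
* Enhancement draws below 1 are floored at 1 (ratios cannot fall below the
  reference in the noiseless generator).
* The calibration-recovery property is assessed against the
  deterministic-detector value (the first ramp pressure at or above
  `P_thr`) on targets surviving the rule-3 screen: with Bernoulli
  activation on a sigmoid centred at `P_thr`, the activation probability at
  the crossing step is ~0.5 whenever `P_thr` sits just below a step
  boundary, so a literal |calibration - P_thr| <= one-step bound cannot hold
  at the 95% level for any stochastic activation model.

## Limitations

* The transmit field is not modelled: target coordinates are inputs,
  steering efficiency is metadata, and transmit-side aberration is out of
  scope.
* Emissions are point sources in a uniform aberration-free medium. This
  reproduces the detection statistics (PSLR, positional error,
  false-positive rate) but yields diffraction-limited -3 dB main lobes of
  roughly 1.7 x 3.8 mm at ~28 mm steering -- narrower than the in vivo
  2.2 x 5.4 mm, which include transcranial phase aberration and distributed
  bubble-cloud sources. Passing the enhancement-recovery and detection
  checks on synthetic data therefore says nothing about transcranial
  focusing quality on real data.
* The T2*w hypointensity read is qualitative in practice; the thresholded
  stand-in here is labelled non-faithful and is off by default in the
  session pipeline.
* RBC areas are consumed as already-summarized values; pixel-level
  segmentation of stained sections is out of scope.
* The in vivo noise spectrum and receiver sensitivities are unknown; noise
  is white per channel plus the coherent clutter model described above, with
  all amplitudes in arbitrary units consistent within a session.
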