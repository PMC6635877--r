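---
title: "Counting organelle proteins by step-wise photobleaching: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting organelle proteins by step-wise photobleaching: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(slimcount)
```

## The measurement problem

A fluorescent focus in a live bacterial cell — a carboxysome carrying
YFP-tagged shell or cargo proteins, say — is diffraction limited:
its image says nothing directly about how many labelled molecules it
contains. Step-wise photobleaching converts intensity into molecule
counts. Under sustained excitation each fluorophore bleaches
irreversibly at a random time, so a focus's intensity decays as a
staircase whose unit step height is the brightness of one fluorophore.
The copy number of a focus is then

$$ S = \frac{I_0}{I_1}, $$

with $I_0$ the background-corrected summed intensity of the focus
extrapolated back to the start of illumination and $I_1$ the
characteristic intensity of a single fluorophore. Everything in this
package serves that division: measuring $I_0$ well, measuring $I_1$
well, and knowing how far to trust the result.

## Image model and simulator

The simulator exists so that every stage of the analysis can be tested
against known ground truth. It renders:

* **Cell geometry.** A spherocylinder (length 3 µm, radius 0.5 µm by
  default) whose envelope is lined by a thylakoid shell (0.1 µm thick).
  Thylakoid and cytosol emit background photons at configurable
  volumetric densities, integrated along the optical axis per pixel.
  This emulates cytosolic fluorescence and chlorophyll bleed-through
  into the detection channel — the background whose distribution the
  subtraction step removes.
* **PSF.** A 3D Gaussian. Lateral $\sigma$ defaults to 160 nm (2 px at
  the 80 nm/px camera magnification), chosen so that fitted focus
  widths come out near the ~250 nm observed for diffraction-limited
  YFP foci at high numerical aperture; axial $\sigma$ defaults to
  400 nm and attenuates photons from defocused emitters by
  $\exp(-z^2/2\sigma_z^2)$. No aberrations, no defocus broadening of
  the lateral width. Organelles are point emitters by default —
  justified because a 200 nm organelle is smaller than $2\sigma$ — with
  an optional uniform-sphere mode that widens the lateral sigma by the
  projected sphere variance ($a^2/5$ for radius $a$).
* **Photophysics.** Each fluorophore emits a fixed photon rate per
  frame until it bleaches. Bleach frames are geometric with per-frame
  survival $e^{-\lambda}$, the discrete analogue of exponential
  bleaching; sub-frame bleaching within a 5 ms exposure is ignored as
  it is orders of magnitude shorter than the bleach timescale.
  Blinking and immature (non-fluorescent) fractions are not simulated.
* **Camera.** Poisson noise on the photon scale, linear gain
  (counts/photon), constant offset, optional Gaussian read noise (off
  by default). With noise disabled the image is the exact expectation,
  which the photon-conservation tests exploit.
* **Motion.** Brownian displacements with per-axis variance $2D\,
  \Delta t$, reflected radially at the spherocylinder surface —
  reflection preserves the uniform stationary density, which is what a
  freely diffusing organelle should have.

All randomness flows from one integer seed recorded in the returned
ground truth; identical seed and configuration give bit-identical
stacks.

What the simulator does *not* emulate — fluorophore blinking,
maturation, spectral bleed-through beyond a uniform shell, stage drift
during Slimfield acquisition, cell-to-cell variability of background —
bounds what a passing test can claim: recovery results show the
*estimators* are correct under the stated model, not that real-cell
systematics are absent.

## Detection and photometry

* **Candidates** come from a top-hat transform (image minus its
  grayscale opening with an 11-px disc) thresholded at a robust
  z-score (default 5 × MAD above the median), followed by local-maximum
  selection with a 2 px exclusion radius.
* **Sub-pixel localization** is iterative Gaussian masking: multiply a
  local background-subtracted window by a Gaussian centred on the
  current estimate, move to the intensity-weighted centroid, repeat
  until the move is below $10^{-3}$ px (cap 100 iterations;
  non-convergence flags the measurement rather than erroring).
  The mask sigma defaults to the PSF sigma.
* **Photometry** sums a circular ROI of radius 5 px (pixel membership
  by centre-in-circle; 81 px when centred) and subtracts
  $n_\mathrm{inner}\times$ the mean of the surrounding 17 × 17 window
  with the inner disk excluded. The SNR is the background-corrected
  mean inner intensity over the sd of the outer region; foci pass only
  if SNR strictly exceeds 0.4. A flat background window (sd 0) maps to
  SNR $+\infty$ for positive signal, 0 otherwise. ROIs touching the
  image edge are flagged and excluded from stoichiometry.
  Because the 17 × 17 window overlaps the PSF tails, the estimator's
  expectation is about 2% below the raw PSF mass in the ROI; tests
  oracle against the estimator's exact expectation, computed by
  independent numeric integration.
* **Linking** is greedy nearest-neighbour per frame pair (shortest
  links first, each focus used once, ties to the lowest track id),
  with a configurable displacement gate. Slimfield foci are sparse, so
  no global assignment is needed. Gap closing is off by default and
  enabled (2–3 frames) where detections flicker: time-lapse tracking
  and end-of-bleach tracking. Bridged frames are linearly interpolated
  when a trace or track needs a uniform time base.
* **Overtracking** continues photometry at a track's last centroid
  after the focus drops below detection. This is essential, not
  cosmetic: the single-fluorophore dwell often sits below the
  detection threshold, and the overtracked tail is where the unit
  intensity lives. The pipeline default is 100 overtracked frames.

## The characteristic single-fluorophore intensity

Two estimators, used to cross-check each other:

* **Endpoint distribution.** Pool intensities from the final quarter
  (configurable) of each track's *visible* bleach course — the end of
  the course judged on a 5-frame running mean so an isolated noise
  spike cannot stretch the window into pure background — plus
  overtracked samples, all gated above a noise floor of 3 × the
  background sd (photometric background for tracked foci; the
  post-bleach trace end for bare traces — the whole-trace difference
  noise would be inflated by photon noise at high copy number). The
  unit is the **lowest substantial local maximum** of the pooled
  kernel density (density at least 10% of the global maximum). The
  lowest, not the global, because the samples are a staircase mixture:
  in small datasets the two- and three-fluorophore dwells can carry
  more mass than the final single-fluorophore dwell, while the unit is
  by construction the lowest quantized level. Its HWHM is the quoted
  uncertainty — and motivates the 0.5-molecule kernel used for
  periodicity analysis downstream.
* **Fourier spectrum.** Intensities clustered at integer multiples of
  the unit form a comb along the intensity axis. A narrow-kernel
  density (bandwidth: range/100), detrended by a wide-kernel envelope,
  is Fourier transformed; the reciprocal of the dominant frequency is
  the unit. Significance is calibrated against a Monte-Carlo null —
  spectra of bootstrap resamples jittered by the envelope kernel,
  which keep the distribution's shape but destroy its periodicity —
  at the 5% level (60 resamples, internally seeded, caller's RNG state
  restored). An insignificant peak returns failure so callers fall
  back to the endpoint method. A degenerate single-level input returns
  that level directly.

On simulated data with several visible terminal steps the two agree
within 15% (tested). Both scale linearly with the camera gain, so copy
numbers are invariant under intensity rescaling (tested).

## Initial intensity and copies

$I_0$ is obtained by fitting a single exponential to the
Chung–Kennedy-filtered trace (frames indexed from 1) over frames above
the noise floor and evaluating it at frame 0 — back-extrapolating
through the bleaching that occurs during the first illuminated frames.
The filter (two adjacent windows, default 10 frames; output a mean of
the forward- and backward-window means weighted by variance to the
power −4) preserves steps exactly on noiseless data; on a smooth decay
it costs a few percent of accuracy, which the recovery tolerances
absorb. If the fit fails the mean of the first 10 frames is used. An
`attenuation_factor` (default 1) rescales intensities recorded through
a neutral-density filter, as needed for high-copy strains, before
division by the unit.

Copies are $I_0/I_1$, exactly. Population distributions are summarized
by the Gaussian-KDE peak ± HWHM; the "standard" bandwidth is
Silverman's rule, with the explicit 0.5-molecule kernel reserved for
periodicity analysis on raw, uncorrected values (mixing corrected
values would dephase the comb).

## Population analytics: choices that were genuinely open

* **Background subtraction** operates on densities:
  $\max(f_s - r\,f_b,\,0)$, renormalized, where the rate $r$ is the
  expected fraction of sample foci that are background. Its
  normalization was open; the default derives $r$ from foci-per-cell
  counts of the labelled strain versus the unlabelled control, and it
  is always explicit, never silent.
* **Triple-Gaussian decomposition** is fit to the KDE curve (weighted
  by density), not the raw values, mirroring how such population
  splits are presented. Components report area fractions normalized to
  one — whether published percentages mean area fractions or
  assignment counts is ambiguous; area fractions are implemented and
  labelled as such. When a *single* Gaussian already explains the
  curve ($R^2 \ge 0.995$) the three-component problem is degenerate
  (overlapping components share mass arbitrarily), so the
  single-component solution is reported with two zero-area degenerate
  components.
* **The overlap model** asks: if $n$ organelles sit uniformly at
  random in the 2D-projected cell, what fraction have a neighbour
  within the resolution radius (default 250 nm, the measured focus
  sigma width)? The analytic mode computes the exact conditional
  probability $1-(1-a(x)/A)^{n-1}$ — $a(x)$ the neighbourhood disk
  clipped to the cell, evaluated by pixelizing the projection
  (grid $\le \rho/40$) and convolving with the disk kernel — averaged
  over positions. The Monte-Carlo mode brute-forces placements
  (≥ 10⁵ points). The two agree within Monte-Carlo error (tested), and
  the self-convolution of a singles distribution predicts where
  merged-pair populations should appear (2 × the singles peak).
* **Confocal calibration** divides the Slimfield modal copy number by
  the confocal modal intensity of the same strain under the reference
  condition; the factor then converts any confocal intensity of that
  strain to molecules. Strain labels are checked; the round trip on
  the reference sample is exact by construction.
* **Condition comparisons** use the two-sided Mann–Whitney U test
  (normal approximation; a permutation oracle agrees within
  Monte-Carlo error in the tests) with stars at P < 0.05 and
  P < 0.005, and fold changes of functional-unit medians. The
  **grouped sampling error** — sd/mean of KDE peaks over random groups
  of 70–100 entries — carries a 5% quality flag. Note that a KDE mode
  converges more slowly than a mean, so this error sits well above the
  naive $\sigma/(\mu\sqrt{g})$ bound; the tests bracket it between 1×
  and 6× that bound rather than pretending mean-like efficiency.

## Diffusion analysis

Tracks from drift-registered time-lapse stacks (translation by Fourier
cross-correlation, parabolic sub-pixel refinement, bilinear
resampling) yield time-averaged MSD profiles up to half the track
length. The apparent diffusion coefficient is slope/4 of an ordinary
least-squares line through the first six MSD points **with a free
intercept**: localization noise adds a constant offset to every MSD
point, and an intercept-free fit would fold that offset into the
slope. (The choice was open; the free intercept is recorded in the
profile object, and on noiseless closed forms the fit is exact.) A
negative slope reports D = 0 with a flag. The anomalous exponent α is
the log–log slope over all positive-MSD lags: 1 for Brownian, 2 for
ballistic, < 1 for confined motion — single-track α is dominated by
the noisy large lags, so ensemble-averaged MSD curves are used when α
itself is the quantity of interest.

## Validation scales

The test suite and acceptance script size their simulations to run in
minutes on one CPU while keeping Monte-Carlo error meaningfully below
the tolerances they assert:

* Diffusion benchmark: 3 organelles of 200 nm at
  $D = 1.3\times10^{-5}\,\mu m^2/s$, 40 frames at 60 s, Poisson noise,
  200-300 replicate stacks (several hundred usable tracks). The per-track estimator
  sd is ~40% — intrinsic to a 6-point fit on a 40-frame track — so the
  ensemble mean carries ~2% standard error.
* Copy-number recovery: populations of 200 organelles at 5, 37, 60 and
  300 copies, simulated at trace level (the image-level and
  trace-level paths share the photophysics; the image path is
  validated separately on smaller scenes), 650 frames at bleach rate
  0.015/frame, unit 1000 counts, background noise 30 counts.
* Mixture, overlap, and comparison checks: n = 2000 samples, ≥ 10⁵
  Monte-Carlo placements, 8000 permutations.

## Known limitations

* The exponential back-extrapolation assumes a single dominant bleach
  rate; strongly heterogeneous bleaching within one focus would bias
  $I_0$.
* The unit-intensity estimators need the bleach course sampled to
  completion (or overtracked); truncated acquisitions bias the unit
  upward in small datasets.
* The simulator's uniform thylakoid shell is a crude stand-in for real
  chlorophyll texture; background-subtraction performance on real
  images depends on how well the unlabelled-cell distribution matches.
* Tracking is greedy nearest-neighbour: adequate for sparse organelles
  (a few per cell), not for dense fields.
* An immature-fluorophore fraction (reported at ≤ 15% for fast-maturing
  YFPs) would scale all copy numbers down by a constant factor; it is
  neither simulated nor corrected.
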