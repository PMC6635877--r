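# slimcount

Absolute counting of fluorescently tagged protein copies in single
organelles of rod-shaped bacteria, from step-wise photobleaching of
millisecond-exposure ("Slimfield") fluorescence image stacks — with the
population analytics, confocal calibration and diffusion analysis that
turn per-organelle counts into biology, and a ground-truth image
simulator to validate every stage.

The motivating system is the β-carboxysome of *Synechococcus elongatus*:
an icosahedral CO₂-fixing microcompartment whose shell and cargo
proteins (CcmK3/K4, CcmL, CcmM, CcmN, CcaA, RbcS, RbcX) can be tagged
with YFP and counted organelle by organelle in live cells. The same
machinery applies to any diffraction-limited fluorescent assembly.

## What it computes

**Copy numbers by photobleaching.** A focus of a YFP-tagged protein
bleaches in discrete steps. Its copy number is

&nbsp;&nbsp;&nbsp;&nbsp;*S* = *I*₀ / *I*₁,

where *I*₀ is the focus's summed, background-corrected intensity
back-extrapolated to the start of illumination and *I*₁ is the
characteristic intensity of a single fluorophore, read from the
distribution of focus intensities at the end of bleaching (and,
independently, from the Fourier spectrum of "overtracked" foci —
intensities sampled past the bleach endpoint). Traces are denoised with
the edge-preserving Chung–Kennedy filter so individual steps survive.

The detection chain is the standard single-molecule recipe: top-hat
candidate detection, iterative Gaussian-mask sub-pixel localization,
summed intensity in a 5-pixel-radius ROI corrected by the mean
background of a surrounding 17 × 17 window, an SNR > 0.4 acceptance
gate, and nearest-neighbour linking through time.

**Population statistics.** Per-organelle copies are summarized as the
kernel-density peak ± half width at half maximum (HWHM); distributions
can be corrected by subtracting a background (chlorophyll) distribution
measured in unlabelled cells, decomposed into three Gaussian
populations, and checked against a nearest-neighbour model for the
probability that two organelles merge into one diffraction-limited
spot. Copies divide by oligomer size into functional units (pentamers,
hexamers, L₈S₈ holoenzymes). Slimfield peaks calibrate confocal
intensity distributions into absolute copies; conditions are compared
with Mann–Whitney U tests.

**Diffusion.** Time-lapse stacks are drift-registered, tracked, and
summarized by the time-averaged mean squared displacement
MSD(τ); the apparent diffusion coefficient is slope/4 of the first six
MSD points (free intercept absorbs localization noise), with a
log–log anomalous exponent α for the full curve.

**Simulator.** `simulate_photobleach_stack()` and
`simulate_diffusion_stack()` render a 3D-Gaussian PSF over a
spherocylindrical cell with thylakoid-shell and cytosol background,
per-fluorophore exponential bleaching, Brownian organelle motion with
reflecting boundaries, and Poisson camera noise — returning the full
ground truth (bleach times, surviving counts, tracks) for
parameter-recovery tests.

## Worked example

Simulate two 37-copy organelles bleaching in a model cyanobacterial
cell, track them, estimate the single-YFP intensity and count copies:

```r
library(slimcount)

optics <- optical_model()                      # 80 nm/px, gain 10, 5 ms
geom   <- cell_geometry(thylakoid_photon_density = 5,
                        cytosol_photon_density  = 2)
orgs <- list(
  organelle_spec(c(-0.8,  0.1, 0), copy_number = 37,
                 photons_per_fluorophore = 100, bleach_rate = 0.015),
  organelle_spec(c( 0.7, -0.1, 0), copy_number = 37,
                 photons_per_fluorophore = 100, bleach_rate = 0.015))

sim    <- simulate_photobleach_stack(geom, orgs, optics,
                                     n_frames = 400, seed = 7)
tracks <- track_stack(sim$stack, max_gap = 3, overtrack_frames = 100)
tracks <- Filter(function(t) nrow(t$measurements) >= 30 &&
                             t$measurements$frame[1] <= 3, tracks)

unit <- unit_intensity_endpoint(tracks)
unit
#> <unit_intensity> 907.5 counts (+/- 1.4e+02), method: endpoint

copies_per_focus(tracks[[1]], unit)
#>   id initial_intensity   copies
#> 1  1           35985.5 39.65504
```

The true single-fluorophore intensity in this simulation is
100 photons × gain 10 ≈ 950 counts inside the ROI (after PSF-tail
losses), and both organelles carry 37 fluorophores: the pipeline reads
back 907 counts and 39.7 / 39.3 copies. Converting the modal copy
number of a pentameric shell protein into functional units:

```r
functional_units(37, 5)
#> [1] 7.4
```

i.e. about 7.4 pentamers per organelle.

A command-line wrapper is installed at `inst/exec/slimcount`:

```sh
slimcount simulate  --config config.yaml --seed 5 --out out/
slimcount slimfield --config analysis.yaml --out out/
```

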