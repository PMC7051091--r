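---
title: "Quantifying pulsatile ribosomal-gene transcription: models and methods"
author: "nucleoPulse authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pulsatile ribosomal-gene transcription: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoPulse)
```

## The biological question and the measurement chain

Ribosomal genes are transcribed by RNA polymerase I inside the FC/DFC units
of the nucleolus. When cells are held at +4&nbsp;°C, pol&nbsp;I transcription
arrests; on return to 37&nbsp;°C it restarts in near-synchrony across the
population. Fixing cohorts of cells at successive time points after release
and quantifying the nascent-RNA signal (e.g. incorporated 5-fluorouridine)
in the nucleoli turns a population of fixed cells into a time course: if
rDNA transcription is pulsatile and the release synchronized the pulses,
the per-time-point population mean undulates; if cells drift out of phase
(or were never synchronized), the mean trace is flat up to noise.

`nucleoPulse` implements that entire chain as testable code:

1. a **synthetic-data generator** for per-cell compartment intensities and
   for 3D confocal-like stacks with ground truth;
2. **unit detection**: 3D spot detection and sub-voxel quantification of
   FC/DFC units;
3. **region segmentation**: nucleus / nucleolus / nucleoplasm masks with
   per-region area and intensity measurements;
4. **time-course statistics**: coefficient of variation, Fourier-amplitude
   periodogram, dominant period with sampling-interval uncertainty,
   compartment correlation, fold changes and the pooled Student's *t*;
5. a **pipeline layer** tying the stages into seeded, manifest-logged runs.

No public image data accompany the study conditions this package emulates,
so the generator is first-class: its defaults *are* the study conditions,
and every downstream claim is validated against its ground truth.

## The kinetics model

The population-mean signal after cold release is modelled as a recovery
ramp multiplied by a damped cosine:

$$M(t) = \min(t/t_r, 1)\,\bigl[1 + a(t)\cos(2\pi (t - t_p)/T)\bigr],
\qquad
a(t) = \begin{cases} a_0 & t \le t_p\\
a_0\, e^{-(t - t_p)/\tau} & t > t_p \end{cases}$$

with defaults $T = 60$ min, first peak $t_p = 30$ min, ramp end
$t_r = 30$ min, $a_0 = 0.5$, damping $\tau = 75$ min (HeLa) or 120 min
(limbal epithelial cells, LEC), baseline $B = 100$ intensity units, and a
15–150 min grid in 15-min steps. This is the minimal form reproducing the
observed facts: maxima at 30, 90 and 150 min, a threefold rise between 15
and 30 min ($M(15) = 0.5$, $M(30) = 1.5$), and a trace CV of ≈ 0.267
(HeLa) or ≈ 0.292 (LEC) — the damping constants are fixed by those CV
values, and the ramp expresses the gradual recovery of the transcription
machinery from the cold arrest. The damping models loss of *population
synchrony*, not cessation of bursting.

Noise model (per cell $i$, time point $t$):

$$I_i(t) = B\,m_i(t)\,b_i\,(1 + \epsilon_i)\,(1 + \beta_t)$$

* $b_i$ — lognormal per-cell brightness, CV 0.2 (expression and staining
  differences between cells);
* $\epsilon_i$ — Gaussian measurement noise, SD 0.1 of the signal;
* $\beta_t$ — Gaussian batch factor, SD 0.07, **one draw per fixation time
  point** shared by every cell measured at that point. Because cohorts
  fixed at different time points are stained and imaged as separate
  batches, this term does not average out with cell number; it is what
  gives the unsynchronized control trace its residual CV of ≈ 0.07.
* Under the random-phase (control) mode each cell draws its own uniform
  cosine phase and the ramp is dropped; phases average out across
  $8 \times 50$ cells and the mean trace is flat at $B$ up to the batch
  factor.

Cells are drawn fresh at every time point (fixed cells cannot be followed),
so the generator produces population samples, never single-cell
trajectories — matching the experimental design it emulates.

The nucleoplasmic signal couples to the same cell's kinetic state with
attenuation $\beta$ plus an independent shared per-time-point fluctuation
$\sigma_{np}$ and per-cell noise (CV 0.2). The defaults
$\beta = r\,\mathrm{CV}_{np}/\mathrm{CV}_{nuc} = 0.414$ and
$\sigma_{np} = \mathrm{CV}_{np}\sqrt{1 - r^2} = 0.13$ are calibrated so the
expected nucleolus–nucleoplasm correlation is $r \approx 0.65$ and the
nucleoplasmic CV $\approx 0.17$.

## Synthetic scenes

Rendered stacks (default $256 \times 256 \times 21$ voxels, z step three
times the xy pixel) contain one elliptical nucleus with a dim uniform
interior (20 intensity units), two disc-shaped nucleoli (radius 20 px)
carrying a diffuse signal at 15 % of the mean spot amplitude, 30
diffraction-limited FC/DFC spots per cell (anisotropic 3D Gaussians,
$\sigma_{xy} = 1.3$ px, $\sigma_z = 0.8$ slices, lognormal amplitude CV
0.3, centres ≥ 6 px apart inside the nucleoli), and 100 dim nucleoplasmic
foci at 10 % amplitude. Poisson shot noise (gain 1) and Gaussian read noise
(SD 2) complete the model — the standard fluorescence noise pair. Spot
amplitudes scale exactly linearly with the requested level, so paired
scenes at two levels have a known true intensity ratio; the level follows
$B\,M(t)$ across a time course, times the cold factor 0.6 for the
cold-state preset.

What the scenes deliberately do **not** model: optical blur beyond the
spot PSF itself, depth-dependent attenuation, chromatic effects, touching
nuclei, deconvolution artefacts, photobleaching, or live-cell drift.
Passing tests on these scenes therefore demonstrate correctness of the
measurement chain under controlled conditions, not robustness to every
pathology of real microscopy.

## Unit detection

Following the projection-first strategy of the original quantification
software: compute the maximum intensity projection (MIP), blur it with a
wide Gaussian ($\sigma = 9$ px, working range 8–10) and threshold with
Otsu's method. The blurred Otsu threshold yields the *nucleus-scale*
foreground; a second Otsu restricted to that foreground isolates the
nucleolar blobs. Two refinements proved necessary and are part of the
design:

* the second-stage histogram is taken on an **eroded core** of the nucleus
  mask, because the blurred boundary ramp otherwise drags the threshold;
  the split is accepted only if its contrast exceeds 5 robust SDs of the
  blurred image (noise floor $\approx \sigma_{hp}/(2\sqrt{\pi}\,\sigma)$
  for blur width $\sigma$), and only if the bright class is also brighter
  in the *unblurred* projection — a uniform nucleus produces neither.
* candidate units are **local maxima of the unblurred MIP** inside the
  nucleolar mask, non-maximum-suppressed to a 3 px minimum separation
  (brighter peak wins, lexicographically smaller coordinate on ties), and
  must exceed the mask median by 5 robust noise SDs. The noise SD is
  estimated from horizontal first differences of the MIP
  ($\mathrm{MAD}/\sqrt 2$), **not** from the MAD of MIP values: the
  maximum projection of a noisy stack has a Gumbel-like right tail that
  makes value-based scales either leaky on blank scenes or blind to dim
  spots.

Each candidate is then quantified on the optical section where it is
brightest: an isotropic 2D Gaussian plus constant offset is fitted by
Levenberg–Marquardt on a 7 × 7 crop, giving the sub-voxel (x, y) centre,
$\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$, the fitted offset as the
record's background, and a scale-invariant goodness of fit
$\chi^2 = \sum r^2 / \sum(\mathrm{model} - \mathrm{offset})^2$ (the
normalization is a package convention — dimensionless and invariant under
intensity rescaling). A failed or wandering fit keeps the unit at its
integer position with `converged = FALSE`. The axial position is refined
by parabolic interpolation through the section profile.

Integral intensities are measured in spheres of radii 1.0–4.0 px
(z distances scaled by the voxel anisotropy — a physical sphere), summing
$\max(v - b, 0)$ with $b$ the median of a 5–7 px scaled annulus. The
per-voxel clamp guarantees monotonicity in the radius. Two conventions
matter with anisotropic voxels: the sphere is centred **axially on the
unit's optical section** (a sub-voxel z centre midway between sections
would leave a 1.5 px sphere empty), and voxel sums across sections
slightly exceed the fully continuous Gaussian sphere mass (by ≈ 6 % at
radius 4) because $\sigma_z = 0.8$ slices undersamples the axial profile
— the per-slice analytic mass is the right reference, and the tests use
it. The 1.5 px radius is the reporting and ranking radius, the value most
resistant to noise.

Deconvolution before counting is intentionally not reproduced; detection
and counting operate on raw stacks.

## Region segmentation

Nuclei: Otsu on the blurred MIP, hole filling, connected components,
discarding components below 500 px (debris; configurable). Nucleoli: the
same second-stage Otsu described above (default blur 4 px here — the
nucleolus-scale structure is preserved better than with the detection-mask
blur). Nucleoplasm is defined as nucleus minus nucleoli, so
integral(nucleus) = integral(nucleoli) + integral(nucleoplasm) holds
exactly on the same projection. All region measurements (area in pixels,
integral, average = integral/area) are taken on the 2D projection; 3D
volumes are out of scope. A wide blur erodes a convex contour by roughly
$\sigma^2 \times$ curvature, which costs a few percent of area on a
realistic nucleus — visible in the tests' tolerances.

## Time-course statistics

* **CV**: population SD (divisor $N$) of the per-time-point means over
  their grand mean. Whether the original analysis pooled cells across
  experiments or averaged per-experiment CVs is not documented; this
  package pools (400 cells per time point), and at the tolerances used the
  divisor choice is immaterial.
* **Periodogram**: $A(T) = \lvert\sum_j (x_j - \bar x)\,
  e^{-2\pi i t_j/T}\rvert$ evaluated by direct sum on a dense period grid
  (default 30–150 min, 1-min steps, from the 2Δt Nyquist period to the
  span). A 10-point series has only five canonical DFT frequencies, none
  near 60 min, so the dense grid is the only way to localize a one-hour
  period; amplitudes at neighbouring periods are correlated, which is
  accepted. Mean subtraction is mandatory, making the amplitude invariant
  under additive offsets.
* **Dominant period**: argmax of $A(T)$, ties toward the smaller period.
  On the noiseless default HeLa trace the argmax falls at 55 min — within
  one sampling interval of the one-hour period; the damping and the
  15-min recovery dip skew the peak slightly below $T$. The uncertainty
  interval attached to a recovered period $P$ is $(P - \Delta t,
  P + \Delta t)$: with 15-min sampling a 60-min period is only localized
  to 45–75 min.
* **Correlation, fold change, t-test**: Pearson $r$ between the two
  compartments' mean traces; ratio of population means between two time
  points; classical pooled-variance two-sample *t* with a two-sided
  p-value (groups with zero pooled variance and equal means return
  $p = 1$ by convention).
* No significance testing of periodogram peaks, no Lomb–Scargle
  normalization variants and no autocorrelation analysis are provided. A
  periodogram peak *below* the 30-min Nyquist period of the 15-min
  sampling design cannot be recovered from these data and is not
  attempted.

## Numerical and reproducibility choices

All randomness flows from one root seed; stage seeds are derived by a
fixed linear map (kept below $2^{31}$), so tables are bit-identical and
stacks voxel-identical under a fixed seed. Otsu thresholding uses a
256-bin histogram spanning the data range with bin values equal to the
mean of the data in each bin, which makes the maximization exact whenever
distinct values occupy distinct bins (e.g. any 8-bit image) and the
threshold equivariant under additive shifts; constant images raise an
error rather than inventing a threshold. Stacks are written as 16-bit
multi-page TIFF (values rounded and clamped — the standard microscopy
container; the floating-point TIFF path of the underlying writer does not
round-trip values outside [0, 1]).

## Problem sizes used by the tests

The unit tests run on reduced scenes ($128 \times 128 \times 9$, 10 units)
chosen to exercise every code path quickly; the acceptance checks use the
full default conditions: $8 \times 50$ cells per time point with 100–200
seeded replicates for the trace statistics, and default
$256\times256\times21$ scenes (30 units, or 50 across three nucleoli for
the two-sample *t* check, matching the 50-cell group size of the
fixed-cell design) for the image chain. These sizes are the package's
definition of its study conditions; enlarging them changes Monte-Carlo
error, not the calibration.

## Known limitations

* The kinetics is a phenomenological population model; it does not model
  single-cell burst statistics, refractory periods, or allele counts.
* Detection assumes diffraction-limited, well-separated spots inside
  nucleoli whose diffuse signal is brighter than the nucleoplasm; densely
  packed or strongly overlapping units would require a deblending step
  that is out of scope.
* Segmentation assumes non-touching nuclei (the generator places one per
  scene); there is no watershed separation.
* The batch factor is shared across experiments within a time point. If
  real batches were per-experiment, the control-trace CV would shrink by
  roughly $\sqrt 8$; the chosen structure reproduces the observed control
  fluctuation level.
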