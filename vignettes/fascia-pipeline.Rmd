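---
title: "Dual-echo UTE processing for deep fascia: models, parameters, and design choices"
author: "uteFascia package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-echo UTE processing for deep fascia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uteFascia)
```

## The imaging problem

Deep fascia, aponeurosis and tendon are collagen-rich connective
tissues whose effective transverse relaxation time T2\* is on the order
of a millisecond. At conventional echo times their signal has decayed
to nothing, so they appear as dark, unmeasurable bands in ordinary MRI.
Dual-echo ultra-short echo time (UTE) acquisitions collect one image at
TE around 0.05 ms — where fascia still carries signal — and a second at
a few milliseconds, where only muscle and fat remain. Subtracting the
second echo from a suitably scaled first echo isolates the short-T2\*
tissue as a thin bright annulus at the muscle periphery.

Every pixel in this package is modelled mono-exponentially:

$$S(\mathrm{TE}) = S_0 \, e^{-\mathrm{TE}/T_2^*},$$

which is the entire physics the pipeline relies on. The package
implements the downstream image-processing chain: intensity matching of
the two echoes, subtraction, enhancement, frequency-domain artifact
suppression, unsupervised segmentation (K-means, watershed), skeleton
based thickness measurement, and muscle-architecture metrics from
streamline tracts. Processing is strictly 2D, slice by slice, because
the through-plane voxel dimension (3–5 mm) is an order of magnitude
coarser than the in-plane resolution (0.3–0.5 mm).

## The synthetic phantom: what it emulates, and what it does not

No scanner data ships with the package. Instead `makePhantom()` renders
a lower-leg axial cross-section from concentric geometry — background
air, subcutaneous fat, a thin deep-fascia annulus, muscle (optionally
split by an aponeurosis-like septum) and bone — and evaluates each
tissue's signal at the two echo times.

Default tissue parameters (the field publishes few T2\* values for
these tissues at 3T, so these are plausible-contrast choices fixed once,
not calibrations): S0 of 0.9/0.8/1.0/0.3/0 and T2\* of 15/1.2/25/0.4 ms
for fat/fascia/muscle/bone (background is air). They reproduce the
qualitative ordering the method depends on: fascia is bright only at
ultra-short TE; muscle and fat persist at the second echo; bone and air
are dark in both. Default echo times are 0.05/5.19 ms, mirroring a
spiral dual-echo UTE protocol, with 0.5 mm in-plane spacing on a
256-pixel grid and 5 mm slice thickness.

Corruptions, applied in physically meaningful order:

* **Bias field** (optional): `exp` of a low-order 2D polynomial in
  normalized coordinates, normalized to mean 1 — a smooth,
  multiplicative, invertible coil-shading surrogate. The default
  coefficient set (`defaultBiasField()`) produces roughly ±30 %
  shading.
* **Periodic noise**: a sinusoidal stripe added to *both* echoes
  (amplitude 0.08, 32 cycles/image at 30° by default). The wave vector
  is quantized to integer DFT bins, so the corruption occupies exactly
  two conjugate frequency bins — which makes the spike-suppression
  contract exactly testable on the discrete grid.
* **Rician noise**: per-pixel magnitude of (signal + complex Gaussian),
  the standard magnitude-MRI noise model, with sigma 0.03 by default
  (SNR ≈ 33 against unit muscle signal).

Geometry is rendered by radial classification at pixel centres with no
anti-aliasing, so the ground-truth annulus thickness is exact in pixel
units. What the phantom does **not** emulate: partial-volume mixing at
tissue boundaries, fat–water chemical shift, motion, k-space trajectory
artifacts of the radial/spiral acquisitions, and anatomical
irregularity of real fascia. Tests passing on the phantom therefore
demonstrate algorithmic correctness under controlled conditions, not
clinical performance.

Stripes are added to both echoes, so region-scaled subtraction already
cancels most stripe power; spike-suppression performance is therefore
assessed on a directly striped echo image, where the corruption is at
full strength.

## Region-specific scaling

The UTE echo has lower SNR and a different intensity regime than the
second echo. `regionSpecificScale()` multiplies the UTE image by a
factor chosen so that a *non-target* region — one whose signal should
vanish on subtraction — matches between echoes. The factor is the ROI
median ratio shTE/UTE; the mean ratio is computed alongside, and when
the two disagree by more than 20 % (skew from bias fields or outliers)
the factor becomes their average and the result is flagged
`"blended"`. The median is the primary statistic because it is robust
to the long intensity tails a bias field induces; the 20 % trigger is a
package choice, logged in every `ScalingResult`.

The ROI defaults to an automatic muscle estimate: Otsu's threshold
separates tissue from air on the shTE image, the histogram mode of the
tissue pixels locates the muscle intensity (muscle is ordinarily the
largest tissue in a leg cross-section), and the largest connected
component within ±0.15 of that mode, eroded by 3 px, becomes the ROI.
A user-supplied ROI always takes precedence and should be preferred
whenever the anatomy violates the largest-tissue assumption.

After `method = "median-ratio"` scaling the ROI median ratio equals 1
to machine precision — asserted by the class validity on every
constructed `ScalingResult`.

## Enhancement stages

* `contrastAdjust()`: linear remap of the window
  [mean − 2·sd, mean + 2·sd] ∩ observed range onto [0, 1]. The ±2·sd
  window covers ~95 % of a Gaussian histogram; the statistics-driven
  window is the package's concrete reading of statistics-based contrast
  enhancement.
* `topHat()`: white top-hat with a disk of radius 10 px — image minus
  its opening, keeping bright features narrower than the disk.
  Sub-millimeter fascia at 0.3–0.5 mm spacing is 2–5 px wide, well
  under the default disk.
* `wienerDenoise()`: pixelwise adaptive Wiener filter over a 20 × 20
  window with noise power estimated as the mean local variance.
  Preferred over erosion/dilation precisely because it does not alter
  the thickness of thin structures.

## FFT spike suppression

Periodic interference appears as isolated bright spikes in the
log-magnitude spectrum. `fftDenoise()` centre-shifts the spectrum,
protects a central disk of radius 0.08·min(dim) (the essential
low-frequency anatomy), flags bins whose log-magnitude exceeds
mean + 3.5·sd of the unprotected bins, zeroes them together with their
conjugate mirrors (keeping the output real), and inverse-transforms.
Spectral power never increases.

The protected-disk radius and spike z-score have no published values;
0.08 and 3.5 are package defaults exposed as configuration. A Gaussian
low-pass (cutoff as a fraction of Nyquist) is available but **disabled
by default**: on images whose object of interest is a 2–5 px annulus, a
0.3-Nyquist low-pass removes roughly a third of the image energy and
visibly erodes the fascia — incompatible with the contract that a clean
image passes through essentially unchanged. Users who want the heavier
smoothing described for noisier data can enable it with
`frequencyFilterSpec(lowpassFrac = 0.3)`.

## Segmentation

`kmeansIntensity()` flattens the image to a 1D intensity vector and
runs Lloyd's algorithm, k = 3 by default (on a subtraction image the
classes are, in practice, dark background/muscle residual, fat
residual, and fascia), with 10 seeded replicates initialized at k
distinct observed intensities; the replicate with the lowest
within-cluster sum of squares wins and clusters are relabelled by
ascending centroid. With 10 restarts the global optimum is reached in
almost all cases, but Lloyd fixed points are not guaranteed optimal;
the acceptance script reports the worst observed ratio against a
brute-force oracle rather than asserting equality by fiat.

`fasciaMaskFromClusters()` takes the brightest cluster as the fascia
candidate and removes stray speckles by keeping only components that
touch the band just outside the enclosed muscle interior (the interior
connected component of non-candidate pixels that does not touch the
image border). When the annulus is broken no closure is applied —
missing arcs stay missing, so the mask never hallucinates fascia.

`watershedSegment()` reproduces the MATLAB-style marker-free watershed:
binarize at 0.6 (on [0, 1]-normalized intensities — every stage output
is normalized for exactly this reason), compute the Euclidean distance
from each foreground pixel to the nearest background pixel, flood the
negated map with 8-connectivity, and label catchment basins; background
stays 0. The flooding itself is EBImage's watershed; a 1-px ridge
(label 0) between adjacent regions is derived afterwards to match the
MATLAB semantics in which watershed lines belong to no basin.

## Thickness measurement

`skeletonThickness()` implements midline-based thickness: the mask is
thinned to a 1-px skeleton (Zhang–Suen, preserving the topology of a
closed ring), spurs shorter than 5 px — thinning artifacts on noisy
annuli — are pruned, and at each skeleton pixel the distances from the
midline to the inner and to the outer boundary are measured along the
local midline normal (tangents from second moments of neighbouring
skeleton pixels in a 5 × 5 window; boundary located at sub-pixel
precision as the midpoint between the last sample inside and the first
outside, step 0.25 px). The two distances are summed, converted to mm,
and averaged over the skeleton; slices are averaged into an overall
mean, with empty slices excluded (an empty slice has no measurements,
so it contributes none rather than a zero).

A doubled Euclidean distance transform at the skeleton is the simpler
realization, but the discrete EDT measures centre-to-centre distances:
any single constant-offset correction is biased by a full pixel for
even pixel thicknesses, where the skeleton cannot sit on the true
midline. The two-sided normal measurement removes that parity bias —
phantom annuli of 2–10 px recover their truth within 0.1 px — and the
EDT convention (2·EDT − 1 px) remains as the fallback for degenerate
skeleton pixels with no usable tangent. At 45° the staircase boundary
of a discrete bar limits accuracy to about 0.75 px, within the 1 px
discretization allowance.

In-plane anisotropy is rejected (row/col spacing must agree within
1 %) rather than silently averaged.

## Architecture metrics

`architectureReport()` consumes streamline tracts produced elsewhere
(tractography itself is out of scope — the package reads a documented
plain-text polyline format) plus a muscle mask stack:

* tract lengths are arc lengths; the plausibility filter keeps the
  **closed** interval [5, 200] mm (the bounds are stated inclusively;
  a 5 mm tract is kept);
* the fascicle vector is the end-to-end chord — one vector per
  fascicle — and the pennation angle is folded to [0°, 90°] via the
  absolute dot product with the line of action, since fibre orientation
  is direction-agnostic;
* the line of action, when not supplied, is the principal eigenvector
  of the foreground voxel covariance, sign-fixed to positive
  through-plane. This is a geometric proxy; the report records which
  vector was used, and a supplied vector always wins;
* PCSA = muscle volume / mean fascicle length, re-asserted exactly on
  every constructed report.

All scalars are invariant under a common rigid rotation of tracts and
line of action (checked to 1e-9 in the tests).

## Numerical choices and degenerate inputs

* Intensities: every stage output is min–max normalized to [0, 1]
  unless flagged raw; constant images pass through unchanged (their
  normalization is undefined).
* Coordinates: 0-based [row, col] thinking, physical position =
  index × spacing, all lengths in mm.
* Constant image into `contrastAdjust()`: rescaled by its maximum with
  a warning. Empty foreground at the watershed threshold: warning and
  zero regions, not an error. Empty masks into thickness: error — a
  thickness of nothing is meaningless.
* K-means requires at least k distinct intensities; fewer is an error,
  not a silent merge.
* Determinism: every stochastic stage takes an explicit seed;
  `runPipeline()` writes a provenance JSON capturing stages, parameters
  and seeds sufficient to reproduce the run.

## Problem sizes

Test and acceptance computations use 192–256 px phantoms, 20-seed
repetitions for the scaling and SNR properties, 1000 synthetic tracts,
and 12-value brute-force K-means oracles — sizes at which every
quantity above is computed from scratch in seconds on one CPU.

## Known limitations

* The phantom's tissue parameters are plausible, not calibrated;
  absolute SNR values on real scanner data will differ from phantom
  values, and the published in-vivo results (absolute fascia thickness
  distributions, fascicle lengths of real muscle) cannot be reproduced
  without the scan data.
* The automatic muscle ROI assumes muscle is the dominant tissue near
  the histogram mode; pathology or unusual anatomy breaks that
  assumption and calls for a user ROI.
* DICOM series must be converted to NIfTI upstream; the package reads
  NIfTI only.
* Segmentation here assists rather than replaces expert delineation:
  K-means and watershed are unsupervised intensity methods with no
  anatomical prior beyond the cluster-to-tissue ordering of the
  subtraction image.
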