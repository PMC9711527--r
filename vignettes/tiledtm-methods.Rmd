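---
title: "Whole-lamella template matching with tiledtm: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-lamella template matching with tiledtm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiledtm)
```

## The imaging problem

A FIB-milled lamella is a 100–250 nm slab of a frozen cell, a few microns
across. To image it completely at high magnification with a condensed
(sub-micron) electron beam, the beam is stepped across the lamella with
beam-image shift in a hexagonal serpentine pattern, one exposure per
position, so that the union of circular illuminated areas covers the whole
slab and each area of the specimen is exposed once. Each tile is then
searched for a known macromolecular complex by 2D template matching (2DTM):
projections of a 3D reference density over a dense grid of orientations are
cross-correlated with the tile, and peaks of the standardized maximum over
the search ("scaled MIP", in SNR units) above an extreme-value threshold are
reported as detections. Finally the tiles are stitched into one montage by
masked cross-correlation and a global least-squares adjustment, which places
every detection in a common 3D frame (x, y from the montage, z from
defocus).

`tiledtm` implements this entire chain, together with a synthetic-scene
generator that produces tile exposures with planted ground truth, so that
every stage can be validated quantitatively without any microscope data.

## Acquisition planning and defocus feedback

Four annotated corners define the lamella. The plan is a hexagonal lattice
with in-row spacing $\sqrt{3}\,f\,r$ and row spacing $\tfrac{3}{2} f r$,
where $r$ is the illuminated radius and $f$ (default 0.95) shrinks the
lattice to guarantee overlap between neighbouring disks; for $f \le 1$ the
disk union covers the plane ($\text{spacing} \le \sqrt{3} r$ is the
hexagonal cover condition). Rows are traversed serpentine so every exposure
is adjacent to the previous one, and the first row lies on the edge between
the first two corners so the initial, uncorrected exposure lands on
expendable area.

Focus is not measured on a sacrificial area. Instead each exposure's
defocus is estimated after the fact, and the next exposure is corrected by
the difference from the 800 nm setpoint:
$\text{nominal}_{k+1} = \text{nominal}_k - (\text{measured}_k - 800)$.
This one-step controller has a closed-form behaviour we test: on a linear
defocus ramp of $\delta$ per exposure the measured defocus settles at
$800 + \delta$ (one-step lag), and on a static field the running mean
converges to the setpoint. `simulate_feedback_acquisition()` reproduces a
whole serpentine collection over an affine "height" field with Gaussian
measurement noise.

## Pre-processing

* **Illumination mask** — lowpass the tile at 100 Å, threshold at 10 % of
  the maximum, lowpass the binary mask again at 100 Å to smooth its edge.
* **Noise fill** — pixels outside the mask are replaced by i.i.d. Gaussian
  draws matched to the illuminated mean and standard deviation. This
  removes the beam edge, which otherwise dominates every cross-correlation
  downstream. A consequence worth noting: after filling, the frame is
  statistically homogeneous by construction, so a mask recomputed from the
  filled image is the full frame — the mask must always be computed from
  the raw tile (our tests check mask stability on the raw image and the
  moment matching of the fill separately).
* **Frame alignment** — movie frames are aligned using only a centered
  crop of half the side length per axis (a quarter of the area), because
  the beam edges do not move with the sample and would anchor a whole-frame
  alignment; the estimated shifts are then applied to the full frames.
* **Exposure filter** — frame $k$ at cumulative dose $D_k$ is weighted in
  Fourier space by $\exp(-D_k / 2 N_c(s))$ with the empirical critical
  exposure $N_c(s) = 0.24499\, s^{-1.6649} + 2.8141$ (e$^-$/Å$^2$, $s$ in
  1/Å).
* **Resampling** — Fourier crop/pad to a 1.5 Å working pixel; output sides
  are rounded to even numbers and the mean is preserved.
* **CTF estimation** — a grid search of the rotationally averaged power
  spectrum against $\mathrm{CTF}^2(s)$ over 0.2–2 µm defocus (default step
  0.01 µm), with optional 2D astigmatic refinement by Nelder–Mead. A
  featureless spectrum sets a low-confidence flag instead of failing.
* **Ice thickness** — Beer–Lambert, $t = \Lambda \ln(I_0 / I)$ with
  $\Lambda = 322$ nm, $I$ the mean masked intensity and $I_0$ the vacuum
  intensity (taken from tile metadata; the generator records it).

## 2D template matching

The tile is whitened (Fourier amplitudes divided by the square root of its
rotationally averaged power spectrum, unit variance inside the mask). For
every orientation on a uniform grid (latitude rings spaced by the
out-of-plane step, azimuth widened by $1/\sin\theta$, all in-plane angles)
and for each of the defocus planes (default 11 planes, 20 nm apart,
centered on the fitted defocus), the template projection is CTF- and
B-factor-filtered, normalized to zero mean and unit L2 norm, and correlated
with the whitened tile by FFT. Each correlation value is then a
matched-filter SNR sample; for pure noise the samples are standard normal
(a property we test directly on `correlation_map()` output). Per-pixel
running means and variances over the whole search standardize the maximum
into the scaled MIP.

The CTF is $-[\sqrt{1-w^2}\sin\chi + w\cos\chi]$ with
$\chi = \pi\lambda z s^2 - \tfrac{\pi}{2} C_s \lambda^3 s^4$,
$w$ the amplitude contrast (0.07), $C_s = 2.7$ mm, 300 kV
($\lambda = 0.0197$ Å). The B-factor envelope is $e^{-B s^2/4}$; a template
B-factor of $B$ is equivalent to a Gaussian lowpass with filter constant
$\sqrt{B/2}$ (120 Å$^2$ → 7.7 Å). The workflow default boosts the atomic
median B-factor of 80 Å$^2$ by 1.5 to 120 Å$^2$.

**Detection threshold.** The threshold $t$ solves
$N \cdot \mathrm{erfc}(t/\sqrt{2})/2 = 1$ where $N$ is the number of search
outcomes of one tile, counted as *masked pixels × orientations*. Defocus
planes are excluded from the count because defocus-adjacent correlations
are strongly dependent; under this convention the printed full-frame search
geometry (5760 × 4092 camera resampled 1.76 → 1.5 Å, 1.5°/1.0° grid)
yields $t = 7.75$. The count convention is recorded in the
`match_result$n_effective` field.

**Independence and the false-positive rate.** The erfc calibration treats
search outcomes as independent. Correlations between neighbouring
orientations reduce the effective number of trials and push the observed
false-positive rate *below* one per tile; this is visible in real data
(regions known to contain no targets show roughly 0.4 false positives per
tile against the nominal 1) and is easy to reproduce here: oversampling the
orientation grid relative to the template's angular correlation length
lowers the rate several-fold without changing the threshold. Our
calibration experiment therefore uses a template/grid pairing in which the
grid step matches the template's angular correlation length (pseudo-atoms
spread over 30 % of a 48 px box, 40°/45° grid), for which 20 noise-only
tiles average about one detection each. The detection pipeline defaults to
a finer 20° grid, which favours recovering targets at arbitrary
orientations at the cost of an over-conservative false-positive rate — the
same trade the full-scale 1.5°/1.0° search makes.

**Desk scale vs full scale.** All defaults in `default_pipeline_config()`
are a scaled-down study: 128 px camera at 8 Å, 45 nm beam radius, 32–48 px
templates, 20°–45° grids, 1–5 defocus planes. They keep a full synthetic
run (plan → simulate → preprocess → match → montage → report) in the
minutes range on one CPU while exercising exactly the code a full-scale
search would use; the full-scale parameters remain plain arguments. Two
desk-scale artifacts are expected and documented: targets at orientations
between grid points lose correlation (recovery ~70–80 % instead of ~100 %),
and strong targets produce secondary peaks within the template footprint
that a fine angular grid would suppress.

## The synthetic scene generator

The generator emulates the statistical structure the pipeline assumes:

* a polygonal lamella with an affine thickness map (default 150 nm) plus a
  smooth stationary random roughness field (sum of random cosine waves,
  default sd 25–35 nm, correlation length 5 nm). Through Beer–Lambert
  attenuation the roughness produces the low-contrast specimen texture that
  montage registration relies on; being stationary and isotropic it is
  fully flattened by the whitening filter, as real structural noise is
  modelled to be;
* planted rigid-body target instances from a homogeneous Poisson process
  (default 500 µm$^{-2}$), excluded from configured organelle polygons,
  with z uniform through the local thickness and uniform orientations;
* a circular beam vignette with a cosine edge and optional damped-cosine
  fringes in the outer 5 % of the disk (the eucentric-focus ripple
  artifact);
* multiplicative camera shading, default a brighter annulus near the
  periphery of the illuminated area (the static background pattern that
  tile averages expose);
* additive Gaussian noise, default sd 10 counts on a 100-count beam —
  the shot-noise scale of the vacuum intensity.

The template stand-in is a cloud of sharp Gaussian pseudo-atoms (width
0.7–1.1 px) in a ball of configurable radius. Sharp, spread scatterers make
projections of distinct orientations decorrelate the way atomic-model
projections do; the `blob_spread` argument sets the angular correlation
length (roughly blob width / cloud radius in radians) and therefore which
grid steps the template can support.

What the generator does *not* emulate: physical electron–specimen
scattering, detector MTF/DQE, FIB damage layers, structured cellular
content beyond the roughness field, and orientation preferences. Passing
tests on these scenes therefore validates the pipeline's statistics and
geometry, not its behaviour on arbitrary real specimens.

## Montage assembly

Tile coordinates initialize from the calibration $c_i = IC\, b_i$. All
pairs with $|c_i - c_j| < D_\text{beam}$ are cross-correlated, masked to
the *predicted overlap lens* of the two illuminated disks (content outside
the shared area would otherwise generate spurious peaks), with the binary
masks eroded by 4 px to drop the static beam-edge rim. The correlation is
searched in a window (default ±20 px) around the predicted displacement,
indexed modulo the frame because offsets near the frame size alias in the
circular correlation; the peak is refined by quadratic interpolation. The
offsets $r_{ij}$ (estimating $c_i - c_j$) feed a linear least-squares
problem $\min_c \sum_{ij} \| r_{ij} - (c_i - c_j) \|^2$, solved per
connected component with the translational gauge fixed to the initial
centroid; cross-correlation and solve alternate for two rounds. Tiles are
blended on a common canvas with mask-weight feathering normalized to unit
total weight per covered pixel.

Detections map into the montage as $m^M = m^T + c_i$; the z coordinate is
the sum of the per-target defocus-plane offset, the deviation of the
tile's estimated defocus from the setpoint, and the tile's nominal focus
term. z is relative (the setpoint focal plane is the origin); the paper's
convention leaves the absolute origin undefined.

## Numerical choices and degenerate inputs

* Pixel conventions: images are `[row, col]` matrices, user-facing
  coordinates are 0-based with x = column, y = row (down). MRC I/O writes
  x-fastest mode-2 float.
* Orientation count for the 1.5°/1.0° grid is computed without
  materializing the 6.6-million-row table (`orientation_grid_size()`).
* The in-plane dimension of the projection bank is generated by 2D rotation
  of one base projection per direction (bilinear, ~1 % interpolation error
  against full 3D rotation), which makes the bank ~10× cheaper.
* Degenerate inputs: a corner quadrilateral collapsed to a point plans a
  single exposure; an all-zero tile raises an empty-mask error; a
  featureless power spectrum flags low confidence instead of failing;
  a pair graph without edges returns the initial coordinates with a
  warning; fewer than two detections in a tile yield no z-extent row.
* Sub-pixel refinements clamp to ±0.5 px; erosion uses an integral-image
  box filter; point-in-polygon uses the even-odd rule.

## Problem sizes used in the tests

The test suite and the acceptance script run, on one CPU: 20 noise-only
128 px tiles for the false-positive calibration (40°/45° grid, one defocus
plane); 15 planted-target tiles for the sensitivity check; 20 planted
defoci for CTF recovery on 192 px spectra; a 3 × 3 crop-fixture montage
for sub-pixel recovery; and a reduced end-to-end run over a 4–10 tile
serpentine block. These sizes were chosen so the full suite completes in a
few minutes while every statistical tolerance stated above remains
testable.

## Known limitations

* The desk-scale orientation grids trade off false-positive calibration
  against off-grid sensitivity (see above); only the full-scale 1.5°/1.0°
  grid achieves both at once, at ~3000× the compute.
* Montage registration accuracy on independently noisy tiles is limited by
  the thin (~10 % fractional) overlap; with the default texture it is a
  few pixels, while noise-free consistent fixtures recover to < 0.5 px.
* The CTF fit assumes an oscillation-bearing spectrum; tiles whose power
  spectrum is dominated by flat noise return the low-confidence flag and
  should fall back to the feedback-loop defocus estimate (the pipeline
  does exactly this).
* `estimate_thickness()` inherits any bias in the vacuum-intensity
  reference; the 322 nm coefficient is treated as covering the full
  energy-filtered setup.
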