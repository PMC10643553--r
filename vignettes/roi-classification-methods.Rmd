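---
title: "Physics-informed RoI selection for scanning X-ray diffraction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-informed RoI selection for scanning X-ray diffraction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptyroi)
```

## The problem

A ptychographic scan records a far-field diffraction pattern
$\mathbf{P}^k \in \mathbb{R}^{N\times M}$ at each of $K$ scan positions.
Reconstruction cost grows with $K$, yet in isolated-sample geometries most
positions see only empty background. `ptyroi` classifies, before any
reconstruction, which scan positions are informative — the region of
interest (RoI) — using only two cheap per-pattern features and
unsupervised two-cluster k-means, so no threshold has to be picked by hand.

## The two feature channels

**Absorption (transmission).** $T^k = \sum_{i,j} P^k_{j,i}$, the total
count on the detector. Positions where the beam crossed absorbing material
transmit less. Mapped to the scan grid this is exactly the STXM
(scanning-transmission) contrast image.

**Scattering direction (center of mass).** The intensity-weighted centroid

$$O^k = \Bigl(\tfrac{1}{T^k}\textstyle\sum_i i \sum_j P^k_{j,i},\;
               \tfrac{1}{T^k}\textstyle\sum_j j \sum_i P^k_{j,i}\Bigr),$$

whose deviation from the beam center encodes the net deflection of the
beam by phase gradients (differential phase contrast). The $K\times 2$
CoM array is standardized column-wise to zero mean and unit variance,

$$\vec O^k = \Bigl(\tfrac{O^k_x - \bar O_x}{\sigma_x},
                   \tfrac{O^k_y - \bar O_y}{\sigma_y}\Bigr),$$

which both calibrates away any constant beam-center offset (and the 0- vs
1-based indexing convention — the package verifies this invariance) and
renders the two axes comparable. The row norm $\lVert \vec O^k \rVert$ is
the scattering-strength feature: large at object boundaries and phase
gradients, near zero over featureless background and flat interiors.

We use the *population* standard deviation in the standardization; the
choice between population and sample denominators is a monotone rescale
that cannot change any clustering outcome, and is fixed only so results
are bit-reproducible. Zero-variance columns (a completely uniform scan)
standardize to zeros and raise a degeneracy flag rather than erroring.
Patterns with zero total intensity have no defined CoM; they are excluded
from the moments and assigned standardized CoM $(0,0)$ — magnitude zero,
i.e. "no evidence of scattering" — with the event counted.

## Conditioning before clustering

Each feature vector is arranged on the scan grid, smoothed with a $3\times
3$ mean filter (replicate-padded at the edges; EMPTY cells — grid cells
with no recorded pattern, as arise in fly scans — are excluded from each
window and stay missing), and then, for the absorption channel only,
log-transformed ($v \mapsto \ln\max(v,\varepsilon)$ with $\varepsilon$
fixed at $10^{-3}$ times the smallest positive value in the map, so the
floor is unit-independent).

The natural log is the right scale for transmitted totals: absorption is
multiplicative (Beer–Lambert), totals are bounded away from zero by the
direct beam, and the log turns material thickness into an approximately
linear signal. The same transform is *not* applied by default to the CoM
magnitudes: they are already dimensionless, and their background is a
noise floor near zero, so a log stretch inflates the spread of pure noise
and pulls the two-means split into the background (we measured the
threshold dropping to $0.3\sigma$, mis-selecting roughly half of the
featureless field on the synthetic reference scene). Both channels'
conditioning flags are arguments of `run_pipeline()` and of the CLI, so
the log-both variant remains one switch away.

## Exact two-cluster k-means in one dimension

Each conditioned channel is split into two clusters. For one-dimensional
data, the optimal 2-means partition is always an interval split of the
sorted values, so `two_means_1d()` finds the *global* optimum
deterministically by scanning all $n-1$ thresholds with prefix sums —
no iterations, no seed, and never worse than Lloyd's algorithm with any
iteration count. A Lloyd mode (`stats::kmeans`, 10 iterations, 10
restarts) is retained for parity experiments and is used in the test
suite as an independent cross-check.

Cluster selection is physics-based and by *centroid order*, never by
cluster size: the lower-centroid cluster of the absorption channel is the
RoI (the object absorbed the beam), the higher-centroid cluster of the
scattering channel is the RoI (the object deflected the beam). A field of
view that is mostly sample therefore still classifies correctly. The two
selections are OR-combined, counting doubly-flagged positions once, and
every selected cell records which channel (and wedge, below) flagged it.

## Azimuthal segmentation for sub-beam features

A feature smaller than the beam, sitting entirely inside the probe,
scatters to $\pm q$ symmetrically, so its contribution to the
*whole-pattern* CoM cancels — the position looks featureless at $n=1$.
The remedy is to partition the detector into $n$ azimuthal wedges of
width $\theta = 360^\circ/n$ about the pattern center and run the entire
recipe per wedge: per-wedge totals $T_s^k$, per-wedge CoMs in full-frame
coordinates, per-wedge standardization across $k$, per-wedge clustering,
and a final OR over all $2n$ selections. An anisotropic scatterer throws
its streak into one wedge (and its mirror wedge), where it no longer
cancels.

Numerical choices that make the partition exact:

* Wedge membership is computed in *turns* (`atan2 / 2π`), in which pixels
  lying exactly on the axes or diagonals bin exactly (IEEE division by a
  power-of-two multiple of the same mantissa); half-open bins
  $[s\theta, (s{+}1)\theta)$ and a fixed rule for the center pixel (wedge
  0) give each pixel exactly one wedge, so per-wedge totals conserve
  $T^k$ to the last bit and the intensity-weighted wedge CoMs recombine
  to the whole-pattern CoM (tested at $10^{-9}$ relative).
* Wedges are anchored at the geometric pattern center $((N{-}1)/2,
  (M{-}1)/2)$ by default, overridable with a calibrated beam center. The
  angular origin is the $+x$ axis, counter-clockwise with $y$ up; results
  for isotropic scenes are origin-insensitive, but for strongly oriented
  scatterers the wedge layout matters (a streak falling on a wedge
  boundary splits its signal).
* `run_pipeline(n_segments = 1)` reduces *bit-identically* to the
  whole-pattern recipe (the same code path computes the features), which
  the suite asserts.

With more wedges each bin holds fewer photons, so the per-wedge CoM noise
grows; past a useful range the high-magnitude cluster fills with noise
and the retained fraction climbs without new features appearing. The
package reproduces this trend (retention at $n=40$ well above $n=8$ on
the reference scene) and we regard $n=8$ as the practical default.

## RoI post-processing

`adjust_border()` grows (positive) or shrinks (negative) the mask by a
per-axis number of scan steps — separable rectangular
dilation/erosion with a $(2|b_y|{+}1)\times(2|b_x|{+}1)$ element, the only
reading of "steps outwards along x and y" consistent with per-axis
counts. Outside the grid is background for dilation (no wrap) but never
counts against a cell during erosion, so closing (dilate-then-erode)
always contains the input; both laws are property-tested. EMPTY cells
hold no pattern and are never selected by growth. `fill_in()` converts
enclosed background (not 4-connected to the grid boundary) into RoI —
useful for weakly absorbing objects where only the boundary scatters.
`retained_fraction()` reports the selected percentage of patterns to
0.1%.

## Baselines

Three conventional contrast maps are provided for head-to-head
comparison, each fed to the same exact 2-means: STXM (identical by
construction to the absorption map; lower cluster), Hilbert differential
phase contrast (normalized left–right detector asymmetry,
$(\Sigma_R - \Sigma_L)/T \in [-1,1]$, center column split evenly;
clustered on absolute value, higher cluster), and computational
dark-field (sum outside a centered circular mask; higher cluster).
`suggest_radius()` proposes the smallest radius enclosing a configurable
fraction (default 99%) of the stack-mean pattern. `baseline_roi()`
clusters the map exactly as given; for comparisons against the main
pipeline we smooth baseline maps with the same $3\times 3$ filter first.

## The synthetic scene: what it emulates, and what it does not

Real scanning-diffraction data with ground truth are not bundled;
`make_scene()`/`simulate_scene()` generate them. The forward model is the
standard thin-sample ptychographic one: exit wave = probe × object
window; far-field intensity = $|\mathrm{DFT}(\psi)|^2$, sampled at
half-integer frequencies so the zero-scattering peak falls exactly on the
geometric detector center used by the CoM, wedge and mask conventions
(for an even-sized frame the usual integer-frequency DFT puts the DC term
half a pixel off-center, which would leak a spurious asymmetry into every
centered feature); counts are scaled so a free-space position collects
`photons` expected counts in total (Parseval-exact, tested at $10^{-9}$),
and each pixel receives independent Poisson noise.

The `"reference"` preset is the frozen study scene:

* 160×160 px object; 24×24 raster with 4 px steps; 64×64 px patterns;
  probe = hard circular aperture, support diameter $D = 20$ px (5 scan
  steps — heavily overlapped, as in real fly scans);
* one main particle: disk, radius 25 px, amplitude transmission 0.5,
  phase 0.5 rad — a large, strongly absorbing object;
* three satellites: phase-only ellipses, semi-axes 4×2 px (major diameter
  8 px, well under the beam), phase 0.9 rad, fixed distinct orientations,
  centers placed so their ground-truth neighborhoods do not overlap the
  main particle's, positions jittered ±3 px by the scene seed. The
  *elongation is essential*: a circular sub-beam particle scatters an
  azimuthally uniform ring, which the per-wedge CoM gains nothing on; a
  plate-like particle throws an oriented streak — the azimuthal-
  segmentation use case. Orientations are fixed scene properties because
  a streak landing on a wedge boundary splits its signal between two
  bins;
* $2\times 10^5$ expected photons per pattern, putting the estimated SNR
  at ≈ 6.4. At ten times this flux the CoM maps are so clean that the
  partial-overlap residual of a satellite (the probe edge clipping it
  asymmetrically) becomes visible to the whole-pattern CoM, and the
  $n=1$ vs $n=8$ contrast that motivates segmentation disappears; the
  moderate-SNR regime is where the method's value shows.

Ground truth: a position is in the RoI iff the probe support disk
intersects the particle's pixel support (exact for any shape); a stricter
overlap requirement can be imposed by the caller by scoring against a
particle subset. `estimate_snr()` is defined here as mean(clean) /
RMS(noisy − clean), averaged over patterns — for Poisson noise on
constant intensity $\lambda$ it converges to $\sqrt\lambda$ (tested).
It is a documented, testable definition, not a reconstruction of any
instrument-specific estimator.

What the scene does **not** emulate: partial coherence, fly-scan motion
blur, detector point spread or hot pixels, probe aberrations beyond a
hard aperture, or multi-material samples. Passing on this scene shows the
pipeline's logic and numerics are right under the stated model; it does
not by itself certify performance on any particular instrument's data.

## Known limitations, measured

Two behaviors of the method are worth stating plainly, both measured on
the reference scene and stable across noise seeds:

* **The RoI boundary sits at the half-overlap contour.** Two-means on a
  contrast continuum places its threshold roughly midway between the
  background and object cluster centroids, so positions where the probe
  barely grazes the object (weak signal) fall in the background cluster.
  Against an *any-overlap* ground truth the whole-pattern recall
  saturates near 0.73 here — the outermost probe radius of truth is a
  wide band when the probe spans 5 scan steps, and its outer half carries
  almost no signal. Precision is ≈ 1.0. This is exactly the gap that
  `adjust_border(+b)` exists to close at reconstruction time.
* **Dark-field on a strongly absorbing object is absorption-dominated.**
  The outer-mask sum over the particle interior drops with the direct
  beam, so 2-means isolates the interior as the low cluster at any mask
  radius, and the "high" cluster covers most of the field — the
  dark-field baseline degenerates on this scene type. STXM and HDPC
  baselines behave canonically and each miss satellites the segmented
  pipeline finds.

## Problem sizes

The test suite and the acceptance script run the full reference study —
576 patterns of 64×64 px, pipelines at $n \in \{1, 8, 40\}$, three
baselines and morphology property sweeps — in well under a minute on one
CPU; the simulation itself takes about a second. Whole-pattern features
for a production-scale dataset ($\sim$16k patterns of 256×256) are a few
seconds of `colSums` work; per-wedge features use one indicator-matrix
crossproduct per stack and scale the same way.
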