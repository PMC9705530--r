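---
title: "voltrace: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voltrace: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

voltrace processes volumetric (4D) calcium-imaging movies from static
light-sheet microscopes: it removes acquisition artifacts, factorizes the
movie into neuronal sources, filters the sources morphologically and
statistically, and maps functional connectivity. This vignette explains the
underlying models, the parameters that matter, and the choices made where
the design was genuinely open. It states no empirical numbers beyond what
the package's own tests and `scripts/acceptance.R` compute.

## The signal model

A movie is a nonnegative array $Y$ over $(t, z, y, x)$ with voxel pitch
$(d_z, d_y, d_x)$ in micrometres (default $(3, 1.3, 1.3)$: 3 µm plane
spacing, a 666 µm lateral field binned to 512 px on a 20x objective) and a
volume period of 0.2 s (20 planes at 10 ms each, i.e. 5 volumes/s). The
factorization stage models

$$Y = AC + B + E$$

where the columns of $A$ are nonnegative, spatially compact 3D footprints
(one per neuron), the rows of $C$ are nonnegative activity traces, $B = bf$
is a rank-$n_b$ background capturing slow drifts and out-of-focus light,
and $E$ is residual noise.

## Sensor kinetics and the synthetic kernel

The red indicator's response is summarized by two measured half-times:
0.09 s from stimulus to half of the peak and 0.78 s from the peak back to
half. `make_kernel()` builds the double-exponential impulse response

$$k(t) \propto (1 - e^{-t/\tau_r})\, e^{-t/\tau_d}, \qquad k(0) = 0,$$

normalized to unit peak. Converting each half-time separately by
$\tau = t_{1/2}/\ln 2$ does **not** reproduce the measured half-times of
the composite kernel: past the peak the rise factor keeps growing, so the
peak-to-half time of that kernel is about 0.90 s rather than 0.78 s. Since
the published values are *measurements of the response*, the default
(`conversion = "calibrated"`) numerically solves for $(\tau_r, \tau_d)$
such that the kernel's measured time-to-half-rise and peak-to-half-decay
equal the stated values; the per-phase conversion remains available as
`conversion = "halflife"` for comparison.

## The synthetic recording generator

No public volumetric recordings accompany the processing configuration the
package implements, so `synth_config()`/`simulate_movie()` generate fully
seeded 4D movies with ground truth. The generator emulates, in order of
assembly:

* **Active neurons** — non-overlapping ellipsoidal somata with semi-axes
  $(4.5, 7, 7)$ µm (about 924 µm³, inside the morphological band used by
  the volume filter), center-weighted footprints, homogeneous Poisson
  firing at 0.1 Hz per neuron, and clean traces equal to the spike train
  convolved with the sensor kernel. Transients peak at ~60 counts over a
  ~50-count resting level.
* **Static neurons** — non-firing somata at the same resting brightness;
  the firing/non-firing brightness ratio is not constrained by the imaging
  physics, so it defaults to 1:1 and is configurable.
* **Out-of-focus fluorescence** — every volume receives an added
  Gaussian-blurred copy of itself whose axial scale is set by the
  light-sheet thickness ($2 w_0 = 8$ µm by default, consistent with a
  sheet thickness below 10 µm), weighted by `oof_strength`.
* **Stripe shadows** — N occluders at random $(y, z)$ positions each cast
  a Gaussian-profile attenuation band that begins at the occluder's $x$
  position and is constant along $+x$ (shadows propagate along the
  illumination axis). The shadow width (σ = 4 µm across $y$) corresponds
  to cell-scale optically dense objects. Attenuation amplitudes carry
  smooth AR(1) temporal jitter — the temporal variance that the Fourier
  filter exploits.
* **Photobleaching** — a global multiplicative $e^{-t/\tau}$ with
  $\tau = 200$ s.
* **Rigid drift** — a smoothed random walk scaled to about one voxel
  laterally (half that axially), matching sub-cellular sample movement.
* **Noise** — Poisson shot noise on expected counts plus additive
  Gaussian read noise (σ = 2 counts).

All randomness is fixed by a single seed; ground truth (footprints, spike
times, clean traces, bleach curve, stripe parameters, drift) is returned
alongside the movie. What the generator does **not** emulate: tissue
scattering, wavelength-dependent attenuation, indicator saturation and
dye-expression heterogeneity. Passing tests on synthetic data therefore
demonstrate algorithmic correctness under the stated statistical structure,
not performance on real organoid recordings.

The default problem size (300 volumes of 64 × 64 × 16 voxels, 20 active
plus 10 static neurons) was chosen so every stage, including the full
two-pass factorization, runs in minutes on one core while preserving the
densities the pipeline assumes.

## Preprocessing

**Bleach correction** divides each volume by its spatial median, which
removes any global multiplicative trend exactly and leaves every volume
with median 1.

**The spatial-Fourier temporal-variance filter** computes the 3D FFT of
every volume, the per-coefficient temporal variance
$\operatorname{E}|f - \operatorname{E} f|^2$, and zeroes — for all time
points — the coefficients at or above the 99th percentile of the variance
map. Stripes and large-scale background flicker concentrate in few
low-frequency coefficients with large temporal variance; almost point-like
neurons spread across the whole spectrum. Numerical choices:

* The variance map of a real movie is Hermitian-symmetric; it is
  explicitly symmetrized against float round-off so the kept set is
  symmetric and the output exactly real.
* The quantile uses the default linear-interpolation estimator
  (`stats::quantile` type 7). Because quantiles commute with monotone
  maps, thresholding the variance or its log10 selects the same
  coefficients.
* Coefficients with exactly zero variance are always kept, so a
  temporally constant movie passes through unchanged (the DC coefficient
  is treated like any other; after bleach correction its variance is near
  zero).
* Filtered movies may carry small negative excursions. They are kept:
  clipping at zero would rectify the removed modes back into spurious
  positive structure. For this reason the nonnegativity invariant of
  `movie4d()` applies to acquired and synthetic movies, not to derived
  (filtered, interpolated) ones.

**A scale caveat.** The 99th-percentile cut removes a fixed 1% of
coefficients. At full acquisition scale (512 × 512 × 20 voxels) neurons
occupy a vanishing fraction of the spectrum and the cut is carried by
stripe and background modes. In the 64 × 64 × 16 synthetic volume the
neurons' own low-frequency flicker dominates the top-variance band, so the
filter also removes neuron energy and spreads ringing ghosts of real
transients across the small volume. The package's stripe-suppression
property (≥ 90% stripe-energy reduction) holds at the default conditions,
but footprint-averaged trace recovery is measurably degraded there — an
effect that shrinks as the volume grows. Segmentation benchmarks on the
synthetic defaults therefore run bleach correction, motion correction and
factorization without the Fourier stage; the full pipeline order
(bleach → Fourier → motion → factorize → filter → connect) remains the
default of `run_pipeline()` for realistically sized data.

## Motion correction

Rigid 3D correction only. The template is the voxelwise median of the
first 30 volumes (configurable, or user-supplied); per-volume shifts
maximize the Fourier-domain cross-correlation with the template, refined
to sub-voxel precision by per-axis quadratic interpolation of the
correlation peak and clamped to `(2, 4, 4)` voxels in $(z, y, x)$.
`apply_shifts()` translates volumes by minus their shift with trilinear
interpolation, filling out-of-field voxels with the volume median. The
piecewise-rigid parameters of the reference configuration (strides,
overlaps, maximum rigid deviation) are recorded in `pipeline_config()` for
provenance but not executed: residual sample movement is sub-cellular, so
the rigid core suffices at the package's scales.

## Factorization

`run_extraction()` runs two passes, mirroring the run-twice strategy of
CNMF pipelines:

1. **Seeding.** The correlation image (mean temporal correlation of each
   voxel with its 6 neighbors) is smoothed at the expected component scale
   `gSig` = (2, 2, 2) voxels; strict local maxima with smoothed value of
   at least `min_corr` = 0.2 become candidate seeds, with a minimum
   separation of 2·`gSig` and at most `K` = 10 seeds per tile of side
   2·`rf`. The `min_corr` gate is the standard seed-quality threshold of
   correlation-image initialization: the correlation image of
   structureless noise stays near zero, so pure-noise movies seed nothing.
2. **Fitting.** Block-coordinate (hierarchical) alternating nonnegative
   least squares: each footprint is solved voxelwise under nonnegativity
   on a support box (side 4·`gSig`+1 around its seed, shrunk to the
   footprint's bounding box each sweep — "almost point-like" sources stay
   local); each trace is the exact nonnegative least-squares solution
   given its footprint; the background is the optimal rank-`nb` truncated
   SVD of $Y - AC$. Every update is an exact constrained block optimum,
   so $\|Y - AC - B\|^2$ is non-increasing; iteration stops at `n_iter`
   or when the relative error change falls below $10^{-4}$.
3. **Evaluation.** Peak SNR $(\max C_i - \operatorname{med} C_i)/\sigma_i$
   with $\sigma_i = 1.4826\,\mathrm{MAD}(\Delta C_i)/\sqrt{2}$, and
   spatial correlation between the footprint and the movie averaged over
   the trace's top-decile frames on the footprint's bounding box.
   Acceptance requires SNR ≥ 1 and spatial correlation ≥ 0.5. These
   formulas are documented approximations of the reference evaluators,
   which are not pinned beyond their thresholds.
4. **Second pass, merge, cleanup.** The whole volume is refit seeded only
   with accepted components; spatially overlapping components with trace
   correlation ≥ 0.8 merge transitively (footprints summed, the merged
   trace refit by nonnegative least squares); a final evaluation follows.
   Accepted footprints are then spatially thresholded at 25% of their
   maximum weight — the classic CNMF `threshold_components` convention —
   which trims the out-of-focus halo that the factorization rightly
   assigns to each neuron but that does not belong to its soma.

Temporal AR($p$) deconvolution is recorded (`p` = 2) but not implemented:
spike inference is downstream future work, and the constrained
least-squares traces are what the connectivity stage consumes.

## Postprocessing

* **Volume filter** — keep components with physical volume in
  [710, 7605] µm³ (inclusive; at the 20x voxel geometry these bounds are
  exactly 141 and 1500 voxels, and comparison carries a $10^{-9}$
  relative epsilon so the decimally exact upper bound is attainable in
  float arithmetic).
* **Variance filter** — min–max normalize each trace and discard
  components with variance above 0.06. Direction rationale: a slow drift
  spans the whole normalized interval and has variance near
  $1/12 \approx 0.083$, while a sparse transient trace with active
  fraction $p$ scores about $p(1-p) \ll 0.06$; the threshold therefore
  separates drift-dominated false positives (removed) from genuine sparse
  activity (kept). The direction is exposed as a switch because it is an
  inference from the filter's stated purpose, not a printed convention.
* **Normalization** — $\Delta F/F = (F - F_{\min})/(F_{\max} - F_{\min})$
  onto $[0, 1]$ (amplitude information lost), or the alternative
  $(F - F_{\min})/F_{\min}$ which preserves sensitivity to event counts.

## Connectivity

Components are ordered by distance from the constellation's center of
mass (the unweighted mean of the accepted centroids — the structural-image
COM is not available in general). The Spearman matrix is the Pearson
correlation of rank-transformed raw (footprint-averaged) traces with
average ranks on ties; rank correlation is invariant under monotone
transforms, hence robust to illumination-driven amplitude differences. The
graph keeps edges with $|R| > 0.8$ (strict), carries the signed
coefficient on each edge, and records node degree for degree-coded
display.

## Optics characterization

`fit_gaussian_1d()`/`fit_gaussian_2d()` implement the standard Gaussian
profile models (the rotated form's cross-term coefficients $a, b, c$ are
built from $\sigma_x, \sigma_y, \theta$, so their mutual consistency holds
by construction; the axis-aligned form fixes $\theta = 0$).
`fit_beam_waist()` fits the Gaussian-beam hyperbola
$w(x) = w_0\sqrt{1 + ((x - x_0)/x_R)^2}$, and
`rayleigh_length()` evaluates $x_R = n\pi w_0^2/\lambda$.
All nonlinear fits use Levenberg–Marquardt with moment-based
initialization, at most 500 iterations and $10^{-12}$ tolerances; widths
are reported as positive by construction. `measure_psf()` detects beads as
non-strict local maxima (a bead centered between voxels forms an
equal-valued plateau), extracts the lateral and axial line profiles
through each center within an 8 µm window (keeping neighboring beads out
of the fit), fits each in physical coordinates, and aggregates per-axis
$\sigma$ as mean ± sd across beads, reported exactly as "1/e radius" in
keeping with the field's labeling (intensity falls to $1/e$ of peak at
$\sqrt{2}\sigma$ for this parameterization).

## Degenerate inputs and tie-breaks

Constant traces are degenerate for min–max normalization and for rank
correlation (row/column zeroed with a warning). Zero-variance voxels
contribute 0 to the correlation image. Seeding ties break by descending
smoothed correlation, then lexicographic $(z, y, x)$. Greedy ground-truth
matching uses descending Jaccard overlap with deterministic index
tie-breaks, making the result independent of component order.

## Known limitations

* Spike-train deconvolution and directed/causal connectivity are out of
  scope.
* Piecewise-rigid (patch) motion correction is recorded in configuration
  only.
* The Fourier filter's fixed-percentile cut is scale-sensitive (see the
  caveat above).
* Real-data segmentation performance is not reproduced: no raw
  recordings or annotations are publicly deposited, and the package's
  synthetic benchmark is not a substitute for them.
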