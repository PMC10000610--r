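---
title: "Quantifying powder-heap surface roughness from contour-slice spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying powder-heap surface roughness from contour-slice spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coneroughness)
```

## The measurement problem

When a powder such as instant milk powder is poured, it settles into a
roughly conical heap.  A free-flowing powder gives a smooth, nearly
ideal cone; moisture-induced clumping produces visible lumps on the
flank.  Grading that lumpiness is traditionally a trained-panel task.
This package implements an objective alternative that works on a 3D
triangulated surface mesh of the heap (e.g. from photogrammetry): it
converts the geometry into per-layer roughness energies and grades the
sample with a small supervised classifier.

The core idea: a horizontal cross-section of an ideal cone is a circle,
so every departure of a cross-section contour from its best-fitting
circle is surface roughness.  Expressed as a function of angle and
analysed in the spatial-frequency domain, lumps of a characteristic
size appear as spectral energy at the corresponding wavelengths.

## The procedure

1. **Slicing.** The mesh is cut with `n_layers` horizontal planes at
   altitudes $z_i = z_{\min} + i\,(z_{\max}-z_{\min})/(n_{\mathrm{layers}}+1)$,
   $i = 1..n_{\mathrm{layers}}$ — equally spaced and strictly interior,
   because the base and apex planes give degenerate intersections.  Each
   crossing face contributes one segment; segments are chained into
   closed loops through shared mesh edges, and the largest-area loop is
   kept, oriented counterclockwise.  The default of 40 layers keeps
   layers thin while leaving enough points per contour.
2. **Circle fit.** Each contour gets a least-squares circle by the Kåsa
   algebraic method (a closed-form linear solve of
   $x^2+y^2 = 2c_xx + 2c_yy + c$).  It is exact on noiseless circles and
   deterministic; for the small deviations seen here it is
   indistinguishable from geometric fits.
3. **Unwrapping.** With centre $(c_x, c_y)$ and radius $R$, the contour
   becomes $r(\theta)$; the deviation is
   $$e(\theta) = R - r(\theta),$$
   mean-centred.  Points are sorted by $\theta$; duplicate angles (a
   lump can make $r(\theta)$ multi-valued) are averaged — the least
   surprising reduction to a single-valued profile.  The profile is
   resampled by periodic linear interpolation onto $M = 512$ uniform
   angles.  $M$ is a power of two for the FFT; 512 resolves every
   wavelength of interest at the mesh resolutions used here, and
   sampling around the closed contour more than once would add no new
   information.
4. **Spectrum and Q.** The unnormalised forward FFT of $e$ gives
   one-sided magnitudes at harmonics $k = 1..M/2$.  DC is excluded (it
   is $\approx 0$ after centring) and no one-sided doubling adjustment
   is applied at DC or Nyquist.  Harmonic $k$ corresponds to spatial
   wavelength $\lambda_k = P/k$ along the fitted-circle perimeter
   $P = 2\pi R$ (equivalently spatial frequency $\beta = 1/\lambda$).
   The layer's roughness energy is
   $$Q = \int |\mathrm{FFT}(e)|\, d\lambda,$$
   a trapezoid over the non-uniform $\lambda$ grid restricted to a band.
   The default band $[2P/M,\ P/2]$ drops the $k=1$ fundamental — an
   ellipse-like centring drift rather than lumpiness — and keeps
   everything down to twice the grid pitch.  Both band edges are
   configurable; abridging the axis further is sensible when the
   expected lump size is known.
5. **Grading.** Each sample's 40 layer Q values (bottom to top) form its
   feature vector.  A degree-2 polynomial-kernel SVM (one-vs-one
   multiclass) is trained on labelled samples and evaluated by
   stratified 4-fold cross-validation (25% held out per fold), pooling
   held-out predictions into a confusion matrix.  Reported metrics are
   per-class sensitivity, per-class positive predictive value — the
   column-wise quantity some grading studies tabulate as "specificity",
   kept here under its correct name `ppv` — the textbook specificity,
   and overall accuracy.

## The synthetic cone generator

No reference meshes are distributed, so the package carries a seeded
generator that emulates the study conditions: 4 roughness classes × 2
powder types × 3 replicates of cone heaps.  A sample starts from an
ideal cone (base radius 60, height 42 distance units — proportions of a
poured heap with an angle of repose near 35°; "distance units" are
arbitrary, with millimetres the natural reading) and adds Gaussian
radial bumps:
$$r(\theta, z) = R_0\!\left(1 - \frac{z}{H}\right) +
  \sum_m a_m \exp\!\left(-\frac{\Delta\theta_m^2}{2\sigma_{\theta,m}^2}
  - \frac{(z - z_m)^2}{2\sigma_{z,m}^2}\right).$$

Design choices, fixed once:

* **Class presets.** Bump count and amplitude grow with class: class 0
  draws 0–2 bumps with amplitude ≤ 0.07, class 1 ~6 bumps ~0.5,
  class 2 ~12 bumps ~1.0, class 3 ~20 bumps ~1.8 (Poisson counts,
  uniform amplitude jitter).  This gives class-0 vs class-3 Q
  separation far beyond 10× at mid-layers while leaving adjacent
  classes close enough that grading is non-trivial.
* **Lump size.** Angular width is set so a bump's ±3σ arc extent at its
  own altitude is ~10 distance units, the lump scale the spectra should
  recover; vertical σ is ~10/6 with mild jitter.
* **Bottom bias.** Bump altitudes are a Beta(1, 3) fraction of H —
  lumps roll toward the base of a poured heap, so lower contours carry
  most of the roughness.
* **Powder types.** Whole-milk samples get a 5% larger amplitude
  multiplier than trim (milk fat promotes clumping); base radius and
  height are jittered ±2% per sample.  The two types make the strata
  realistic but are not separate classes.
* **Open surface.** No base cap is generated; slicing only needs the
  lateral flank.

What the generator does *not* emulate: photogrammetric measurement
noise, non-conical gross shape errors, texture, overhangs beyond what
radial bumps produce, and the irregular, roughly uniform-density
triangulation of scanned meshes — the generator's ring-structured grid
gives every layer a similar contour point count, whereas scanned meshes
have more data on the longer bottom contours.  Passing tests therefore
demonstrate the correctness of the geometry/spectral pipeline and the
achievability of accurate grading under controlled lumpiness, not field
performance on scanned heaps.

## Numerical choices and degenerate inputs

* Vertices exactly on a slicing plane are avoided by nudging the plane
  up by $10^{-9}(z_{\max}-z_{\min})$ — far below any geometric scale.
* Segment chaining uses canonical mesh-edge identities, not
  floating-point endpoint matching, so it is exact and independent of
  face winding; STL input is therefore vertex-merged on load (tolerance
  $10^{-8}$) to restore shared edges.
* Multiple closed loops at one altitude (overhanging lumps, disjoint
  components): only the largest-area loop is kept — each layer is
  treated as a single boundary.
* Failed layers (open surface at that altitude, < 16 contour points)
  are flagged absent and imputed with Q = 0 — the perfect-smoothness
  null — keeping feature vectors fixed-length; extraction errors only
  if more than half the layers fail.
* Per-layer standard deviation is computed on the resampled grid (the
  same signal the FFT sees), population convention; it is reported for
  the centred signal, which makes it invariant to DC offsets.
* The tessellation noise floor — the Q a *perfect* meshed cone shows —
  is bounded analytically by the chord sagitta:
  $Q \le M\,R(1-\cos(\pi/n_\theta))\,(\lambda_{\max}-\lambda_{\min})$.
  Measured perfect-cone Q sits orders of magnitude below class-1
  levels.
* A "dominant wavelength" summary is provided as the magnitude-weighted
  harmonic centroid $P/\bar k$.  A single Gaussian lump has a magnitude
  envelope that decays monotonically with $k$, so the literal in-band
  argmax always sits at the long-wavelength band edge and carries no
  size information; the centroid recovers the generating arc length
  within a factor ~1.3 (an argmax variant is still exposed for
  narrowband signals).

## Classifier configuration

The SVM hyperparameters are fixed at degree 2, `coef0 = 1`
(inhomogeneous kernel, so linear terms participate), `gamma = 0.1`,
`C = 10`, with the feature matrix scaled by a *single* global standard
deviation estimated from the training folds.  Global rather than
per-column standardisation is deliberate: near-apex layers carry
essentially no lumpiness (bumps are bottom-biased), and z-scoring each
column would blow those noise-only columns up to unit variance, letting
~a dozen random directions dominate the kernel at n = 24.  Measured on
the synthetic study, per-column scaling with C = 1 loses 15–25
accuracy points against the global-scale configuration; both modes
remain available (`scale = "columns"` / `"none"`).  Whether the Q
features should be transformed (log, square root) was examined and
rejected: both transforms compress the class-0/class-1 gap and hurt
accuracy.

Cross-validation strata are shuffled with a seeded RNG and each class's
remainder samples go to the lightest folds, so 24 samples in 4 classes
always split 6/6/6/6.

## Problem sizes and runtimes

Defaults reproduce the study scale: 24 cones, 40 layers, M = 512,
meshes of 192 × 96 rings (≈ 37k triangles — an intermediate resolution
chosen so a full 10-replicate experiment, 240 cones, completes in a few
minutes on one CPU; the method is resolution-independent above the
lump scale).  Unit tests use smaller cones (48–96 vertices per ring)
where only correctness, not study scale, is at stake.

## Known limitations

* The method presumes a star-shaped-ish, single-component cross
  section; heavily overhanging lumps are reduced to the largest loop
  and angle-averaged.
* Q depends on the FFT magnitude convention and on M; values are
  comparable only within a fixed configuration (the package never
  mixes conventions).
* Absolute Q thresholds between classes are generator-specific; on real
  meshes the classifier must be retrained on labelled samples.
* The binary PLY reader handles little-endian files with scalar vertex
  properties and list-indexed faces — the common case — not the full
  PLY zoo; big-endian files are rejected explicitly.
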