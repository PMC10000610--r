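# coneroughness

Objective surface-roughness grading of conical powder heaps from 3D
surface meshes.

When a powder (the motivating case is instant milk powder) is poured
into a heap, clumping caused by moisture shows up as lumps on the
flank of the cone.  `coneroughness` quantifies that lumpiness from a
triangulated mesh of the heap and grades samples into four roughness
classes:

1. the mesh is sliced with ~40 equally spaced horizontal planes;
2. each closed cross-section contour gets a least-squares (Kåsa)
   circle; the deviation **e(θ) = R − r(θ)** is mean-centred and
   resampled on a uniform angular grid (M = 512);
3. the one-sided FFT magnitude of e, mapped to spatial wavelength
   λ = P/k along the perimeter P = 2πR, is integrated over a
   wavelength band to the per-layer roughness energy
   **Q = ∫|FFT(e)| dλ**;
4. the 40-layer Q vector of each sample feeds a degree-2
   polynomial-kernel SVM, evaluated by stratified 4-fold
   cross-validation with confusion-matrix metrics (sensitivity, PPV,
   specificity, accuracy).

Because no reference meshes are deposited anywhere, the package
includes a seeded synthetic-cone generator (Gaussian radial bumps on an
ideal cone, bump count/amplitude growing with class, bottom-biased
placement) that emulates the full 24-sample study: 4 classes × 2 powder
types × 3 replicates.

## Worked example

```r
library(coneroughness)

# a rough (class 3) synthetic sample and a perfect cone
rough   <- make_class_sample(3, "trim", seed = 11)
perfect <- make_perfect_cone(60, 42)

# slice -> fit -> unwrap -> spectrum -> Q, for the middle layer
sl  <- slice_mesh(rough, 40)
cs  <- sl[[20]]
fit <- fit_circle(cs)
print(fit)
#> circle_fit: center (0.0235178, -0.116165), R = 31.1215, rms residual 0.267
prof <- unwrap(cs, fit)
spec <- spectrum(prof)
compute_Q(spec)
#> [1] 1818.201
layer_std(prof)
#> [1] 0.2644387
dominant_wavelength(spec)
#> [1] 9.688408

# the same layer of the perfect cone is ~5 orders of magnitude quieter
cs0 <- slice_mesh(perfect, 40)[[20]]
compute_Q(spectrum(unwrap(cs0, fit_circle(cs0))))
#> [1] 0.005016762
```

The rough sample's mid-layer radius is ~31 distance units; its
deviation profile has σ ≈ 0.26 and roughness energy Q ≈ 1818
concentrated near the ~10-unit lump wavelength (dominant wavelength
9.7), while the ideal cone shows only tessellation noise (Q ≈ 0.005).

The full experiment — generate 24 cones, extract features,
cross-validate the grader — is one call (or `inst/cli/coneroughness
demo` from a shell):

```r
res <- run_pipeline(pipeline_config(seed = 101, out_dir = "results"))
#> [coneroughness] accuracy 95.8% (loss 0.042); wrote results/report.json
res$cv$confusion
#>     predicted
#> true 0 1 2 3
#>    0 6 0 0 0
#>    1 0 6 0 0
#>    2 0 0 6 0
#>    3 0 0 1 5
```

A benchmark worked example ships with the package: the reference
24-cone confusion matrix (6 per class; classes 0 and 3 fully correct;
one class-1 and two class-2 samples misgraded) evaluates to

```r
matrix_metrics(reference_confusion_matrix())
#> accuracy 0.875; sensitivity 100/83.3/66.7/100%; ppv 75/83.3/100/100%
```

## Command-line interface

`inst/cli/coneroughness` exposes the pipeline as subcommands `synth`,
`slice`, `features`, `classify`, `demo` (flags `--n-layers`, `--grid`,
`--lam-min/--lam-max`, `--folds`, `--seed`, `--format`, `--out`).
Meshes are read and written in OBJ, PLY (ASCII + binary little-endian)
and STL (ASCII + binary).
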