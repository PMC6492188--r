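# dager

Joint k-q reconstruction of highly accelerated diffusion MRI in R.

Diffusion MRI acquires one image volume per diffusion-encoding direction
(a q-space sample), and scan time forces aggressive undersampling of
each volume's k-space — in-plane (factor R) and/or simultaneous
multislice (MB slices at once).  At high total acceleration the
parallel-imaging inverse problem is ill-conditioned and conventional
SENSE reconstructions drown in amplified noise.  This package
reconstructs *all diffusion volumes jointly*, regularizing the k-space
inversion with a Gaussian-process prior over q-space: the diffusion
signal varies smoothly with the encoding direction, so volumes at
nearby q-space points are redundant — provided they sample
*complementary* k-space lines, which a graph-coloring sampling designer
arranges.

For a single voxel the signal across directions is modelled as a
zero-mean GP with the compactly supported spherical covariance of the
angle θ between directions,

    Σ_ij = λ C_θ(θ_ij; a),   C_θ(θ; a) = 1 − 3θ/(2a) + θ³/(2a³)  (θ ≤ a),

and all volumes are recovered as the MAP estimate

    û = argmin_u  (1/σ_k²) ‖A u − d‖² + (Pᴴu − ū)ᴴ (Σ⁻¹ ⊗ I) (Pᴴu − ū),

where `A` is the coil/Fourier/sampling encoding operator, `P` the
per-volume motion-phase operator, `ū` the GP posterior-mean prediction
from the previous iterate, and the hyper-parameters `(a, λ, σ_im)` are
re-estimated from the data each iteration by marginal likelihood — no
hand-tuned regularization weight.  The noise weight `σ_k` is calibrated
once from the image-noise map divided by the parallel-imaging noise
propagation (g-factor) map.

The package also contains everything needed to exercise the method
without scanner data: a ball-and-stick digital phantom, simulated coil
arrays, per-volume motion phase errors, complex k-space noise, the k-q
sampling designer, Tikhonov SENSE / SMS-SENSE baselines with L-curve
weight selection, three phase-error estimators, quantitative evaluation
(NRMSE, covariance-vs-angle), text/NIfTI I/O, and a command-line
interface (`inst/cli/dager.R`).

## A worked example

Simulate a 32×32 ball-and-stick phantom acquired with 8 coils, 64
directions at b = 1000 s/mm², 6-fold in-plane undersampling with
variable k-q sampling and motion phase errors, then reconstruct with
both Tikhonov SENSE and the GP-constrained joint solver:

```r
library(dager)
ex <- run_experiment("inplane-r6", size = 32, n_dir = 64, seed = 7)
print(ex)
#> k-q reconstruction experiment: inplane-r6|size=32|ndir=64|ncoils=8|R=6|...
#>   SENSE  NRMSE: mean 0.5118 (range 0.2105 - 0.8213)
#>   DAGER  NRMSE: mean 0.1030 (range 0.0877 - 0.1287)
#>   improvement ratio (SENSE / DAGER): 4.97
#>   k-q coloring conflicts: 0
coef(ex$fit)
#>          a     lambda   sigma_im    sigma_k
#> 1.80641578 0.08286819 0.27909901 0.08778657
```

The per-volume NRMSE is computed inside the brain mask against the
noise-free ground truth: conventional SENSE at R = 6 with 8 coils
leaves ~51% RMS error (noise amplification plus residual aliasing),
while the joint reconstruction reduces it to ~10%, a 5-fold
improvement at this scale.  `coef()` returns the learned
hyper-parameters: angular threshold `a` (radians), signal variance
`lambda`, image-noise level `sigma_im`, and the frozen k-space noise
calibration `sigma_k`.  `plot(ex$fit)` shows the normalized solution
update and the per-iteration NRMSE; `summary(ex$fit)` prints the full
iteration trace.

Lower-level entry points: `make_phantom()`, `simulate_coils()`,
`design_plan()`, `simulate_acquisition()`, `sense_reconstruct()`,
`estimate_hyperparameters()`, `dager_solve()`, `dager_pipeline()`,
`nrmse()`, `covariance_vs_angle()`.  The methods vignette
(`vignettes/dager-methods.Rmd`) documents the model, the estimators,
the numerical design and the generator's realism limits.

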