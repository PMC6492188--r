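---
title: "Gaussian-process constrained k-q reconstruction: models, algorithms and design choices"
author: "dager package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian-process constrained k-q reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Diffusion MRI acquires one image volume per diffusion-encoding direction
(q-space sample).  Scan time forces undersampling: in-plane (skipping
phase-encode lines, factor $R$) and/or simultaneous multislice (SMS,
factor $MB$).  At high total acceleration the parallel-imaging inverse
problem is ill-conditioned — with 8 coils, $R = 10$ is beyond the
theoretical SENSE limit — and conventional reconstructions drown in
amplified noise and residual aliasing.

The idea implemented here is to regularize the *spatial* (k-space)
inverse problem with information from the *angular* (q-space) domain:
the diffusion signal varies smoothly with the encoding direction, so
volumes acquired at nearby q-space points are highly redundant.  If
neighboring q-space points additionally sample *different* k-space
lines, each volume's missing data are constrained by its neighbors.
Two coupled components deliver this:

1. a **Gaussian-process (GP) prior over q-space** whose smoothness
   hyper-parameters are estimated from the data by marginal likelihood,
   with no hand-tuned regularization weight;
2. a **k-q sampling design** that assigns complementary shifted
   sampling patterns within each local q-space neighborhood, via graph
   coloring.

# Signal model

## GP over q-space

At one voxel, the real-valued signal across the $N_d$ directions is
modelled as a zero-mean GP,
$$ u \sim \mathcal N(0, \Sigma), \qquad
   \Sigma_{ij} = \lambda\, C_\theta(\theta_{ij}; a), $$
with the compactly supported **spherical covariance**
$$ C_\theta(\theta; a) = 1 - \tfrac{3\theta}{2a} +
   \tfrac{\theta^3}{2a^3} \;\; (\theta \le a), \qquad 0 \;\; (\theta > a), $$
where $\theta_{ij}$ is the angle between directions $i$ and $j$.  For
single-shell data the covariance depends only on this angle.  The
`symmetric` flag of a `qspace_protocol` selects the antipodally
identified angle $\arccos|\langle g_i, g_j\rangle|$ (used for simulated
data, where the signal is exactly antipodal) or the plain angle
(preferable for measured data where eddy-current asymmetries matter).

Observed images add q-space-uncorrelated noise of standard deviation
$\sigma_{im}$, giving $\Sigma_y = \Sigma + \sigma_{im}^2 I$.  The GP
posterior mean
$$ \bar u = \Sigma\, (\Sigma + \sigma_{im}^2 I)^{-1} y $$
is the denoised/interpolated prediction of the noise-free signal
(`posterior_mean()`), applied voxel-wise across an image stack.

## Encoding model

Each volume is acquired through the linear model $d = A u + n$, where
$A$ multiplies by coil sensitivities, applies the orthonormal discrete
Fourier transform and restricts to the acquired phase-encode lines
(`forward_encode()` / `adjoint_encode()`).  SMS acquisitions are encoded
on the extended-FOV grid of $MB$ stacked slices with $k_z$ sampled by
the blipped-CAIPI blip cycle — the 3D k-space view of multiband.  The
k-space noise is i.i.d. complex Gaussian with per-component standard
deviation $\sigma_k$ per channel.

Per-volume motion during the diffusion preparation multiplies the image
by an unknown unit-magnitude phase map $P$ (constant plus
approximately linear in image space for rigid motion).  Since the GP
assumption holds for the phase-*aligned* signal, the reconstruction
includes $P^H$ to realign volumes.

## The joint MAP problem

All volumes are reconstructed jointly (`dager_solve()`):
$$ \hat u = \arg\min_u \; \frac{1}{\sigma_k^2}\|A u - d\|_2^2
   + (P^H u - \bar u)^H\, (\Sigma^{-1} \otimes I_{N_v})\, (P^H u - \bar u), $$
a strictly convex quadratic coupling the volumes through $\Sigma^{-1}$
at every voxel.  Note that the "regularization weight" is not free: it
is fixed by the calibrated noise level $\sigma_k$ and the estimated
signal covariance.

# Hyper-parameter estimation

$(a, \lambda, \sigma_{im})$ are estimated by minimizing the negative
log marginal likelihood
$$ \tfrac12 y^T \Sigma_y^{-1} y + \tfrac12 \log|\Sigma_y|
   + \tfrac{N_d}{2}\log 2\pi $$
independently at randomly sampled brain voxels (1000 by default) and
averaging the per-voxel estimates (`estimate_hyperparameters()`).

Two optimizers are provided.  The default (`"profile"`) exploits the
structure of the problem: for a fixed angular threshold $a$ the
covariance $C_\theta(a)$ is eigendecomposed once, the likelihood
separates over eigenmodes, and the $(\log\lambda, \log\sigma)$
subproblem is solved by a damped Newton iteration *vectorized across
all sampled voxels simultaneously*; $a$ is then profiled over a grid
(40 points spanning the metric's range) with parabolic refinement.
This is exact maximum likelihood, deterministic, and fast enough to
re-run every outer iteration.  The alternative (`"cg"`) is per-voxel
nonlinear conjugate gradient with analytic gradients in
$(\log\lambda, a, \log\sigma)$, three restarts from
$a \in \{0.5, 1.0, 1.5\}$; it optimizes the same criterion (the two
agree in tests) but costs two to three orders of magnitude more over
1000 voxels, which matters when the estimation runs inside an
iterative reconstruction.  Positivity of $\lambda$ and $\sigma$ is
enforced by the log (exponential) reparameterization in both.

Degenerate voxels (no variability across directions) are excluded;
per-voxel estimates are recorded on the returned object for
diagnostics (`write_hyperparam_diagnostics()`).

# Noise calibration

The MAP data weight needs the k-space noise level $\sigma_k$, while the
images provide the per-voxel image-space level $\sigma_{im}^0(\rho)$.
The two are linked by the parallel-imaging noise propagation factor
$$ g^*(\rho) = \sqrt{R_{tot}}\,
   \sqrt{\big[(S^H \Phi^{-1} S)^{-1}\big]_{\rho\rho}}, $$
computed over each voxel's aliasing set (`gfactor_map()`), so that an
image reconstructed from data with noise $\sigma_k$ has per-component
voxel noise $\sigma_k\, g^*(\rho)$ — the $\sqrt{R_{tot}}$ factor makes
this exact under the orthonormal Fourier convention, and is verified
against Monte-Carlo SENSE reconstructions of pure noise in the test
suite.  For regularized inversions (needed when the aliasing set
exceeds the coil count, e.g. $R = 10$ with 8 channels, where the
classical factor is infinite) the propagation of the Tikhonov
inversion $(A^H A + wI)^{-1} A^H$ is used instead.

$\sigma_k$ is then calibrated once as the mean of
$\sigma_{im}^0(\rho)/g^*(\rho)$ over 1000 sampled brain voxels and
frozen for all later iterations (`calibrate_sigma_k()`).  The pooling
is a plain mean — no outlier rejection is applied, since the robust
per-voxel MAD already bounds the influence of individual directions;
voxels with non-finite propagation factors are excluded.

The per-voxel map $\sigma_{im}^0(\rho)$ is estimated from differences
between each volume and its nearest angular neighbor, scaled by
$1/\sqrt2$, with a robust MAD scale across directions
(`estimate_sigma_im_map()`).  The smooth q-space signal largely cancels
in neighbor differences, so this estimator is insensitive to the signal
model.  The GP nugget is *not* used for this purpose: on signals the GP
can represent well, the marginal-likelihood nugget absorbs part of the
noise into the smooth covariance (we measure a factor ~2 downward bias
on ball-and-stick phantoms), whereas the neighbor-difference estimator
recovers injected noise levels to within a few percent.

# The alternating pipeline

`dager_pipeline()` iterates:

0. **Initialize** with Tikhonov SENSE / SMS-SENSE.  The baseline weight
   comes from the L-curve corner (`lcurve_select()`, maximum Menger
   curvature of the log residual-norm vs log solution-norm curve); the
   initialization and phase-estimation reconstruction deliberately use
   a lower weight (`low_reg_factor`, default 0.1) because residual
   aliasing harms phase estimates more than noise does.
1. **Estimate phase maps** (see below), calibrate $\sigma_k$ (once).
2. **Iterate**: estimate $(a, \lambda)$ on 1000 freshly drawn brain
   voxels from the phase-corrected real part of the current volumes;
   build $\Sigma$; predict $\bar u$ by the GP posterior mean; solve the
   joint MAP problem by preconditioned conjugate gradient, warm-started
   from the previous iterate.
3. **Stop** when the normalized solution update
   $\|u_n - u_{n-1}\| / \|u_{n-1}\|$ falls below 0.002 or after 20
   iterations.

## Why `sigma_im` is frozen after iteration 1

The one deliberate departure from re-estimating all three
hyper-parameters every iteration: $\sigma_{im}$ is estimated from the
initialization and then held fixed (`freeze_sigma_im`, default
`TRUE`).  The reason is an identifiability failure specific to the
alternation.  The reconstruction output conforms to the prior used to
produce it; when the underlying signal is (as in any smooth phantom)
representable by the GP, the nugget re-fit on the *regularized output*
collapses toward zero.  With $\sigma_{im} \to 0$ the posterior mean
degenerates to $\bar u \approx u_{n-1}$: the prior stops smoothing and
instead pins the iterate to itself, and reconstruction error drifts
upward monotonically.  In controlled experiments the full re-fit
drifts (e.g. NRMSE $0.23 \to 0.32$ over 8 iterations on a small
in-plane problem) while the frozen-$\sigma_{im}$ scheme converges
cleanly ($0.23 \to 0.14$, update below 0.002 within ~7 iterations) —
the qualitative convergence behavior the method is designed to have.
The initialization is the one iterate whose noise level is well
defined, which makes it the natural calibration point; $a$ and
$\lambda$ remain data-driven every iteration.  Setting
`freeze_sigma_im = FALSE` restores the literal re-estimation.

## Phase-error estimation

Three estimators are provided (`phase_mode`):

* `central_kspace`: the phase of the low-frequency image from a small
  fully sampled central k-space block.  For simulated acquisitions the
  simulator stores such a block per volume (`phase_ref`; a navigator
  equivalent), which captures the simulated zeroth/first-order motion
  phase essentially exactly (~0.05 rad weighted error at SNR 20).
  Without a stored block the estimate falls back to windowing the
  initialization image's k-space, which inherits that image's
  artifacts.
* `navigator`: SENSE reconstruction of an acquired low-resolution
  navigator, smoothed by 2D Hamming apodization in k-space and
  zero-pad interpolated to the imaging grid.
* `navigator_free`: total-variation denoising (Chambolle) of the
  low-regularization reconstruction, phase taken from the denoised
  image.  By default the rigid-motion model is then fit
  (`phase_model = "linear"`): ramp slopes from magnitude-weighted
  autocorrelation between adjacent pixels (no unwrapping), offset from
  the weighted mean after de-ramping.  The parametric fit pools all
  voxels and therefore survives residual aliasing that corrupts
  voxelwise phase maps (we measure 0.7-1.0 rad voxelwise error vs
  ~0.05 rad for the parametric fit at total acceleration 12);
  `phase_model = "full"` keeps the voxelwise map for nonlinear phase
  errors.

# k-q sampling design

For in-plane factor $R$ there are $R$ distinct patterns obtained by
shifting the undersampled trajectory along $k_y$; with SMS the $k_z$
blip offset shifts as well, giving $R \cdot MB$ patterns
(`shifted_patterns()`).  Each q-space point is a graph vertex connected
to its $R_{tot} - 1$ angular nearest neighbors (`build_graph()`), and a
greedy coloring in Welsh–Powell (descending-degree) order assigns
patterns so that no neighborhood repeats one (`greedy_color()`).  When
the graph needs more than $R_{tot}$ colors the least-used color among
the neighbors is assigned and the conflict counted — the assignment
never fails, matching the NP-completeness of exact coloring.  On the
package's preset direction sets the greedy coloring is conflict-free,
verified by exhaustive neighborhood audits; on random small graphs its
conflict count equals the brute-force minimum.

For SMS designs the neighborhood size defaults to the *total*
acceleration $R \cdot MB$ (all patterns distinct within a
neighborhood); `design_plan(neighborhood_size = )` restricts it, e.g.
to the in-plane factor alone, where one might prefer denser pattern
reuse for very large $R \cdot MB$ relative to the number of
directions.

# Numerical implementation

* **Fourier convention**: orthonormal transforms, DC-first (unshifted)
  k-space storage, 0-based k-space indices, ky along the second image
  axis.  All containers document this.
* **Aliasing-set unfolding**: every shifted pattern is a translated
  coset of one sampling lattice (including the sheared blipped-CAIPI
  lattice) whenever $n_y$ is divisible by $R$; then
  $F^H M_t F = \tfrac{1}{R_{tot}} w_t w_t^H$ on each aliasing set with
  a unit-modulus translation phase $w_t$.  Consequently the SENSE
  normal matrix per set is unitarily equivalent to
  $C_g/R_{tot} + wI$ with a *pattern-independent* factorization —
  Tikhonov SENSE unfolds exactly with one small Cholesky per set — and
  the joint MAP operator applies in a few milliseconds per iteration
  via a compiled block-Gram kernel.  Non-lattice patterns (e.g.
  $R = 10$ on a 48 grid) fall back to an FFT-along-$k_y$ operator;
  both paths are verified against dense first-principles encoding
  matrices.
* **Conjugate gradient**: relative-residual tolerance $10^{-6}$, cap
  250 iterations, warm starts across outer iterations; the quadratic
  objective is monitored and non-increasing.  The preconditioner
  inverts exactly the separable surrogate
  $\bar c\, I + \Sigma^{-1}$ per voxel in the eigenbasis of $\Sigma$
  ($\bar c$ = mean data-term diagonal), which removes the stiffness of
  the prior precision and cuts iteration counts by roughly 3x.
* **Cholesky jitter**: covariance factorizations retry with an
  escalating diagonal jitter from $10^{-10}\,\mathrm{tr}(\Sigma)/N_d$
  up to $10^{-4}$ relative before declaring degenerate
  hyper-parameters.
* **Clamping**: direction dot products are clamped to $[-1, 1]$ before
  `acos`.
* **Ties**: nearest-neighbor ties in graph construction break by index
  order, making designs reproducible and rotation invariant for
  generic direction sets.

# The synthetic acquisition generator

`make_phantom()` builds a 2D/thin-3D ball-and-stick phantom with
brain-like parameters at $b = 1000\,$s/mm$^2$: elliptical isotropic
tissue ($d = 0.8\times10^{-3}$ mm$^2$/s), two crossing fiber bundles
($f = 0.55$ single-fiber, $0.35 + 0.35$ in the crossing), a CSF-like
blob ($d = 2.7\times10^{-3}$), and a smooth S0 modulation; bundle
geometry rotates across slices.  The q-space signal
$$ S = S_0\Big[(1 - {\textstyle\sum_j} f_j)\, e^{-b d}
   + {\textstyle\sum_j} f_j\, e^{-b d (g\cdot v_j)^2}\Big] $$
is smooth in the direction by construction — precisely the structural
assumption the GP prior needs, and the reason parameter-recovery tests
on this phantom say nothing about signals that violate it.

`simulate_coils()` provides two sensitivity models.  `"loop"` is the
classic analytic loop ring (radial decay, slowly varying phase),
emulating idealized simulated 8-channel head coils.  `"array"`
multiplies the loop envelope by a per-channel band-limited complex
Gaussian random field; this restores the spatial diversity of measured
arrays, and its geometry was calibrated so the 32-channel MB = 4,
FOV/4, R = 3 configuration reproduces unit-normalized g-factors
reported for real 32-channel head coils (median ~1.6, maxima ~5) —
conditioning, not visual appearance, is what the reconstruction
experiments are sensitive to.  The in-plane presets use `"loop"`
(mirroring simulation studies built on the shared simulated 8-channel
coil); the SMS preset uses `"array"` (mirroring measured 32-channel
maps).

Motion phase errors are drawn per volume: a constant offset uniform in
$[-\pi, \pi]$ plus a linear ramp equivalent to a $k_y$ shift uniform in
$[0, 2\Delta k_y]$ (`sample_phase_errors()`).  Noise is added in
k-space per channel as circular complex Gaussian with per-component
standard deviation $\sigma_k = \bar S_0 / \mathrm{SNR}$, where
$\bar S_0$ is the mean noise-free $b = 0$ magnitude inside the support
mask — the SNR convention is a package definition (the convention used
for the reference experiments is not printed anywhere we could adopt
it from).  Direction sets come from electrostatic repulsion of
antipodal point pairs (seeded, deterministic), with a spherical-spiral
fallback.

What the generator does *not* emulate: EPI trajectory physics and
distortion, eddy currents, partial Fourier, Rician magnitude noise,
multi-shell protocols, and — most importantly — signals rougher in
q-space than the ball-and-stick class.  Passing tests on these
phantoms demonstrate the machinery is correct under the method's own
assumptions, not that the method wins on arbitrary in vivo data.

# Study conditions and problem sizes

The two preset experiments (`run_experiment()`) mirror the reference
study at desk scale, and are the conditions the acceptance script
reproduces:

* `inplane-r10`: $48\times48$ phantom, 8 `"loop"` coils, 128
  directions, $R = 10$ variable k-q sampling, SNR 20, central-k-space
  phase correction; ~1-2 min on one CPU.
* `sms-mb4r3`: $48\times48\times4$ phantom, 32 `"array"` coils, 192
  directions, $MB = 4$ with FOV/4 CAIPI and $R = 3$ (total 12), SNR
  20, navigator-free phase estimation; ~5-8 min.

Unit tests run on $8\times8$ to $32\times32$ problems where dense
oracle matrices and brute-force enumerations are feasible.

# Known limitations

* The zero-mean GP treats the large direction-averaged signal as
  covariance; the fitted angular threshold therefore tends to the top
  of its admissible range on phantom data, and $\lambda$ is not
  interpretable as the angular-contrast variance alone.  The fit is
  still the exact ML optimum of the stated model, and reconstruction
  quality — which depends on the implied $\Sigma$, not on the
  interpretation of its factors — is insensitive to this.
* At SNR 20 the converged reconstruction error of the in-plane
  $R = 10$ preset is close to the thermal noise floor of a fully
  sampled acquisition; improvement ratios over SENSE are bounded by
  that floor.
* Navigator-free phase estimation with `phase_model = "full"` degrades
  when the initialization carries strong residual aliasing; the
  parametric default only covers rigid-motion (constant + linear)
  phase errors.
* Only single-shell protocols are supported; the covariance model has
  no cross-shell structure, and magnitude-domain (Rician) noise is not
  modelled.
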