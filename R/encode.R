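## Orthonormal discrete Fourier transforms.  k-space arrays are stored in
## unshifted (DC-first) FFT order with 0-based index semantics; image
## voxel indices are 0-based in the documentation and 1-based in R arrays.
fft_ortho <- function(x) stats::fft(x) / sqrt(length(x))
ifft_ortho <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

## frequency index (0-based, unshifted order) of each position along a
## dimension of length n: 0, 1, ..., floor(n/2), -(ceiling(n/2)-1), ..., -1
freq_index <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

## logical keep-vector selecting the w lowest absolute frequencies of a
## length-n axis (ties between +/- f broken toward the positive
## frequency, matching the DFT's half-spectrum convention); w = n keeps
## everything
rank_window <- function(n, w) {
  f <- freq_index(n)
  ord <- order(abs(f + 0.25))
  keep <- rep(FALSE, n)
  keep[ord[seq_len(w)]] <- TRUE
  keep
}

as_image3 <- function(u) {
  if (is.null(dim(u))) stop("'u' must be a matrix or 3-d array")
  if (length(dim(u)) == 2L) dim(u) <- c(dim(u), 1L)
  if (length(dim(u)) != 3L) stop("'u' must be nx x ny (x nz)")
  u
}

#' Forward and adjoint encoding of one diffusion volume
#'
#' The linear acquisition model `d = A u + n`: the image is multiplied by
#' the per-volume motion phase map, by each coil sensitivity, transformed
#' by the orthonormal discrete Fourier transform, and restricted to the
#' acquired phase-encode lines of the sampling pattern.  SMS volumes are
#' encoded on the extended-FOV grid (`nz = MB` stacked slices) with kz
#' sampling following the pattern's blip scheme, i.e. a 3D k-space view of
#' the multiband acquisition.  `adjoint_encode()` is the exact adjoint
#' under this orthonormal convention and zero-fills unacquired lines.
#'
#' @param u complex image, `nx x ny` or `nx x ny x nz`.
#' @param sens a [coil_set()] on the same grid.
#' @param pattern a [sampling_pattern()] with matching `(ny, nz)`.
#' @param phase optional unit-magnitude phase map (same grid as `u`)
#'   applied before encoding.
#' @return `forward_encode()`: a `kspace_volume` — list with `data`
#'   (`nx x n_acq x Nc` complex array over the acquired lines) and
#'   `pattern`.  `adjoint_encode()`: a complex image `nx x ny x nz`.
#' @export
forward_encode <- function(u, sens, pattern, phase = NULL) {
  u <- as_image3(u)
  d <- dim(sens$maps)
  if (!all(dim(u) == d[1:3]))
    stop("image grid ", paste(dim(u), collapse = "x"),
         " does not match sensitivity grid ", paste(d[1:3], collapse = "x"))
  if (pattern$ny != d[2] || pattern$nz != d[3])
    stop("sampling pattern grid does not match the image grid")
  if (!is.null(phase)) {
    phase <- as_image3(phase)
    if (!all(dim(phase) == dim(u))) stop("phase map grid mismatch")
    u <- u * phase
  }
  nc <- d[4]
  nacq <- length(pattern$idx)
  out <- array(0i, c(d[1], nacq, nc))
  for (cc in seq_len(nc)) {
    Sc <- sens$maps[, , , cc, drop = FALSE]
    dim(Sc) <- d[1:3]
    k <- fft_ortho(u * Sc)
    dim(k) <- c(d[1], d[2] * d[3])
    out[, , cc] <- k[, pattern$idx, drop = FALSE]
  }
  structure(list(data = out, pattern = pattern), class = "kspace_volume")
}

#' @rdname forward_encode
#' @param d a `kspace_volume` as returned by `forward_encode()` (or any
#'   list with `data` and `pattern`).
#' @export
adjoint_encode <- function(d, sens, pattern = d$pattern, phase = NULL) {
  dm <- dim(sens$maps)
  nc <- dm[4]
  dat <- d$data
  if (dim(dat)[2] != length(pattern$idx) || dim(dat)[3] != nc)
    stop("k-space data shape does not match pattern / coil count")
  u <- array(0i, dm[1:3])
  kfull <- matrix(0i, dm[1], dm[2] * dm[3])
  for (cc in seq_len(nc)) {
    kfull[] <- 0i
    kfull[, pattern$idx] <- dat[, , cc]
    img <- ifft_ortho(array(kfull, dm[1:3]))
    Sc <- sens$maps[, , , cc, drop = FALSE]
    dim(Sc) <- dm[1:3]
    u <- u + Conj(Sc) * img
  }
  if (!is.null(phase)) u <- u * Conj(as_image3(phase))
  u
}

## ---------------------------------------------------------------------
## SENSE noise propagation
## ---------------------------------------------------------------------

#' SENSE noise-propagation (g-factor) map
#'
#' Computes the per-voxel factor `g*` by which the k-space noise standard
#' deviation is amplified in the image after parallel-imaging inversion:
#' `sd(image voxel) = sigma_k * g*`, per complex component, for k-space
#' noise of per-component standard deviation `sigma_k` and coil covariance
#' `Phi`.  For the unregularized inversion on a lattice pattern this is
#' the classical unfolding result \eqn{g^*(\rho) = \sqrt{R_{tot}}
#' \sqrt{[(S^H\Phi^{-1}S)^{-1}]_{\rho\rho}}} over the voxel's aliasing
#' set.  With `weight > 0` the propagation of the Tikhonov-regularized
#' inversion `(A^H A + w I)^{-1} A^H` is returned instead, which stays
#' finite when the aliasing set is larger than the coil count.
#'
#' @param sens a [coil_set()].
#' @param pattern a [sampling_pattern()].
#' @param weight Tikhonov weight of the inversion whose noise propagation
#'   is sought (0 = plain least squares).
#' @return numeric array `nx x ny x nz`; voxels whose reduced sensitivity
#'   matrix is rank deficient (only possible at `weight = 0`) are `Inf`.
#' @export
gfactor_map <- function(sens, pattern, weight = 0) {
  ws <- whiten_coils(sens)
  ctx <- recon_context(ws$sens, list(pattern), vol_pattern = 1L)
  gfactor_from_context(ctx, weight)
}

## internal: g map from a prebuilt context (single pattern); see
## recon_context() for the two voxel-coupling representations.
gfactor_from_context <- function(ctx, weight = 0) {
  nx <- ctx$nx; ny <- ctx$ny; nz <- ctx$nz
  g2 <- numeric(nx * ny * nz)
  if (ctx$type == "lattice") {
    Rt <- ctx$R_total
    for (gset in seq_len(ctx$n_sets)) {
      vox <- ctx$set_members[, gset]
      Cg <- matrix(ctx$C[, , gset], Rt, Rt) / Rt
      ns <- Rt
      if (weight > 0) {
        Tm <- solve(Cg + diag(weight, ns))
        cov <- Tm %*% Cg %*% Conj(t(Tm))
        g2[vox] <- Re(diag(cov))
      } else {
        ev <- eigen(Cg, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < 1e-10 * max(ev, 1)) {
          g2[vox] <- Inf
        } else {
          g2[vox] <- Re(diag(solve(Cg)))
        }
      }
    }
  } else {
    ## circulant-in-ky coupling: one ny x ny system per (x, z, pattern)
    H <- ctx$H[[1L]]                   # ny x ny, single pattern here
    S <- ctx$S                         # nvox x Nc
    for (xz in seq_len(nx * nz)) {
      ix <- ((xz - 1L) %% nx) + 1L
      iz <- ((xz - 1L) %/% nx) + 1L
      vox <- ix + nx * ((seq_len(ny) - 1L) + ny * (iz - 1L))
      Sv <- S[vox, , drop = FALSE]
      G <- (Conj(Sv) %*% t(Sv)) * H    # sum_c conj(S_c(y)) H(y,y') S_c(y')
      if (weight > 0) {
        Tm <- solve(G + diag(weight, ny))
        cov <- Tm %*% G %*% Conj(t(Tm))
        g2[vox] <- Re(diag(cov))
      } else {
        ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < 1e-10 * max(ev, 1)) g2[vox] <- Inf
        else g2[vox] <- Re(diag(solve(G)))
      }
    }
  }
  array(sqrt(g2), c(nx, ny, nz))
}

#' Per-voxel image-space noise map from q-space neighbor differences
#'
#' Estimates the q-space-uncorrelated noise standard deviation at every
#' voxel from differences between each diffusion volume and its nearest
#' angular neighbor, scaled by `1/sqrt(2)` so independent noise of equal
#' variance gives the per-volume standard deviation, with a robust MAD
#' scale across directions (and across the real/imaginary channels for
#' complex input).  The smooth q-space signal largely cancels in the
#' neighbor differences, so the estimate is insensitive to the signal
#' model — unlike the marginal-likelihood nugget, which inherits any
#' mismatch between the data and the GP covariance.
#'
#' @param volumes real or complex array with trailing volume dimension
#'   (or an `Nvox x Nd` matrix).
#' @param protocol the [qspace_protocol()] of the volumes.
#' @return numeric vector/array of per-voxel noise standard deviations
#'   (per component for complex input).
#' @export
estimate_sigma_im_map <- function(volumes, protocol) {
  nd <- nrow(protocol$directions)
  if (nd < 2L) stop("need at least two volumes")
  dm <- dim(volumes)
  Y <- matrix(volumes, length(volumes) / nd, nd)
  th <- angular_distance_matrix(protocol)
  diag(th) <- Inf
  nn <- apply(th, 1, which.min)
  D <- (Y - Y[, nn, drop = FALSE]) / sqrt(2)
  Dm <- if (is.complex(D)) cbind(Re(D), Im(D)) else D
  out <- apply(Dm, 1, stats::mad)
  if (length(dm) > 2L) array(out, dm[-length(dm)]) else out
}

#' Calibrate the k-space noise level from an image-space noise map
#'
#' Estimates `sigma_k` as the mean over randomly sampled mask voxels of
#' `sigma_im(v) / g*(v)`: the image-space noise standard deviation divided
#' by the parallel-imaging noise propagation factor.  In the DAGER
#' pipeline this calibration is performed once, on the initial SENSE
#' reconstruction, and frozen for all later iterations.
#'
#' @param sigma_im_map per-voxel image-space noise standard deviation
#'   (array or vector; `NA` voxels are excluded).
#' @param g_map per-voxel noise propagation map, aligned with
#'   `sigma_im_map` (see [gfactor_map()]).
#' @param mask logical array of voxels eligible for sampling.
#' @param n_voxels number of voxels to sample (default 1000).
#' @param seed integer seed for the voxel draw.
#' @return scalar `sigma_k`.
#' @export
calibrate_sigma_k <- function(sigma_im_map, g_map, mask,
                              n_voxels = 1000L, seed = 1L) {
  sim <- as.vector(sigma_im_map)
  g <- as.vector(g_map)
  ok <- as.vector(mask) & !is.na(sim) & is.finite(g) & g > 0
  if (!any(ok)) stop("no usable voxels: empty mask or all g-factors flagged")
  idx <- which(ok)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  take <- idx[sort(sample.int(length(idx), min(n_voxels, length(idx))))]
  mean(sim[take] / g[take])
}
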