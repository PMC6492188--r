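## unit-magnitude phase of a complex array (1 where magnitude is zero)
unit_phase <- function(x) {
  m <- Mod(x)
  out <- x
  out[m > 0] <- x[m > 0] / m[m > 0]
  out[m == 0] <- 1 + 0i
  out
}

#' Total-variation denoising (Chambolle projection)
#'
#' Rudin-Osher-Fatemi denoising of a real 2D image by Chambolle's dual
#' projection algorithm; complex inputs are denoised channel-wise (real
#' and imaginary parts separately), and 3D arrays slice by slice.
#' `weight = 0` returns the input unchanged.
#'
#' @param img real or complex matrix / 3D array.
#' @param weight TV regularization weight (in image units).
#' @param n_iter number of dual iterations.
#' @return denoised array of the same shape and mode as `img`.
#' @export
tv_denoise <- function(img, weight, n_iter = 30L) {
  if (weight == 0) return(img)
  if (is.complex(img))
    return(tv_denoise(Re(img), weight, n_iter) +
             1i * tv_denoise(Im(img), weight, n_iter))
  if (length(dim(img)) == 3L) {
    for (iz in seq_len(dim(img)[3]))
      img[, , iz] <- tv_denoise_2d(img[, , iz], weight, n_iter)
    return(img)
  }
  tv_denoise_2d(img, weight, n_iter)
}

tv_denoise_2d <- function(f, weight, n_iter) {
  nx <- nrow(f); ny <- ncol(f)
  px <- matrix(0, nx, ny); py <- matrix(0, nx, ny)
  tau <- 0.25
  gradx <- function(u) rbind(u[-1, , drop = FALSE] - u[-nx, , drop = FALSE],
                             rep(0, ny))
  grady <- function(u) cbind(u[, -1, drop = FALSE] - u[, -ny, drop = FALSE],
                             rep(0, nx))
  divp <- function(px, py) {
    dx <- px - rbind(rep(0, ny), px[-nx, , drop = FALSE])
    dx[nx, ] <- -px[nx - 1, ]
    dy <- py - cbind(rep(0, nx), py[, -ny, drop = FALSE])
    dy[, ny] <- -py[, ny - 1]
    dx + dy
  }
  for (it in seq_len(n_iter)) {
    u <- divp(px, py) - f / weight
    gx <- gradx(u); gy <- grady(u)
    den <- 1 + tau * sqrt(gx^2 + gy^2)
    px <- (px + tau * gx) / den
    py <- (py + tau * gy) / den
  }
  f - weight * divp(px, py)
}

#' Phase-error estimate from the central k-space of the imaging data
#'
#' Keeps only a centred low-frequency window (default 32 x 32 along the
#' in-plane axes, per slice) of the volume's k-space, inverse-transforms,
#' and returns the unit-magnitude phase image.  For simulated motion
#' consisting of a constant offset plus a linear ramp this captures the
#' phase error essentially exactly.
#'
#' @param img complex image (`nx x ny` or `nx x ny x nz`), typically an
#'   initial SENSE reconstruction of one volume.
#' @param window in-plane window size, `c(wx, wy)` (a scalar is used for
#'   both); clipped to the grid with a warning if larger.
#' @return unit-magnitude complex phase map, same shape as `img`.
#' @export
estimate_phase_central_kspace <- function(img, window = c(32L, 32L)) {
  img <- as_image3(img)
  if (length(window) == 1L) window <- rep(window, 2L)
  nx <- dim(img)[1]; ny <- dim(img)[2]; nz <- dim(img)[3]
  if (window[1] > nx || window[2] > ny) {
    warning("phase window ", paste(window, collapse = "x"),
            " clipped to the ", nx, "x", ny, " grid")
    window <- pmin(window, c(nx, ny))
  }
  keepx <- rank_window(nx, window[1])
  keepy <- rank_window(ny, window[2])
  out <- img
  for (iz in seq_len(nz)) {
    k <- stats::fft(img[, , iz])
    k[!keepx, ] <- 0i
    k[, !keepy] <- 0i
    out[, , iz] <- stats::fft(k, inverse = TRUE) / (nx * ny)
  }
  unit_phase(out)
}

#' Phase map from a stored central-k-space reference block
#'
#' Zero-pads a small fully sampled central k-space block (per slice) to
#' the imaging grid, inverse-transforms, and returns the unit-magnitude
#' phase.  Used with the `phase_ref` blocks recorded by
#' [simulate_acquisition()].
#'
#' @param block complex `wx x wy x nz` central k-space block (DC-first
#'   frequency subset).
#' @param grid imaging grid `c(nx, ny, nz)`.
#' @return unit-magnitude complex phase map on the imaging grid.
#' @export
phase_from_central_block <- function(block, grid) {
  if (length(dim(block)) == 2L) dim(block) <- c(dim(block), 1L)
  if (length(grid) == 2L) grid <- c(grid, dim(block)[3])
  keepx <- rank_window(grid[1], dim(block)[1])
  keepy <- rank_window(grid[2], dim(block)[2])
  out <- array(0i, grid)
  for (iz in seq_len(grid[3])) {
    k <- matrix(0i, grid[1], grid[2])
    k[keepx, keepy] <- block[, , iz]
    out[, , iz] <- stats::fft(k, inverse = TRUE) / sqrt(grid[1] * grid[2])
  }
  unit_phase(out)
}

#' Navigator-based phase-error estimate
#'
#' Reconstructs a fully sampled low-resolution navigator by sensitivity-
#' weighted coil combination, smooths it with a 2D Hamming apodization in
#' k-space to suppress ringing and noise, zero-pad interpolates it to the
#' imaging grid, and returns its unit-magnitude phase.
#'
#' @param nav_kspace complex `nxn x nyn x Nc` array of fully sampled
#'   navigator k-space (single slice), DC-first order.
#' @param sens a [coil_set()] at imaging resolution; maps are cropped in
#'   k-space to the navigator grid for the coil combination.
#' @param grid target imaging grid `c(nx, ny)` (defaults to the
#'   sensitivity grid).
#' @return unit-magnitude complex phase map on the imaging grid.
#' @export
estimate_phase_navigator <- function(nav_kspace, sens,
                                     grid = dim(sens$maps)[1:2]) {
  dn <- dim(nav_kspace)
  if (length(dn) != 3L) stop("navigator must be nxn x nyn x Nc")
  nxn <- dn[1]; nyn <- dn[2]; nc <- dn[3]
  if (dim(sens$maps)[4] != nc) stop("coil count mismatch")
  if (nxn > grid[1] || nyn > grid[2])
    stop("navigator grid must not exceed the imaging grid")
  ## sensitivities at navigator resolution by k-space cropping
  keepx <- rank_window(grid[1], nxn)
  keepy <- rank_window(grid[2], nyn)
  img <- array(0i, c(nxn, nyn))
  sos <- array(0, c(nxn, nyn))
  scale <- sqrt((nxn * nyn) / (grid[1] * grid[2]))
  for (cc in seq_len(nc)) {
    ks <- stats::fft(sens$maps[, , 1L, cc])[keepx, keepy] * scale
    slow <- stats::fft(ks, inverse = TRUE) / (nxn * nyn)
    nav <- stats::fft(nav_kspace[, , cc], inverse = TRUE) / sqrt(nxn * nyn)
    img <- img + Conj(slow) * nav
    sos <- sos + Mod(slow)^2
  }
  img[sos > 0] <- img[sos > 0] / sos[sos > 0]
  ## Hamming apodization in navigator k-space: symmetric in +/- f so the
  ## smoothing kernel is real and phase is not perturbed
  k <- stats::fft(img)
  wx <- 0.54 + 0.46 * cos(2 * pi * freq_index(nxn) / nxn)
  wy <- 0.54 + 0.46 * cos(2 * pi * freq_index(nyn) / nyn)
  k <- k * outer(wx, wy)
  ## zero-pad to the imaging grid
  kbig <- matrix(0i, grid[1], grid[2])
  kbig[keepx, keepy] <- k
  big <- stats::fft(kbig, inverse = TRUE) / (grid[1] * grid[2])
  unit_phase(array(big, c(grid[1], grid[2], 1L)))
}

#' Fit a constant + linear (rigid-motion) phase model to an image
#'
#' Bulk motion during the diffusion preparation produces a zeroth-order
#' phase offset plus a linear phase ramp in image space.  This fits that
#' three-parameter model per slice without phase unwrapping: the ramp
#' slopes come from the argument of the magnitude-weighted
#' autocorrelation between adjacent pixels along each axis, and the
#' offset from the weighted mean after de-ramping.  Because the
#' estimator pools all voxels it is robust to residual aliasing and
#' noise that corrupt voxelwise phase maps.
#'
#' @param img complex image (`nx x ny` or `nx x ny x nz`).
#' @param weight optional non-negative weight image (defaults to the
#'   squared magnitude of `img`).
#' @return unit-magnitude phase map of the fitted model, with attribute
#'   `"coef"` (per-slice offset and ramps in radians/pixel).
#' @export
fit_linear_phase <- function(img, weight = NULL) {
  img <- as_image3(img)
  nx <- dim(img)[1]; ny <- dim(img)[2]; nz <- dim(img)[3]
  if (is.null(weight)) weight <- Mod(img)^2 else weight <- as_image3(weight)
  out <- array(0i, dim(img))
  coefs <- matrix(0, nz, 3, dimnames = list(NULL, c("offset", "dx", "dy")))
  xr <- seq_len(nx) - (nx + 1) / 2
  yr <- seq_len(ny) - (ny + 1) / 2
  for (iz in seq_len(nz)) {
    sl <- img[, , iz]; w <- weight[, , iz]
    acx <- sum(Conj(sl[-nx, ]) * sl[-1, ] * sqrt(w[-nx, ] * w[-1, ]))
    acy <- sum(Conj(sl[, -ny]) * sl[, -1] * sqrt(w[, -ny] * w[, -1]))
    dx <- Arg(acx); dy <- Arg(acy)
    ramp <- outer(dx * xr, dy * yr, "+")
    off <- Arg(sum(w * sl * exp(-1i * ramp)))
    out[, , iz] <- exp(1i * (off + ramp))
    coefs[iz, ] <- c(off, dx, dy)
  }
  attr(out, "coef") <- coefs
  out
}

#' Navigator-free phase-error estimate
#'
#' Reconstructs the imaging data with SENSE/SMS-SENSE at a deliberately
#' low regularization weight, denoises the real and imaginary channels by
#' total variation, and uses the phase of the denoised image as the
#' phase-error estimate.  Background voxels, where the phase is pure
#' noise, are reset to zero phase via the magnitude mask.  The denoised
#' image is also returned for use as the reconstruction initialization.
#'
#' @param d k-space data (see [sense_reconstruct()]).
#' @param sens a [coil_set()].
#' @param pattern pattern / plan argument passed on to
#'   [sense_reconstruct()].
#' @param low_reg_weight Tikhonov weight for the initial reconstruction
#'   (should be below the L-curve optimum).
#' @param tv_weight TV denoising weight (0 reproduces the SENSE phase).
#' @param mask optional logical array: voxels outside get unit (zero)
#'   phase (full model only).
#' @param phase_model `"linear"` (default) fits the rigid-motion
#'   constant + linear ramp model to the denoised phase via
#'   [fit_linear_phase()], which stays reliable even when the
#'   low-regularization reconstruction carries residual aliasing;
#'   `"full"` keeps the voxelwise denoised phase, appropriate for
#'   nonlinear (e.g. cardiac-driven) phase errors.
#' @return list with `phase` (list of unit-magnitude maps, one per
#'   volume) and `init` (complex array of denoised images).
#' @export
estimate_phase_navfree <- function(d, sens, pattern = NULL, low_reg_weight,
                                   tv_weight = 0.02, mask = NULL,
                                   phase_model = c("linear", "full")) {
  phase_model <- match.arg(phase_model)
  rec <- sense_reconstruct(d, sens, pattern, tikhonov_weight = low_reg_weight)
  if (length(dim(rec)) == 3L) dim(rec) <- c(dim(rec), 1L)
  nd <- dim(rec)[4]
  phase <- vector("list", nd)
  init <- rec
  wmask <- if (is.null(mask)) NULL else array(as.numeric(mask), dim(rec)[1:3])
  for (j in seq_len(nd)) {
    den <- tv_denoise(rec[, , , j, drop = TRUE], tv_weight)
    den <- as_image3(den)
    init[, , , j] <- den
    if (phase_model == "linear") {
      w <- Mod(den)^2
      if (!is.null(wmask)) w <- w * wmask
      phase[[j]] <- fit_linear_phase(den, weight = w)
    } else {
      ph <- unit_phase(den)
      if (!is.null(mask)) ph[!mask] <- 1 + 0i
      phase[[j]] <- ph
    }
  }
  list(phase = phase, init = init)
}
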