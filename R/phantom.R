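#' Ball-and-stick diffusion signal
#'
#' The ball-and-stick model describes the diffusion-weighted signal as an
#' isotropic ("ball") compartment plus perfectly anisotropic ("stick")
#' fiber compartments: \deqn{S = S_0\Big[(1 - \sum_j f_j)\, e^{-b d} +
#' \sum_j f_j\, e^{-b d (g \cdot v_j)^2}\Big].}
#'
#' @param S0 non-diffusion-weighted signal.
#' @param d diffusivity (mm^2/s).
#' @param f numeric vector of fiber volume fractions (possibly empty),
#'   with `sum(f) <= 1`.
#' @param v matrix of unit fiber orientations, one row per fiber (may
#'   have zero rows).
#' @param g unit gradient direction(s): 3-vector or matrix of row vectors.
#' @param b b-value(s) in s/mm^2.
#' @return signal value(s), one per row of `g` / element of `b`.
#' @export
ball_and_stick_signal <- function(S0, d, f, v, g, b) {
  if (is.null(dim(g))) g <- matrix(g, ncol = 3)
  nf <- length(f)
  if (nf > 0) {
    v <- matrix(v, ncol = 3)
    if (nrow(v) != nf) stop("one orientation per fiber fraction required")
  }
  if (sum(f) > 1 + 1e-9) stop("fiber fractions must sum to at most 1")
  iso <- (1 - sum(f)) * exp(-b * d)
  sig <- iso
  if (nf > 0) for (j in seq_len(nf)) {
    dp <- as.vector(g %*% v[j, ])^2
    sig <- sig + f[j] * exp(-b * d * dp)
  }
  S0 * sig
}

#' Build a digital ball-and-stick phantom
#'
#' Constructs a 2D or thin-3D phantom with brain-like parameter ranges at
#' b = 1000 s/mm^2: an elliptical isotropic "tissue" support, two crossing
#' anisotropic fiber bundles (voxels in the overlap carry two sticks), and
#' a small CSF-like high-diffusivity blob.  Bundle geometry rotates
#' smoothly across slices so multiband slices are distinct.  The q-space
#' signal is smooth by construction, which is the structural assumption a
#' q-space smoothness prior requires.
#'
#' @param grid `c(nx, ny)` or `c(nx, ny, nz)`.
#' @param layout `"crossing"` (default: two bundles crossing at 90
#'   degrees) or `"empty"` (zero-signal phantom).
#' @param seed integer seed for the smooth S0 modulation.
#' @return object of class `bs_phantom`: list with per-voxel arrays `S0`,
#'   `d` (diffusivity), `f` (`nvox x 2` fiber fractions), `v` (array
#'   `nvox x 3 x 2` of orientations), `mask` (support), `n_fibers`, and
#'   the grid dimensions.
#' @export
make_phantom <- function(grid = c(48, 48), layout = c("crossing", "empty"),
                         seed = 1L) {
  layout <- match.arg(layout)
  if (length(grid) == 2L) grid <- c(grid, 1L)
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  nvox <- nx * ny * nz
  S0 <- array(0, grid); dmap <- array(0, grid)
  f <- matrix(0, nvox, 2)
  v <- array(0, c(nvox, 3, 2))
  nfib <- array(0L, grid)
  mask <- array(FALSE, grid)
  if (layout == "empty")
    return(structure(list(S0 = S0, d = dmap, f = f, v = v, mask = mask,
                          n_fibers = nfib, grid = grid),
                     class = "bs_phantom"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  xg <- (seq_len(nx) - (nx + 1) / 2) / (nx / 2)
  yg <- (seq_len(ny) - (ny + 1) / 2) / (ny / 2)
  X <- outer(xg, rep(1, ny)); Y <- outer(rep(1, nx), yg)
  ## smooth S0 modulation shared across slices
  mod <- 1 + 0.12 * sin(2.1 * X + stats::runif(1, 0, 2 * pi)) *
    cos(1.7 * Y + stats::runif(1, 0, 2 * pi))
  for (iz in seq_len(nz)) {
    sl_rot <- (iz - 1) * pi / 12          # bundle geometry varies by slice
    cs <- cos(sl_rot); sn <- sin(sl_rot)
    Xr <- cs * X + sn * Y; Yr <- -sn * X + cs * Y
    supp <- (X / 0.92)^2 + (Y / 0.88)^2 <= 1
    mask[, , iz] <- supp
    S0sl <- ifelse(supp, mod, 0)
    dsl <- ifelse(supp, 0.8e-3, 0)
    ## CSF-like blob near the centre
    csf <- (X + 0.25)^2 + (Y - 0.3)^2 <= 0.12^2
    dsl[csf & supp] <- 2.7e-3
    S0sl[csf & supp] <- 1.4 * mod[csf & supp]
    ## two crossing bundles in rotated coordinates
    band1 <- abs(Yr) <= 0.22 & supp & !csf    # along rotated x
    band2 <- abs(Xr) <= 0.22 & supp & !csf    # along rotated y
    dir1 <- c(cs, -sn, 0); dir2 <- c(sn, cs, 0)
    off <- (iz - 1L) * nx * ny
    idx1 <- which(band1 & !band2) + off
    idx2 <- which(band2 & !band1) + off
    idxb <- which(band1 & band2) + off
    f[idx1, 1] <- 0.55; v[idx1, , 1] <- matrix(dir1, length(idx1), 3,
                                               byrow = TRUE)
    f[idx2, 1] <- 0.55; v[idx2, , 1] <- matrix(dir2, length(idx2), 3,
                                               byrow = TRUE)
    f[idxb, 1] <- 0.35; f[idxb, 2] <- 0.35
    v[idxb, , 1] <- matrix(dir1, length(idxb), 3, byrow = TRUE)
    v[idxb, , 2] <- matrix(dir2, length(idxb), 3, byrow = TRUE)
    nf <- array(0L, c(nx, ny))
    nf[band1 | band2] <- 1L
    nf[band1 & band2] <- 2L
    nfib[, , iz] <- nf
    S0[, , iz] <- S0sl
    dmap[, , iz] <- dsl
  }
  structure(list(S0 = S0, d = dmap, f = f, v = v, mask = mask,
                 n_fibers = nfib, grid = grid),
            class = "bs_phantom")
}

#' @export
print.bs_phantom <- function(x, ...) {
  cat("ball-and-stick phantom:", paste(x$grid, collapse = " x "),
      "grid;", sum(x$mask), "support voxels;",
      sum(x$n_fibers == 2L), "two-fiber voxels\n")
  invisible(x)
}

#' Evaluate the phantom signal for a protocol
#'
#' @param phantom a [bs_phantom()].
#' @param protocol a [qspace_protocol()].
#' @return real array `nx x ny x nz x Nd` of noise-free signals.
#' @export
phantom_signal <- function(phantom, protocol) {
  g <- protocol$directions; b <- protocol$bvalues
  nd <- nrow(g)
  nvox <- prod(phantom$grid)
  S0v <- as.vector(phantom$S0); dv <- as.vector(phantom$d)
  ftot <- rowSums(phantom$f)
  out <- matrix(0, nvox, nd)
  for (j in seq_len(nd)) {
    e_iso <- exp(-b[j] * dv)
    sig <- (1 - ftot) * e_iso
    for (k in 1:2) {
      has <- phantom$f[, k] > 0
      if (any(has)) {
        dp <- (phantom$v[has, 1, k] * g[j, 1] +
               phantom$v[has, 2, k] * g[j, 2] +
               phantom$v[has, 3, k] * g[j, 3])^2
        sig[has] <- sig[has] + phantom$f[has, k] * exp(-b[j] * dv[has] * dp)
      }
    }
    out[, j] <- S0v * sig
  }
  array(out, c(phantom$grid, nd))
}

#' Per-volume motion phase errors
#'
#' Each diffusion volume receives an independent bulk-motion phase error:
#' a constant offset drawn uniformly from `offset_range` plus a linear
#' phase ramp along the phase-encoding direction, equivalent to a shift of
#' the acquired k-space centre along ky by a distance drawn uniformly from
#' `shift_range` (in units of the phase-encode step).  The resulting map
#' is `exp(i(phi0 + 2 pi s (y - ny/2) / ny))`.
#'
#' @param n_volumes number of volumes.
#' @param grid image grid `c(nx, ny)` or `c(nx, ny, nz)`.
#' @param offset_range range of the constant offset (radians); default
#'   `c(-pi, pi)`.
#' @param shift_range range of the ky shift in phase-encode steps;
#'   default `c(0, 2)`.
#' @param seed integer seed.
#' @param per_slice if `TRUE`, multiband slices get independent draws;
#'   default is one draw per volume (shared across the simultaneously
#'   excited slices of a shot).
#' @return list of unit-magnitude complex phase maps (one per volume),
#'   with attribute `"draws"` (data frame of the sampled offsets/shifts).
#' @export
sample_phase_errors <- function(n_volumes, grid,
                                offset_range = c(-pi, pi),
                                shift_range = c(0, 2), seed = 1L,
                                per_slice = FALSE) {
  if (length(grid) == 2L) grid <- c(grid, 1L)
  if (any(!is.finite(c(offset_range, shift_range))))
    stop("ranges must be finite")
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  set.seed(as.integer(seed) %% .Machine$integer.max)
  ndraw <- if (per_slice) n_volumes * nz else n_volumes
  phi0 <- stats::runif(ndraw, offset_range[1], offset_range[2])
  sft <- stats::runif(ndraw, shift_range[1], shift_range[2])
  yramp <- 2 * pi * ((seq_len(ny) - 1) - ny / 2) / ny
  maps <- vector("list", n_volumes)
  for (j in seq_len(n_volumes)) {
    m <- array(0i, grid)
    for (iz in seq_len(nz)) {
      k <- if (per_slice) (j - 1L) * nz + iz else j
      ph <- phi0[k] + sft[k] * yramp
      m[, , iz] <- exp(1i * matrix(ph, nx, ny, byrow = TRUE))
    }
    maps[[j]] <- m
  }
  attr(maps, "draws") <- data.frame(
    volume = if (per_slice) rep(seq_len(n_volumes), each = nz)
             else seq_len(n_volumes),
    slice = if (per_slice) rep(seq_len(nz), n_volumes) else 1L,
    offset = phi0, shift = sft)
  maps
}

#' Simulate a full k-q accelerated diffusion acquisition
#'
#' Evaluates the phantom's ball-and-stick signal for every direction of
#' the protocol, applies per-volume motion phase errors, encodes each
#' volume through the coil/Fourier/sampling forward model following the
#' k-q plan, and adds complex Gaussian k-space noise.  The noise level is
#' set by `snr`, defined as the mean noise-free b = 0 magnitude inside
#' the support mask divided by the per-component (real or imaginary)
#' k-space noise standard deviation per channel; the injected value is
#' recorded as `sigma_k_true`.  Noise-free ground-truth magnitude images
#' and the true phase maps are stored for evaluation.
#'
#' @param phantom a [bs_phantom()].
#' @param protocol a [qspace_protocol()].
#' @param coils a [coil_set()] on the phantom grid.
#' @param plan a [kq_plan()] (or a single [sampling_pattern()] applied to
#'   every volume).
#' @param phase `"random"` (draw from [sample_phase_errors()]), `"none"`,
#'   or a precomputed list of phase maps.
#' @param snr signal-to-noise ratio as defined above; `Inf` for noiseless.
#' @param seed master seed; phase draws and noise use seeds derived from
#'   it.
#' @param phase_ref_window if non-`NULL` (default 32 x 32, clipped to the
#'   grid), the simulator also stores a small fully sampled central
#'   k-space block of each phase-corrupted volume (per slice, with the
#'   same noise level) as `phase_ref`.  This emulates the low-frequency
#'   phase information a navigator or calibration block provides, and is
#'   what the `central_kspace` phase mode consumes for simulated data,
#'   where it captures the zeroth/first-order motion phase essentially
#'   exactly.
#' @return object of class `kq_dataset`: list with `kdata` (a
#'   [kq_data()]), `protocol`, `plan`, `truth` (real array
#'   `nx x ny x nz x Nd`), `phase_maps`, `mask`, `sigma_k_true`, `snr`,
#'   `seed`.
#' @export
simulate_acquisition <- function(phantom, protocol, coils, plan,
                                 phase = "random", snr = 20, seed = 1L,
                                 phase_ref_window = c(32L, 32L)) {
  grid <- phantom$grid
  nd <- nrow(protocol$directions)
  if (inherits(plan, "sampling_pattern"))
    plan <- list(patterns = list(plan), pattern_id = rep(0L, nd))
  if (length(plan$pattern_id) != nd)
    stop("plan does not cover all ", nd, " volumes")
  truth <- phantom_signal(phantom, protocol)
  if (identical(phase, "none")) {
    phase_maps <- NULL
  } else if (identical(phase, "random")) {
    phase_maps <- sample_phase_errors(nd, grid, seed = seed + 1L)
  } else phase_maps <- phase
  s0 <- mean(phantom$S0[phantom$mask])
  sigma_k <- if (is.finite(snr)) s0 / snr else 0
  set.seed((as.integer(seed) + 2L) %% .Machine$integer.max)
  vols <- vector("list", nd)
  phase_ref <- NULL
  keepx <- keepy <- NULL
  if (!is.null(phase_ref_window)) {
    wref <- pmin(phase_ref_window, grid[1:2])
    keepx <- rank_window(grid[1], wref[1])
    keepy <- rank_window(grid[2], wref[2])
    phase_ref <- vector("list", nd)
  }
  nc <- dim(coils$maps)[4]
  for (j in seq_len(nd)) {
    pat <- plan$patterns[[plan$pattern_id[j] + 1L]]
    u <- array(truth[, , , j], grid)
    ph <- if (is.null(phase_maps)) NULL else phase_maps[[j]]
    kv <- forward_encode(u, coils, pat, phase = ph)$data
    if (sigma_k > 0) {
      n <- length(kv)
      kv <- kv + complex(real = stats::rnorm(n, sd = sigma_k),
                         imaginary = stats::rnorm(n, sd = sigma_k))
    }
    vols[[j]] <- kv
    if (!is.null(phase_ref)) {
      up <- if (is.null(ph)) u else u * ph
      blk <- array(0i, c(sum(keepx), sum(keepy), grid[3]))
      for (iz in seq_len(grid[3])) {
        kz <- stats::fft(up[, , iz]) / sqrt(grid[1] * grid[2])
        blk[, , iz] <- kz[keepx, keepy]
      }
      if (sigma_k > 0)
        blk <- blk + complex(real = stats::rnorm(length(blk), sd = sigma_k),
                             imaginary = stats::rnorm(length(blk),
                                                      sd = sigma_k))
      phase_ref[[j]] <- blk
    }
  }
  kd <- kq_data(vols, plan$patterns, plan$pattern_id + 1L)
  structure(list(kdata = kd, protocol = protocol, plan = plan,
                 truth = truth, phase_maps = phase_maps,
                 phase_ref = phase_ref,
                 mask = phantom$mask, sigma_k_true = sigma_k, snr = snr,
                 seed = seed),
            class = "kq_dataset")
}

#' @export
print.kq_dataset <- function(x, ...) {
  cat("simulated k-q dataset:", length(x$kdata$volumes), "volumes on a",
      paste(dim(x$truth)[1:3], collapse = " x "), "grid\n")
  cat("  SNR =", x$snr, " (sigma_k =", format(x$sigma_k_true, digits = 4),
      "),", if (is.null(x$phase_maps)) "no" else "with",
      "motion phase errors\n")
  invisible(x)
}
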