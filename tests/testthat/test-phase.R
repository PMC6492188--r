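test_that("central k-space phase estimate recovers constant + linear ramps", {
  nx <- 48; ny <- 48
  ## smooth positive object
  xg <- (seq_len(nx) - 24.5) / 24; yg <- (seq_len(ny) - 24.5) / 24
  obj <- outer(exp(-xg^2 * 2), exp(-yg^2 * 2))
  phi0 <- 0.8; slope <- 1.7                    # cycles-free linear ramp
  ramp <- matrix(phi0 + slope * 2 * pi * (seq_len(ny) - 25) / ny,
                 nx, ny, byrow = TRUE)
  img <- obj * exp(1i * ramp)
  supp <- obj > 0.3 * max(obj)
  ## full-window estimate recovers the ramp exactly
  pfull <- estimate_phase_central_kspace(img, window = c(48, 48))
  expect_lt(max(abs(Arg(pfull[, , 1] * exp(-1i * ramp)))[supp]), 1e-8)
  ## 32x32 window: small truncation ringing, ramp still accurate
  pe <- estimate_phase_central_kspace(img, window = c(32, 32))
  err <- Arg(pe[, , 1] * exp(-1i * ramp))
  expect_lt(stats::quantile(abs(err[supp]), 0.95), 0.05)
  ## recovered ramp slope within 2 percent (wrap-free parametric fit of
  ## the windowed phase estimate)
  co <- attr(fit_linear_phase(array(obj * pe[, , 1], c(nx, ny, 1))),
             "coef")
  expect_lt(abs(co[1, "dy"] * ny / (2 * pi) - slope) / slope, 0.02)
  ## real non-negative object: phase approximately zero in the support
  p0 <- estimate_phase_central_kspace(obj, window = c(32, 32))
  expect_lt(stats::quantile(abs(Arg(p0[, , 1][supp])), 0.95), 0.01)
  ## unit-magnitude contract + window clipping warning
  expect_equal(Mod(pe), array(1, dim(pe)), tolerance = 1e-12)
  expect_warning(estimate_phase_central_kspace(obj[1:16, 1:16],
                                               window = c(32, 32)),
                 "clipped")
})

test_that("stored central-k-space reference blocks reproduce simulated phase", {
  fx <- small_dataset(size = 32, n_dir = 8, n_coils = 4, R = 2, seed = 3)
  ds <- fx$dataset
  expect_length(ds$phase_ref, 8L)
  for (j in c(1L, 5L)) {
    pm <- phase_from_central_block(ds$phase_ref[[j]], c(32, 32, 1))
    err <- Arg(pm * Conj(ds$phase_maps[[j]]))
    m <- array(ds$mask, dim(pm))
    expect_lt(median(abs(err[m])), 0.1)
    expect_equal(Mod(pm), array(1, dim(pm)), tolerance = 1e-12)
  }
})

test_that("navigator phase estimation round-trips a known smooth phase", {
  nx <- 32; ny <- 32
  sens <- simulate_coils(4, c(nx, ny), seed = 6)
  xg <- (seq_len(nx) - 16.5) / 16; yg <- (seq_len(ny) - 16.5) / 16
  obj <- outer(exp(-xg^2 * 3), exp(-yg^2 * 3))
  ph_true <- 0.5 + outer(0.6 * xg, rep(1, ny)) + outer(rep(1, nx), 0.9 * yg)
  img <- obj * exp(1i * ph_true)
  ## noiseless fully sampled navigator at half resolution
  nav <- array(0i, c(16, 16, 4))
  keep16 <- dager:::rank_window(32, 16)
  for (cc in 1:4) {
    k <- stats::fft(img * sens$maps[, , 1, cc]) / 32
    nav[, , cc] <- k[keep16, keep16] * (16 / 32)
  }
  pe <- estimate_phase_navigator(nav, sens, grid = c(nx, ny))
  supp <- obj > 0.1 * max(obj)
  err <- Arg(pe[, , 1] * exp(-1i * ph_true))
  expect_lt(max(abs(err[supp])), 0.1)
  expect_equal(Mod(pe), array(1, dim(pe)), tolerance = 1e-12)
  ## constant-phase object returns constant phase (uniform coil, so the
  ## low-resolution coil combination is exact)
  su <- simulate_coils(1, c(nx, ny), geometry = "uniform")
  navc <- array(0i, c(16, 16, 1))
  k <- stats::fft(obj * exp(1i * 1.1)) / 32
  navc[, , 1] <- k[keep16, keep16]
  pc <- estimate_phase_navigator(navc, su, grid = c(nx, ny))
  supp2 <- obj > 0.3 * max(obj)       # away from interpolation ringing
  ## exact up to the unpaired Nyquist coefficient of the even grid
  expect_lt(max(abs(Arg(pc[, , 1][supp2] * exp(-1i * 1.1)))), 1e-3)
})

test_that("TV denoising reduces total variation and is the identity at 0", {
  set.seed(8)
  img <- matrix(rnorm(32 * 32), 32)
  img[10:20, 10:20] <- img[10:20, 10:20] + 4
  expect_identical(tv_denoise(img, 0), img)
  den <- tv_denoise(img, 0.5, n_iter = 40)
  tv <- function(u) sum(abs(diff(u))) + sum(abs(t(diff(t(u)))))
  expect_lt(tv(den), tv(img))
  ## complex input denoises channels independently
  z <- img + 1i * img
  dz <- tv_denoise(z, 0.5, n_iter = 40)
  expect_equal(Re(dz), den, tolerance = 1e-12)
  expect_equal(Im(dz), den, tolerance = 1e-12)
})

test_that("navigator-free phase estimation recovers phase on clean data", {
  fx <- small_dataset(size = 24, n_dir = 6, n_coils = 8, R = 2,
                      snr = Inf, seed = 4)
  ds <- fx$dataset
  nf <- estimate_phase_navfree(ds$kdata, fx$coils, low_reg_weight = 1e-6,
                               tv_weight = 0.01, mask = ds$mask,
                               phase_model = "full")
  for (j in c(1L, 4L)) {
    err <- Arg(nf$phase[[j]] * Conj(ds$phase_maps[[j]]))
    m <- array(ds$mask, dim(err)) & array(ds$truth[, , , j] > 0.15,
                                          dim(err))
    expect_lt(stats::quantile(abs(err[m]), 0.95), 0.05)
  }
  ## background voxels flagged to unit phase via the mask (full model)
  expect_true(all(nf$phase[[1]][!ds$mask] == 1 + 0i))
  ## the parametric rigid-motion model recovers the simulated ramps too
  nfl <- estimate_phase_navfree(ds$kdata, fx$coils, low_reg_weight = 1e-6,
                                tv_weight = 0.01, mask = ds$mask,
                                phase_model = "linear")
  for (j in c(1L, 4L)) {
    err <- Arg(nfl$phase[[j]] * Conj(ds$phase_maps[[j]]))
    m <- array(ds$mask, dim(err))
    expect_lt(stats::quantile(abs(err[m]), 0.95), 0.05)
  }
  ## zero TV weight reproduces the plain SENSE phase (voxelwise model)
  nf0 <- estimate_phase_navfree(ds$kdata, fx$coils, low_reg_weight = 1e-6,
                                tv_weight = 0, mask = NULL,
                                phase_model = "full")
  rec <- sense_reconstruct(ds$kdata, fx$coils, tikhonov_weight = 1e-6)
  expect_equal(Arg(nf0$phase[[2]]),
               array(Arg(dager:::unit_phase(rec[, , , 2, drop = FALSE])),
                     dim(nf0$phase[[2]])),
               tolerance = 1e-10, ignore_attr = TRUE)
})
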