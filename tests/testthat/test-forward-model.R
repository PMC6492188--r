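test_that("single uniform coil with full sampling is a unitary round trip", {
  set.seed(1)
  s1 <- simulate_coils(1, c(8, 8), geometry = "uniform")
  pfull <- sampling_pattern(8, 1, R = 1)
  x <- array(rcplx(64), c(8, 8, 1))
  k <- forward_encode(x, s1, pfull)
  expect_equal(adjoint_encode(k, s1, pfull), x, tolerance = 1e-10)
  ## energy preservation (orthonormal transform contract)
  expect_equal(sqrt(sum(Mod(k$data)^2)), sqrt(sum(Mod(x)^2)),
               tolerance = 1e-10)
  ## adjoint of forward of a delta is the delta
  d0 <- array(0i, c(8, 8, 1)); d0[3, 5, 1] <- 1
  expect_equal(adjoint_encode(forward_encode(d0, s1, pfull), s1, pfull),
               d0, tolerance = 1e-10)
})

test_that("undersampling keeps the expected line count and adjoint(0) = 0", {
  sens <- simulate_coils(2, c(8, 8), seed = 3)
  p2 <- sampling_pattern(8, 1, R = 2)
  x <- array(rcplx(64), c(8, 8, 1))
  k <- forward_encode(x, sens, p2)
  expect_equal(dim(k$data)[2], 4L)          # half the ky lines
  z <- k; z$data[] <- 0i
  expect_equal(adjoint_encode(z, sens, p2),
               array(0i, c(8, 8, 1)), tolerance = 0)
})

test_that("forward is linear and exactly adjoint to adjoint_encode", {
  set.seed(7)
  sens <- simulate_coils(2, c(8, 8), seed = 3)
  p <- sampling_pattern(8, 1, R = 2, ky_shift = 1)
  ph <- array(exp(1i * matrix(rnorm(64), 8)), c(8, 8, 1))
  x <- array(rcplx(64), c(8, 8, 1))
  y <- array(rcplx(64), c(8, 8, 1))
  a <- 2 - 1i; b <- -0.5 + 3i
  fx <- forward_encode(x, sens, p, ph)$data
  fy <- forward_encode(y, sens, p, ph)$data
  fab <- forward_encode(a * x + b * y, sens, p, ph)$data
  expect_equal(fab, a * fx + b * fy, tolerance = 1e-12)
  d <- array(rcplx(length(fx)), dim(fx))
  lhs <- sum(Re(Conj(fx) * d))
  rhs <- sum(Re(Conj(x) * adjoint_encode(list(data = d), sens, p, ph)))
  expect_equal(lhs, rhs, tolerance = 1e-10 * abs(lhs))
})

test_that("forward/adjoint agree with an explicitly built dense matrix", {
  set.seed(9)
  sens <- simulate_coils(2, c(8, 8), seed = 3)
  p <- sampling_pattern(8, 1, R = 2, ky_shift = 1)
  A <- dense_encoding_matrix(sens, p)
  x <- array(rcplx(64), c(8, 8, 1))
  fw <- forward_encode(x, sens, p)$data
  expect_equal(as.vector(aperm(fw, c(1, 2, 3))),
               as.vector(A %*% as.vector(x)), tolerance = 1e-10)
  d <- rcplx(nrow(A))
  adj <- adjoint_encode(as_kvol(d, 8, p, 2), sens, p)
  expect_equal(as.vector(adj), as.vector(Conj(t(A)) %*% d),
               tolerance = 1e-10)
})

test_that("multiband encoding with zero kz blips collapses to the slice sum", {
  set.seed(12)
  sens2 <- simulate_coils(3, c(8, 8, 2), seed = 4)
  ## fov_shift_fraction = 0: kz = 0 acquired for every line
  psms <- sampling_pattern(8, 2, R = 1, MB = 2, fov_shift_fraction = 0)
  x <- array(rcplx(128), c(8, 8, 2))
  ksms <- forward_encode(x, sens2, psms)$data
  ## single-band encodings of each slice with the matching coil profile
  pf <- sampling_pattern(8, 1, R = 1)
  ssum <- 0
  for (iz in 1:2) {
    sz <- coil_set(array(sens2$maps[, , iz, ], c(8, 8, 1, 3)))
    ssum <- ssum + forward_encode(array(x[, , iz], c(8, 8, 1)),
                                  sz, pf)$data
  }
  expect_equal(ksms, ssum / sqrt(2), tolerance = 1e-10)
})

test_that("g-factor is 1 without undersampling and matches a 2x2 hand unfold", {
  s <- simulate_coils(4, c(6, 6), seed = 2)   # sum-of-squares normalized
  expect_equal(as.vector(gfactor_map(s, sampling_pattern(6, 1, R = 1))),
               rep(1, 36), tolerance = 1e-9)
  ## hand-computed 2-coil, R=2 unfolding at one voxel pair
  s2 <- simulate_coils(2, c(4, 4), seed = 5)
  p2 <- sampling_pattern(4, 1, R = 2)
  g <- gfactor_map(s2, p2)
  ix <- 2; y1 <- 1; y2 <- 3                  # aliasing pair (0-based dy = 2)
  Sm <- cbind(s2$maps[ix, y1, 1, ], s2$maps[ix, y2, 1, ])
  ginv <- solve(Conj(t(Sm)) %*% Sm)
  expect_equal(g[ix, y1, 1], sqrt(2 * Re(ginv[1, 1])), tolerance = 1e-9)
  expect_equal(g[ix, y2, 1], sqrt(2 * Re(ginv[2, 2])), tolerance = 1e-9)
})

test_that("Monte-Carlo SENSE noise matches sigma_k * g within 5 percent", {
  set.seed(77)
  sens <- simulate_coils(2, c(8, 8), seed = 3)
  pat <- sampling_pattern(8, 1, R = 2)
  g <- gfactor_map(sens, pat)
  sigk <- 0.7
  ntr <- 10000
  vols <- lapply(seq_len(ntr), function(i)
    array(rcplx(8 * 4 * 2, sd = sigk), c(8, 4, 2)))
  kd <- kq_data(vols, list(pat), rep(1L, ntr))
  rec <- sense_reconstruct(kd, sens, tikhonov_weight = 0)
  M <- matrix(rec, 64, ntr)
  sd_obs <- sqrt((rowSums(Re(M)^2) + rowSums(Im(M)^2)) / (2 * ntr))
  expect_lt(max(abs(sd_obs / (sigk * as.vector(g)) - 1)), 0.05)
})

test_that("sigma_k calibration: identity propagation and determinism", {
  g1 <- array(1, c(5, 5, 1))
  sim <- array(0.37, c(5, 5, 1))
  mask <- array(TRUE, c(5, 5, 1))
  expect_equal(calibrate_sigma_k(sim, g1, mask, seed = 1), 0.37)
  simr <- sim * runif(25)
  expect_identical(calibrate_sigma_k(simr, g1, mask, n_voxels = 10,
                                     seed = 7),
                   calibrate_sigma_k(simr, g1, mask, n_voxels = 10,
                                     seed = 7))
  expect_error(calibrate_sigma_k(sim, array(Inf, c(5, 5, 1)), mask),
               "no usable voxels")
})

test_that("injected sigma_k is recovered through the noise-map calibration", {
  fx <- small_dataset(size = 24, n_dir = 96, R = 2, phase = "none",
                      mode = "fixed", seed = 5)
  ds <- fx$dataset
  rec <- sense_reconstruct(ds$kdata, fx$coils, tikhonov_weight = 0)
  smap <- estimate_sigma_im_map(matrix(rec, 24 * 24, 96), fx$protocol)
  gmap <- gfactor_map(fx$coils, sampling_pattern(24, 1, R = 2))
  sk <- calibrate_sigma_k(smap, gmap, ds$mask, n_voxels = 300, seed = 3)
  expect_lt(abs(sk - ds$sigma_k_true) / ds$sigma_k_true, 0.10)
})
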