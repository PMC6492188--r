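test_that("ball-and-stick signal matches its closed form", {
  v <- c(0, 0, 1)
  ## b = 0: no diffusion weighting
  expect_equal(ball_and_stick_signal(2, 8e-4, 0.5, v, c(1, 0, 0), 0), 2)
  ## pure ball: isotropic in g
  s1 <- ball_and_stick_signal(1, 8e-4, numeric(0), NULL, c(1, 0, 0), 1000)
  s2 <- ball_and_stick_signal(1, 8e-4, numeric(0), NULL, c(0, 0, 1), 1000)
  expect_equal(s1, exp(-0.8)); expect_equal(s1, s2)
  ## single stick perpendicular to g at b*d = 1, f = 0.5
  s3 <- ball_and_stick_signal(1, 1e-3, 0.5, v, c(1, 0, 0), 1000)
  expect_equal(s3, 0.5 * exp(-1) + 0.5, tolerance = 1e-12)
  ## bounded in (0, S0] and antipodally symmetric
  set.seed(1)
  g <- qspace_directions(24, seed = 4)
  s <- ball_and_stick_signal(1.3, 8e-4, c(0.4, 0.3),
                             rbind(c(1, 0, 0), c(0, 1, 0)), g, 1000)
  expect_true(all(s > 0 & s <= 1.3))
  expect_equal(s, ball_and_stick_signal(1.3, 8e-4, c(0.4, 0.3),
                                        rbind(c(1, 0, 0), c(0, 1, 0)),
                                        -g, 1000))
  expect_error(ball_and_stick_signal(1, 1e-3, c(0.7, 0.7),
                                     rbind(v, v), v, 1000), "at most 1")
})

test_that("phantom construction: empty layout, crossings, smooth q-profile", {
  p0 <- make_phantom(c(16, 16), layout = "empty")
  expect_true(all(p0$S0 == 0))
  ph <- make_phantom(c(32, 32), seed = 2)
  expect_gt(sum(ph$n_fibers == 2L), 0)          # crossing region exists
  two <- which(as.vector(ph$n_fibers) == 2L)[1]
  expect_true(all(ph$f[two, ] > 0))
  ## orientations of the two sticks are orthogonal by construction
  expect_lt(abs(sum(ph$v[two, , 1] * ph$v[two, , 2])), 1e-9)
  ## deterministic under seed
  expect_identical(make_phantom(c(32, 32), seed = 2)$S0, ph$S0)
  ## signal covariance decays with angular distance (smoothness audit)
  prot <- qspace_protocol(qspace_directions(48, seed = 1), 1000)
  sig <- phantom_signal(ph, prot)
  cva <- covariance_vs_angle(sig, prot, ph$mask)
  cb <- bin_covariance_curve(cva, breaks = seq(0, pi / 2, length.out = 7))
  expect_gt(cb$covariance[1], cb$covariance[nrow(cb)])
  ## a GP fit on the phantom signal finds finite positive smoothness
  hp <- estimate_hyperparameters(sig, prot, mask = ph$mask,
                                 n_voxels = 200, seed = 1)
  expect_true(is.finite(hp$a) && hp$a > 0 && hp$lambda > 0)
})

test_that("simulated coils: uniform map, distinct ring profiles, determinism", {
  u1 <- simulate_coils(1, c(12, 12), geometry = "uniform")
  expect_true(all(u1$maps == 1 + 0i))
  s8 <- simulate_coils(8, c(24, 24), seed = 3)
  ## sum-of-squares normalization
  sos <- apply(Mod(s8$maps)^2, 1:3, sum)
  expect_equal(as.vector(sos), rep(1, 24 * 24), tolerance = 1e-10)
  ## adjacent coils have distinct spatial profiles
  for (cc in 1:7) {
    m1 <- abs(as.vector(s8$maps[, , , cc]))
    m2 <- abs(as.vector(s8$maps[, , , cc + 1]))
    expect_lt(stats::cor(m1, m2), 0.99)
  }
  expect_identical(simulate_coils(8, c(24, 24), seed = 3)$maps, s8$maps)
})

test_that("phase error draws respect their ranges and distributions", {
  z <- sample_phase_errors(3, c(8, 8), offset_range = c(0, 0),
                           shift_range = c(0, 0), seed = 1)
  expect_true(all(vapply(z, function(m) all(m == 1 + 0i), logical(1))))
  big <- sample_phase_errors(10000, c(2, 4), seed = 2)
  dr <- attr(big, "draws")
  expect_true(all(dr$shift >= 0 & dr$shift <= 2))
  expect_true(all(dr$offset >= -pi & dr$offset <= pi))
  ## mean offset within 3 standard errors of 0
  se <- 2 * pi / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(dr$offset)), 3 * se)
  expect_equal(Mod(big[[17]]), array(1, c(2, 4, 1)), tolerance = 1e-12)
})

test_that("noiseless closed loop and injected noise level are exact", {
  ## infinite SNR, R = 1, uniform coil: SENSE recon equals ground truth
  prot <- qspace_protocol(qspace_directions(5, seed = 2), 1000)
  phan <- make_phantom(c(16, 16), seed = 1)
  u1 <- simulate_coils(1, c(16, 16), geometry = "uniform")
  plan1 <- design_plan(prot, R = 1, ny = 16, mode = "fixed")
  ds <- simulate_acquisition(phan, prot, u1, plan1, phase = "none",
                             snr = Inf, seed = 3)
  rec <- sense_reconstruct(ds$kdata, u1, tikhonov_weight = 0)
  expect_equal(Mod(rec), ds$truth, tolerance = 1e-8, ignore_attr = TRUE)
  ## measured k-space noise std matches the injected value within 2%
  c8 <- simulate_coils(8, c(16, 16), seed = 2)
  ds2 <- simulate_acquisition(phan, prot, c8, plan1, phase = "none",
                              snr = 10, seed = 4)
  ds0 <- simulate_acquisition(phan, prot, c8, plan1, phase = "none",
                              snr = Inf, seed = 4)
  nz <- unlist(lapply(1:5, function(j)
    ds2$kdata$volumes[[j]] - ds0$kdata$volumes[[j]]))
  comp <- c(Re(nz), Im(nz))
  expect_gt(length(comp), 2e4)
  expect_lt(abs(stats::sd(comp) / ds2$sigma_k_true - 1), 0.02)
  ## bit-reproducible under the master seed
  ds3 <- simulate_acquisition(phan, prot, c8, plan1, phase = "none",
                              snr = 10, seed = 4)
  expect_identical(ds3$kdata$volumes, ds2$kdata$volumes)
})

test_that("blipped-CAIPI SMS encoding separates shifted slices", {
  ## MB = 2, R = 1, FOV/2 shift: slices recoverable from the kz blip
  ## structure plus coil variation along z
  prot <- qspace_protocol(qspace_directions(3, seed = 2), 1000)
  phan <- make_phantom(c(16, 16, 2), seed = 2)
  u1 <- simulate_coils(4, c(16, 16, 2), seed = 5)
  plan <- design_plan(prot, R = 1, MB = 2, fov_shift_fraction = 1 / 2,
                      ny = 16, nz = 2, mode = "fixed")
  ds <- simulate_acquisition(phan, prot, u1, plan, phase = "none",
                             snr = Inf, seed = 1)
  rec <- sense_reconstruct(ds$kdata, u1, tikhonov_weight = 0)
  expect_equal(Mod(rec), ds$truth, tolerance = 1e-6, ignore_attr = TRUE)
  ## undersampling factor bookkeeping: MB*ny lines, ny acquired
  expect_equal(length(plan$patterns[[1]]$idx), 16L)
})
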