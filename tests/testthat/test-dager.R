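test_that("infinite noise limit returns the phase-modulated prior mean", {
  set.seed(2)
  fx <- small_dataset(size = 16, n_dir = 12, n_coils = 4, R = 2, seed = 2)
  ds <- fx$dataset
  cov <- gp_covariance(fx$protocol, gp_hyperparams(0.9, 0.5, 0.1))
  ub <- matrix(rnorm(16 * 16 * 12, sd = 0.2), 16 * 16, 12)
  sol <- dager_solve(ds$kdata, fx$coils, phase_maps = ds$phase_maps,
                     cov = cov, u_bar = ub, sigma_k = 1e6, maxit = 300)
  Pm <- sapply(ds$phase_maps, as.vector)
  expect_equal(matrix(sol$u, 16 * 16, 12), Pm * ub, tolerance = 1e-4)
})

test_that("vanishing prior precision reduces to per-volume SENSE", {
  set.seed(3)
  fx <- small_dataset(size = 16, n_dir = 8, n_coils = 6, R = 2,
                      phase = "none", seed = 3)
  ds <- fx$dataset
  ## lambda -> infinity with u_bar = 0: Sigma^-1 -> 0
  cov <- gp_covariance(fx$protocol, gp_hyperparams(0.9, 1e8, 0))
  sol <- dager_solve(ds$kdata, fx$coils, cov = cov, u_bar = 0,
                     sigma_k = ds$sigma_k_true, tol = 1e-10, maxit = 500)
  sen <- sense_reconstruct(ds$kdata, fx$coils, tikhonov_weight = 0)
  expect_lt(sqrt(sum(Mod(sol$u - sen)^2) / sum(Mod(sen)^2)), 1e-4)
})

test_that("the returned stationary point satisfies first-order optimality", {
  set.seed(4)
  fx <- small_dataset(size = 16, n_dir = 10, n_coils = 4, R = 2, seed = 4)
  ds <- fx$dataset
  cov <- gp_covariance(fx$protocol, gp_hyperparams(1.1, 0.3, 0.2))
  sol <- dager_solve(ds$kdata, fx$coils, phase_maps = ds$phase_maps,
                     cov = cov, u_bar = 0, sigma_k = ds$sigma_k_true,
                     tol = 1e-8, maxit = 400)
  expect_true(sol$info$converged)
  expect_lt(sol$info$relres, 1e-8)
  ## monitored quadratic objective is non-increasing across CG iterations
  ob <- sol$info$objective
  expect_true(all(diff(ob) <= 1e-8 * (abs(ob[1]) + 1)))
})

test_that("with one volume and trivial encoding DAGER is the scalar shrinkage", {
  set.seed(5)
  nx <- 8; ny <- 8
  s1 <- simulate_coils(1, c(nx, ny), geometry = "uniform")
  pfull <- sampling_pattern(ny, 1, R = 1)
  u <- array(rcplx(nx * ny), c(nx, ny, 1))
  kv <- forward_encode(u, s1, pfull)
  kd <- kq_data(list(kv$data), list(pfull), 1L)
  lam <- 0.7; sk <- 0.4
  p1 <- qspace_protocol(c(0, 0, 1))
  cov <- gp_covariance(p1, gp_hyperparams(1, lam, sk))
  sol <- dager_solve(kd, s1, cov = cov, u_bar = 0, sigma_k = sk,
                     tol = 1e-12, maxit = 200)
  ## Eq for a single voxel/volume: u_hat = d * lambda / (lambda + sigma^2),
  ## identical to the GP posterior-mean shrinkage applied in image space
  expect_equal(as.vector(sol$u), as.vector(u) * lam / (lam + sk^2),
               tolerance = 1e-8)
  expect_equal(as.vector(sol$u),
               as.vector(posterior_mean(matrix(as.vector(u), 1), cov)),
               tolerance = 1e-8)
})

test_that("reconstruction is invariant to known phase corruption", {
  set.seed(6)
  ## exact invariance at full sampling: with sum-of-squares-normalized
  ## coils the encoding is isometric, so multiplying truth and data by a
  ## unit phase map and supplying it as P gives the identical
  ## phase-corrected problem
  nx <- 16
  sens <- simulate_coils(4, c(nx, nx), seed = 2)
  pfull <- sampling_pattern(nx, 1, R = 1)
  prot <- qspace_protocol(qspace_directions(6, seed = 1), 1000)
  cov <- gp_covariance(prot, gp_hyperparams(1.0, 0.4, 0.15))
  U <- matrix(rcplx(nx * nx * 6, sd = 0.4), nx * nx, 6)
  ph <- sample_phase_errors(6, c(nx, nx), seed = 9)
  enc <- function(phase) kq_data(lapply(1:6, function(j)
    forward_encode(array(U[, j], c(nx, nx, 1)), sens, pfull,
                   phase = phase[[j]])$data),
    list(pfull), rep(1L, 6))
  sol0 <- dager_solve(enc(rep(list(NULL), 6)), sens, cov = cov,
                      u_bar = 0, sigma_k = 0.05, tol = 1e-10, maxit = 400)
  sol1 <- dager_solve(enc(ph), sens, phase_maps = ph, cov = cov,
                      u_bar = 0, sigma_k = 0.05, tol = 1e-10, maxit = 400)
  expect_lt(sqrt(sum(Mod(sol1$x - sol0$x)^2) / sum(Mod(sol0$x)^2)), 1e-6)
  expect_lt(max(abs(Mod(sol1$u) - Mod(sol0$u))), 1e-6 * max(Mod(sol0$u)))
})
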