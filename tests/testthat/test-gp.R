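test_that("spherical covariance matches hand-derived values and support", {
  expect_equal(spherical_covariance(0, 0.8), 1)
  expect_equal(spherical_covariance(0.8, 0.8), 0)       # 1 - 3/2 + 1/2
  expect_equal(spherical_covariance(0.4, 0.8), 0.3125)  # 1 - 3/4 + 1/16
  expect_error(spherical_covariance(0.1, -1), "positive")
  ## non-increasing on [0, a], exactly zero beyond, continuous at a
  th <- seq(0, pi, length.out = 2001)
  v <- spherical_covariance(th, 0.7)
  expect_true(all(diff(v[th <= 0.7]) <= 1e-12))
  expect_true(all(v[th > 0.7] == 0))
  expect_lt(abs(spherical_covariance(0.7 - 1e-9, 0.7)), 1e-8)
})

test_that("covariance model matches hand evaluation and is permutation-consistent", {
  ## two identical directions: C_theta(0) = 1 everywhere
  p <- qspace_protocol(rbind(c(0, 0, 1), c(0, 0, 1)), 1000)
  cm <- gp_covariance(p, gp_hyperparams(a = 1, lambda = 2, sigma_im = 0.5))
  expect_equal(cm$Sigma, matrix(2, 2, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(cm$Sigma_y, matrix(c(2.25, 2, 2, 2.25), 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  ## all pairwise angles beyond the threshold: Sigma = lambda I
  p2 <- qspace_protocol(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), 1000)
  cm2 <- gp_covariance(p2, gp_hyperparams(a = 0.3, lambda = 1.7,
                                          sigma_im = 0.1))
  expect_equal(cm2$Sigma, diag(1.7, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  ## permutation of directions permutes rows/columns
  p3 <- tiny_protocol(9)
  hp <- gp_hyperparams(0.9, 1.2, 0.2)
  S <- gp_covariance(p3, hp)$Sigma
  perm <- c(4, 1, 9, 2, 7, 3, 8, 5, 6)
  p3p <- qspace_protocol(p3$directions[perm, ], 1000)
  Sp <- gp_covariance(p3p, hp)$Sigma
  expect_equal(Sp, S[perm, perm], tolerance = 1e-12)
  ## well-spread 64-direction model is positive definite
  p64 <- qspace_protocol(qspace_directions(64, seed = 1), 1000)
  cm64 <- gp_covariance(p64, gp_hyperparams(0.7, 1, 0.1))
  ev <- eigen(cm64$Sigma_y, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("marginal likelihood agrees with dense-inverse evaluation", {
  set.seed(11)
  for (nd in c(5, 12, 16)) {
    p <- tiny_protocol(nd, seed = nd)
    hp <- gp_hyperparams(a = 0.8 + 0.05 * nd / 16, lambda = 1.3,
                         sigma_im = 0.3)
    y <- rnorm(nd)
    v <- as.numeric(gp_neg_log_marglik(y, p, hp, gradient = FALSE))
    th <- angular_distance_matrix(p)
    Sy <- hp$lambda * spherical_covariance(th, hp$a) +
      diag(hp$sigma_im^2, nd)
    brute <- 0.5 * drop(t(y) %*% solve(Sy) %*% y) +
      0.5 * determinant(Sy)$modulus + nd / 2 * log(2 * pi)
    expect_equal(v, as.numeric(brute), tolerance = 1e-8)
  }
})

test_that("marginal likelihood closed forms: scalar and whitened cases", {
  p1 <- qspace_protocol(c(0, 0, 1))
  hp1 <- gp_hyperparams(a = 1, lambda = 2, sigma_im = 0.5)
  v1 <- as.numeric(gp_neg_log_marglik(3, p1, hp1, gradient = FALSE))
  expect_equal(v1, 0.5 * 9 / 2.25 + 0.5 * log(2.25) + 0.5 * log(2 * pi),
               tolerance = 1e-12)
  ## Sigma_y ~ I: lambda -> 0, sigma = 1
  set.seed(4)
  p <- tiny_protocol(8)
  y <- rnorm(8)
  v <- as.numeric(gp_neg_log_marglik(
    y, p, gp_hyperparams(a = 1, lambda = 1e-14, sigma_im = 1),
    gradient = FALSE))
  expect_equal(v, 0.5 * sum(y^2) + 4 * log(2 * pi), tolerance = 1e-6)
  expect_error(gp_neg_log_marglik(c(1, NA), tiny_protocol(2)), "finite")
})

test_that("analytic gradient matches central finite differences", {
  set.seed(21)
  p <- tiny_protocol(14, seed = 6)
  y <- rnorm(14)
  for (par in list(c(0.9, 1.3, 0.3), c(0.5, 0.4, 0.6))) {
    hp <- gp_hyperparams(a = par[1], lambda = par[2], sigma_im = par[3])
    gr <- attr(gp_neg_log_marglik(y, p, hp), "gradient")
    f <- function(q) as.numeric(gp_neg_log_marglik(
      y, p, gp_hyperparams(a = q[2], lambda = exp(q[1]),
                           sigma_im = exp(q[3])), gradient = FALSE))
    q0 <- c(log(par[2]), par[1], log(par[3]))
    eps <- 1e-6
    fd <- vapply(1:3, function(k) {
      qp <- q0; qm <- q0
      qp[k] <- qp[k] + eps; qm[k] <- qm[k] - eps
      (f(qp) - f(qm)) / (2 * eps)
    }, numeric(1))
    expect_equal(unname(gr), fd, tolerance = 1e-5)
  }
})

test_that("posterior mean satisfies its identities and limiting cases", {
  set.seed(5)
  p <- tiny_protocol(10)
  hp <- gp_hyperparams(0.9, 1.3, 0.3)
  cm <- gp_covariance(p, hp)
  y <- rnorm(10)
  ub <- posterior_mean(y, cm)
  ## algebraic identity with the (sigma^-2 I + Sigma^-1)^-1 sigma^-2 form
  alt <- solve(diag(10) / hp$sigma_im^2 + solve(cm$Sigma)) %*%
    (y / hp$sigma_im^2)
  expect_equal(ub, drop(alt), tolerance = 1e-8)
  ## sigma -> infinity: prior mean (0); sigma -> 0: data
  expect_lt(max(abs(posterior_mean(
    y, gp_covariance(p, gp_hyperparams(0.9, 1.3, 1e4))))), 1e-6)
  expect_equal(posterior_mean(
    y, gp_covariance(p, gp_hyperparams(0.9, 1.3, 1e-7))), y,
    tolerance = 1e-6)
  ## scalar shrinkage lambda / (lambda + sigma^2)
  p1 <- qspace_protocol(c(0, 0, 1))
  expect_equal(posterior_mean(3, gp_covariance(
    p1, gp_hyperparams(1, 2, 0.5))), 2 / 2.25 * 3, tolerance = 1e-12)
  ## matrix input applies column-wise
  Y <- cbind(y, 2 * y)
  UB <- posterior_mean(Y, cm)
  expect_equal(UB[, 2], 2 * ub, tolerance = 1e-10)
})

test_that("hyper-parameters are recovered from GP-simulated voxels", {
  set.seed(31)
  p <- qspace_protocol(qspace_directions(128, seed = 3), 1000)
  hpT <- gp_hyperparams(a = 0.9, lambda = 1, sigma_im = 0.2)
  L <- t(chol(gp_covariance(p, hpT)$Sigma_y))
  Y <- L %*% matrix(rnorm(128 * 600), 128)
  est <- estimate_hyperparameters(Y, p, n_voxels = 600, seed = 9)
  pv <- attr(est, "per_voxel")
  expect_lt(abs(median(pv$a, na.rm = TRUE) - 0.9) / 0.9, 0.15)
  expect_lt(abs(median(pv$lambda, na.rm = TRUE) - 1), 0.15)
  expect_lt(abs(median(pv$sigma_im, na.rm = TRUE) - 0.2) / 0.2, 0.20)
  ## means as reported are close too
  expect_lt(abs(est$a - 0.9) / 0.9, 0.15)
  expect_lt(abs(est$lambda - 1), 0.15)
  ## determinism under a fixed seed
  est2 <- estimate_hyperparameters(Y, p, n_voxels = 600, seed = 9)
  expect_identical(est[c("a", "lambda", "sigma_im")],
                   est2[c("a", "lambda", "sigma_im")])
})

test_that("profile and conjugate-gradient optimizers agree", {
  set.seed(13)
  p <- qspace_protocol(qspace_directions(64, seed = 2), 1000)
  hpT <- gp_hyperparams(a = 0.9, lambda = 1, sigma_im = 0.25)
  L <- t(chol(gp_covariance(p, hpT)$Sigma_y))
  Y <- L %*% matrix(rnorm(64 * 20), 64)
  ep <- estimate_hyperparameters(Y, p, n_voxels = 20, seed = 1,
                                 optimizer = "profile")
  ec <- estimate_hyperparameters(Y, p, n_voxels = 20, seed = 1,
                                 optimizer = "cg")
  expect_equal(ep$a, ec$a, tolerance = 0.15)
  expect_equal(ep$lambda, ec$lambda, tolerance = 0.2)
  expect_equal(ep$sigma_im, ec$sigma_im, tolerance = 0.2)
})

test_that("degenerate voxels are flagged and excluded from the average", {
  set.seed(2)
  p <- tiny_protocol(16)
  hpT <- gp_hyperparams(0.9, 1, 0.2)
  L <- t(chol(gp_covariance(p, hpT)$Sigma_y))
  Y <- L %*% matrix(rnorm(16 * 10), 16)
  Y[, 4] <- 3                      # constant across directions
  est <- estimate_hyperparameters(Y, p, n_voxels = 10, seed = 1)
  pv <- attr(est, "per_voxel")
  expect_true(pv$degenerate[4])
  expect_true(is.na(pv$lambda[4]))
  expect_equal(attr(est, "n_used"), 9L)
  ## diagnostics export: one record per sampled voxel
  f <- tempfile()
  write_hyperparam_diagnostics(est, f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), 10L)
  unlink(f)
})
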