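#' Gaussian-process hyper-parameters for the q-space signal model
#'
#' The single-shell diffusion signal at one voxel, viewed as a function of
#' the gradient direction, is modelled as a zero-mean Gaussian process with
#' covariance \deqn{C(q_i, q_j) = \lambda\, C_\theta(\theta_{ij}; a) +
#' \sigma_{im}^2 \delta_{ij},} where \eqn{C_\theta} is the compactly
#' supported spherical covariance function of the angle between the two
#' directions.  Four hyper-parameters govern the model:
#'
#' * `a` — angular threshold (radians): covariance decays to zero at
#'   angular distance `a`;
#' * `lambda` — signal variance (squared signal units);
#' * `sigma_im` — image-space noise standard deviation (signal units),
#'   uncorrelated across q-space;
#' * `sigma_k` — k-space noise standard deviation per complex component
#'   (signal units), used to weight the data-consistency term of the
#'   reconstruction.  Calibrated once from `sigma_im` via the parallel-
#'   imaging noise propagation map, see [calibrate_sigma_k()].
#'
#' @param a angular threshold in radians, `> 0`.
#' @param lambda signal variance, `> 0`.
#' @param sigma_im image-space noise standard deviation, `>= 0`.
#' @param sigma_k k-space noise standard deviation, `>= 0` (may be `NA`
#'   before calibration).
#' @return An object of class `gp_hyperparams`.
#' @export
gp_hyperparams <- function(a, lambda, sigma_im, sigma_k = NA_real_) {
  if (!is.finite(a) || a <= 0) stop("'a' must be a positive angle (radians)")
  if (!is.finite(lambda) || lambda <= 0) stop("'lambda' must be positive")
  if (!is.finite(sigma_im) || sigma_im < 0) stop("'sigma_im' must be >= 0")
  if (!is.na(sigma_k) && sigma_k < 0) stop("'sigma_k' must be >= 0")
  structure(list(a = a, lambda = lambda, sigma_im = sigma_im,
                 sigma_k = sigma_k),
            class = "gp_hyperparams")
}

#' @export
print.gp_hyperparams <- function(x, digits = 4, ...) {
  cat("q-space GP hyper-parameters:\n")
  cat("  a        =", format(x$a, digits = digits), "rad\n")
  cat("  lambda   =", format(x$lambda, digits = digits), "\n")
  cat("  sigma_im =", format(x$sigma_im, digits = digits), "\n")
  cat("  sigma_k  =", format(x$sigma_k, digits = digits), "\n")
  invisible(x)
}

#' Spherical covariance function
#'
#' The compactly supported spherical covariance of angular distance,
#' \deqn{C_\theta(\theta; a) = 1 - \frac{3\theta}{2a} +
#' \frac{\theta^3}{2a^3}} for \eqn{\theta \le a} and 0 beyond, continuous
#' and non-increasing on `[0, a]`.
#'
#' @param theta angular distance(s) in radians, `>= 0`.
#' @param a angular threshold in radians, `> 0`.
#' @return covariance value(s) in `[0, 1]`.
#' @export
spherical_covariance <- function(theta, a) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a single positive number")
  r <- theta / a
  v <- 1 - 1.5 * r + 0.5 * r^3
  v[theta > a] <- 0
  v
}

## d C_theta / d a, elementwise; zero beyond the support (continuous at a)
spherical_covariance_da <- function(theta, a) {
  v <- 1.5 * theta / a^2 - 1.5 * theta^3 / a^4
  v[theta > a] <- 0
  v
}

#' Build the GP covariance model for a protocol
#'
#' Constructs `Sigma[i,j] = lambda * C_theta(theta_ij; a)` from the pairwise
#' angular distances of the protocol, `Sigma_y = Sigma + sigma_im^2 I`, and
#' caches Cholesky factors of both (with an escalating diagonal-jitter
#' fallback for numerically semi-definite cases).
#'
#' @param protocol a [qspace_protocol()] (single shell).
#' @param hp a [gp_hyperparams()].
#' @return An object of class `gp_covariance`: list with `Sigma`,
#'   `Sigma_y`, `chol_y` (upper-triangular factor of `Sigma_y`),
#'   `chol_sigma` (factor of the possibly jittered `Sigma`), `jitter`
#'   actually applied to `Sigma`, `hp` and the protocol dimensions.
#' @export
gp_covariance <- function(protocol, hp) {
  stopifnot(inherits(protocol, "qspace_protocol"),
            inherits(hp, "gp_hyperparams"))
  if (length(unique(protocol$bvalues[protocol$bvalues > 0])) > 1L)
    stop("the GP covariance model is single-shell: all b-values must match")
  th <- angular_distance_matrix(protocol)
  Sigma <- hp$lambda * spherical_covariance(th, hp$a)
  nd <- nrow(Sigma)
  Sigma_y <- Sigma + diag(hp$sigma_im^2, nd)
  cy <- chol_with_jitter(Sigma_y)
  cs <- chol_with_jitter(Sigma)
  structure(list(Sigma = Sigma, Sigma_y = Sigma_y,
                 chol_y = cy$R, jitter_y = cy$jitter,
                 chol_sigma = cs$R, jitter = cs$jitter,
                 hp = hp, nd = nd),
            class = "gp_covariance")
}

#' @export
print.gp_covariance <- function(x, ...) {
  cat("GP q-space covariance model:", x$nd, "directions\n")
  print(x$hp)
  if (x$jitter > 0)
    cat("  (Sigma factorized with diagonal jitter", format(x$jitter), ")\n")
  invisible(x)
}

## Cholesky with escalating diagonal jitter.  Base jitter follows the mean
## diagonal magnitude; escalates x10 up to 1e-4 * tr/n before failing.
chol_with_jitter <- function(S, base = 1e-10, max_rel = 1e-4) {
  n <- nrow(S)
  scale <- sum(diag(S)) / n
  if (!is.finite(scale) || scale <= 0) scale <- 1
  jit <- 0
  repeat {
    R <- tryCatch(chol(S + diag(jit, n)), error = function(e) NULL)
    if (!is.null(R)) return(list(R = R, jitter = jit))
    jit <- if (jit == 0) base * scale else jit * 10
    if (jit > max_rel * scale)
      stop("covariance matrix is not positive definite even after jitter ",
           "escalation: degenerate hyper-parameters?")
  }
}

## solve S x = b given upper Cholesky factor R (S = R'R); backsolve()
## is real-only, so complex right-hand sides are split channel-wise
chol_solve <- function(R, b) {
  if (is.complex(b))
    return(backsolve(R, backsolve(R, Re(b), transpose = TRUE)) +
             1i * backsolve(R, backsolve(R, Im(b), transpose = TRUE)))
  backsolve(R, backsolve(R, b, transpose = TRUE))
}

#' Negative log marginal likelihood of the q-space GP
#'
#' Evaluates \deqn{\tfrac12 y^T \Sigma_y^{-1} y + \tfrac12 \log|\Sigma_y| +
#' \tfrac{N_d}{2}\log 2\pi} through the Cholesky factor of
#' `Sigma_y = lambda C_theta(a) + sigma_im^2 I`, together with its analytic
#' gradient in the positivity-preserving parameterization
#' `(log lambda, a, log sigma_im)`.
#'
#' @param y numeric vector of the voxel's signals across the protocol's
#'   directions (finite).
#' @param protocol a [qspace_protocol()].
#' @param hp a [gp_hyperparams()].
#' @param gradient logical; also return the gradient.
#' @return the scalar value, with attribute `"gradient"` (named vector over
#'   `log_lambda`, `a`, `log_sigma`) when `gradient = TRUE`.
#' @export
gp_neg_log_marglik <- function(y, protocol, hp, gradient = TRUE) {
  if (!all(is.finite(y))) stop("'y' must be finite")
  nd <- length(y)
  if (nd != nrow(protocol$directions))
    stop("length(y) must equal the number of protocol directions")
  th <- angular_distance_matrix(protocol)
  C0 <- spherical_covariance(th, hp$a)
  Sy <- hp$lambda * C0 + diag(hp$sigma_im^2, nd)
  R <- chol_with_jitter(Sy)$R
  alpha <- chol_solve(R, y)
  val <- 0.5 * sum(y * alpha) + sum(log(diag(R))) + 0.5 * nd * log(2 * pi)
  if (!gradient) return(val)
  Kinv <- chol2inv(R)
  ## d/dphi = 0.5 * ( tr(Kinv dS) - alpha' dS alpha )
  gfun <- function(dS) 0.5 * (sum(Kinv * dS) - drop(crossprod(alpha, dS %*% alpha)))
  dS_loglam <- hp$lambda * C0
  dS_a <- hp$lambda * spherical_covariance_da(th, hp$a)
  dS_logsig <- diag(2 * hp$sigma_im^2, nd)
  g <- c(log_lambda = gfun(dS_loglam), a = gfun(dS_a),
         log_sigma = gfun(dS_logsig))
  attr(val, "gradient") <- g
  val
}

#' Posterior-mean q-space signal at a voxel
#'
#' Under the zero-mean GP prior the posterior mean of the noise-free signal
#' given observations `y` is \deqn{\bar u = (\sigma_{im}^{-2} I +
#' \Sigma^{-1})^{-1} \sigma_{im}^{-2} y,} computed in the numerically
#' equivalent form \eqn{\Sigma (\Sigma + \sigma_{im}^2 I)^{-1} y}.  `y` may
#' be a matrix with one column per voxel, in which case the shrinkage is
#' applied column-wise.
#'
#' @param y Nd-vector, or Nd x Nvox matrix of q-space signals.
#' @param cov a [gp_covariance()].
#' @return object of the same shape as `y`.
#' @export
posterior_mean <- function(y, cov) {
  stopifnot(inherits(cov, "gp_covariance"))
  y <- as.matrix(y)
  if (nrow(y) != cov$nd) stop("y has ", nrow(y), " rows; expected ", cov$nd)
  out <- cov$Sigma %*% chol_solve(cov$chol_y, y)
  if (ncol(out) == 1L) drop(out) else out
}

## ---------------------------------------------------------------------
## Per-voxel hyper-parameter estimation
## ---------------------------------------------------------------------

## Profile estimation over a grid of angular thresholds.  For each a the
## spherical covariance C_theta(a) is eigendecomposed once; in that basis
## Sigma_y is diagonal, so the per-voxel marginal likelihood reduces to
## sums over eigenmodes and a damped Newton iteration in
## (log lambda, log sigma) runs vectorized across all voxels at once.
fit_gp_profile <- function(Y, th, a_grid, newton_iter = 14L) {
  nd <- nrow(Y); nv <- ncol(Y)
  na <- length(a_grid)
  best_f <- rep(Inf, nv)
  best <- list(a = rep(NA_real_, nv), u = rep(NA_real_, nv),
               w = rep(NA_real_, nv))
  fgrid <- matrix(Inf, na, nv)         # profile NLL per (a, voxel)
  vy <- colMeans(Y^2)                  # raw second moment about zero mean
  for (k in seq_len(na)) {
    C0 <- spherical_covariance(th, a_grid[k])
    e <- eigen(C0, symmetric = TRUE)
    d <- pmax(e$values, 0)
    Z2 <- crossprod(e$vectors, Y)^2    # nd x nv
    ## init: split the raw power between signal and noise
    u <- log(pmax(0.75 * vy, 1e-12))   # log lambda
    w <- 0.5 * log(pmax(0.25 * vy, 1e-12))  # log sigma
    for (it in seq_len(newton_iter)) {
      lam <- exp(u); s2 <- exp(2 * w)
      r <- outer(d, lam) + rep(s2, each = nd)    # nd x nv
      q <- (r - Z2) / r^2
      gl_u <- 0.5 * colSums(q * d) * lam         # d f / d u
      gl_w <- colSums(q) * s2                    # d f / d w
      ## Gauss-Newton style curvature (expected information, positive):
      ## E[d2f] for u: 0.5 * sum( (d lam / r)^2 ), etc.
      hl_uu <- 0.5 * colSums((outer(d, lam) / r)^2)
      hl_ww <- 2 * colSums((rep(s2, each = nd) / r)^2)
      hl_uw <- colSums(outer(d, lam) * rep(s2, each = nd) / r^2)
      det <- hl_uu * hl_ww - hl_uw^2
      det[det < 1e-12] <- 1e-12
      du <- -(hl_ww * gl_u - hl_uw * gl_w) / det
      dw <- -(hl_uu * gl_w - hl_uw * gl_u) / det
      step <- pmax(abs(du), abs(dw))
      sc <- ifelse(step > 2, 2 / step, 1)        # damp large steps
      u <- u + sc * du
      w <- w + sc * dw
      u[u < -40] <- -40; u[u > 40] <- 40
      w[w < -40] <- -40; w[w > 40] <- 40
    }
    lam <- exp(u); s2 <- exp(2 * w)
    r <- outer(d, lam) + rep(s2, each = nd)
    f <- 0.5 * colSums(Z2 / r + log(r)) + 0.5 * nd * log(2 * pi)
    fgrid[k, ] <- f
    upd <- which(f < best_f)
    if (length(upd)) {
      best_f[upd] <- f[upd]
      best$a[upd] <- a_grid[k]
      best$u[upd] <- u[upd]
      best$w[upd] <- w[upd]
    }
  }
  ## parabolic refinement of a around the per-voxel best grid point
  ki <- apply(fgrid, 2, which.min)
  a_ref <- best$a
  inner <- which(ki > 1L & ki < na)
  if (length(inner)) {
    i0 <- ki[inner]
    f0 <- fgrid[cbind(i0, inner)]
    fm <- fgrid[cbind(i0 - 1L, inner)]
    fp <- fgrid[cbind(i0 + 1L, inner)]
    denom <- fm - 2 * f0 + fp
    shift <- ifelse(denom > 1e-12, 0.5 * (fm - fp) / denom, 0)
    shift <- pmin(1, pmax(-1, shift))
    da <- a_grid[pmin(i0 + 1L, na)] - a_grid[i0]
    a_ref[inner] <- best$a[inner] + shift * da
  }
  data.frame(a = a_ref, lambda = exp(best$u), sigma_im = exp(best$w),
             nll = best_f, converged = is.finite(best_f))
}

## Nonlinear conjugate-gradient fit of one voxel with analytic gradients,
## restarted from several angular thresholds.
fit_gp_cg <- function(y, protocol, restarts = c(0.5, 1.0, 1.5),
                      maxit = 200L, reltol = 1e-10) {
  vy <- mean(y^2)
  if (vy <= 0) return(data.frame(a = NA_real_, lambda = NA_real_,
                                 sigma_im = NA_real_, nll = NA_real_,
                                 converged = FALSE))
  a_max <- if (protocol$symmetric) pi / 2 else pi
  obj <- function(p) {
    hp <- gp_hyperparams(a = min(max(p[2], 1e-3), a_max + 0.5),
                         lambda = exp(p[1]), sigma_im = exp(p[3]))
    as.numeric(gp_neg_log_marglik(y, protocol, hp, gradient = FALSE))
  }
  grd <- function(p) {
    hp <- gp_hyperparams(a = min(max(p[2], 1e-3), a_max + 0.5),
                         lambda = exp(p[1]), sigma_im = exp(p[3]))
    attr(gp_neg_log_marglik(y, protocol, hp, gradient = TRUE), "gradient")
  }
  best <- NULL
  for (a0 in restarts) {
    p0 <- c(log(0.75 * vy), min(a0, a_max), 0.5 * log(0.25 * vy))
    fit <- tryCatch(
      stats::optim(p0, obj, grd, method = "CG",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) return(data.frame(a = NA_real_, lambda = NA_real_,
                                       sigma_im = NA_real_, nll = NA_real_,
                                       converged = FALSE))
  data.frame(a = min(max(best$par[2], 1e-3), a_max + 0.5),
             lambda = exp(best$par[1]), sigma_im = exp(best$par[3]),
             nll = best$value, converged = best$convergence %in% c(0L, 1L))
}

#' Estimate GP hyper-parameters from image data
#'
#' Draws a random subset of mask voxels, fits the marginal likelihood of
#' the q-space GP independently at each voxel, and averages the per-voxel
#' estimates.  Degenerate voxels (zero signal variance) and failed fits are
#' dropped.  Two optimizers are provided: `"profile"` (default) profiles
#' the likelihood over a grid of angular thresholds, solving the
#' `(lambda, sigma_im)` subproblem by a vectorized Newton iteration in an
#' eigenbasis where it is exactly separable; `"cg"` is a per-voxel
#' nonlinear conjugate-gradient descent with analytic gradients in
#' `(log lambda, a, log sigma)` with three restarts.  Both maximize the
#' same likelihood; the profile path is deterministic and orders of
#' magnitude faster for many voxels.
#'
#' @param volumes Nd x Nvox matrix of real-valued q-space signals (one
#'   column per voxel: phase-corrected real part, or magnitude), or an
#'   array with last dimension Nd (then `mask` selects voxels).
#' @param protocol a [qspace_protocol()].
#' @param mask logical vector/array of voxels eligible for sampling (used
#'   when `volumes` is an array; ignored for a pre-extracted matrix).
#' @param n_voxels number of voxels to sample (default 1000; capped at the
#'   mask size).
#' @param seed integer seed controlling the voxel draw.
#' @param optimizer `"profile"` or `"cg"`.
#' @param a_grid grid of angular thresholds for the profile optimizer;
#'   defaults to 40 points spanning the metric's range.
#' @param average `"natural"` (arithmetic mean of the per-voxel estimates)
#'   or `"log"` (geometric mean for lambda and sigma).
#' @return a [gp_hyperparams()] (with `sigma_k = NA`), with attributes
#'   `"per_voxel"` (data frame of per-voxel estimates, including the sampled
#'   voxel indices) and `"n_used"`.
#' @export
estimate_hyperparameters <- function(volumes, protocol, mask = NULL,
                                     n_voxels = 1000L, seed = 1L,
                                     optimizer = c("profile", "cg"),
                                     a_grid = NULL,
                                     average = c("natural", "log")) {
  optimizer <- match.arg(optimizer)
  average <- match.arg(average)
  nd <- nrow(protocol$directions)
  if (is.matrix(volumes) && nrow(volumes) == nd && is.null(mask)) {
    Y <- volumes
    vox_index <- seq_len(ncol(Y))
  } else {
    a <- as.array(volumes)
    dd <- dim(a)
    if (dd[length(dd)] != nd)
      stop("last dimension of 'volumes' must index the ", nd, " directions")
    nv <- prod(dd[-length(dd)])
    Y <- t(matrix(a, nv, nd))
    if (is.null(mask)) mask <- rep(TRUE, nv)
    vox_index <- which(as.logical(mask))
    if (!length(vox_index)) stop("empty mask")
    Y <- Y[, vox_index, drop = FALSE]
  }
  if (any(!is.finite(Y))) stop("non-finite signal values")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n_take <- min(n_voxels, ncol(Y))
  pick <- sort(sample.int(ncol(Y), n_take))
  Y <- Y[, pick, drop = FALSE]
  vox_index <- vox_index[pick]
  ## degenerate voxels: no variability across directions
  degen <- apply(Y, 2, function(col) stats::var(col) <= 1e-12 * mean(col^2) ||
                                     all(col == col[1]))
  th <- angular_distance_matrix(protocol)
  a_max <- if (protocol$symmetric) pi / 2 else pi
  if (is.null(a_grid))
    a_grid <- seq(max(0.12, min(th[th > 0]) * 0.8), a_max * 1.15,
                  length.out = 40L)
  fits <- if (optimizer == "profile") {
    f <- fit_gp_profile(Y, th, a_grid)
    f[degen, ] <- NA
    f
  } else {
    do.call(rbind, lapply(seq_len(ncol(Y)), function(j) {
      if (degen[j]) data.frame(a = NA_real_, lambda = NA_real_,
                               sigma_im = NA_real_, nll = NA_real_,
                               converged = FALSE)
      else fit_gp_cg(Y[, j], protocol)
    }))
  }
  fits$voxel <- vox_index
  fits$degenerate <- degen
  ok <- !degen & !is.na(fits$a) & isTRUE_vec(fits$converged)
  n_bad <- sum(!ok & !degen)
  if (n_bad > 0)
    warning(n_bad, " voxel fit(s) did not converge and were dropped")
  if (!any(ok)) stop("all per-voxel hyper-parameter fits failed")
  hp <- if (average == "natural") {
    gp_hyperparams(a = mean(fits$a[ok]), lambda = mean(fits$lambda[ok]),
                   sigma_im = mean(fits$sigma_im[ok]))
  } else {
    gp_hyperparams(a = mean(fits$a[ok]),
                   lambda = exp(mean(log(fits$lambda[ok]))),
                   sigma_im = exp(mean(log(fits$sigma_im[ok]))))
  }
  attr(hp, "per_voxel") <- fits
  attr(hp, "n_used") <- sum(ok)
  hp
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Write per-voxel hyper-parameter diagnostics
#'
#' Exports the per-voxel estimates recorded by
#' [estimate_hyperparameters()] as a tab-separated text table, one record
#' per sampled voxel.
#'
#' @param hp a [gp_hyperparams()] returned by [estimate_hyperparameters()].
#' @param path output file path.
#' @export
write_hyperparam_diagnostics <- function(hp, path) {
  pv <- attr(hp, "per_voxel")
  if (is.null(pv)) stop("no per-voxel diagnostics recorded on this object")
  utils::write.table(pv, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
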