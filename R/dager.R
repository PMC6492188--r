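#' Reconstruction configuration
#'
#' Collects the tunable parameters of the iterative reconstruction.
#' Defaults follow the method's standard operating point: at most 20
#' outer iterations, stopping early when the normalized solution update
#' `||u_n - u_{n-1}|| / ||u_{n-1}||` falls below 0.002; inner conjugate
#' gradient at relative-residual tolerance 1e-6 with a 250-iteration cap,
#' warm-started across outer iterations; hyper-parameters re-estimated
#' each outer iteration from 1000 randomly drawn brain voxels.
#'
#' @param max_outer_iterations outer iteration cap (>= 1).
#' @param update_threshold stopping threshold on the normalized solution
#'   update (> 0).
#' @param inner_tol,inner_maxit conjugate-gradient tolerance and cap.
#' @param tikhonov_weight Tikhonov weight for the SENSE baseline and
#'   initialization; `NULL` selects it by L-curve.
#' @param lcurve_weights candidate weights for the L-curve sweep.
#' @param low_reg_factor multiplier (< 1) giving the deliberately low
#'   weight used for the initialization / phase-estimation reconstruction.
#' @param tv_weight total-variation weight of the navigator-free phase
#'   estimate.
#' @param phase_model navigator-free phase model: `"linear"` fits the
#'   rigid-motion constant + ramp model (robust to residual aliasing in
#'   the initialization; matches the simulator's zeroth/first-order
#'   motion phase), `"full"` keeps the voxelwise denoised phase.
#' @param phase_mode one of `"central_kspace"`, `"navigator"`,
#'   `"navigator_free"`, `"oracle"` (simulated true phase; testing only),
#'   `"none"`.
#' @param phase_window in-plane window of the central-k-space phase
#'   estimate.
#' @param n_hyper_voxels voxels sampled per hyper-parameter estimation.
#' @param hyper_optimizer `"profile"` or `"cg"` (see
#'   [estimate_hyperparameters()]).
#' @param signal_channel hyper-parameter fits use the phase-corrected
#'   `"real"` part (default) or the `"magnitude"` of the current images.
#' @param freeze_sigma_im if `TRUE` (default), the image-noise
#'   hyper-parameter is estimated once, from the initialization, and held
#'   fixed while `a` and `lambda` are re-estimated every outer iteration.
#'   On signals that the GP can interpolate exactly, the nugget of a
#'   regularized iterate is not identifiable (it collapses toward zero,
#'   which removes the posterior-mean smoothing and destabilizes the
#'   alternation); the initialization is the one iterate whose noise
#'   level is well defined.  Set to `FALSE` to re-estimate all three
#'   hyper-parameters each iteration.
#' @param track_nrmse record per-iteration NRMSE when ground truth is
#'   available.
#' @param seed master seed; per-iteration voxel draws use seeds derived
#'   from it.
#' @return object of class `recon_config`.
#' @export
recon_config <- function(max_outer_iterations = 20L,
                         update_threshold = 0.002,
                         inner_tol = 1e-6, inner_maxit = 250L,
                         tikhonov_weight = NULL,
                         lcurve_weights = 10^seq(-5, -0.5, length.out = 13),
                         low_reg_factor = 0.1,
                         tv_weight = 0.02,
                         phase_model = c("linear", "full"),
                         phase_mode = c("central_kspace", "navigator",
                                        "navigator_free", "oracle", "none"),
                         phase_window = c(32L, 32L),
                         n_hyper_voxels = 1000L,
                         hyper_optimizer = c("profile", "cg"),
                         signal_channel = c("real", "magnitude"),
                         freeze_sigma_im = TRUE,
                         track_nrmse = TRUE,
                         seed = 1L) {
  phase_mode <- match.arg(phase_mode)
  phase_model <- match.arg(phase_model)
  hyper_optimizer <- match.arg(hyper_optimizer)
  signal_channel <- match.arg(signal_channel)
  if (max_outer_iterations < 1L) stop("need at least one outer iteration")
  if (update_threshold <= 0 || inner_tol <= 0) stop("thresholds must be > 0")
  structure(list(max_outer_iterations = as.integer(max_outer_iterations),
                 update_threshold = update_threshold,
                 inner_tol = inner_tol,
                 inner_maxit = as.integer(inner_maxit),
                 tikhonov_weight = tikhonov_weight,
                 lcurve_weights = lcurve_weights,
                 low_reg_factor = low_reg_factor,
                 tv_weight = tv_weight,
                 phase_model = phase_model,
                 phase_mode = phase_mode,
                 phase_window = phase_window,
                 n_hyper_voxels = as.integer(n_hyper_voxels),
                 hyper_optimizer = hyper_optimizer,
                 signal_channel = signal_channel,
                 freeze_sigma_im = isTRUE(freeze_sigma_im),
                 track_nrmse = isTRUE(track_nrmse),
                 seed = as.integer(seed)),
            class = "recon_config")
}

#' @export
print.recon_config <- function(x, ...) {
  cat("reconstruction configuration:\n")
  cat("  outer iterations <=", x$max_outer_iterations,
      "; update threshold", x$update_threshold, "\n")
  cat("  inner CG: tol", x$inner_tol, ", cap", x$inner_maxit, "\n")
  cat("  phase mode:", x$phase_mode, "; hyper voxels:", x$n_hyper_voxels,
      "(", x$hyper_optimizer, "optimizer )\n")
  invisible(x)
}

## phase-map list -> nvox x nd complex matrix (or NULL)
phase_matrix <- function(phase_maps, nvox, nd) {
  if (is.null(phase_maps)) return(NULL)
  Pm <- matrix(0i, nvox, nd)
  for (j in seq_len(nd)) Pm[, j] <- as.vector(phase_maps[[j]])
  Pm
}

#' Joint MAP reconstruction of all diffusion volumes
#'
#' Solves the quadratic MAP problem that couples all diffusion volumes
#' through the q-space Gaussian-process prior:
#' \deqn{\hat u = \arg\min_u \frac{1}{\sigma_k^2}\|A u - d\|_2^2 +
#' (P^H u - \bar u)^H (\Sigma^{-1} \otimes I)(P^H u - \bar u)}
#' by preconditioned conjugate gradient on the normal equations, with
#' matrix-free encoding operators, the prior applied across the volume
#' dimension voxel-wise through the cached Cholesky factor of `Sigma`,
#' and the motion-phase operator `P` realigning the volumes' image phase.
#'
#' @param d k-space data: a [kq_data()] or dataset.
#' @param sens a [coil_set()].
#' @param plan a [kq_plan()] (or `NULL` when `d` carries its patterns).
#' @param phase_maps list of per-volume unit-magnitude phase maps, or
#'   `NULL` for unit phase.
#' @param cov a [gp_covariance()] built for the dataset's protocol.
#' @param u_bar prior-mean volumes (`nvox x Nd` matrix or
#'   `nx x ny x nz x Nd` array), typically the posterior-mean prediction
#'   of the previous iterate; 0 for a zero prior mean.
#' @param sigma_k calibrated k-space noise standard deviation (> 0).
#' @param tol,maxit inner CG tolerance / cap.
#' @param x0 optional warm start (phase-corrected stack, `nvox x Nd`).
#' @return list with `u` (complex array `nx x ny x nz x Nd`), `x` (the
#'   phase-corrected stack), and `info` (iterations, relative residual,
#'   monitored quadratic objective trace, convergence flag).
#' @export
dager_solve <- function(d, sens, plan = NULL, phase_maps = NULL, cov,
                        u_bar = 0, sigma_k, tol = 1e-6, maxit = 250L,
                        x0 = NULL) {
  stopifnot(inherits(cov, "gp_covariance"), sigma_k > 0)
  kd <- as_kq_data(d)
  if (!is.null(plan) && inherits(plan, "kq_plan")) {
    kd$patterns <- plan$patterns
    kd$vol_pattern <- plan$pattern_id + 1L
  }
  ws <- whiten_coils(sens)
  kd <- whiten_kq_data(kd, ws$L_inv)
  ctx <- recon_context(ws$sens, kd$patterns, kd$vol_pattern)
  nd <- ctx$nd
  if (nd != cov$nd) stop("covariance model is for ", cov$nd,
                         " volumes, data has ", nd)
  Pm <- phase_matrix(phase_maps, ctx$nvox, nd)
  SigmaInv <- chol2inv(cov$chol_sigma)
  Ubar <- if (is.matrix(u_bar)) u_bar else matrix(as.vector(u_bar),
                                                  ctx$nvox, nd)
  isk2 <- 1 / sigma_k^2
  rhs <- ctx_adjoint_all(ctx, kd$volumes, ws$sens)
  if (!is.null(Pm)) rhs <- Conj(Pm) * rhs
  rhs <- isk2 * rhs + Ubar %*% SigmaInv
  apply_G <- function(X) isk2 * ctx_normal_apply(ctx, X, Pm) +
    X %*% SigmaInv
  ## volume-space preconditioner: per voxel, invert exactly the separable
  ## surrogate  mean-data-diagonal * I + Sigma^{-1}  in the eigenbasis of
  ## Sigma (the prior precision is the stiff part of the system)
  es <- eigen(cov$Sigma + diag(cov$jitter, nd), symmetric = TRUE)
  dinv <- 1 / pmax(es$values, 1e-12 * max(es$values))
  cbar <- isk2 * rowMeans(ctx$normal_diag)
  denom <- outer(cbar, dinv, "+")
  Q <- es$vectors
  pre_fun <- function(R) ((R %*% Q) / denom) %*% t(Q)
  res <- pcg_solve(apply_G, rhs, x0 = x0, tol = tol, maxit = maxit,
                   precond = pre_fun, track_objective = TRUE)
  if (!res$converged)
    warning("DAGER conjugate gradient stopped at relative residual ",
            format(res$relres, digits = 3), " after ", res$iterations,
            " iterations (tolerance ", format(tol), ")")
  u <- if (is.null(Pm)) res$x else Pm * res$x
  list(u = array(u, c(ctx$nx, ctx$ny, ctx$nz, nd)), x = res$x,
       info = res[c("iterations", "relres", "converged", "objective")])
}

#' Otsu threshold mask of a magnitude image
#'
#' @param img real-valued array (e.g. mean magnitude across volumes).
#' @param nbins histogram bins.
#' @return logical array of the same shape.
#' @export
otsu_mask <- function(img, nbins = 128L) {
  v <- as.vector(img)
  br <- seq(min(v), max(v), length.out = nbins + 1L)
  h <- hist(v, breaks = br, plot = FALSE)$counts
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  thr <- br[which.max(sb) + 1L]
  array(img > thr, dim(img))
}

#' Alternating hyper-parameter estimation and reconstruction
#'
#' The full iterative pipeline: (1) initialize with a Tikhonov SENSE /
#' SMS-SENSE reconstruction (at a deliberately low weight for the phase-
#' estimation modes that need minimal aliasing); (2) estimate per-volume
#' motion phase maps; (3) calibrate the k-space noise level `sigma_k`
#' once, from the per-voxel image-noise estimates of the initialization
#' divided by the parallel-imaging noise-propagation map, and keep it
#' fixed; (4) alternate between estimating GP hyper-parameters from the
#' current images, building the q-space covariance, predicting the
#' posterior-mean volumes, and solving the joint MAP problem
#' ([dager_solve()]), warm-started from the previous iterate; (5) stop at
#' the iteration cap or when the normalized solution update drops below
#' the threshold.
#'
#' @param dataset a [simulate_acquisition()] dataset, or a [kq_data()].
#' @param sens a [coil_set()].
#' @param plan a [kq_plan()]; defaults to the dataset's plan.
#' @param config a [recon_config()].
#' @param protocol required when `dataset` is a bare [kq_data()].
#' @param mask brain mask; defaults to the dataset's phantom support (or
#'   an Otsu threshold of the initialization magnitude).
#' @return object of class `dager_fit` — list with `volumes` (complex
#'   array `nx x ny x nz x Nd`), `init` (initialization images),
#'   `phase_maps`, `hyperparams` (final [gp_hyperparams()], including the
#'   frozen `sigma_k`), `diagnostics` (one row per outer iteration:
#'   hyper-parameters, normalized update, inner CG iterations, NRMSE when
#'   ground truth is known), `sense_weight`, `config`, `converged`.
#' @export
dager_pipeline <- function(dataset, sens, plan = NULL,
                           config = recon_config(), protocol = NULL,
                           mask = NULL) {
  if (inherits(dataset, "kq_dataset")) {
    kd <- dataset$kdata
    if (is.null(protocol)) protocol <- dataset$protocol
    if (is.null(plan)) plan <- dataset$plan
    if (is.null(mask)) mask <- dataset$mask
    truth <- dataset$truth
  } else {
    kd <- as_kq_data(dataset)
    truth <- NULL
  }
  if (is.null(protocol)) stop("a q-space protocol is required")
  if (!is.null(plan) && inherits(plan, "kq_plan")) {
    kd$patterns <- plan$patterns
    kd$vol_pattern <- plan$pattern_id + 1L
  }
  nd <- length(kd$volumes)
  dm <- dim(sens$maps)
  nvox <- prod(dm[1:3])
  ## --- baseline weight ---------------------------------------------------
  w <- config$tikhonov_weight
  if (is.null(w))
    w <- lcurve_select(kd, sens, candidate_weights = config$lcurve_weights)$weight
  low_w <- w * config$low_reg_factor
  ## --- initialization & phase estimation ---------------------------------
  phase_maps <- NULL
  if (config$phase_mode == "navigator_free") {
    nf <- estimate_phase_navfree(kd, sens, low_reg_weight = low_w,
                                 tv_weight = config$tv_weight, mask = mask,
                                 phase_model = config$phase_model)
    init <- nf$init
    phase_maps <- nf$phase
  } else {
    init <- sense_reconstruct(kd, sens, tikhonov_weight = low_w)
    if (length(dim(init)) == 3L) dim(init) <- c(dim(init), 1L)
    phase_maps <- switch(config$phase_mode,
      central_kspace = {
        if (!is.null(dataset$phase_ref))
          lapply(dataset$phase_ref, phase_from_central_block,
                 grid = dm[1:3])
        else lapply(seq_len(nd), function(j)
          estimate_phase_central_kspace(init[, , , j, drop = TRUE],
                                        window = config$phase_window))
      },
      navigator = {
        if (is.null(dataset$navigators))
          stop("phase_mode = \"navigator\" needs dataset$navigators")
        lapply(dataset$navigators, estimate_phase_navigator, sens = sens)
      },
      oracle = {
        if (is.null(dataset$phase_maps))
          stop("phase_mode = \"oracle\" needs simulated true phase maps")
        dataset$phase_maps
      },
      none = NULL)
  }
  if (is.null(mask)) mask <- otsu_mask(apply(Mod(init), 1:3, mean))
  Pm <- phase_matrix(phase_maps, nvox, nd)
  X <- matrix(init, nvox, nd)
  if (!is.null(Pm)) X <- Conj(Pm) * X
  signal_of <- function(X) {
    if (config$signal_channel == "real") Re(X) else Mod(X)
  }
  ## --- sigma_k calibration (iteration 1, then frozen) ---------------------
  ## per-voxel noise map from the (complex) initialization via robust
  ## q-space neighbor differences; divided by the noise-propagation map
  sim_map <- estimate_sigma_im_map(matrix(init, nvox, nd), protocol)
  hp0 <- estimate_hyperparameters(
    array(signal_of(X), c(dm[1:3], nd)), protocol, mask = mask,
    n_voxels = config$n_hyper_voxels, seed = config$seed,
    optimizer = config$hyper_optimizer)
  ws <- whiten_coils(sens)
  gctx <- recon_context(ws$sens, kd$patterns[1L], 1L)
  g_map <- gfactor_from_context(gctx, weight = low_w)
  sigma_k <- calibrate_sigma_k(sim_map, g_map, mask,
                               n_voxels = config$n_hyper_voxels,
                               seed = config$seed)
  ## --- outer loop ---------------------------------------------------------
  diag_rows <- vector("list", config$max_outer_iterations)
  hp <- hp0
  converged <- FALSE
  x_warm <- X
  sol <- NULL
  for (it in seq_len(config$max_outer_iterations)) {
    if (it > 1L) {
      ## after the first pass the angular threshold moves slowly: refine
      ## the profile grid around the previous estimate
      agrid <- if (config$hyper_optimizer == "profile") {
        amax <- if (protocol$symmetric) pi / 2 else pi
        seq(max(0.12, hp$a - 0.45), min(amax * 1.15, hp$a + 0.45),
            length.out = 16L)
      } else NULL
      hp <- estimate_hyperparameters(
        array(signal_of(X), c(dm[1:3], nd)), protocol, mask = mask,
        n_voxels = config$n_hyper_voxels, seed = config$seed + it,
        optimizer = config$hyper_optimizer, a_grid = agrid)
      if (config$freeze_sigma_im)
        hp <- gp_hyperparams(hp$a, hp$lambda, hp0$sigma_im)
    }
    cov <- gp_covariance(protocol, hp)
    Ybar <- posterior_mean(t(signal_of(X)), cov)        # nd x nvox
    sol <- dager_solve(kd, sens, phase_maps = phase_maps, cov = cov,
                       u_bar = t(Ybar), sigma_k = sigma_k,
                       tol = config$inner_tol, maxit = config$inner_maxit,
                       x0 = x_warm)
    upd <- sqrt(cplx_dot(sol$x - X, sol$x - X)) / sqrt(cplx_dot(X, X))
    if (!is.finite(upd)) {
      warning("non-finite solution update at outer iteration ", it,
              "; aborting with diagnostics intact")
      break
    }
    nr <- NA_real_
    if (config$track_nrmse && !is.null(truth)) {
      rec <- array(Mod(sol$u), c(dm[1:3], nd))
      nr <- mean(nrmse(rec, truth, mask))
    }
    diag_rows[[it]] <- data.frame(
      iteration = it, a = hp$a, lambda = hp$lambda, sigma_im = hp$sigma_im,
      sigma_k = sigma_k, update = upd, inner_iterations = sol$info$iterations,
      nrmse = nr)
    X <- sol$x
    x_warm <- X
    if (upd < config$update_threshold) { converged <- TRUE; break }
  }
  diagnostics <- do.call(rbind, diag_rows[!vapply(diag_rows, is.null,
                                                  logical(1))])
  volumes <- if (is.null(sol)) array(init, c(dm[1:3], nd)) else sol$u
  structure(list(volumes = volumes, init = init, phase_maps = phase_maps,
                 hyperparams = gp_hyperparams(hp$a, hp$lambda, hp$sigma_im,
                                              sigma_k),
                 diagnostics = diagnostics, sense_weight = w,
                 low_reg_weight = low_w, mask = mask, config = config,
                 protocol = protocol, converged = converged),
            class = "dager_fit")
}

#' @export
print.dager_fit <- function(x, ...) {
  d <- dim(x$volumes)
  cat("DAGER reconstruction:", d[4], "volumes on a",
      paste(d[1:3], collapse = " x "), "grid\n")
  n <- nrow(x$diagnostics)
  cat("  ", n, "outer iteration(s);",
      if (x$converged) "converged (update < threshold)" else "iteration cap",
      "\n")
  if (n > 0)
    cat("   final normalized update:",
        format(x$diagnostics$update[n], digits = 3), "\n")
  print(x$hyperparams)
  invisible(x)
}

#' @export
summary.dager_fit <- function(object, ...) {
  cat("DAGER fit summary\n-----------------\n")
  print(object)
  cat("\nper-iteration diagnostics:\n")
  print(object$diagnostics, row.names = FALSE, digits = 4)
  invisible(object$diagnostics)
}

#' @export
coef.dager_fit <- function(object, ...) {
  hp <- object$hyperparams
  c(a = hp$a, lambda = hp$lambda, sigma_im = hp$sigma_im,
    sigma_k = hp$sigma_k)
}

#' @export
fitted.dager_fit <- function(object, ...) Mod(object$volumes)

#' @export
plot.dager_fit <- function(x, ...) {
  d <- x$diagnostics
  op <- graphics::par(mfrow = c(1, if (any(is.finite(d$nrmse))) 2 else 1))
  on.exit(graphics::par(op))
  graphics::plot(d$iteration, d$update, type = "b", log = "y",
                 xlab = "outer iteration", ylab = "normalized update",
                 main = "solution update", ...)
  graphics::abline(h = x$config$update_threshold, lty = 2)
  if (any(is.finite(d$nrmse)))
    graphics::plot(d$iteration, d$nrmse, type = "b",
                   xlab = "outer iteration", ylab = "mean NRMSE",
                   main = "error vs ground truth", ...)
  invisible(x)
}
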