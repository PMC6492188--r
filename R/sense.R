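#' Multi-volume k-space data container
#'
#' Bundles per-volume, per-coil k-space samples with the sampling pattern
#' of each volume.  `volumes[[j]]` is a complex `nx x n_acq_j x Nc` array
#' over the acquired phase-encode lines of pattern
#' `patterns[[vol_pattern[j]]]`.
#'
#' @param volumes list of complex k-space arrays.
#' @param patterns list of [sampling_pattern()]s.
#' @param vol_pattern integer vector mapping each volume to its pattern.
#' @return object of class `kq_data`.
#' @export
kq_data <- function(volumes, patterns, vol_pattern) {
  vol_pattern <- as.integer(vol_pattern)
  if (length(volumes) != length(vol_pattern))
    stop("one pattern id per volume is required")
  if (any(vol_pattern < 1L) || any(vol_pattern > length(patterns)))
    stop("'vol_pattern' indices out of range")
  for (j in seq_along(volumes)) {
    p <- patterns[[vol_pattern[j]]]
    if (dim(volumes[[j]])[2] != length(p$idx))
      stop("volume ", j, ": sample count does not match its pattern")
  }
  structure(list(volumes = volumes, patterns = patterns,
                 vol_pattern = vol_pattern),
            class = "kq_data")
}

#' @export
print.kq_data <- function(x, ...) {
  d <- dim(x$volumes[[1]])
  cat("k-q data:", length(x$volumes), "volumes,", d[3], "coils,",
      length(x$patterns), "sampling pattern(s)\n")
  invisible(x)
}

## normalize the (d, pattern/plan) argument pair into a kq_data
as_kq_data <- function(d, pattern = NULL) {
  if (inherits(d, "kq_data")) return(d)
  if (inherits(d, "kspace_volume")) {
    p <- if (is.null(pattern)) d$pattern else pattern
    return(kq_data(list(d$data), list(p), 1L))
  }
  if (inherits(d, "kq_dataset")) return(d$kdata)
  if (is.array(d) && !is.null(pattern))
    return(kq_data(list(d), list(pattern), 1L))
  stop("cannot interpret 'd' as k-space data")
}

## apply coil noise whitening to a kq_data (L_inv from whiten_coils)
whiten_kq_data <- function(kd, L_inv) {
  if (is.null(L_inv)) return(kd)
  kd$volumes <- lapply(kd$volumes, function(v) {
    d <- dim(v)
    m <- matrix(v, d[1] * d[2], d[3]) %*% t(L_inv)
    array(m, d)
  })
  kd
}

#' SENSE / SMS-SENSE reconstruction
#'
#' Solves the Tikhonov-regularized parallel-imaging problem
#' \deqn{\hat u = \arg\min_u \|A u - d\|_2^2 + w \|u\|_2^2} independently
#' for each diffusion volume.  SMS data are handled through the
#' extended-FOV (stacked-slice) encoding, i.e. SMS-SENSE as a 3D k-space
#' problem.  On shifted-lattice patterns the exact minimizer is computed
#' by direct unfolding of each aliasing set; otherwise the normal
#' equations are solved by preconditioned conjugate gradient.
#'
#' @param d a `kspace_volume`, [kq_data()], or dataset from
#'   [simulate_acquisition()].
#' @param sens a [coil_set()].
#' @param pattern a [sampling_pattern()] when `d` is a bare k-space array
#'   or single volume; ignored otherwise.
#' @param tikhonov_weight regularization weight `w >= 0`.
#' @param method `"auto"` (direct unfolding when exact, else CG),
#'   `"direct"`, or `"cg"`.
#' @param tol,maxit CG stopping parameters (relative residual; iteration
#'   cap).  Non-convergence within the cap gives a warning and returns the
#'   best iterate.
#' @return complex image array `nx x ny x nz` (single volume) or
#'   `nx x ny x nz x Nd`, with attribute `"cg_info"` for the CG path.
#' @export
sense_reconstruct <- function(d, sens, pattern = NULL, tikhonov_weight = 0,
                              method = c("auto", "direct", "cg"),
                              tol = 1e-6, maxit = 250L) {
  method <- match.arg(method)
  kd <- as_kq_data(d, pattern)
  ws <- whiten_coils(sens)
  kd <- whiten_kq_data(kd, ws$L_inv)
  ctx <- recon_context(ws$sens, kd$patterns, kd$vol_pattern)
  rhs <- ctx_adjoint_all(ctx, kd$volumes, ws$sens)
  out <- sense_solve(ctx, rhs, tikhonov_weight, method, tol, maxit)
  x <- out$x
  info <- out$info
  single <- length(kd$volumes) == 1L
  res <- if (single) array(x[, 1L], c(ctx$nx, ctx$ny, ctx$nz))
         else array(x, c(ctx$nx, ctx$ny, ctx$nz, ctx$nd))
  attr(res, "cg_info") <- info
  res
}

## core solve given context + rhs = A^H d (nvox x nd)
sense_solve <- function(ctx, rhs, weight, method = "auto", tol = 1e-6,
                        maxit = 250L, x0 = NULL) {
  if (method == "auto")
    method <- if (ctx$type == "lattice") "direct" else "cg"
  if (method == "direct") {
    if (ctx$type != "lattice")
      stop("direct unfolding requires lattice patterns; use method = \"cg\"")
    Rt <- ctx$R_total
    Tm <- ctx$Wc * rhs
    X <- Tm
    for (g in seq_len(ctx$n_sets)) {
      vox <- ctx$set_members[, g]
      M <- matrix(ctx$C[, , g], Rt, Rt) / Rt + diag(weight, Rt)
      X[vox, ] <- solve(M, Tm[vox, , drop = FALSE])
    }
    return(list(x = ctx$W * X, info = NULL))
  }
  pre <- ctx$normal_diag + weight
  res <- pcg_solve(function(v) ctx_normal_apply(ctx, v) + weight * v,
                   rhs, x0 = x0, tol = tol, maxit = maxit, precond = pre)
  if (!res$converged)
    warning("SENSE conjugate gradient did not reach tolerance ",
            format(tol), " within ", maxit, " iterations (relative ",
            "residual ", format(res$relres, digits = 3), ")")
  list(x = res$x, info = res[c("iterations", "relres", "converged")])
}

#' L-curve choice of the Tikhonov weight
#'
#' Reconstructs the data at each candidate weight, records the L-curve
#' point (log residual norm, log solution norm), and returns the weight
#' at the corner of maximum (Menger) curvature.  If the curve is
#' degenerate (collinear within tolerance), the smallest candidate is
#' returned with a warning.  A subset of volumes can be used to keep the
#' sweep cheap on large datasets.
#'
#' @inheritParams sense_reconstruct
#' @param candidate_weights numeric vector of weights; at least 3 spanning
#'   two orders of magnitude are recommended (a single candidate is
#'   returned as is).
#' @param volumes optional indices of the volumes used for the sweep.
#' @return list with `weight`, `index`, and `curve` (data frame of
#'   weight, residual norm, solution norm, curvature).
#' @export
lcurve_select <- function(d, sens, pattern = NULL, candidate_weights,
                          volumes = NULL, tol = 1e-6, maxit = 250L) {
  stopifnot(length(candidate_weights) >= 1)
  candidate_weights <- sort(candidate_weights)
  if (length(candidate_weights) == 1L)
    return(list(weight = candidate_weights, index = 1L,
                curve = data.frame(weight = candidate_weights,
                                   resid_norm = NA_real_,
                                   soln_norm = NA_real_,
                                   curvature = NA_real_)))
  if (length(candidate_weights) < 3L)
    stop("supply one candidate, or at least 3 spanning the range")
  if (max(candidate_weights) / min(candidate_weights) < 100)
    warning("candidate weights span less than 2 orders of magnitude")
  kd <- as_kq_data(d, pattern)
  ws <- whiten_coils(sens)
  kd <- whiten_kq_data(kd, ws$L_inv)
  if (is.null(volumes)) volumes <- seq_len(min(6L, length(kd$volumes)))
  kd$volumes <- kd$volumes[volumes]
  kd$vol_pattern <- kd$vol_pattern[volumes]
  ctx <- recon_context(ws$sens, kd$patterns, kd$vol_pattern)
  rhs <- ctx_adjoint_all(ctx, kd$volumes, ws$sens)
  dnorm2 <- sum(vapply(kd$volumes, function(v) sum(Mod(v)^2), numeric(1)))
  rn <- sn <- numeric(length(candidate_weights))
  for (k in seq_along(candidate_weights)) {
    x <- sense_solve(ctx, rhs, candidate_weights[k], tol = tol,
                     maxit = maxit)$x
    fw <- ctx_forward_all(ctx, x, ws$sens)
    ## ||Au - d||^2 = ||Au||^2 - 2 Re<Au, d> + ||d||^2
    r2 <- dnorm2
    for (j in seq_along(fw))
      r2 <- r2 + sum(Mod(fw[[j]])^2) -
        2 * cplx_dot(fw[[j]], kd$volumes[[j]])
    rn[k] <- sqrt(max(r2, 0))
    sn[k] <- sqrt(cplx_dot(x, x))
  }
  lx <- log(pmax(rn, 1e-300)); ly <- log(pmax(sn, 1e-300))
  curv <- rep(NA_real_, length(lx))
  for (k in 2:(length(lx) - 1L)) {
    a <- c(lx[k - 1], ly[k - 1]); b <- c(lx[k], ly[k]); cc <- c(lx[k + 1], ly[k + 1])
    cross <- (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1])
    la <- sqrt(sum((b - a)^2)); lb <- sqrt(sum((cc - b)^2))
    lc <- sqrt(sum((cc - a)^2))
    curv[k] <- if (la * lb * lc > 0) 2 * cross / (la * lb * lc) else 0
  }
  ## corner: maximum curvature bending toward the origin (positive cross
  ## product with this orientation: residual increases with weight)
  ok <- which(is.finite(curv) & curv > 1e-6)
  if (!length(ok)) {
    warning("degenerate (collinear) L-curve; returning smallest weight")
    idx <- 1L
  } else idx <- ok[which.max(curv[ok])]
  list(weight = candidate_weights[idx], index = idx,
       curve = data.frame(weight = candidate_weights, resid_norm = rn,
                          soln_norm = sn, curvature = curv))
}
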