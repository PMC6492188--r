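## ---------------------------------------------------------------------
## Internal reconstruction context
##
## All iterative reconstructions need repeated application of the SENSE
## normal operator  N_j = A_j^H A_j  for each volume j.  Because the
## readout (kx) is fully sampled, the orthonormal x-transform cancels in
## N and voxel coupling happens only along (y, z).  Two representations
## are used:
##
##  * "lattice": every pattern is a translated coset of one (possibly
##    sheared, for blipped-CAIPI) sampling lattice.  Then F^H M_t F
##    restricted to an aliasing set is the rank-1 matrix (1/R_tot) w w^H
##    with the unit-modulus translation phase w(v) = exp(2i*pi*(t_y y/ny
##    + t_z z/nz)), so N_j = D_{w} (C_g / R_tot) D_{w}^H with the per-set
##    coil Gram C_g = S_g^H S_g.  This gives exact direct unfolding for
##    SENSE and a cheap matrix-free normal operator for DAGER.
##
##  * "fftky": general Cartesian row subsets (e.g. R that does not divide
##    ny).  N is applied per coil by an orthonormal FFT along ky (and kz),
##    a per-volume (ky, kz) mask, and the inverse transform.
## ---------------------------------------------------------------------

## thin wrapper over the compiled kernel (see src/block_gram.cpp)
block_gram_apply <- function(C, members, X) .block_gram_apply(C, members, X)

recon_context <- function(sens, patterns, vol_pattern, phase = NULL) {
  dm <- dim(sens$maps)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]; nc <- dm[4]
  nvox <- nx * ny * nz
  vol_pattern <- as.integer(vol_pattern)
  nd <- length(vol_pattern)
  S <- matrix(sens$maps, nvox, nc)
  p1 <- patterns[[1L]]
  same_family <- all(vapply(patterns, function(p)
    p$R == p1$R && p$MB == p1$MB && p$f == p1$f &&
      p$ny == ny && p$nz == nz, logical(1)))
  lattice_ok <- same_family && p1$lattice &&
    (nz == 1L || abs(p1$fov_shift_fraction * ny -
                       round(p1$fov_shift_fraction * ny)) < 1e-9)
  ctx <- list(nx = nx, ny = ny, nz = nz, nc = nc, nvox = nvox, nd = nd,
              S = S, patterns = patterns, vol_pattern = vol_pattern,
              n_acq = vapply(patterns, function(p) length(p$idx),
                             integer(1)))
  if (lattice_ok) {
    ctx$type <- "lattice"
    Rt <- p1$R * p1$MB
    ctx$R_total <- Rt
    ## dual (aliasing) displacement set in the (y, z) plane
    dz <- rep(0:(nz - 1L), each = ny)
    dy <- rep(0:(ny - 1L), times = nz)
    keep <- (p1$R * dy / ny + p1$f * dz / nz) %% 1 < 1e-9
    dy <- dy[keep]; dz <- dz[keep]
    stopifnot(length(dy) == Rt)
    ## orbits of (y, z) under the dual displacements
    yz_y <- rep(0:(ny - 1L), times = nz)
    yz_z <- rep(0:(nz - 1L), each = ny)
    orb <- matrix(0L, Rt, ny * nz)     # linear yz index (1-based)
    for (k in seq_len(Rt))
      orb[k, ] <- ((yz_y + dy[k]) %% ny) + ny * ((yz_z + dz[k]) %% nz) + 1L
    rep_id <- apply(orb, 2, min)
    reps <- which(rep_id == seq_len(ny * nz))   # orbit representatives
    n_sets_yz <- length(reps)
    stopifnot(n_sets_yz * Rt == ny * nz)
    members_yz <- orb[, reps, drop = FALSE]     # Rt x n_sets_yz
    ## expand over x: voxel index = x + nx*(yz - 1)
    n_sets <- n_sets_yz * nx
    members <- matrix(0L, Rt, n_sets)
    for (ix in seq_len(nx))
      members[, (ix - 1L) * n_sets_yz + seq_len(n_sets_yz)] <-
        ix + nx * (members_yz - 1L)
    ctx$n_sets <- n_sets
    ctx$set_members <- members
    ## per-set coil Gram matrices C[p, q, g] = sum_c conj(S_c(vp)) S_c(vq)
    C <- array(0i, c(Rt, Rt, n_sets))
    for (g in seq_len(n_sets)) {
      Sv <- S[members[, g], , drop = FALSE]
      C[, , g] <- Conj(Sv) %*% t(Sv)
    }
    ctx$C <- C
    ## translation phases per pattern: w_t(v) = exp(2i pi (ty*y/ny + tz*z/nz))
    vy <- rep(rep(0:(ny - 1L), each = nx), times = nz)
    vz <- rep(0:(nz - 1L), each = nx * ny)
    W0 <- matrix(0i, nvox, length(patterns))
    for (tpat in seq_along(patterns))
      W0[, tpat] <- exp(2i * pi * (patterns[[tpat]]$ky_shift * vy / ny +
                                   patterns[[tpat]]$kz_shift * vz / nz))
    ctx$W <- W0[, vol_pattern, drop = FALSE]
    ctx$Wc <- Conj(ctx$W)
    ## diagonal of the data normal operator (per volume constant over sets)
    cdiag <- numeric(nvox)
    dix <- cbind(seq_len(Rt), seq_len(Rt))
    for (g in seq_len(n_sets))
      cdiag[members[, g]] <- Re(matrix(C[, , g], Rt, Rt)[dix]) / Rt
    ctx$normal_diag <- matrix(cdiag, nvox, nd)
  } else {
    if (nz > 1L)
      stop("multiband patterns must form a sampling lattice ",
           "(ny divisible by R and fov_shift_fraction * ny integer)")
    ctx$type <- "fftky"
    ## per-pattern acquisition mask over ky and circulant kernels
    Mk <- matrix(0, ny, length(patterns))
    for (tpat in seq_along(patterns)) Mk[patterns[[tpat]]$ky + 1L, tpat] <- 1
    ctx$mask_ky <- Mk[, vol_pattern, drop = FALSE]      # ny x nd
    ## circulant coupling kernel H[y, y'] = (1/ny) sum_ky e^{2i pi ky (y-y')/ny}
    dyy <- outer(0:(ny - 1L), 0:(ny - 1L), "-")
    ctx$H <- lapply(patterns, function(p) {
      ker <- matrix(0i, ny, ny)
      for (ky in p$ky) ker <- ker + exp(2i * pi * ky * dyy / ny)
      ker / ny
    })
    sos <- rowSums(Mod(S)^2)
    ctx$normal_diag <- outer(sos, ctx$n_acq[vol_pattern] / ny)
  }
  ctx
}

## Apply the data normal operator N (all volumes at once).
## X: nvox x nd complex matrix (phase-corrected image stack).
## Pm: optional nvox x nd unit-magnitude phase matrix (motion phase).
ctx_normal_apply <- function(ctx, X, Pm = NULL) {
  if (!is.null(Pm)) X <- Pm * X
  if (ctx$type == "lattice") {
    T1 <- ctx$Wc * X
    T2 <- block_gram_apply(ctx$C, ctx$set_members, T1)
    Y <- ctx$W * T2 / ctx$R_total
  } else {
    nx <- ctx$nx; ny <- ctx$ny; nd <- ctx$nd
    Y <- matrix(0i, ctx$nvox, nd)
    mask <- ctx$mask_ky                     # ny x nd
    bigmask <- mask[, rep(seq_len(nd), each = nx)]     # ny x (nx*nd)
    for (cc in seq_len(ctx$nc)) {
      Tc <- ctx$S[, cc] * X
      dim(Tc) <- c(nx, ny, nd)
      Tc <- aperm(Tc, c(2L, 1L, 3L))
      dim(Tc) <- c(ny, nx * nd)
      K <- stats::mvfft(Tc) * bigmask
      Tc <- stats::mvfft(K, inverse = TRUE) / ny
      dim(Tc) <- c(ny, nx, nd)
      Tc <- aperm(Tc, c(2L, 1L, 3L))
      dim(Tc) <- c(ctx$nvox, nd)
      Y <- Y + Conj(ctx$S[, cc]) * Tc
    }
  }
  if (!is.null(Pm)) Y <- Conj(Pm) * Y
  Y
}

## A^H d for every volume, as an nvox x nd complex matrix
ctx_adjoint_all <- function(ctx, kdata, sens) {
  Y <- matrix(0i, ctx$nvox, ctx$nd)
  for (j in seq_len(ctx$nd)) {
    p <- ctx$patterns[[ctx$vol_pattern[j]]]
    Y[, j] <- as.vector(adjoint_encode(list(data = kdata[[j]]), sens, p))
  }
  Y
}

## forward encode a stack (nvox x nd) -> list of k-space arrays
ctx_forward_all <- function(ctx, X, sens, Pm = NULL, volumes = NULL) {
  if (is.null(volumes)) volumes <- seq_len(ctx$nd)
  out <- vector("list", length(volumes))
  for (i in seq_along(volumes)) {
    j <- volumes[i]
    u <- X[, j]
    if (!is.null(Pm)) u <- Pm[, j] * u
    dim(u) <- c(ctx$nx, ctx$ny, ctx$nz)
    out[[i]] <- forward_encode(u, sens,
                               ctx$patterns[[ctx$vol_pattern[j]]])$data
  }
  out
}

## ---------------------------------------------------------------------
## Preconditioned conjugate gradient for Hermitian positive definite
## operators on complex image stacks, with monitored quadratic objective
## phi(x) = 0.5 Re<x, Gx> - Re<b, x> (non-increasing across iterations).
## ---------------------------------------------------------------------
cplx_dot <- function(a, b) sum(Re(a) * Re(b) + Im(a) * Im(b))

pcg_solve <- function(apply_G, b, x0 = NULL, tol = 1e-6, maxit = 250L,
                      precond = NULL, track_objective = FALSE) {
  apply_M <- if (is.null(precond)) identity
             else if (is.function(precond)) precond
             else function(r) r / precond
  x <- if (is.null(x0)) b * 0i else x0
  r <- b - apply_G(x)
  bnorm <- sqrt(cplx_dot(b, b))
  if (bnorm == 0) bnorm <- 1
  z <- apply_M(r)
  p <- z
  rz <- cplx_dot(r, z)
  obj <- if (track_objective)
    0.5 * cplx_dot(x, b - r) - cplx_dot(b, x) else NULL
  it <- 0L
  relres <- sqrt(cplx_dot(r, r)) / bnorm
  while (relres > tol && it < maxit) {
    it <- it + 1L
    Gp <- apply_G(p)
    pGp <- cplx_dot(p, Gp)
    if (pGp <= 0) break                       # loss of positive definiteness
    alpha <- rz / pGp
    x <- x + alpha * p
    r <- r - alpha * Gp
    z <- apply_M(r)
    rz_new <- cplx_dot(r, z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
    relres <- sqrt(cplx_dot(r, r)) / bnorm
    if (track_objective)
      obj <- c(obj, 0.5 * cplx_dot(x, b - r) - cplx_dot(b, x))
  }
  list(x = x, iterations = it, relres = relres, converged = relres <= tol,
       objective = obj)
}
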