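#' Normalized root-mean-square error within a mask
#'
#' `||(|recon| - |truth|) * mask||_2 / ||truth * mask||_2`, per volume.
#' Magnitudes are compared by default (complex inputs are `Mod`-ed);
#' set `channel = "complex"` to compare complex values directly.
#'
#' @param recon reconstructed image(s): `nx x ny (x nz)` or with a
#'   trailing volume dimension.
#' @param truth ground-truth image(s) of matching shape.
#' @param mask logical array over the voxel grid (nonempty).
#' @param channel `"magnitude"` (default) or `"complex"`.
#' @return numeric vector of per-volume NRMSE values (`>= 0`).
#' @export
nrmse <- function(recon, truth, mask, channel = c("magnitude", "complex")) {
  channel <- match.arg(channel)
  if (is.null(dim(recon))) stop("'recon' must be an array")
  if (!identical(dim(recon), dim(truth)))
    stop("'recon' and 'truth' grids differ")
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty mask")
  nvox <- length(mask)
  nd <- length(recon) / nvox
  if (nd != round(nd))
    stop("mask size does not divide the image array")
  R <- matrix(recon, nvox, nd)[mask, , drop = FALSE]
  T_ <- matrix(truth, nvox, nd)[mask, , drop = FALSE]
  if (channel == "magnitude") { R <- Mod(R); T_ <- Mod(T_) }
  tn <- sqrt(colSums(Mod(T_)^2))
  if (any(tn == 0)) stop("ground truth has zero norm inside the mask")
  sqrt(colSums(Mod(R - T_)^2)) / tn
}

#' Signal covariance versus angular distance
#'
#' For every ordered pair of diffusion volumes, computes the covariance
#' of the masked voxel signals across space; pairs at angular distance 0
#' (a volume with itself) give the per-volume signal variance.  All
#' values are normalized by the median of the variances.  Angular
#' smoothing in a reconstruction shows up as inflated covariance at large
#' angular distances relative to the ground truth's curve.
#'
#' @param volumes real array `nx x ny (x nz) x Nd` (magnitudes), or an
#'   `Nvox x Nd` matrix of masked signals.
#' @param protocol the [qspace_protocol()] of the volumes.
#' @param mask logical voxel mask (ignored for matrix input).
#' @return data frame with columns `i`, `j`, `angle` (radians) and
#'   `covariance` (normalized); `i == j` rows are the variance points.
#'   The normalizing median variance is attached as attribute
#'   `"median_variance"`.
#' @export
covariance_vs_angle <- function(volumes, protocol, mask = NULL) {
  nd <- nrow(protocol$directions)
  if (is.matrix(volumes) && is.null(mask)) {
    M <- volumes
  } else {
    nvox <- length(volumes) / nd
    M <- matrix(volumes, nvox, nd)
    if (!is.null(mask)) M <- M[as.logical(mask), , drop = FALSE]
  }
  if (ncol(M) != nd) stop("volume count does not match the protocol")
  if (nd < 2L) stop("at least two volumes are required")
  C <- stats::cov(M)
  v <- diag(C)
  if (any(v <= 0))
    warning(sum(v <= 0), " volume(s) have zero spatial variance")
  medv <- stats::median(v)
  th <- angular_distance_matrix(protocol)
  idx <- which(upper.tri(C, diag = TRUE), arr.ind = TRUE)
  out <- data.frame(i = idx[, 1], j = idx[, 2],
                    angle = th[idx], covariance = C[idx] / medv)
  attr(out, "median_variance") <- medv
  out
}

#' Binned average of a covariance-vs-angle point set
#'
#' @param cva data frame from [covariance_vs_angle()].
#' @param breaks bin breaks in radians (default 24 bins over the range).
#' @return data frame with bin centre `angle` and mean `covariance`.
#' @export
bin_covariance_curve <- function(cva, breaks = NULL) {
  if (is.null(breaks))
    breaks <- seq(0, max(cva$angle) + 1e-9, length.out = 25L)
  bin <- cut(cva$angle, breaks, include.lowest = TRUE)
  agg <- stats::aggregate(cva$covariance, list(bin = bin), mean)
  ctr <- (breaks[-1] + breaks[-length(breaks)]) / 2
  data.frame(angle = ctr[match(agg$bin, levels(bin))], covariance = agg$x)
}
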