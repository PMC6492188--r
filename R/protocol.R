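#' Diffusion q-space protocol
#'
#' A q-space protocol records where in q-space each diffusion volume was
#' acquired: a unit gradient direction and a b-value per volume.  The object
#' also carries the choice of angular metric used throughout the package:
#' with `symmetric = TRUE` the angle between two directions is computed on
#' antipodally identified directions (`acos(|<g1,g2>|)`, range `[0, pi/2]`),
#' reflecting the antipodal symmetry of the diffusion signal; with
#' `symmetric = FALSE` the plain angle `acos(<g1,g2>)` in `[0, pi]` is used.
#'
#' @param directions numeric matrix with 3 columns (or a length-3 vector for
#'   a single direction); rows are gradient directions and must have unit
#'   Euclidean norm to within `tol`.
#' @param bvalues numeric vector of b-values in s/mm^2, one per direction.
#'   A single value is recycled.
#' @param symmetric logical; use the antipodally symmetric angular metric.
#' @param tol tolerance on the unit-norm check.
#' @return An object of class `qspace_protocol`: a list with elements
#'   `directions` (Nd x 3 matrix of unit row vectors), `bvalues` (length Nd)
#'   and `symmetric`.
#' @seealso [angular_distance()], [read_bvec()], [qspace_directions()]
#' @export
qspace_protocol <- function(directions, bvalues = 1000, symmetric = TRUE,
                            tol = 1e-6) {
  if (is.null(dim(directions))) directions <- matrix(directions, ncol = 3)
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L)
    stop("'directions' must have 3 columns")
  nd <- nrow(directions)
  if (nd < 1L) stop("at least one direction is required")
  nrm <- sqrt(rowSums(directions^2))
  bvalues <- rep_len(as.numeric(bvalues), nd)
  ## b = 0 volumes have no meaningful direction; skip the norm check there
  chk <- bvalues > 0
  if (any(abs(nrm[chk] - 1) > tol))
    stop("directions must have unit norm (max deviation ",
         format(max(abs(nrm[chk] - 1))), ")")
  directions[chk, ] <- directions[chk, , drop = FALSE] / nrm[chk]
  structure(list(directions = directions, bvalues = bvalues,
                 symmetric = isTRUE(symmetric)),
            class = "qspace_protocol")
}

#' @export
print.qspace_protocol <- function(x, ...) {
  cat("q-space protocol:", nrow(x$directions), "volumes,",
      length(unique(x$bvalues)), "shell(s), b =",
      paste(unique(x$bvalues), collapse = ", "), "s/mm^2\n")
  cat("angular metric:",
      if (x$symmetric) "antipodally symmetric" else "non-symmetric", "\n")
  invisible(x)
}

#' @export
length.qspace_protocol <- function(x) nrow(x$directions)

#' Angular distance between diffusion directions
#'
#' Computes the angle between two unit direction vectors, optionally on
#' antipodally identified directions.  The dot product is clamped to
#' `[-1, 1]` before `acos` to absorb floating-point rounding.
#'
#' @param g1,g2 unit 3-vectors (or matrices of row vectors with 3 columns;
#'   vectors are recycled against matrices row-wise).
#' @param symmetric logical; if `TRUE`, returns `acos(|<g1,g2>|)` in
#'   `[0, pi/2]`, otherwise `acos(<g1,g2>)` in `[0, pi]`.
#' @param tol tolerance on the unit-norm check.
#' @return angle(s) in radians.
#' @export
angular_distance <- function(g1, g2, symmetric = TRUE, tol = 1e-6) {
  if (is.null(dim(g1))) g1 <- matrix(g1, ncol = 3)
  if (is.null(dim(g2))) g2 <- matrix(g2, ncol = 3)
  if (any(abs(sqrt(rowSums(g1^2)) - 1) > tol) ||
      any(abs(sqrt(rowSums(g2^2)) - 1) > tol))
    stop("angular_distance() requires unit-norm inputs")
  n <- max(nrow(g1), nrow(g2))
  if (nrow(g1) == 1L) g1 <- g1[rep(1L, n), , drop = FALSE]
  if (nrow(g2) == 1L) g2 <- g2[rep(1L, n), , drop = FALSE]
  d <- rowSums(g1 * g2)
  d <- pmin(1, pmax(-1, d))
  if (symmetric) acos(abs(d)) else acos(d)
}

#' Pairwise angular distance matrix of a protocol
#'
#' @param protocol a [qspace_protocol()].
#' @param symmetric optional override of the protocol's angular metric.
#' @return Nd x Nd matrix of angles in radians.
#' @export
angular_distance_matrix <- function(protocol, symmetric = NULL) {
  stopifnot(inherits(protocol, "qspace_protocol"))
  if (is.null(symmetric)) symmetric <- protocol$symmetric
  g <- protocol$directions
  d <- tcrossprod(g)
  d <- pmin(pmax(d, -1), 1)       # clamp, preserving dim
  if (symmetric) acos(abs(d)) else acos(d)
}

#' Generate a set of diffusion directions
#'
#' Directions are produced either by electrostatic repulsion (antipodal
#' point charges on the sphere, relaxed by projected gradient descent from a
#' deterministic spherical-spiral start with a small seeded perturbation) or
#' by the plain deterministic spherical spiral.  Repulsion sets are close to
#' the uniform antipodal designs commonly used for single-shell acquisition.
#'
#' @param n number of directions.
#' @param method `"repulsion"` (default) or `"spiral"`.
#' @param iterations gradient-descent iterations for the repulsion method.
#' @param seed integer seed for the initial perturbation (repulsion only).
#' @return n x 3 matrix of unit row vectors.
#' @export
qspace_directions <- function(n, method = c("repulsion", "spiral"),
                              iterations = 300, seed = 1) {
  method <- match.arg(method)
  ## spherical Fibonacci spiral on the upper hemisphere (antipodal designs)
  i <- seq_len(n) - 0.5
  z <- i / n                      # z in (0, 1): hemisphere
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  g <- cbind(r * cos(phi), r * sin(phi), z)
  if (method == "spiral" || n < 3L) return(g)
  rs <- local({ set.seed(as.integer(seed) %% .Machine$integer.max)
                matrix(stats::rnorm(3 * n, sd = 0.02), n, 3) })
  g <- g + rs
  g <- g / sqrt(rowSums(g^2))
  step <- 0.1 / n
  for (it in seq_len(iterations)) {
    ## antipodal electrostatic forces: charges at +/- g_j
    d1 <- tcrossprod(g)                       # cos angles
    frc <- matrix(0, n, 3)
    for (sgn in c(1, -1)) {
      ## displacement g_i - sgn*g_j, squared distance 2 - 2*sgn*cos
      d2 <- pmax(2 - 2 * sgn * d1, 1e-9)
      w <- 1 / (d2 * sqrt(d2))               # 1/d^3 (Coulomb on 1/d energy)
      diag(w) <- 0
      frc <- frc + (colSums(w) * g) - sgn * (t(w) %*% g)
    }
    g <- g + step * frc
    g <- g / sqrt(rowSums(g^2))
  }
  ## canonical hemisphere for reproducibility
  flip <- g[, 3] < 0
  g[flip, ] <- -g[flip, , drop = FALSE]
  g
}

#' Read and write FSL-style bvec / bval files
#'
#' `bvec` files hold a 3 x Nd whitespace-separated table of gradient
#' directions; `bval` files a 1 x Nd table of b-values.  Non-unit bvec
#' columns (with nonzero b) are normalized with a warning.
#'
#' @param bvec,bval file paths.
#' @param symmetric angular metric flag stored on the returned protocol.
#' @return `read_bvec_bval()` returns a [qspace_protocol()].
#' @export
read_bvec_bval <- function(bvec, bval, symmetric = TRUE) {
  v <- as.matrix(utils::read.table(bvec))
  if (nrow(v) != 3L && ncol(v) == 3L) v <- t(v)
  if (nrow(v) != 3L) stop("bvec file '", bvec, "' is not a 3 x Nd table")
  b <- as.numeric(as.matrix(utils::read.table(bval)))
  if (length(b) != ncol(v))
    stop("bval file '", bval, "' has ", length(b),
         " entries but bvec has ", ncol(v), " columns")
  g <- t(v)
  nrm <- sqrt(rowSums(g^2))
  bad <- b > 0 & abs(nrm - 1) > 1e-4
  if (any(bad)) {
    warning("normalizing ", sum(bad), " non-unit bvec column(s)")
    g[bad, ] <- g[bad, , drop = FALSE] / nrm[bad]
  }
  qspace_protocol(g, b, symmetric = symmetric, tol = 1e-3)
}

#' @rdname read_bvec_bval
#' @param protocol a [qspace_protocol()] to write.
#' @export
write_bvec_bval <- function(protocol, bvec, bval) {
  stopifnot(inherits(protocol, "qspace_protocol"))
  utils::write.table(t(protocol$directions), bvec, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(t(protocol$bvalues), bval, row.names = FALSE,
                     col.names = FALSE)
  invisible(protocol)
}

#' @rdname read_bvec_bval
#' @export
read_bvec <- function(bvec, symmetric = TRUE) {
  v <- as.matrix(utils::read.table(bvec))
  if (nrow(v) != 3L && ncol(v) == 3L) v <- t(v)
  qspace_protocol(t(v), 1000, symmetric = symmetric, tol = 1e-3)
}
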