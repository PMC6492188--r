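#' Cartesian k-space sampling pattern
#'
#' A sampling pattern records which phase-encoding lines are acquired for
#' one diffusion volume.  The readout direction (kx) is always fully
#' sampled; undersampling happens along ky (in-plane factor `R`) and, for
#' simultaneous-multislice (SMS) acquisitions encoded on the extended
#' slice dimension, along kz (`MB` simultaneous slices).  Blipped-CAIPI is
#' modelled by advancing kz by `f` steps (mod `MB`) per acquired ky line,
#' with `f = fov_shift_fraction * R * MB`, which reproduces the standard
#' interslice image shift (e.g. FOV/4 for `fov_shift_fraction = 1/4`).
#'
#' k-space indices are 0-based on the unshifted (DC-first) FFT grid.
#'
#' @param ny,nz phase-encoding and slice grid sizes (`nz = MB`).
#' @param R in-plane undersampling factor (`>= 1`).
#' @param MB multiband factor (`>= 1`).
#' @param ky_shift integer ky offset of the acquired lattice, in
#'   `0 .. R-1`.
#' @param kz_shift integer kz offset, in `0 .. MB-1`.
#' @param fov_shift_fraction interslice image shift as a fraction of the
#'   field of view (e.g. `1/4`); `f = fov_shift_fraction * R * MB` must be
#'   an integer.
#' @return object of class `sampling_pattern` with the acquired `ky`,
#'   `kz` index vectors, their linear index `idx` into the flattened
#'   `(ky, kz)` grid, and a `lattice` flag marking patterns that form an
#'   exact coset of a (sheared) sampling lattice (`ny` divisible by `R`),
#'   for which fast image-domain unfolding applies.
#' @export
sampling_pattern <- function(ny, nz = 1L, R = 1L, MB = nz,
                             ky_shift = 0L, kz_shift = 0L,
                             fov_shift_fraction = 0) {
  R <- as.integer(R); MB <- as.integer(MB)
  if (R < 1L || MB < 1L) stop("'R' and 'MB' must be >= 1")
  if (MB != nz) stop("'nz' must equal 'MB' (extended-slice encoding)")
  if (ky_shift < 0L || ky_shift >= R) stop("'ky_shift' must be in 0 .. R-1")
  if (MB > 1L && (kz_shift < 0L || kz_shift >= MB))
    stop("'kz_shift' must be in 0 .. MB-1")
  f <- fov_shift_fraction * R * MB
  ## tolerance admits fractions that passed through decimal serialization
  if (abs(f - round(f)) > 1e-6)
    stop("fov_shift_fraction * R * MB must be an integer")
  f <- as.integer(round(f))
  ky <- seq.int(ky_shift, ny - 1L, by = R)
  m <- seq_along(ky) - 1L
  kz <- if (MB > 1L) (kz_shift + f * m) %% MB else rep(0L, length(ky))
  lattice <- (ny %% R == 0L)
  structure(list(ny = as.integer(ny), nz = as.integer(nz), R = R, MB = MB,
                 ky_shift = as.integer(ky_shift),
                 kz_shift = as.integer(kz_shift),
                 fov_shift_fraction = fov_shift_fraction, f = f,
                 ky = as.integer(ky), kz = as.integer(kz),
                 idx = as.integer(ky + ny * kz + 1L),
                 lattice = lattice),
            class = "sampling_pattern")
}

#' @export
print.sampling_pattern <- function(x, ...) {
  cat("sampling pattern: R =", x$R, "MB =", x$MB,
      sprintf("shifts (ky, kz) = (%d, %d)", x$ky_shift, x$kz_shift),
      "\n  ", length(x$ky), "of", x$ny * x$nz, "phase-encode lines",
      if (x$lattice) "(lattice coset)" else "(non-lattice)", "\n")
  invisible(x)
}

#' Enumerate the shifted sampling patterns of an accelerated EPI scheme
#'
#' For an in-plane factor `R` there are `R` distinct patterns produced by
#' shifting the undersampled trajectory along ky; for SMS acquisitions the
#' kz blip offset is shifted as well, giving `R * MB` distinct patterns.
#' Patterns are enumerated in a fixed lexicographic `(kz_shift, ky_shift)`
#' cycle so that consecutive pattern ids differ in ky first.
#'
#' @inheritParams sampling_pattern
#' @return list of `R` (non-SMS) or `R * MB` (SMS) [sampling_pattern()]s.
#' @export
shifted_patterns <- function(R, MB = 1L, fov_shift_fraction = 0,
                             ny, nz = MB) {
  R <- as.integer(R); MB <- as.integer(MB)
  out <- list()
  k <- 1L
  for (sz in 0:(MB - 1L)) {
    for (sy in 0:(R - 1L)) {
      out[[k]] <- sampling_pattern(ny, nz, R, MB, ky_shift = sy,
                                   kz_shift = sz,
                                   fov_shift_fraction = fov_shift_fraction)
      k <- k + 1L
    }
  }
  out
}

## logical acquisition mask over the (ky, kz) grid
pattern_mask <- function(pattern) {
  m <- matrix(FALSE, pattern$ny, pattern$nz)
  m[pattern$idx] <- TRUE
  m
}

#' Serialize sampling patterns to structured text
#'
#' Writes (reads) a pattern as a small YAML document carrying `R`, `MB`,
#' the shifts, FOV shift fraction, grid size, and the explicit acquired
#' index list.
#'
#' @param pattern a [sampling_pattern()].
#' @param path file path.
#' @export
write_sampling_pattern <- function(pattern, path) {
  yaml::write_yaml(list(ny = pattern$ny, nz = pattern$nz, R = pattern$R,
                        MB = pattern$MB, ky_shift = pattern$ky_shift,
                        kz_shift = pattern$kz_shift,
                        fov_shift_fraction = pattern$fov_shift_fraction,
                        ky = pattern$ky, kz = pattern$kz), path,
                   precision = 15L)
  invisible(path)
}

#' @rdname write_sampling_pattern
#' @export
read_sampling_pattern <- function(path) {
  s <- yaml::read_yaml(path)
  for (f in c("ny", "nz", "R", "MB", "ky_shift", "kz_shift",
              "fov_shift_fraction"))
    if (is.null(s[[f]])) stop("pattern file '", path,
                              "' is missing field '", f, "'")
  p <- sampling_pattern(s$ny, s$nz, s$R, s$MB, s$ky_shift, s$kz_shift,
                        s$fov_shift_fraction)
  if (!identical(p$ky, as.integer(s$ky)) ||
      !identical(p$kz, as.integer(s$kz)))
    stop("pattern file '", path, "': stored index list is inconsistent ",
         "with the stored shifts")
  p
}
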