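## ---------------------------------------------------------------------
## Dataset container: a documented directory layout holding multi-volume
## k-space data and metadata.
##
##   <dir>/meta.json          dimensions, coil count, pattern table,
##                            volume -> pattern map, scalar metadata
##   <dir>/kspace.bin         float64 little-endian, interleaved
##                            (re, im), volumes concatenated in order,
##                            each volume column-major nx x n_acq x Nc
##   <dir>/coils.bin          optional coil sensitivities (interleaved
##                            complex, nx x ny x nz x Nc)
##   <dir>/truth.bin          optional ground truth (float64, real)
##   <dir>/phase.bin          optional true phase maps (interleaved
##                            complex, nx x ny x nz x Nd)
##   <dir>/mask.bin           optional mask (uint8)
##   <dir>/bvecs, <dir>/bvals optional FSL-style protocol tables
##
## Images use 0-based voxel indices with ky along the second axis;
## k-space index lists are 0-based in the unshifted (DC-first) FFT order.
## ---------------------------------------------------------------------

write_complex_bin <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  buf <- numeric(2 * n)
  buf[seq(1, 2 * n, by = 2)] <- Re(x)
  buf[seq(2, 2 * n, by = 2)] <- Im(x)
  writeBin(buf, con, size = 8, endian = "little")
}

read_complex_bin <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  buf <- readBin(con, "double", n = 2 * n, size = 8, endian = "little")
  complex(real = buf[seq(1, 2 * n, by = 2)],
          imaginary = buf[seq(2, 2 * n, by = 2)])
}

#' Write / read a k-q dataset container
#'
#' Serializes a [kq_data()] or full [simulate_acquisition()] dataset to a
#' directory: JSON metadata plus raw little-endian float64 blobs (complex
#' values interleaved re/im).  The round trip is lossless (bitwise-equal
#' arrays).
#'
#' @param x a `kq_data` or `kq_dataset`.
#' @param dir target directory (created if needed).
#' @param coils optional [coil_set()] stored alongside the data so the
#'   container is self-sufficient for reconstruction.
#' @return `read_kq_dataset()` returns a `kq_dataset` (with `truth`,
#'   `phase_maps`, `mask`, `protocol`, `coils` when present in the
#'   container).
#' @export
write_kq_dataset <- function(x, dir, coils = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kd <- if (inherits(x, "kq_dataset")) x$kdata else as_kq_data(x)
  pats <- lapply(kd$patterns, function(p)
    list(ny = p$ny, nz = p$nz, R = p$R, MB = p$MB, ky_shift = p$ky_shift,
         kz_shift = p$kz_shift, fov_shift_fraction = p$fov_shift_fraction))
  dims <- dim(kd$volumes[[1]])
  meta <- list(format = "dager-kq-dataset", version = 1L,
               nx = dims[1], n_coils = dims[3],
               n_volumes = length(kd$volumes),
               n_acq = vapply(kd$volumes, function(v) dim(v)[2], integer(1)),
               patterns = pats, vol_pattern = kd$vol_pattern)
  all_k <- unlist(lapply(kd$volumes, as.vector))
  write_complex_bin(all_k, file.path(dir, "kspace.bin"))
  if (!is.null(coils)) {
    meta$coil_grid <- dim(coils$maps)
    write_complex_bin(as.vector(coils$maps), file.path(dir, "coils.bin"))
  }
  if (inherits(x, "kq_dataset")) {
    meta$grid <- dim(x$truth)[1:3]
    meta$snr <- x$snr
    meta$sigma_k_true <- x$sigma_k_true
    meta$seed <- x$seed
    con <- file(file.path(dir, "truth.bin"), "wb")
    writeBin(as.vector(x$truth), con, size = 8, endian = "little")
    close(con)
    if (!is.null(x$phase_maps)) {
      ph <- unlist(lapply(x$phase_maps, as.vector))
      write_complex_bin(ph, file.path(dir, "phase.bin"))
    }
    if (!is.null(x$phase_ref)) {
      meta$phase_ref_dim <- dim(x$phase_ref[[1]])
      write_complex_bin(unlist(lapply(x$phase_ref, as.vector)),
                        file.path(dir, "phase_ref.bin"))
    }
    if (!is.null(x$mask)) {
      con <- file(file.path(dir, "mask.bin"), "wb")
      writeBin(as.integer(as.vector(x$mask)), con, size = 1)
      close(con)
    }
    if (!is.null(x$protocol))
      write_bvec_bval(x$protocol, file.path(dir, "bvecs"),
                      file.path(dir, "bvals"))
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_kq_dataset
#' @export
read_kq_dataset <- function(dir) {
  mf <- file.path(dir, "meta.json")
  if (!file.exists(mf)) stop("not a dataset container: missing meta.json")
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(meta$format, "dager-kq-dataset"))
    stop("meta.json: unrecognized 'format' field")
  nd <- meta$n_volumes
  nx <- meta$nx; nc <- meta$n_coils
  n_acq <- as.integer(meta$n_acq)
  patterns <- lapply(seq_len(nrow(meta$patterns)), function(i) {
    p <- meta$patterns[i, ]
    sampling_pattern(p$ny, p$nz, p$R, p$MB, p$ky_shift, p$kz_shift,
                     p$fov_shift_fraction)
  })
  total <- sum(nx * n_acq * nc)
  all_k <- read_complex_bin(file.path(dir, "kspace.bin"), total)
  volumes <- vector("list", nd)
  off <- 0L
  for (j in seq_len(nd)) {
    n <- nx * n_acq[j] * nc
    volumes[[j]] <- array(all_k[off + seq_len(n)], c(nx, n_acq[j], nc))
    off <- off + n
  }
  kd <- kq_data(volumes, patterns, as.integer(meta$vol_pattern))
  out <- list(kdata = kd, protocol = NULL, plan = NULL, truth = NULL,
              phase_maps = NULL, mask = NULL, coils = NULL,
              sigma_k_true = meta$sigma_k_true, snr = meta$snr,
              seed = meta$seed)
  if (!is.null(meta$coil_grid) &&
      file.exists(file.path(dir, "coils.bin"))) {
    cg <- as.integer(meta$coil_grid)
    cm <- read_complex_bin(file.path(dir, "coils.bin"), prod(cg))
    out$coils <- coil_set(array(cm, cg))
  }
  if (!is.null(meta$grid)) {
    grid <- as.integer(meta$grid)
    tf <- file.path(dir, "truth.bin")
    if (file.exists(tf)) {
      con <- file(tf, "rb")
      tr <- readBin(con, "double", n = prod(grid) * nd, size = 8,
                    endian = "little")
      close(con)
      out$truth <- array(tr, c(grid, nd))
    }
    pf <- file.path(dir, "phase.bin")
    if (file.exists(pf)) {
      ph <- read_complex_bin(pf, prod(grid) * nd)
      out$phase_maps <- lapply(seq_len(nd), function(j)
        array(ph[(j - 1) * prod(grid) + seq_len(prod(grid))], grid))
    }
    prf <- file.path(dir, "phase_ref.bin")
    if (!is.null(meta$phase_ref_dim) && file.exists(prf)) {
      pd <- as.integer(meta$phase_ref_dim)
      pr <- read_complex_bin(prf, prod(pd) * nd)
      out$phase_ref <- lapply(seq_len(nd), function(j)
        array(pr[(j - 1) * prod(pd) + seq_len(prod(pd))], pd))
    }
    mf2 <- file.path(dir, "mask.bin")
    if (file.exists(mf2)) {
      con <- file(mf2, "rb")
      mk <- readBin(con, "integer", n = prod(grid), size = 1)
      close(con)
      out$mask <- array(mk > 0, grid)
    }
  }
  if (file.exists(file.path(dir, "bvecs")))
    out$protocol <- read_bvec_bval(file.path(dir, "bvecs"),
                                   file.path(dir, "bvals"))
  structure(out, class = "kq_dataset")
}

#' Export image volumes as NIfTI
#'
#' Writes the magnitude (and optionally the phase) of a reconstructed
#' volume stack as NIfTI files via the RNifti package.  Voxel indices are
#' 0-based with ky along the second image axis.
#'
#' @param volumes complex or real array `nx x ny x nz x Nd` (or 3D).
#' @param path output path for the magnitude image (`.nii` / `.nii.gz`).
#' @param phase_path optional output path for the phase image (radians).
#' @param voxel_size voxel dimensions in mm recorded in the header.
#' @return `path`, invisibly.
#' @export
write_nifti_volumes <- function(volumes, path, phase_path = NULL,
                                voxel_size = c(1.5, 1.5, 1.5)) {
  mag <- Mod(volumes)
  img <- RNifti::asNifti(mag, pixdim = voxel_size)
  RNifti::writeNifti(img, path)
  if (!is.null(phase_path)) {
    ph <- Arg(volumes)
    RNifti::writeNifti(RNifti::asNifti(ph, pixdim = voxel_size), phase_path)
  }
  invisible(path)
}

#' Read / write a reconstruction configuration as YAML
#'
#' The file mirrors the [recon_config()] field names exactly.
#'
#' @param config a [recon_config()].
#' @param path file path.
#' @export
write_recon_config <- function(config, path) {
  stopifnot(inherits(config, "recon_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_recon_config
#' @export
read_recon_config <- function(path) {
  s <- yaml::read_yaml(path)
  known <- names(formals(recon_config))
  unknown <- setdiff(names(s), known)
  if (length(unknown))
    stop("config file '", path, "': unknown field(s) ",
         paste(unknown, collapse = ", "))
  do.call(recon_config, s)
}
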