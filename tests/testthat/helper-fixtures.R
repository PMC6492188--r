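## Shared fixture builders for the test suite.  Everything is generated
## in code under fixed seeds; no data files.

## small q-space protocol with well-spread directions
tiny_protocol <- function(n = 12, seed = 2, b = 1000, symmetric = TRUE)
  qspace_protocol(qspace_directions(n, seed = seed), b,
                  symmetric = symmetric)

## dense encoding matrix built from first principles (DFT matrices, coil
## diagonals, row selection) -- independent of forward_encode()
dense_encoding_matrix <- function(sens, pattern, phase = NULL) {
  d <- dim(sens$maps)
  nx <- d[1]; ny <- d[2]; nz <- d[3]; nc <- d[4]
  Fx <- exp(-2i * pi * outer(0:(nx - 1), 0:(nx - 1)) / nx) / sqrt(nx)
  Fy <- exp(-2i * pi * outer(0:(ny - 1), 0:(ny - 1)) / ny) / sqrt(ny)
  Fz <- exp(-2i * pi * outer(0:(nz - 1), 0:(nz - 1)) / nz) / sqrt(nz)
  F3 <- kronecker(Fz, kronecker(Fy, Fx))   # vec() col-major, x fastest
  sel <- as.vector(outer(1:nx, (pattern$idx - 1) * nx, "+"))
  P <- if (is.null(phase)) 1 else diag(as.vector(phase))
  do.call(rbind, lapply(seq_len(nc), function(cc) {
    Sc <- diag(as.vector(sens$maps[, , , cc]))
    M <- F3 %*% Sc
    if (!is.null(phase)) M <- M %*% P
    M[sel, , drop = FALSE]
  }))
}

## random complex array
rcplx <- function(n, sd = 1)
  complex(real = stats::rnorm(n, sd = sd),
          imaginary = stats::rnorm(n, sd = sd))

## reshape a dense-matrix k-space vector into the kspace_volume layout
as_kvol <- function(dvec, nx, pattern, nc) {
  na <- length(pattern$idx)
  structure(list(data = array(dvec, c(nx, na, nc)), pattern = pattern),
            class = "kspace_volume")
}

## brute-force minimum-conflict coloring by exhaustive enumeration
brute_min_conflicts <- function(graph, R_total) {
  n <- graph$n
  if (nrow(graph$edges) == 0L) return(0L)
  best <- Inf
  all_assign <- do.call(expand.grid, rep(list(0:(R_total - 1L)), n))
  for (r in seq_len(nrow(all_assign))) {
    cc <- as.integer(all_assign[r, ])
    conf <- sum(cc[graph$edges[, 1]] == cc[graph$edges[, 2]])
    if (conf < best) best <- conf
    if (best == 0L) break
  }
  as.integer(best)
}

## small end-to-end simulated dataset used across test files
small_dataset <- function(size = 24, n_dir = 48, n_coils = 8, R = 4,
                          snr = 20, seed = 1, phase = "random",
                          mode = "variable") {
  protocol <- qspace_protocol(qspace_directions(n_dir, seed = seed), 1000)
  phantom <- make_phantom(c(size, size), seed = seed)
  coils <- simulate_coils(n_coils, c(size, size), seed = seed)
  plan <- design_plan(protocol, R = R, ny = size, mode = mode, seed = seed)
  ds <- simulate_acquisition(phantom, protocol, coils, plan, phase = phase,
                             snr = snr, seed = seed)
  list(protocol = protocol, phantom = phantom, coils = coils, plan = plan,
       dataset = ds)
}
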