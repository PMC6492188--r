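#' q-space neighborhood graph
#'
#' Builds the graph used to assign k-space sampling patterns across
#' q-space: each q-space point is a vertex, and an edge connects two
#' points whenever one belongs to the other's neighborhood, defined as
#' the point itself plus its `R_total - 1` angular nearest neighbors
#' (ties broken by index order).  The edge set is symmetrized, so every
#' vertex has degree at least `R_total - 1`.
#'
#' @param protocol a [qspace_protocol()].
#' @param R_total number of available sampling patterns (neighborhood
#'   size).
#' @return object of class `kq_graph`: list with `n`, `edges` (2-column
#'   matrix of index pairs, `i < j`), `adjacency` (list of neighbor index
#'   vectors), and `R_total`.
#' @export
build_graph <- function(protocol, R_total) {
  nd <- nrow(protocol$directions)
  if (nd < R_total)
    stop("need at least R_total = ", R_total, " q-space points, got ", nd)
  edges <- matrix(integer(0), 0, 2)
  if (R_total > 1L) {
    th <- angular_distance_matrix(protocol)
    diag(th) <- Inf
    k <- R_total - 1L
    ee <- vector("list", nd)
    for (i in seq_len(nd)) {
      nn <- order(th[i, ])[seq_len(k)]   # order() breaks ties by index
      ee[[i]] <- cbind(pmin(i, nn), pmax(i, nn))
    }
    edges <- unique(do.call(rbind, ee))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  adj <- rep(list(integer(0)), nd)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  structure(list(n = nd, edges = edges, adjacency = adj,
                 R_total = as.integer(R_total)),
            class = "kq_graph")
}

#' @export
print.kq_graph <- function(x, ...) {
  cat("q-space neighborhood graph:", x$n, "vertices,", nrow(x$edges),
      "edges (R_total =", x$R_total, ")\n")
  invisible(x)
}

#' Greedy graph coloring with conflict-minimizing fallback
#'
#' Visits vertices in the given order and assigns each the lowest color in
#' `0 .. R_total - 1` not used by an already-colored neighbor.  If all
#' colors are blocked (the graph may need more than `R_total` colors),
#' the color least used among the neighbors is assigned and the conflict
#' is recorded, so an assignment is always produced.
#'
#' @param graph a [build_graph()] result.
#' @param R_total number of colors available.
#' @param order integer permutation of the vertices giving the visiting
#'   order; defaults to descending degree (Welsh-Powell style).
#' @return integer vector of colors in `0 .. R_total - 1`, with attribute
#'   `"conflicts"`: the number of edges whose endpoints share a color.
#' @export
greedy_color <- function(graph, R_total = graph$R_total, order = NULL) {
  n <- graph$n
  deg <- lengths(graph$adjacency)
  if (is.null(order)) order <- order(-deg, seq_len(n))
  if (!identical(sort(order), seq_len(n)))
    stop("'order' must be a permutation of the vertices")
  color <- rep(NA_integer_, n)
  for (v in order) {
    used <- color[graph$adjacency[[v]]]
    used <- used[!is.na(used)]
    free <- setdiff(0:(R_total - 1L), used)
    if (length(free)) {
      color[v] <- free[1L]
    } else {
      cnt <- tabulate(used + 1L, nbins = R_total)
      color[v] <- which.min(cnt) - 1L     # least used; ties -> lowest
    }
  }
  conflicts <- if (nrow(graph$edges))
    sum(color[graph$edges[, 1]] == color[graph$edges[, 2]]) else 0L
  attr(color, "conflicts") <- conflicts
  color
}

#' Design a k-q sampling plan
#'
#' Composes pattern enumeration, q-space neighborhood graph construction
#' and greedy coloring into a per-volume sampling-pattern assignment: in
#' `"variable"` mode no two q-space points within a local neighborhood
#' share a pattern (when a conflict-free coloring is found); `"fixed"`
#' mode assigns pattern 0 to every volume (the conventional scheme, kept
#' as a control).
#'
#' @param protocol a [qspace_protocol()].
#' @param R in-plane undersampling factor.
#' @param MB multiband factor.
#' @param fov_shift_fraction CAIPI interslice image shift fraction.
#' @param ny,nz k-space grid sizes for the generated patterns.
#' @param mode `"variable"` or `"fixed"`.
#' @param order_strategy `"degree"` (Welsh-Powell descending degree) or
#'   `"random"` (seeded random order).
#' @param neighborhood_size size of the q-space neighborhood used to
#'   build the coloring graph; defaults to the total number of patterns
#'   (`R * MB` for SMS designs).  Set to `R` to restrict neighborhoods
#'   to the in-plane factor only.
#' @param seed integer seed (used by the random order strategy).
#' @return object of class `kq_plan`: list with `pattern_id` (0-based,
#'   one per volume), `patterns`, `R`, `MB`, `fov_shift_fraction`,
#'   `conflicts`, `mode`, `order_strategy`, `seed`.
#' @export
design_plan <- function(protocol, R, MB = 1L, fov_shift_fraction = 0,
                        ny, nz = MB, mode = c("variable", "fixed"),
                        order_strategy = c("degree", "random"),
                        neighborhood_size = NULL, seed = 1L) {
  mode <- match.arg(mode)
  order_strategy <- match.arg(order_strategy)
  patterns <- shifted_patterns(R, MB, fov_shift_fraction, ny, nz)
  R_total <- length(patterns)
  if (is.null(neighborhood_size)) neighborhood_size <- R_total
  nd <- nrow(protocol$directions)
  if (mode == "fixed") {
    ids <- rep(0L, nd)
    conflicts <- NA_integer_
    graph <- NULL
  } else {
    graph <- build_graph(protocol, neighborhood_size)
    ord <- if (order_strategy == "random") {
      set.seed(as.integer(seed) %% .Machine$integer.max)
      sample.int(nd)
    } else NULL
    ids <- greedy_color(graph, R_total, order = ord)
    conflicts <- attr(ids, "conflicts")
    attributes(ids) <- NULL
  }
  structure(list(pattern_id = as.integer(ids), patterns = patterns,
                 R = as.integer(R), MB = as.integer(MB),
                 fov_shift_fraction = fov_shift_fraction,
                 conflicts = conflicts, mode = mode,
                 order_strategy = order_strategy, seed = as.integer(seed),
                 graph = graph),
            class = "kq_plan")
}

#' @export
print.kq_plan <- function(x, ...) {
  cat("k-q sampling plan:", length(x$pattern_id), "volumes,",
      length(x$patterns), "patterns (R =", x$R, ", MB =", x$MB, ")\n")
  cat("  mode:", x$mode,
      if (!is.na(x$conflicts)) paste0("; coloring conflicts: ", x$conflicts),
      "\n")
  invisible(x)
}

#' Audit a plan's q-space neighborhoods for pattern repeats
#'
#' For every q-space point, counts how often its own sampling pattern
#' reappears among its `R_total - 1` angular nearest neighbors — the
#' property a conflict-free coloring guarantees (each point's pattern is
#' unique within its own neighborhood; two neighbors of a point that are
#' not neighbors of each other may legitimately share a pattern).
#'
#' @param plan a [kq_plan()].
#' @param protocol the [qspace_protocol()] the plan was designed for.
#' @return integer: total number of centre-pattern repeats; 0 for any
#'   conflict-free coloring.
#' @export
audit_plan_neighborhoods <- function(plan, protocol) {
  R_total <- length(plan$patterns)
  th <- angular_distance_matrix(protocol)
  diag(th) <- Inf
  reps <- 0L
  for (i in seq_len(nrow(th))) {
    nb <- order(th[i, ])[seq_len(R_total - 1L)]
    reps <- reps + sum(plan$pattern_id[nb] == plan$pattern_id[i])
  }
  reps
}

#' Read / write a k-q sampling plan as structured text
#'
#' The plan file is YAML: header fields (`R`, `MB`, `fov_shift_fraction`,
#' grid sizes, mode, seed, conflicts) plus the per-volume pattern id
#' table; pattern index lists are reconstructed from the shifts.
#'
#' @param plan a [kq_plan()].
#' @param path file path.
#' @export
write_kq_plan <- function(plan, path) {
  yaml::write_yaml(list(R = plan$R, MB = plan$MB,
                        fov_shift_fraction = plan$fov_shift_fraction,
                        ny = plan$patterns[[1]]$ny,
                        nz = plan$patterns[[1]]$nz,
                        mode = plan$mode,
                        order_strategy = plan$order_strategy,
                        seed = plan$seed,
                        conflicts = if (is.na(plan$conflicts)) -1L
                                    else plan$conflicts,
                        pattern_id = plan$pattern_id), path,
                   precision = 15L)
  invisible(path)
}

#' @rdname write_kq_plan
#' @export
read_kq_plan <- function(path) {
  s <- yaml::read_yaml(path)
  for (f in c("R", "MB", "fov_shift_fraction", "ny", "nz", "mode",
              "pattern_id"))
    if (is.null(s[[f]])) stop("plan file '", path,
                              "' is missing field '", f, "'")
  patterns <- shifted_patterns(s$R, s$MB, s$fov_shift_fraction, s$ny, s$nz)
  ids <- as.integer(s$pattern_id)
  if (any(ids < 0L) || any(ids >= length(patterns)))
    stop("plan file '", path, "': pattern_id out of range")
  structure(list(pattern_id = ids, patterns = patterns,
                 R = as.integer(s$R), MB = as.integer(s$MB),
                 fov_shift_fraction = s$fov_shift_fraction,
                 conflicts = if (identical(s$conflicts, -1L)) NA_integer_
                             else as.integer(s$conflicts),
                 mode = s$mode,
                 order_strategy = if (is.null(s$order_strategy)) "degree"
                                  else s$order_strategy,
                 seed = if (is.null(s$seed)) NA_integer_
                        else as.integer(s$seed),
                 graph = NULL),
            class = "kq_plan")
}
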