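test_that("shifted pattern enumeration covers all ky/kz shift combinations", {
  p3 <- shifted_patterns(3, 1, 0, ny = 12)
  expect_length(p3, 3L)
  expect_equal(vapply(p3, function(p) p$ky_shift, integer(1)), 0:2)
  expect_equal(unique(vapply(p3, function(p) length(p$idx), integer(1))), 4L)
  p1 <- shifted_patterns(1, 1, 0, ny = 12)
  expect_length(p1, 1L)
  expect_equal(length(p1[[1]]$idx), 12L)    # full sampling
  p6 <- shifted_patterns(2, 3, 1 / 3, ny = 12, nz = 3)
  expect_length(p6, 6L)
  key <- vapply(p6, function(p) paste(p$ky_shift, p$kz_shift), character(1))
  expect_equal(sort(key), sort(as.vector(outer(0:1, 0:2, paste))))
})

test_that("neighborhood graph connects angular nearest neighbors", {
  ## R_total = 1: no edges
  p <- tiny_protocol(6)
  g1 <- build_graph(p, 1)
  expect_equal(nrow(g1$edges), 0L)
  ## 4 points on a great circle, R_total = 2: each links its closest
  ang <- c(0, 0.3, 1.4, 1.6)
  gc <- qspace_protocol(cbind(cos(ang), sin(ang), 0), 1000)
  g2 <- build_graph(gc, 2)
  expect_equal(g2$adjacency[[1]], 2L)
  expect_equal(g2$adjacency[[2]], 1L)
  expect_equal(g2$adjacency[[3]], 4L)
  expect_equal(g2$adjacency[[4]], 3L)
  ## degree invariant and error on too-few points
  g3 <- build_graph(tiny_protocol(20), 4)
  expect_true(all(lengths(g3$adjacency) >= 3L))
  expect_error(build_graph(tiny_protocol(3), 4), "at least")
})

test_that("greedy coloring handles cliques, empty graphs and records conflicts", {
  ## complete graph on R_total vertices: all colors used, no conflicts
  p <- tiny_protocol(4)
  g <- build_graph(p, 4)              # neighborhood = everything
  col <- greedy_color(g, 4)
  expect_setequal(col, 0:3)
  expect_equal(attr(col, "conflicts"), 0L)
  ## empty edge set: everything color 0
  g0 <- build_graph(tiny_protocol(5), 1)
  expect_true(all(greedy_color(g0, 1) == 0L))
  ## fallback: clique larger than the palette cannot be conflict-free
  g5 <- build_graph(tiny_protocol(5), 5)
  col2 <- greedy_color(g5, 3)
  expect_true(all(col2 %in% 0:2))
  expect_gt(attr(col2, "conflicts"), 0L)
})

test_that("greedy conflicts match the brute-force minimum on small graphs", {
  set.seed(42)
  for (trial in 1:6) {
    n <- sample(6:9, 1)
    Rt <- sample(2:3, 1)
    p <- qspace_protocol(qspace_directions(n, seed = trial * 11), 1000)
    g <- build_graph(p, Rt)
    col <- greedy_color(g, Rt)
    expect_equal(attr(col, "conflicts"), brute_min_conflicts(g, Rt),
                 info = sprintf("trial %d (n=%d, R=%d)", trial, n, Rt))
  }
})

test_that("design_plan composes, audits clean, and is rotation invariant", {
  p <- qspace_protocol(qspace_directions(64, seed = 3), 1000)
  plan <- design_plan(p, R = 6, ny = 48, seed = 1)
  expect_length(plan$pattern_id, 64L)
  expect_true(all(plan$pattern_id %in% 0:5))
  if (plan$conflicts == 0L)
    expect_equal(audit_plan_neighborhoods(plan, p), 0L)
  ## fixed mode: every volume pattern 0
  pf <- design_plan(p, R = 6, ny = 48, mode = "fixed")
  expect_true(all(pf$pattern_id == 0L))
  ## invariance under a global rotation of the direction set
  th <- 0.41
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  prot <- qspace_protocol(p$directions %*% t(Rz), 1000)
  plan_rot <- design_plan(prot, R = 6, ny = 48, seed = 1)
  expect_identical(plan_rot$pattern_id, plan$pattern_id)
})

test_that("conflicts do not increase as more patterns become available", {
  for (seed in 1:3) {
    p <- qspace_protocol(qspace_directions(40, seed = seed), 1000)
    conf <- vapply(2:6, function(Rt)
      attr(greedy_color(build_graph(p, Rt), Rt), "conflicts"), integer(1))
    expect_true(all(diff(conf) <= 0L) || all(conf == 0L))
  }
})

test_that("plans serialize to text and round-trip losslessly", {
  p <- qspace_protocol(qspace_directions(24, seed = 2), 1000)
  plan <- design_plan(p, R = 2, MB = 3, fov_shift_fraction = 1 / 6,
                      ny = 12, nz = 3, seed = 4)
  f <- tempfile(fileext = ".yaml")
  write_kq_plan(plan, f)
  plan2 <- read_kq_plan(f)
  expect_identical(plan2$pattern_id, plan$pattern_id)
  expect_identical(plan2$R, plan$R)
  expect_identical(plan2$MB, plan$MB)
  expect_equal(plan2$fov_shift_fraction, plan$fov_shift_fraction)
  expect_identical(plan2$conflicts, plan$conflicts)
  expect_equal(lapply(plan2$patterns, `[[`, "idx"),
               lapply(plan$patterns, `[[`, "idx"))
  unlink(f)
  ## malformed file errors with the offending field named
  yaml::write_yaml(list(R = 2, MB = 3), f)
  expect_error(read_kq_plan(f), "fov_shift_fraction")
  unlink(f)
  ## pattern serialization round trip
  f2 <- tempfile(fileext = ".yaml")
  write_sampling_pattern(plan$patterns[[4]], f2)
  expect_equal(read_sampling_pattern(f2)$idx, plan$patterns[[4]]$idx)
  unlink(f2)
})
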