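test_that("Voronoi cell areas tile the domain in both geometries", {
  g2 <- plane_geometry()
  v <- voronoi_cells(uniform_pattern(600, g2, seed = 3), g2)
  expect_equal(sum(v$areas), g2$A_m, tolerance = 1e-4)
  expect_true(all(v$areas > 0))

  g3 <- sphere_geometry()
  v3 <- voronoi_cells(uniform_pattern(400, g3, seed = 3), g3)
  expect_equal(sum(v3$areas), 4 * pi * g3$R^2, tolerance = 1e-6)
  expect_false(anyNA(v3$areas))
})

test_that("periodic 2D cell areas agree with an independent tessellation", {
  skip_if_not_installed("spatstat.geom")
  g2 <- plane_geometry()
  pts <- uniform_pattern(500, g2, seed = 4)
  v <- voronoi_cells(pts, g2)
  X <- spatstat.geom::ppp(pts[, 1], pts[, 2],
    window = spatstat.geom::owin(c(0, g2$L), c(0, g2$L))
  )
  da <- spatstat.geom::dirichletAreas(X)
  # interior cells are unaffected by the boundary treatment
  interior <- pts[, 1] > 1.2 & pts[, 1] < g2$L - 1.2 &
    pts[, 2] > 1.2 & pts[, 2] < g2$L - 1.2
  expect_equal(v$areas[interior], da[interior], tolerance = 1e-6)
})

test_that("threshold calibration separates clustered from uniform polygons", {
  g2 <- plane_geometry()
  fx <- planted_cluster_fixture(seed = 7)
  thr <- calibrate_threshold(fx$points, g2, n_controls = 20, seed = 11)
  # threshold sits between the tight-cluster polygon scale (~sigma^2) and
  # the uniform polygon scale A/N
  expect_gt(thr$size_threshold, 1e-4)
  expect_lt(thr$size_threshold, g2$A_m / nrow(fx$points))
  # deterministic under a fixed seed
  thr2 <- calibrate_threshold(fx$points, g2, n_controls = 20, seed = 11)
  expect_identical(thr$size_threshold, thr2$size_threshold)
})

test_that("planted clusters are recovered with high precision and recall", {
  g2 <- plane_geometry()
  fx <- planted_cluster_fixture(seed = 7)
  thr <- calibrate_threshold(fx$points, g2, n_controls = 20, seed = 11)
  cl <- detect_clusters(fx$points, thr, g2)
  expect_equal(length(cl$clusters), 2)
  for (k in seq_along(cl$clusters)) {
    mem <- cl$clusters[[k]]$members
    planted <- fx$labels[mem]
    major <- as.integer(names(which.max(table(planted))))
    expect_gt(major, 0)
    precision <- mean(planted == major)
    recall <- sum(planted == major) / sum(fx$labels == major)
    expect_gte(precision, 0.9)
    expect_gte(recall, 0.9)
    # centroid lands on the planted center
    ctr <- fx$centers[[major]]
    expect_lt(sqrt(sum((cl$clusters[[k]]$centroid - ctr)^2)), 0.3)
  }

  # uniform negative control yields no clusters
  u <- uniform_pattern(nrow(fx$points), g2, seed = 12)
  expect_equal(length(detect_clusters(u, thr, g2)$clusters), 0)

  # count filter removes small groups
  cl_strict <- detect_clusters(fx$points, thr, g2, count_min = 400)
  expect_equal(length(cl_strict$clusters), 0)

  # fewer than 3 points: empty result with a warning
  expect_warning(
    c0 <- detect_clusters(fx$points[1:2, ], thr, g2),
    "fewer than 3"
  )
  expect_equal(length(c0$clusters), 0)
})

test_that("detection is invariant under rigid motion and id relabeling", {
  g2 <- plane_geometry()
  fx <- planted_cluster_fixture(seed = 9)
  thr <- calibrate_threshold(fx$points, g2, n_controls = 15, seed = 3)
  cl_a <- detect_clusters(fx$points, thr, g2)
  shifted <- (fx$points + 1.77) %% g2$L
  cl_b <- detect_clusters(shifted, thr, g2)
  expect_equal(length(cl_a$clusters), length(cl_b$clusters))
  sizes <- function(cl) sort(vapply(cl$clusters, `[[`, 0L, "n_molecules"))
  expect_equal(sizes(cl_a), sizes(cl_b))

  perm <- sample(nrow(fx$points))
  cl_c <- detect_clusters(fx$points[perm, ], thr, g2)
  expect_equal(sizes(cl_a), sizes(cl_c))
})

test_that("spherical planted clusters are detected on the sphere", {
  g3 <- sphere_geometry()
  fx <- planted_cluster_fixture(seed = 21, geometry = g3)
  thr <- calibrate_threshold(fx$points, g3, n_controls = 15, seed = 5)
  cl <- detect_clusters(fx$points, thr, g3)
  expect_equal(length(cl$clusters), 2)
  u <- uniform_pattern(nrow(fx$points), g3, seed = 6)
  expect_equal(length(detect_clusters(u, thr, g3)$clusters), 0)
})

test_that("state statistics match hand-counted values", {
  s <- data.frame(
    t = c(0, 10, 20, 30, 40),
    state = factor(c("0", "1", "1", "2+", "1"), levels = c("0", "1", "2+"))
  )
  st <- state_statistics(s)
  expect_equal(as.numeric(st$occupancy), c(0.2, 0.6, 0.2))
  expect_equal(st$transitions["0", "1"], 1)
  expect_equal(st$transitions["1", "1"], 0.5)
  expect_equal(st$transitions["1", "2+"], 0.5)
  expect_equal(st$transitions["2+", "1"], 1)
  # dwell times sum to the total time spent per state
  expect_equal(sum(st$dwell[["1"]]), 30)

  const <- data.frame(
    t = seq(0, 100, 10),
    state = factor(rep("1", 11), levels = c("0", "1", "2+"))
  )
  stc <- state_statistics(const)
  expect_equal(as.numeric(stc$occupancy[["1"]]), 1)
  expect_true(all(is.na(stc$transitions["0", ])))
  expect_equal(stc$dwell[["1"]], 110)

  # occupancies always sum to one; rows with observed exits are stochastic
  expect_equal(sum(st$occupancy), 1)
  rs <- rowSums(st$transitions)
  expect_equal(unname(rs[!is.na(rs)]), rep(1, sum(!is.na(rs))))
})

test_that("resampling to 120-s intervals mimics experimental scoring", {
  tm <- matrix(c(
    0.9, 0.1, 0,
    0.05, 0.9, 0.05,
    0, 0.2, 0.8
  ), 3, byrow = TRUE)
  s <- experimental_like_count_series(24000, 10, tm, init = "1", seed = 13)
  st_native <- state_statistics(s)
  st_coarse <- state_statistics(s, resample_interval = 120)
  expect_equal(st_coarse$interval, 120)
  expect_equal(st_coarse$n, floor((nrow(s) - 1) / 12) + 1)
  # occupancy is sampling-rate independent (same underlying path)
  expect_equal(
    as.numeric(st_coarse$occupancy), as.numeric(st_native$occupancy),
    tolerance = 0.1
  )
})

test_that("count series round-trip through tabular text", {
  tm <- diag(3)
  s <- experimental_like_count_series(1200, 120, tm, init = "2+", seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(s[, c("t", "n_clusters")], f,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  back <- read_count_series(f)
  expect_equal(back$state, s$state)
})
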