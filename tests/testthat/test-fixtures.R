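test_that("uniform patterns have exact counts and uniform statistics", {
  g2 <- plane_geometry()
  pts <- uniform_pattern(3000, g2, seed = 1)
  expect_equal(nrow(pts), 3000)
  expect_true(all(pts >= 0 & pts < g2$L))

  # mean nearest-neighbor distance of a Poisson process: 0.5 / sqrt(n / A)
  nn <- vapply(seq_len(500), function(i) {
    d2 <- (pts[i, 1] - pts[-i, 1])^2 + (pts[i, 2] - pts[-i, 2])^2
    sqrt(min(d2))
  }, numeric(1))
  expected <- 0.5 / sqrt(3000 / g2$A_m)
  se <- 0.5 * expected / sqrt(500) # approximate spread of the mean
  expect_lt(abs(mean(nn) - expected), 4 * se)

  # sphere: z-coordinate uniform on [-R, R] (Archimedes' hat-box)
  g3 <- sphere_geometry()
  p3 <- uniform_pattern(2000, g3, seed = 2)
  expect_equal(sqrt(rowSums(p3^2)), rep(g3$R, 2000), tolerance = 1e-9)
  ks <- suppressWarnings(ks.test(p3[, 3], "punif", -g3$R, g3$R))
  expect_gt(ks$p.value, 0.01)

  # cytosolic: radius^3 uniform in the ball
  pc <- uniform_pattern(2000, g3, compartment = "cytosol", seed = 3)
  r3 <- rowSums(pc^2)^(3 / 2)
  ks2 <- suppressWarnings(ks.test(r3, "punif", 0, g3$R^3))
  expect_gt(ks2$p.value, 0.01)

  expect_equal(nrow(uniform_pattern(0, g2)), 0)
})

test_that("uniform generators pass a chi-squared bin-occupancy check", {
  g2 <- plane_geometry()
  pvals <- vapply(1:10, function(s) {
    pts <- uniform_pattern(2000, g2, seed = 100 + s)
    bins <- table(
      cut(pts[, 1], seq(0, g2$L, length.out = 5)),
      cut(pts[, 2], seq(0, g2$L, length.out = 5))
    )
    suppressWarnings(chisq.test(as.vector(bins)))$p.value
  }, numeric(1))
  # aggregate uniformity: p-values not collapsing to small values
  expect_gt(mean(pvals > 0.01), 0.7)
})

test_that("Gaussian cluster patterns realize the requested dispersion", {
  g2 <- plane_geometry()
  pts <- gaussian_cluster_pattern(3000, sigma = 0.2, geometry = g2, seed = 1)
  # per-axis sample sd within sampling error of 0.2
  se <- 0.2 / sqrt(2 * 3000)
  expect_lt(abs(sd(pts[, 1]) - 0.2), 4 * se)
  expect_lt(abs(sd(pts[, 2]) - 0.2), 4 * se)

  # sigma -> 0 collapses onto the center
  p0 <- gaussian_cluster_pattern(50, sigma = 0, geometry = g2, seed = 1)
  expect_true(all(abs(p0[, 1] - g2$L / 2) < 1e-12))

  # sphere variants stay on the sphere, tangent and vMF agree on spread
  g3 <- sphere_geometry()
  p3 <- gaussian_cluster_pattern(1000, sigma = 0.2, geometry = g3, seed = 4)
  expect_equal(sqrt(rowSums(p3^2)), rep(g3$R, 1000), tolerance = 1e-9)
  pv <- gaussian_cluster_pattern(1000,
    sigma = 0.2, geometry = g3,
    method = "vmf", seed = 5
  )
  ang <- function(m) acos(pmin(1, m[, 3] / g3$R))
  expect_equal(mean(ang(p3)) * g3$R, mean(ang(pv)) * g3$R, tolerance = 0.1)
})

test_that("generators are reproducible under a fixed seed", {
  g <- plane_geometry()
  expect_identical(
    uniform_pattern(100, g, seed = 9),
    uniform_pattern(100, g, seed = 9)
  )
  expect_identical(
    gaussian_cluster_pattern(100, sigma = 0.3, geometry = g, seed = 9),
    gaussian_cluster_pattern(100, sigma = 0.3, geometry = g, seed = 9)
  )
  # seeded calls do not disturb the caller's RNG stream
  set.seed(1)
  a <- runif(1)
  set.seed(1)
  invisible(uniform_pattern(10, g, seed = 5))
  expect_identical(runif(1), a)
})

test_that("fixed seed layouts are evenly spaced and sized correctly", {
  g <- plane_geometry()
  s <- fixed_seed_layout(15, g)
  expect_equal(nrow(s), 15)
  d <- sqrt((s[, 1] - g$L / 2)^2 + (s[, 2] - g$L / 2)^2)
  expect_equal(d, rep(g$L / 4, 15), tolerance = 1e-9)
  expect_equal(nrow(fixed_seed_layout(0, g)), 0)

  g3 <- sphere_geometry()
  s3 <- fixed_seed_layout(10, g3)
  expect_equal(sqrt(rowSums(s3^2)), rep(g3$R, 10), tolerance = 1e-9)

  ex <- matrix(c(1, 1, 7, 7), 2, byrow = TRUE)
  expect_identical(fixed_seed_layout(2, g, positions = ex), ex)
})

test_that("synthetic count series follow the requested Markov structure", {
  tm <- matrix(c(
    0.8, 0.2, 0,
    0.1, 0.8, 0.1,
    0, 0.3, 0.7
  ), 3, byrow = TRUE)
  s <- experimental_like_count_series(4000, 120, tm, init = "1", seed = 3)
  expect_equal(nrow(s), floor(4000 / 120) + 1) # 34 samples
  expect_identical(levels(s$state), c("0", "1", "2+"))
  expect_true(all(s$n_clusters %in% 0:2))

  # degenerate chain: constant series
  id3 <- diag(3)
  s1 <- experimental_like_count_series(1200, 120, id3, init = "1", seed = 1)
  expect_true(all(s1$state == "1"))

  # long series: state_statistics recovers the transition matrix
  long <- experimental_like_count_series(3e5, 100, tm, init = "1", seed = 8)
  st <- state_statistics(long)
  n_from <- table(factor(long$state[-nrow(long)], levels = c("0", "1", "2+")))
  for (i in 1:3) {
    for (j in 1:3) {
      phat <- st$transitions[i, j]
      p <- tm[i, j]
      se <- sqrt(p * (1 - p) / n_from[i])
      expect_lt(abs(phat - p), 4 * se + 1e-12)
    }
  }
})
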