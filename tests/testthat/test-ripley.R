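test_that("uniform patterns give K near zero in both geometries", {
  g2 <- plane_geometry()
  k2 <- vapply(1:50, function(s) {
    ripley_k(uniform_pattern(1000, g2, seed = s), g2)$K
  }, numeric(1))
  expect_lt(abs(mean(k2)), 3 * sd(k2) / sqrt(50) + 0.05)
  expect_true(all(abs(k2) < 0.3))

  g3 <- sphere_geometry()
  k3 <- vapply(1:50, function(s) {
    ripley_k(uniform_pattern(1000, g3, seed = s), g3)$K
  }, numeric(1))
  expect_lt(mean(k3), 1) # on the 0..78.5 scale of the sphere statistic
})

test_that("coincident points reach the closed-form K maximum", {
  g2 <- plane_geometry()
  # all pairs at distance ~0: CDF = 1 everywhere, K(r) = sqrt(A/pi) - r
  pm <- matrix(rep(c(4, 4), each = 60), ncol = 2) +
    1e-9 * matrix(rnorm(120), ncol = 2)
  kf <- ripley_k(pm, g2)
  expect_equal(kf$K, sqrt(g2$A_m / pi), tolerance = 0.01) # 5.0 for A = 78.54
  expect_equal(sqrt(g2$A_m / pi), 5, tolerance = 1e-4)

  g3 <- sphere_geometry()
  pm3 <- gaussian_cluster_pattern(60, sigma = 1e-6, geometry = g3, seed = 1)
  kf3 <- ripley_k(pm3, g3)
  expect_equal(kf3$K, 4 * pi * g3$R^2, tolerance = 0.01 * 78.54) # 78.54
})

test_that("grid-accumulated CDF equals the brute-force all-pairs computation", {
  g2 <- plane_geometry()
  set.seed(5)
  pts <- rbind(
    gaussian_cluster_pattern(100, c(2, 2), 0.3, g2),
    gaussian_cluster_pattern(100, c(7, 7), 0.3, g2)
  )
  kf <- ripley_k(pts, g2, nbins = 120)
  L <- g2$L
  dx <- abs(outer(pts[, 1], pts[, 1], "-"))
  dy <- abs(outer(pts[, 2], pts[, 2], "-"))
  dx <- pmin(dx, L - dx)
  dy <- pmin(dy, L - dy)
  dmi <- sqrt(dx^2 + dy^2)
  dmi <- dmi[row(dx) != col(dx)]
  cdf_bf <- vapply(kf$r, function(rr) mean(dmi <= rr), numeric(1))
  expect_equal(kf$cdf, cdf_bf, tolerance = 1e-12)
  # K value equals the formula applied to the brute-force CDF
  k_bf <- max(sqrt(g2$A_m / pi * cdf_bf) - kf$r, na.rm = TRUE)
  expect_equal(kf$K, max(k_bf), tolerance = 1e-9)

  # 3D: geodesic distances
  g3 <- sphere_geometry()
  p3 <- uniform_pattern(150, g3, seed = 6)
  kf3 <- ripley_k(p3, g3, nbins = 100)
  cosd <- tcrossprod(p3) / g3$R^2
  gd <- g3$R * acos(pmin(1, pmax(-1, cosd)))
  gd <- gd[row(cosd) != col(cosd)]
  cdf3 <- vapply(kf3$r, function(rr) mean(gd <= rr), numeric(1))
  expect_equal(kf3$cdf, cdf3, tolerance = 1e-12)
})

test_that("P integrates to one and K is invariant under rigid motions", {
  g2 <- plane_geometry()
  pts <- gaussian_cluster_pattern(300, c(3, 3), 0.5, g2, seed = 2)
  kf <- ripley_k(pts, g2)
  expect_equal(sum(kf$P_density * diff(c(0, kf$r))), 1, tolerance = 1e-12)

  shifted <- (pts + 2.34) %% g2$L # periodic translation
  expect_equal(ripley_k(shifted, g2)$K, kf$K, tolerance = 1e-9)

  g3 <- sphere_geometry()
  p3 <- gaussian_cluster_pattern(200, sigma = 0.4, geometry = g3, seed = 3)
  th <- 1.1
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  expect_equal(
    ripley_k(p3 %*% rot, g3)$K, ripley_k(p3, g3)$K,
    tolerance = 1e-9
  )
})

test_that("K decreases monotonically with cluster dispersion", {
  g2 <- plane_geometry()
  sigmas <- c(0.05, 0.1, 0.2, 0.5, 1.0)
  kmean <- vapply(sigmas, function(s) {
    mean(vapply(1:20, function(r) {
      ripley_k(
        gaussian_cluster_pattern(400, sigma = s, geometry = g2, seed = 1000 * s + r),
        g2
      )$K
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(kmean) < 0))
  expect_gt(kmean[3], 3) # sigma = 0.2 cluster is on the stable-polarity scale
})

test_that("the literal 2D normalization reproduces its analytic uniform bias", {
  # applied to a uniform pattern the printed formula gives r^2 - r, not 0
  g2 <- plane_geometry()
  pts <- uniform_pattern(4000, g2, seed = 11)
  kl <- ripley_k(pts, g2, mode = "literal")
  sel <- !is.na(kl$K_of_r) & kl$r > 0.5
  expect_equal(
    kl$K_of_r[sel], kl$r[sel]^2 - kl$r[sel],
    tolerance = 0.08
  )
  expect_gt(kl$K, 3) # the bias alone crosses the polarity thresholds
})

test_that("degenerate inputs and state classification behave as specified", {
  g2 <- plane_geometry()
  expect_warning(k0 <- ripley_k(matrix(c(1, 1), 1), g2), "fewer than 2")
  expect_equal(k0$K, 0)

  expect_equal(as.character(classify_polarity(1.2, "plane2d")), "unpolarized")
  expect_equal(as.character(classify_polarity(1.5, "plane2d")), "polarized")
  expect_equal(as.character(classify_polarity(3, "plane2d")), "stable")
  expect_equal(as.character(classify_polarity(29.9, "sphere3d")), "unpolarized")
  expect_equal(as.character(classify_polarity(30, "sphere3d")), "polarized")
  expect_equal(as.character(classify_polarity(50, "sphere3d")), "stable")
})

test_that("window summaries of K series are computed correctly", {
  kser <- data.frame(t = seq(0, 4000, 10), K = 2)
  expect_equal(fraction_time_polarized(kser), 1)
  kser$K <- rep(c(1, 2), length.out = nrow(kser))
  expect_equal(fraction_time_polarized(kser), 0.5, tolerance = 0.01)

  ks2 <- data.frame(t = c(0, 10, 20, 30), K = c(0.5, 1.0, 3.2, 3.5))
  expect_equal(time_to_threshold(ks2, 3), 20)
  expect_true(is.na(time_to_threshold(ks2, 10)))
  # persistence window: a blip does not count
  ks3 <- data.frame(t = seq(0, 50, 10), K = c(0.5, 3.5, 0.5, 3.2, 3.3, 3.4))
  expect_equal(time_to_threshold(ks3, 3, hold = 20), 30)

  dall <- delta_statistic(data.frame(t = seq(2000, 4000, 10), K = 2),
    window = c(2000, 4000)
  )
  expect_equal(dall$delta_frac, 1)
  dhalf <- delta_statistic(
    data.frame(t = seq(2000, 4000, 10), K = rep(c(1, 2), length.out = 201)),
    window = c(2000, 4000)
  )
  expect_lt(abs(dhalf$delta_frac), 0.01)
})

test_that("regime scan recovers a known logistic and its boundaries", {
  alpha <- 0.85
  b_true <- 0.25
  c_true <- 100
  nsamp <- 200
  x <- seq(70, 130, by = 10)
  set.seed(42)
  kser_by_x <- lapply(x, function(xx) {
    lapply(1:5, function(r) {
      # per-run polarized fraction from the logistic plus binomial noise
      pfrac <- 1 / (1 + exp(-b_true * (xx - c_true)))
      npol <- rbinom(1, nsamp, pfrac)
      data.frame(
        t = seq(10, nsamp * 10, 10),
        K = rep(c(2, 1), c(npol, nsamp - npol))
      )
    })
  })
  sc <- regime_scan(kser_by_x, x, alpha = alpha, window = c(0, Inf))
  expect_equal(sc$logistic_b, b_true, tolerance = 0.2)
  expect_equal(sc$logistic_c, c_true, tolerance = 0.03)

  # boundary formula against brute-force root finding on the fitted curve
  f <- function(xx) {
    (2 * sc$n_samples / (1 + exp(-sc$logistic_b * (xx - sc$logistic_c))) -
      sc$n_samples) / sc$n_samples
  }
  root_lo <- uniroot(function(z) f(z) + alpha, c(0, sc$logistic_c))$root
  root_hi <- uniroot(function(z) f(z) - alpha, c(sc$logistic_c, 300))$root
  expect_equal(sc$boundary_lower, root_lo, tolerance = 1e-6)
  expect_equal(sc$boundary_upper, root_hi, tolerance = 1e-6)

  # extreme levels classify as pure regimes, middle as transient
  reg <- sc$summary$regime[order(sc$summary$x)]
  expect_equal(reg[1], "unpolarized")
  expect_equal(reg[length(reg)], "polarized")
  expect_true("transient" %in% reg)
})
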