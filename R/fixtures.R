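#' Synthetic point patterns
#'
#' Generators for all point patterns the pipeline needs: uniform patterns on
#' the periodic square or sphere (negative controls and initial conditions),
#' Gaussian clusters of stated dispersion (pre-polarized initial conditions,
#' planted ground truth for cluster detection), and fixed seed layouts.
#' Coordinates are returned as a matrix with columns `x, y` (plane) or
#' `x, y, z` (sphere).
#'
#' @param n Number of points.
#' @param geometry A [plane_geometry()] or [sphere_geometry()].
#' @param compartment `"membrane"` (default) places sphere points on the
#'   surface; `"cytosol"` places them uniformly inside the ball. Ignored for
#'   the plane, where both compartments share the periodic square.
#' @param seed Optional RNG seed (an integer); when supplied the generator is
#'   reproducible and the caller's RNG state is untouched.
#' @return Numeric matrix of coordinates, one row per point.
#' @examples
#' pts <- uniform_pattern(100, plane_geometry(), seed = 1)
#' @export
uniform_pattern <- function(n, geometry = plane_geometry(),
                            compartment = "membrane", seed = NULL) {
  assert_geometry(geometry)
  stopifnot(n >= 0)
  with_seed(seed, {
    if (is_plane(geometry)) {
      cbind(x = runif(n, 0, geometry$L), y = runif(n, 0, geometry$L))
    } else if (compartment == "membrane") {
      p <- matrix(rnorm(3 * n), ncol = 3)
      r <- sqrt(rowSums(p^2))
      r[r == 0] <- 1
      p <- p / r * geometry$R
      colnames(p) <- c("x", "y", "z")
      p
    } else {
      # uniform in the ball: uniform direction, radius ~ R * U^(1/3)
      p <- matrix(rnorm(3 * n), ncol = 3)
      r <- sqrt(rowSums(p^2))
      r[r == 0] <- 1
      rad <- geometry$R * runif(n)^(1 / 3)
      p <- p / r * rad
      colnames(p) <- c("x", "y", "z")
      p
    }
  })
}

#' @rdname uniform_pattern
#' @param center Cluster center: length-2 (plane, defaults to the domain
#'   center) or length-3 (sphere, defaults to the north pole `(0, 0, R)`;
#'   projected onto the surface).
#' @param sigma Gaussian standard deviation per axis, um.
#' @param method Sphere clusters: `"tangent"` (Gaussian in the tangent plane
#'   at `center`, projected to the surface; the default) or `"vmf"`
#'   (von Mises-Fisher with concentration `(R / sigma)^2`).
#' @export
gaussian_cluster_pattern <- function(n, center = NULL, sigma = 0.2,
                                     geometry = plane_geometry(),
                                     method = c("tangent", "vmf"),
                                     seed = NULL) {
  assert_geometry(geometry)
  stopifnot(n >= 0, sigma >= 0)
  method <- match.arg(method)
  with_seed(seed, {
    if (is_plane(geometry)) {
      if (is.null(center)) center <- c(geometry$L / 2, geometry$L / 2)
      m <- cbind(
        x = rnorm(n, center[1], sigma) %% geometry$L,
        y = rnorm(n, center[2], sigma) %% geometry$L
      )
      m
    } else {
      R <- geometry$R
      if (is.null(center)) center <- c(0, 0, R)
      center <- center / sqrt(sum(center^2)) * R
      if (n == 0) {
        return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
      }
      if (method == "vmf" && sigma > 0) {
        p <- rvmf_sphere(n, center / R, kappa = (R / sigma)^2) * R
      } else if (sigma == 0) {
        p <- matrix(rep(center, each = n), ncol = 3)
      } else {
        # orthonormal tangent basis at center
        u <- center / R
        a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        e1 <- a - sum(a * u) * u
        e1 <- e1 / sqrt(sum(e1^2))
        e2 <- c(
          u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1]
        )
        d1 <- rnorm(n, 0, sigma)
        d2 <- rnorm(n, 0, sigma)
        p <- matrix(rep(center, each = n), ncol = 3) +
          outer(d1, e1) + outer(d2, e2)
        p <- p / sqrt(rowSums(p^2)) * R
      }
      colnames(p) <- c("x", "y", "z")
      p
    }
  })
}

# von Mises-Fisher sampler on the unit sphere (Wood 1994 rejection-free
# inversion for the polar angle about the mean direction mu).
rvmf_sphere <- function(n, mu, kappa) {
  u <- runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  theta <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  a <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * mu) * mu
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    mu[2] * e1[3] - mu[3] * e1[2],
    mu[3] * e1[1] - mu[1] * e1[3],
    mu[1] * e1[2] - mu[2] * e1[1]
  )
  outer(w, mu) + outer(s * cos(theta), e1) + outer(s * sin(theta), e2)
}

#' Fixed seed layouts for immobile membrane catalysts
#'
#' Positions for immobile Far1-GEF "seed" molecules used to visualize
#' competition between nucleated Cdc42 clusters. Default arrangement places
#' the seeds evenly: on a ring of radius `L / 4` about the domain center
#' (plane) or as a Fibonacci lattice (sphere).
#'
#' @param k Number of seeds.
#' @param geometry A [plane_geometry()] or [sphere_geometry()].
#' @param arrangement `"ring"`/`"fibonacci"` (default per geometry) or
#'   `"explicit"` with `positions` supplied.
#' @param positions Explicit coordinate matrix when `arrangement = "explicit"`.
#' @return Coordinate matrix, one row per seed.
#' @export
fixed_seed_layout <- function(k, geometry = plane_geometry(),
                              arrangement = NULL, positions = NULL) {
  assert_geometry(geometry)
  stopifnot(k >= 0)
  if (!is.null(positions)) {
    stopifnot(nrow(positions) == k)
    return(positions)
  }
  if (k == 0) {
    nc <- if (is_plane(geometry)) 2L else 3L
    return(matrix(numeric(0), ncol = nc))
  }
  if (is_plane(geometry)) {
    ang <- 2 * pi * (seq_len(k) - 1) / k
    r <- geometry$L / 4
    cbind(
      x = (geometry$L / 2 + r * cos(ang)) %% geometry$L,
      y = (geometry$L / 2 + r * sin(ang)) %% geometry$L
    )
  } else {
    # Fibonacci lattice: near-even coverage of the sphere
    i <- seq_len(k) - 0.5
    phi <- pi * (1 + sqrt(5)) * i
    z <- 1 - 2 * i / k
    s <- sqrt(pmax(0, 1 - z^2))
    geometry$R * cbind(x = s * cos(phi), y = s * sin(phi), z = z)
  }
}

#' Synthetic cluster-count series from a known Markov chain
#'
#' Generates a 0/1/2+ cluster-count time series from a specified Markov
#' chain, mimicking the structure of experimentally scored series (counts at
#' 120-s intervals). Used to exercise the cluster-dynamics statistics
#' end-to-end with known ground truth.
#'
#' @param duration Total duration, s.
#' @param interval Sampling interval, s (120 s matches experimental scoring).
#' @param transition Row-stochastic 3x3 matrix over states `0, 1, 2+`.
#' @param init Initial state distribution (length 3, sums to 1) or a single
#'   state label.
#' @param seed Optional RNG seed.
#' @return Data frame with columns `t`, `n_clusters` (0, 1, 2 meaning 2+),
#'   `state` (factor with levels `0`, `1`, `2+`).
#' @export
experimental_like_count_series <- function(duration, interval = 120,
                                           transition, init = c(1, 0, 0),
                                           seed = NULL) {
  stopifnot(duration > 0, interval > 0)
  transition <- as.matrix(transition)
  stopifnot(
    all(dim(transition) == c(3L, 3L)), all(transition >= 0),
    all(abs(rowSums(transition) - 1) < 1e-9)
  )
  states <- c("0", "1", "2+")
  times <- seq(0, duration, by = interval)
  with_seed(seed, {
    s <- integer(length(times))
    s[1] <- if (is.character(init) || length(init) == 1L) {
      match(as.character(init), states)
    } else {
      sample.int(3L, 1L, prob = init)
    }
    for (i in seq_along(times)[-1]) {
      s[i] <- sample.int(3L, 1L, prob = transition[s[i - 1L], ])
    }
    data.frame(
      t = times,
      n_clusters = c(0L, 1L, 2L)[s],
      state = factor(states[s], levels = states)
    )
  })
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
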