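#' Normalized Ripley's K polarity statistic
#'
#' Measures the deviation of a point pattern from spatial uniformity via the
#' cumulative distribution `P(r)` of pairwise distances, counting all
#' `N(N-1)` ordered pairs. With `CDF(r)` the integral of `P` up to `r`:
#'
#' * plane (periodic square, minimum-image distances):
#'   `K(r) = sqrt((A / pi) * CDF(r)) - r` (default `mode = "sqrt"`), which is
#'   identically 0 for a uniform pattern and reaches `sqrt(A / pi)` as all
#'   points merge. The unnormalized variant `(A / pi) * CDF(r) - r` is
#'   available as `mode = "literal"`.
#' * sphere (geodesic distances):
#'   `K(r) = 4 pi R^2 * CDF(r) - 2 pi R^2 (1 - cos(r / R))`, zero for a
#'   uniform pattern and approaching `4 pi R^2` at small `r` as points merge.
#'
#' The scalar polarity statistic `K` is the maximum of `K(r)` over the
#' distance grid (plane: up to `L / 2`, the minimum-image bound; sphere: up
#' to `pi R`, the geodesic bound).
#'
#' @param points Coordinate matrix (columns `x, y` on the plane or
#'   `x, y, z` on the sphere).
#' @param geometry A [plane_geometry()] or [sphere_geometry()].
#' @param nbins Number of distance bins.
#' @param mode Plane normalization, `"sqrt"` (default) or `"literal"`.
#' @return A `polar_kfun`: list with `r` (bin upper edges), `P_density`,
#'   `cdf`, `K_of_r`, scalar `K`, `N`, `geometry`, `mode`. For `N < 2`,
#'   `K = 0` with a warning.
#' @examples
#' pts <- uniform_pattern(500, plane_geometry(), seed = 1)
#' ripley_k(pts, plane_geometry())$K # near 0
#' @export
ripley_k <- function(points, geometry = plane_geometry(), nbins = 200,
                     mode = c("sqrt", "literal")) {
  assert_geometry(geometry)
  mode <- match.arg(mode)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) {
    warning("K is defined as 0 for fewer than 2 points")
    return(structure(
      list(
        r = numeric(0), P_density = numeric(0), cdf = numeric(0),
        K_of_r = numeric(0), K = 0, N = n, geometry = geometry, mode = mode
      ),
      class = "polar_kfun"
    ))
  }
  if (is_plane(geometry)) {
    # histogram covers the full minimum-image range (up to L/sqrt(2)) so
    # P integrates to 1; K is evaluated only up to the L/2 bound where the
    # uniform pair-distance CDF is exactly pi r^2 / A
    rk <- geometry$L / 2
    dr <- rk / nbins
    nb_full <- ceiling(geometry$L / sqrt(2) / dr) + 1L
    h <- .ps_pair_hist_2d(points, geometry$L, nb_full, nb_full * dr)
  } else {
    rk <- pi * geometry$R
    dr <- rk / nbins
    nb_full <- nbins
    h <- .ps_pair_hist_3d(points, geometry$R, nb_full, rk)
  }
  r <- seq_len(nb_full) * dr # bin upper edges
  npairs <- n * (n - 1)
  p_density <- h / npairs / dr
  cdf <- cumsum(h) / npairs
  if (is_plane(geometry)) {
    A <- geometry$A_m
    k_of_r <- if (mode == "sqrt") {
      sqrt(A / pi * cdf) - r
    } else {
      A / pi * cdf - r
    }
    k_of_r[r > rk] <- NA_real_
  } else {
    R <- geometry$R
    k_of_r <- 4 * pi * R^2 * cdf - 2 * pi * R^2 * (1 - cos(r / R))
  }
  structure(
    list(
      r = r, P_density = p_density, cdf = cdf, K_of_r = k_of_r,
      K = max(k_of_r, na.rm = TRUE), N = n, geometry = geometry, mode = mode
    ),
    class = "polar_kfun"
  )
}

#' @export
print.polar_kfun <- function(x, ...) {
  cat(sprintf(
    "<polar_kfun> N = %d on %s: K = %.3f\n", x$N, x$geometry$mode, x$K
  ))
  invisible(x)
}

#' Classify a K value into polarity states
#'
#' Thresholds: on the plane, `K < 1.5` unpolarized, `K >= 1.5` polarized,
#' `K >= 3` stable polarity; on the sphere, `K < 30` unpolarized,
#' `K >= 30` polarized, `K >= 50` stable. Boundaries are inclusive on the
#' polarized side.
#'
#' @param K Numeric vector of K values.
#' @param geometry_mode `"plane2d"` or `"sphere3d"`.
#' @return Factor with levels `unpolarized`, `polarized`, `stable`.
#' @export
classify_polarity <- function(K, geometry_mode = "plane2d") {
  th <- polarity_thresholds(geometry_mode)
  factor(
    ifelse(K >= th[2], "stable", ifelse(K >= th[1], "polarized", "unpolarized")),
    levels = c("unpolarized", "polarized", "stable")
  )
}

polarity_thresholds <- function(geometry_mode) {
  geometry_mode <- match.arg(geometry_mode, c("plane2d", "sphere3d"))
  if (geometry_mode == "plane2d") c(polarized = 1.5, stable = 3) else
    c(polarized = 30, stable = 50)
}

#' K-value time series of a trajectory
#'
#' Computes the scalar polarity statistic K on the recorded positions of the
#' active Cdc42 species for every snapshot.
#'
#' @param traj A `polar_trajectory`.
#' @param species Species whose positions are analyzed (default: active
#'   Cdc42, i.e. Cdc42-GTP free and in complex).
#' @param nbins,mode Passed to [ripley_k()].
#' @return Data frame with columns `t`, `K`, `state`.
#' @export
k_series <- function(traj, species = ACTIVE_CDC42_SPECIES, nbins = 200,
                     mode = "sqrt") {
  stopifnot(inherits(traj, "polar_trajectory"))
  geometry <- traj$params$geometry
  K <- vapply(seq_along(traj$times), function(i) {
    pts <- get_positions(traj, i, species = species)
    if (nrow(pts) < 2) return(0)
    ripley_k(pts, geometry, nbins = nbins, mode = mode)$K
  }, numeric(1))
  data.frame(
    t = traj$times, K = K,
    state = classify_polarity(K, geometry$mode)
  )
}

#' Fraction of time spent polarized
#'
#' Ratio of K values at or above the polarization threshold to the total
#' number of K values inside a time window (the window 2000-4000 s is used
#' to avoid initial transients at full scale).
#'
#' @param kser Data frame from [k_series()] (columns `t`, `K`).
#' @param window Length-2 time window, s.
#' @param threshold Polarization threshold (default 1.5, the plane value).
#' @return Fraction in `[0, 1]`.
#' @export
fraction_time_polarized <- function(kser, window = c(2000, 4000),
                                    threshold = 1.5) {
  keep <- kser$t >= window[1] & kser$t <= window[2]
  if (!any(keep)) stop("no K samples inside the requested window")
  mean(kser$K[keep] >= threshold)
}

#' First time the K series reaches a threshold
#'
#' @param kser Data frame from [k_series()].
#' @param threshold Threshold on K (3 marks stable polarity on the plane,
#'   50 on the sphere).
#' @param hold Require K to stay at or above the threshold for this long
#'   (s) from the crossing; 0 (default) takes the first crossing.
#' @return Crossing time in seconds, or `NA` if never reached.
#' @export
time_to_threshold <- function(kser, threshold, hold = 0) {
  above <- kser$K >= threshold
  if (hold > 0) {
    nhold <- max(1L, ceiling(hold / median(diff(kser$t))))
    ok <- vapply(seq_along(above), function(i) {
      j <- min(length(above), i + nhold - 1L)
      all(above[i:j])
    }, logical(1))
  } else {
    ok <- above
  }
  i <- which(ok)[1]
  if (is.na(i)) NA_real_ else kser$t[i]
}

#' Polarized-unpolarized balance of one run
#'
#' The difference between the number of polarized (`K >= threshold`) and
#' unpolarized (`K < threshold`) samples among the K values recorded in the
#' analysis window (by default the second half of the run, matching the
#' last-2000-s-of-4000-s convention).
#'
#' @param kser Data frame from [k_series()].
#' @param threshold Polarization threshold.
#' @param window Analysis window, s; `NULL` uses the second half of the run.
#' @return List with `delta`, `n` (number of samples), `delta_frac`.
#' @export
delta_statistic <- function(kser, threshold = 1.5, window = NULL) {
  if (is.null(window)) {
    window <- c(min(kser$t) + (max(kser$t) - min(kser$t)) / 2, max(kser$t))
  }
  k <- kser$K[kser$t >= window[1] & kser$t <= window[2]]
  if (!length(k)) stop("no K samples inside the analysis window")
  delta <- sum(k >= threshold) - sum(k < threshold)
  list(delta = delta, n = length(k), delta_frac = delta / length(k))
}

#' Polarity-regime scan over molecule abundance
#'
#' Classifies the polarity regime along an abundance axis from per-run
#' K-value series. For each run the balance statistic `delta` (see
#' [delta_statistic()]) is computed; the transient-polarity regime is
#' `|delta / N| <= alpha` with `alpha = 0.85`, large positive values are
#' polarized and large negative values unpolarized. The mean delta as a
#' function of abundance `x` is fitted with the logistic
#' `delta(x) = 2 N / (1 + exp(-b (x - c))) - N`, and the regime boundaries
#' are the abundances where `|delta(x) / N| = alpha`, i.e.
#' `x = c -/+ log((1 + alpha) / (1 - alpha)) / b`.
#'
#' @param kser_by_x List (one element per abundance level) of lists of
#'   [k_series()] data frames (one per replicate run).
#' @param x Numeric abundance levels, same length as `kser_by_x`.
#' @param alpha Transient-regime threshold on `|delta / N|`.
#' @param threshold Polarization threshold on K.
#' @param window Analysis window passed to [delta_statistic()].
#' @return A `polar_regime_scan`: per-level delta summaries and regimes,
#'   fitted `b` and `c`, and the unpolarized-transient and
#'   transient-polarized boundary abundances (`NA` if the fit fails).
#' @export
regime_scan <- function(kser_by_x, x, alpha = 0.85, threshold = 1.5,
                        window = NULL) {
  stopifnot(length(kser_by_x) == length(x), length(x) >= 2)
  per_level <- lapply(seq_along(x), function(i) {
    ds <- lapply(kser_by_x[[i]], delta_statistic,
      threshold = threshold, window = window
    )
    data.frame(
      x = x[i],
      delta = vapply(ds, `[[`, 0, "delta"),
      n = vapply(ds, `[[`, 0L, "n")
    )
  })
  runs <- do.call(rbind, per_level)
  agg <- do.call(rbind, lapply(split(runs, runs$x), function(d) {
    data.frame(
      x = d$x[1], delta_mean = mean(d$delta), n = round(mean(d$n)),
      delta_frac = mean(d$delta) / mean(d$n)
    )
  }))
  agg$regime <- ifelse(agg$delta_frac > alpha, "polarized",
    ifelse(agg$delta_frac < -alpha, "unpolarized", "transient")
  )

  nsamp <- stats::median(runs$n)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      delta_mean ~ 2 * nsamp / (1 + exp(-b * (x - cc))) - nsamp,
      data = agg,
      start = list(b = 0.1, cc = mean(range(agg$x)))
    ),
    error = function(e) NULL
  )
  b <- cc <- lower <- upper <- NA_real_
  if (!is.null(fit)) {
    b <- coef(fit)[["b"]]
    cc <- coef(fit)[["cc"]]
    shift <- log((1 + alpha) / (1 - alpha)) / b
    lower <- cc - shift # unpolarized -> transient boundary
    upper <- cc + shift # transient -> polarized boundary
  }
  structure(
    list(
      runs = runs, summary = agg, alpha = alpha, n_samples = nsamp,
      logistic_b = b, logistic_c = cc,
      boundary_lower = lower, boundary_upper = upper
    ),
    class = "polar_regime_scan"
  )
}

#' @export
print.polar_regime_scan <- function(x, ...) {
  cat("<polar_regime_scan>\n")
  print(x$summary, row.names = FALSE)
  if (!is.na(x$logistic_b)) {
    cat(sprintf(
      "logistic fit: b = %.4f, c = %.2f; transient regime %.1f .. %.1f\n",
      x$logistic_b, x$logistic_c, x$boundary_lower, x$boundary_upper
    ))
  } else {
    cat("logistic fit failed; boundaries undefined\n")
  }
  invisible(x)
}
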