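#' Voronoi tessellation of a point pattern
#'
#' Computes the Voronoi (Dirichlet) cell area of every point and the
#' Delaunay adjacency between points. On the periodic plane the tessellation
#' is made periodic by tiling: points within a margin of each border are
#' replicated into the neighboring images before tessellating, and only the
#' central-copy cells are kept (for small patterns the full 3x3 tiling is
#' used). On the sphere the spherical tessellation is computed from the
#' convex-hull Delaunay dual with geodesic polygon areas.
#'
#' @param points Coordinate matrix.
#' @param geometry A [plane_geometry()] or [sphere_geometry()].
#' @return List with `areas` (um^2 per point) and `edges` (2-column matrix
#'   of adjacent point indices).
#' @export
voronoi_cells <- function(points, geometry = plane_geometry()) {
  assert_geometry(geometry)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) stop("Voronoi tessellation needs at least 3 points")
  if (is_sphere(geometry)) {
    vor <- .ps_sphere_voronoi(points, geometry$R)
    return(list(areas = vor$areas, edges = vor$edges))
  }
  L <- geometry$L
  # margin wide enough that border cells see their true periodic neighbors
  margin <- min(L / 2, max(1, 5 * sqrt(geometry$A_m / n)))
  if (n < 20) margin <- L / 2 # full tiling for tiny patterns
  shifts <- expand.grid(sx = c(-L, 0, L), sy = c(-L, 0, L))
  shifts <- shifts[!(shifts$sx == 0 & shifts$sy == 0), ]
  ghost_x <- ghost_y <- numeric(0)
  ghost_id <- integer(0)
  for (k in seq_len(nrow(shifts))) {
    gx <- points[, 1] + shifts$sx[k]
    gy <- points[, 2] + shifts$sy[k]
    keep <- gx > -margin & gx < L + margin & gy > -margin & gy < L + margin
    ghost_x <- c(ghost_x, gx[keep])
    ghost_y <- c(ghost_y, gy[keep])
    ghost_id <- c(ghost_id, which(keep))
  }
  allx <- c(points[, 1], ghost_x)
  ally <- c(points[, 2], ghost_y)
  dd <- deldir::deldir(
    allx, ally,
    rw = c(-margin, L + margin, -margin, L + margin),
    suppressMsge = TRUE
  )
  areas <- dd$summary$dir.area[seq_len(n)]
  # Delaunay edges among originals (ghost edges mapped back to originals)
  owner <- c(seq_len(n), ghost_id)
  e1 <- owner[dd$delsgs$ind1]
  e2 <- owner[dd$delsgs$ind2]
  keep <- dd$delsgs$ind1 <= n | dd$delsgs$ind2 <= n
  e1 <- e1[keep]
  e2 <- e2[keep]
  swap <- e1 > e2
  tmp <- e1[swap]; e1[swap] <- e2[swap]; e2[swap] <- tmp
  edges <- unique(cbind(e1, e2))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  dimnames(edges) <- NULL
  list(areas = areas, edges = edges)
}

#' Calibrate the Voronoi polygon-size threshold from uniform controls
#'
#' Generates `n_controls` uniform patterns with the same molecule count and
#' geometry as the analyzed snapshots (the negative control), estimates the
#' probability densities of Voronoi polygon sizes for the controls and for
#' the snapshots on a common grid, and takes the size at which the two
#' densities intersect: below it polygons are denser than uniformity can
#' explain.
#'
#' @param snapshots A coordinate matrix, or a list of coordinate matrices
#'   (areas are pooled).
#' @param geometry A geometry object.
#' @param n_controls Number of uniform control realizations.
#' @param seed RNG seed for the controls.
#' @return A `polar_vthreshold`: `size_threshold` (um^2), the common
#'   `breaks`, `control_density`, `sample_density`, `n_controls`.
#' @export
calibrate_threshold <- function(snapshots, geometry = plane_geometry(),
                                n_controls = 50, seed = NULL) {
  if (is.matrix(snapshots) || is.data.frame(snapshots)) {
    snapshots <- list(as.matrix(snapshots))
  }
  if (!length(snapshots)) stop("no snapshots supplied")
  sample_areas <- unlist(lapply(snapshots, function(p) {
    voronoi_cells(p, geometry)$areas
  }))
  ns <- vapply(snapshots, nrow, 0L)
  control_areas <- with_seed(seed, {
    unlist(lapply(seq_len(n_controls), function(i) {
      n <- ns[((i - 1L) %% length(ns)) + 1L]
      voronoi_cells(
        uniform_pattern(n, geometry, compartment = "membrane"), geometry
      )$areas
    }))
  })
  pooled <- c(sample_areas, control_areas)
  pooled <- pooled[is.finite(pooled)]
  # common histogram binning (Freedman-Diaconis on the pooled areas)
  iqr <- stats::IQR(pooled)
  bw <- if (iqr > 0) 2 * iqr / length(pooled)^(1 / 3) else diff(range(pooled)) / 50
  breaks <- seq(0, max(pooled) + bw, by = bw)
  dens <- function(a) {
    h <- graphics::hist(pmin(a, max(breaks)), breaks = breaks, plot = FALSE)
    h$density
  }
  ds <- dens(sample_areas)
  dc <- dens(control_areas)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  # walk up from the sample's small-area mode to the first crossing where
  # the uniform control becomes the more probable explanation
  mode_bin <- which.max(ds)
  cross <- which(dc[mode_bin:length(dc)] >= ds[mode_bin:length(ds)])
  if (!length(cross)) {
    stop("polygon-size densities do not intersect; threshold undefined ",
      "(degenerate or identical inputs)")
  }
  thr <- mids[mode_bin + cross[1] - 1L]
  structure(
    list(
      size_threshold = thr, breaks = breaks, mids = mids,
      control_density = dc, sample_density = ds, n_controls = n_controls
    ),
    class = "polar_vthreshold"
  )
}

#' @export
print.polar_vthreshold <- function(x, ...) {
  cat(sprintf(
    "<polar_vthreshold> polygon-size threshold %.4f um^2 (%d uniform controls)\n",
    x$size_threshold, x$n_controls
  ))
  invisible(x)
}

#' Detect molecule clusters by Voronoi tessellation
#'
#' A cluster is a group of adjacent Voronoi polygons whose sizes fall below
#' the calibrated polygon-size threshold. Polygons above the threshold are
#' removed; the remaining polygons are grouped by Delaunay adjacency, and
#' groups are kept if they pass the cluster-area filter (total polygon area
#' at most `area_max`, matching a polarity-site diameter of about 1 um) and
#' the molecule-count filter (at least `count_min` molecules).
#'
#' @param points Coordinate matrix of the analyzed molecules (active Cdc42).
#' @param threshold A `polar_vthreshold` from [calibrate_threshold()], or a
#'   numeric polygon-size threshold in um^2.
#' @param geometry A geometry object.
#' @param area_max Cluster-area filter, um^2.
#' @param area_rule `"max"` (default): keep groups with total area `<=`
#'   `area_max`; `"min"`: keep groups with total area `>=` `area_max`.
#' @param count_min Minimum number of molecules per cluster.
#' @return A `polar_clusters`: list of clusters (each with `members`,
#'   `n_molecules`, `area`, `centroid`) plus the inputs used. Empty list if
#'   `nrow(points) < 3` (with a warning).
#' @export
detect_clusters <- function(points, threshold, geometry = plane_geometry(),
                            area_max = 0.785, area_rule = c("max", "min"),
                            count_min = 20) {
  area_rule <- match.arg(area_rule)
  points <- as.matrix(points)
  if (nrow(points) < 3) {
    warning("fewer than 3 points: no tessellation, no clusters")
    return(structure(
      list(clusters = list(), size_threshold = NA_real_),
      class = "polar_clusters"
    ))
  }
  thr <- if (inherits(threshold, "polar_vthreshold")) {
    threshold$size_threshold
  } else {
    as.numeric(threshold)
  }
  vor <- voronoi_cells(points, geometry)
  keep <- which(is.finite(vor$areas) & vor$areas <= thr)
  clusters <- list()
  if (length(keep) >= 1) {
    # connected components of the adjacency graph restricted to kept polygons
    comp <- components_from_edges(length(vor$areas), vor$edges, keep)
    for (members in comp) {
      area <- sum(vor$areas[members])
      ok_area <- if (area_rule == "max") area <= area_max else area >= area_max
      if (ok_area && length(members) >= count_min) {
        clusters[[length(clusters) + 1L]] <- list(
          members = members,
          n_molecules = length(members),
          area = area,
          centroid = pattern_centroid(points[members, , drop = FALSE], geometry)
        )
      }
    }
  }
  structure(
    list(clusters = clusters, size_threshold = thr),
    class = "polar_clusters"
  )
}

#' @export
print.polar_clusters <- function(x, ...) {
  cat(sprintf("<polar_clusters> %d cluster(s)\n", length(x$clusters)))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf(
      "  #%d: %d molecules, area %.3f um^2\n", i, cl$n_molecules, cl$area
    ))
  }
  invisible(x)
}

# Union-find over the subgraph induced by `keep`
components_from_edges <- function(n, edges, keep) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  inkeep <- logical(n)
  inkeep[keep] <- TRUE
  if (nrow(edges)) {
    use <- inkeep[edges[, 1]] & inkeep[edges[, 2]]
    e <- edges[use, , drop = FALSE]
    for (k in seq_len(nrow(e))) {
      a <- find(e[k, 1])
      b <- find(e[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(keep, find, 0L)
  split(keep, roots)
}

# Centroid respecting the geometry: circular mean per axis on the periodic
# plane; normalized vector mean projected to the surface on the sphere.
pattern_centroid <- function(points, geometry) {
  if (is_plane(geometry)) {
    L <- geometry$L
    vapply(1:2, function(j) {
      ang <- points[, j] / L * 2 * pi
      (atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi)) %% 1 * L
    }, numeric(1))
  } else {
    m <- colMeans(points)
    m / sqrt(sum(m^2)) * geometry$R
  }
}

#' Cluster-count time series of a trajectory
#'
#' Runs cluster detection on the active-Cdc42 positions of every snapshot
#' and derives the 0 / 1 / 2+ cluster-state series.
#'
#' @param traj A `polar_trajectory`.
#' @param threshold A `polar_vthreshold` or numeric threshold; `NULL`
#'   calibrates one from the trajectory's own snapshots (pooled) against
#'   uniform controls.
#' @param species Analyzed species (default active Cdc42).
#' @param every Analyze every `every`-th snapshot (1 = all).
#' @param n_controls,seed Passed to [calibrate_threshold()] when calibrating.
#' @param ... Passed to [detect_clusters()].
#' @return A `polar_cluster_series` data frame with columns `t`,
#'   `n_clusters`, `state` (levels `0`, `1`, `2+`), and the threshold used
#'   as attribute `size_threshold`.
#' @export
cluster_series <- function(traj, threshold = NULL,
                           species = ACTIVE_CDC42_SPECIES, every = 1L,
                           n_controls = 50, seed = 1L, ...) {
  stopifnot(inherits(traj, "polar_trajectory"))
  geometry <- traj$params$geometry
  sel <- seq(1L, length(traj$times), by = every)
  pts <- lapply(sel, function(i) get_positions(traj, i, species = species))
  if (is.null(threshold)) {
    usable <- pts[vapply(pts, nrow, 0L) >= 3]
    if (!length(usable)) stop("no snapshot has 3+ analyzed molecules")
    threshold <- calibrate_threshold(
      usable, geometry, n_controls = n_controls, seed = seed
    )
  }
  ncl <- vapply(pts, function(p) {
    if (nrow(p) < 3) return(0L)
    length(detect_clusters(p, threshold, geometry, ...)$clusters)
  }, 0L)
  out <- data.frame(
    t = traj$times[sel],
    n_clusters = ncl,
    state = factor(
      ifelse(ncl >= 2, "2+", as.character(ncl)),
      levels = c("0", "1", "2+")
    )
  )
  attr(out, "size_threshold") <- if (inherits(threshold, "polar_vthreshold")) {
    threshold$size_threshold
  } else {
    threshold
  }
  class(out) <- c("polar_cluster_series", "data.frame")
  out
}

#' Occupancy, transition and dwell-time statistics of a cluster-state series
#'
#' @param series A data frame with columns `t` and `state` (factor over
#'   `0`, `1`, `2+`), e.g. from [cluster_series()] or
#'   [experimental_like_count_series()].
#' @param resample_interval Optionally resample the series to this interval
#'   (s) before computing statistics, e.g. 120 s to match experimentally
#'   scored series.
#' @return List with `occupancy` (fraction of samples per state),
#'   `transitions` (row-stochastic matrix over observed consecutive pairs;
#'   rows with no observed exit are `NA`), `dwell` (list of run lengths in
#'   seconds per state), `n`, `interval`.
#' @export
state_statistics <- function(series, resample_interval = NULL) {
  stopifnot(all(c("t", "state") %in% names(series)), nrow(series) >= 2)
  s <- series
  if (!is.null(resample_interval)) {
    dt0 <- stats::median(diff(s$t))
    stride <- max(1L, round(resample_interval / dt0))
    s <- s[seq(1L, nrow(s), by = stride), , drop = FALSE]
  }
  st <- factor(s$state, levels = c("0", "1", "2+"))
  occupancy <- prop.table(table(st))
  from <- st[-length(st)]
  to <- st[-1]
  trans <- table(from, to)
  tm <- matrix(NA_real_, 3, 3, dimnames = list(levels(st), levels(st)))
  for (i in 1:3) {
    tot <- sum(trans[i, ])
    if (tot > 0) tm[i, ] <- trans[i, ] / tot
  }
  interval <- stats::median(diff(s$t))
  runs <- rle(as.integer(st))
  dwell <- split(runs$lengths * interval, factor(levels(st)[runs$values],
    levels = levels(st)))
  list(
    occupancy = occupancy, transitions = tm, dwell = dwell,
    n = nrow(s), interval = interval
  )
}

#' Read an experimental-style cluster-count series from tabular text
#'
#' Expects columns `t` (s) and `n_clusters`, e.g. counts scored at 120-s
#' intervals; derives the 0/1/2+ state factor.
#'
#' @param path File path (tab- or whitespace-separated with header).
#' @return Data frame with `t`, `n_clusters`, `state`.
#' @export
read_count_series <- function(path) {
  d <- utils::read.table(path, header = TRUE)
  stopifnot(all(c("t", "n_clusters") %in% names(d)))
  d$state <- factor(
    ifelse(d$n_clusters >= 2, "2+", as.character(d$n_clusters)),
    levels = c("0", "1", "2+")
  )
  d
}
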