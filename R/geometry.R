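#' Simulation geometries
#'
#' The simulator supports two domains: a periodic square of side `L`
#' (`plane_geometry()`), representing a flattened patch of cell membrane with
#' a well-mixed cytosol projected onto it, and a sphere of radius `R`
#' (`sphere_geometry()`), representing a whole cell with membrane-bound
#' species diffusing on the surface and cytosolic species inside.
#'
#' Defaults match the modeled yeast cell: a membrane area of
#' `4 * pi * 2.5^2 = 78.540` um^2, i.e. a periodic square of side
#' `sqrt(78.540) = 8.8623` um, and a cell radius of 2.5 um.
#'
#' @param L Side length of the periodic square, um.
#' @param R Cell radius, um.
#' @param R_absorb Radius of the absorbing shell for extracellular pheromone,
#'   um. Must exceed `R`. Only used by pheromone protocols.
#' @return An object of class `polar_geometry` with fields `mode`
#'   (`"plane2d"` or `"sphere3d"`), `A_m` (membrane area, um^2), and for the
#'   sphere `V_c` (cytosolic volume, um^3).
#' @examples
#' plane_geometry()$A_m          # 78.540 um^2
#' sphere_geometry(R = 2.5)$V_c  # (4/3) pi 2.5^3
#' @export
plane_geometry <- function(L = sqrt(4 * pi * 2.5^2)) {
  stopifnot(is.numeric(L), length(L) == 1L, L > 0)
  structure(
    list(mode = "plane2d", L = L, A_m = L^2, dim = 2L),
    class = "polar_geometry"
  )
}

#' @rdname plane_geometry
#' @export
sphere_geometry <- function(R = 2.5, R_absorb = NULL) {
  stopifnot(is.numeric(R), length(R) == 1L, R > 0)
  if (!is.null(R_absorb) && R_absorb <= R) {
    stop("R_absorb must exceed the cell radius R")
  }
  structure(
    list(
      mode = "sphere3d", R = R, A_m = 4 * pi * R^2,
      V_c = (4 / 3) * pi * R^3, R_absorb = R_absorb, dim = 3L
    ),
    class = "polar_geometry"
  )
}

#' @export
print.polar_geometry <- function(x, ...) {
  if (x$mode == "plane2d") {
    cat(sprintf("Periodic square: L = %.4f um, A_m = %.3f um^2\n", x$L, x$A_m))
  } else {
    cat(sprintf(
      "Sphere: R = %.2f um, A_m = %.3f um^2, V_c = %.3f um^3\n",
      x$R, x$A_m, x$V_c
    ))
    if (!is.null(x$R_absorb)) {
      cat(sprintf("  absorbing shell at %.2f um\n", x$R_absorb))
    }
  }
  invisible(x)
}

is_plane <- function(geometry) geometry$mode == "plane2d"
is_sphere <- function(geometry) geometry$mode == "sphere3d"

assert_geometry <- function(geometry) {
  if (!inherits(geometry, "polar_geometry")) {
    stop("`geometry` must be created by plane_geometry() or sphere_geometry()")
  }
  invisible(geometry)
}

#' Convert molecule counts to cytosolic concentration
#'
#' Expresses a molecule count as a nanomolar concentration in the cytosolic
#' volume of a spherical cell, `n / (N_A * V_c)`. With the default cell
#' radius of 2.5 um, 3000 molecules correspond to 76.1 nM.
#'
#' @param n Molecule count (non-negative).
#' @param geometry A sphere geometry from [sphere_geometry()].
#' @return Concentration in nM.
#' @examples
#' molecules_to_concentration(3000, sphere_geometry())  # 76.1 nM
#' @export
molecules_to_concentration <- function(n, geometry = sphere_geometry()) {
  assert_geometry(geometry)
  if (!is_sphere(geometry)) stop("concentration conversion requires a sphere geometry")
  if (any(n < 0)) stop("molecule count must be non-negative")
  # V_c in um^3 = 1e-15 L; result in nM = 1e9 * mol/L
  n / (.N_AVOGADRO * geometry$V_c * 1e-15) * 1e9
}

#' @rdname molecules_to_concentration
#' @param conc Concentration in nM.
#' @return `concentration_to_molecules()`: expected molecule count (not rounded).
#' @export
concentration_to_molecules <- function(conc, geometry = sphere_geometry()) {
  assert_geometry(geometry)
  if (!is_sphere(geometry)) stop("concentration conversion requires a sphere geometry")
  if (any(conc < 0)) stop("concentration must be non-negative")
  conc * 1e-9 * .N_AVOGADRO * geometry$V_c * 1e-15
}
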