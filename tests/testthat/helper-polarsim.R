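# Shared helpers for the test suite. All fixtures are generated in code.

# A small core-circuit parameter set for fast engine tests.
small_core <- function(n_cdc42 = 300, n_bem1 = 30, geometry = plane_geometry()) {
  build_circuit("core", geometry, c(Cdc42 = n_cdc42, Bem1GEF = n_bem1))
}

# Parameter set containing a single species and no reactions: pure diffusion.
diffusion_only_params <- function(species_name = "Cdc42D_m", n = 500,
                                  geometry = plane_geometry(), D = NULL) {
  sp <- polarsim::polar_species_table()
  sp <- sp[sp$name == species_name, , drop = FALSE]
  sp$D <- if (is.null(D)) {
    if (geometry$mode == "plane2d") sp$D_2d else sp$D_3d
  } else {
    D
  }
  sp$mobile <- sp$D > 0
  rownames(sp) <- NULL
  empty_rx <- data.frame(
    label = character(0), kind = character(0), r1 = character(0),
    r2 = character(0), p1 = character(0), p2 = character(0),
    rate = numeric(0), unit = character(0), rho = numeric(0),
    description = character(0), stringsAsFactors = FALSE
  )
  grp <- strsplit(sp$group, "+", fixed = TRUE)[[1]][1]
  structure(
    list(
      circuit = "core", geometry = geometry, dt = 1e-4,
      species = sp, reactions = empty_rx,
      abundances = stats::setNames(list(n), grp),
      init_species = stats::setNames(species_name, grp),
      groups = stats::setNames(list(species_name), grp)
    ),
    class = "polar_params"
  )
}

# Deterministic planted-cluster fixture: two tight Gaussians over a sparse
# uniform background; returns points plus the ground-truth labels.
planted_cluster_fixture <- function(seed = 7, geometry = plane_geometry(),
                                    n_bg = 200, n_cl = 300, sigma = 0.1) {
  centers <- if (geometry$mode == "plane2d") {
    list(c(2.5, 2.5), c(6.5, 6.5))
  } else {
    list(c(0, 0, geometry$R), c(0, 0, -geometry$R))
  }
  bg <- uniform_pattern(n_bg, geometry, seed = seed)
  c1 <- gaussian_cluster_pattern(n_cl, centers[[1]], sigma, geometry, seed = seed + 1)
  c2 <- gaussian_cluster_pattern(n_cl, centers[[2]], sigma, geometry, seed = seed + 2)
  list(
    points = rbind(bg, c1, c2),
    labels = rep(c(0L, 1L, 2L), c(n_bg, n_cl, n_cl)),
    centers = centers
  )
}
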