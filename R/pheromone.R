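#' Extracellular pheromone protocols
#'
#' Describes the pheromone environment of a receiver cell centered at the
#' origin. Pheromone molecules diffuse at 150 um^2/s outside the cell(s),
#' are removed at a spherical absorbing boundary (default 7 um from the
#' origin), and reflect off cell membranes. Modes:
#'
#' * `"uniform"`: a bath held at `background_nM` by re-injecting a molecule
#'   at a random position whenever one is lost to absorption or binding.
#' * `"point_source"`: molecules emitted in a Poisson stream of
#'   `emission_rate` per second from a single point on the emitter cell's
#'   surface (the point facing the receiver by default), optionally on top
#'   of a `background_nM` bath.
#' * `"uniform_then_gradient"`: uniform bath until `switch_time`, then the
#'   point-source gradient (run as two chained simulations).
#'
#' The default two-cell arrangement places the emitter (radius 2.5 um)
#' along +z with a 0.1-um gap between the membranes; the source sits at the
#' emitter's receiver-facing pole.
#'
#' @param mode Protocol mode.
#' @param background_nM Uniform background concentration, nM.
#' @param emission_rate Emission rate, molecules/s.
#' @param switch_time Protocol change point, s (`"uniform_then_gradient"`).
#' @param R_absorb Absorbing-shell radius, um.
#' @param emitter_center Emitter-cell center (length 3), um.
#' @param emitter_R Emitter-cell radius, um; 0 removes the emitter body
#'   (the source point is kept).
#' @param source Source position; default the emitter pole facing the
#'   receiver.
#' @return A `polar_pheromone` protocol object.
#' @export
pheromone_protocol <- function(mode = c("uniform", "point_source",
                                        "uniform_then_gradient"),
                               background_nM = 0, emission_rate = 0,
                               switch_time = NULL, R_absorb = 7,
                               emitter_center = c(0, 0, 5.1),
                               emitter_R = 2.5, source = NULL) {
  mode <- match.arg(mode)
  stopifnot(background_nM >= 0, emission_rate >= 0, R_absorb > 0)
  if (is.null(source)) {
    u <- emitter_center / sqrt(sum(emitter_center^2))
    source <- emitter_center - u * emitter_R
  }
  if (mode == "uniform_then_gradient" && is.null(switch_time)) {
    switch_time <- 300 # 5 min of uniform exposure before the gradient
  }
  structure(
    list(
      mode = mode, background_nM = background_nM,
      emission_rate = emission_rate, switch_time = switch_time,
      R_absorb = R_absorb, emitter_center = emitter_center,
      emitter_R = emitter_R, source = source
    ),
    class = "polar_pheromone"
  )
}

# Number of molecules that realize `conc_nM` in the simulation domain
# (shell between the receiver membrane and the absorbing boundary, minus
# the emitter body).
bath_molecules <- function(protocol, geometry) {
  vol <- (4 / 3) * pi * (protocol$R_absorb^3 - geometry$R^3)
  if (protocol$emitter_R > 0) vol <- vol - (4 / 3) * pi * protocol$emitter_R^3
  round(concentration_to_molecules(
    protocol$background_nM,
    sphere_geometry(R = (3 * vol / (4 * pi))^(1 / 3))
  ))
}

# Engine-facing encoding of a protocol. Uniform mode closes the domain
# (reflecting outer shell) and holds the bath count, which keeps the bath
# exactly uniform at equilibrium; point-source mode uses the absorbing
# shell and explicit emission, with any uniform background carried as a
# superposed analytic component (see ring_concentrations).
pheromone_engine_config <- function(protocol, geometry) {
  stopifnot(inherits(protocol, "polar_pheromone"))
  if (!is_sphere(geometry)) stop("pheromone protocols require a sphere geometry")
  emitting <- protocol$mode == "point_source"
  list(
    emitter = if (protocol$emitter_R > 0) {
      c(protocol$emitter_center, protocol$emitter_R)
    } else {
      NULL
    },
    emission = if (emitting && protocol$emission_rate > 0) {
      c(protocol$emission_rate, protocol$source)
    } else {
      NULL
    },
    bath_target = if (!emitting && protocol$background_nM > 0) {
      bath_molecules(protocol, geometry)
    } else {
      -1L
    },
    absorb_on = emitting,
    R_absorb = protocol$R_absorb
  )
}

# Seed the initial bath population uniformly in the domain.
add_pheromone_particles <- function(state, protocol, params, seed = NULL) {
  if (!"Pheromone" %in% params$species$name) {
    return(state)
  }
  n <- if (protocol$mode != "point_source" && protocol$background_nM > 0) {
    bath_molecules(protocol, params$geometry)
  } else {
    0
  }
  if (n == 0) {
    return(state)
  }
  geometry <- params$geometry
  pos <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
    out <- matrix(0, n, 3)
    i <- 0L
    while (i < n) {
      m <- (n - i) * 2L
      g <- matrix(rnorm(3 * m), ncol = 3)
      g <- g / sqrt(rowSums(g^2))
      r3 <- geometry$R^3 + runif(m) * (protocol$R_absorb^3 - geometry$R^3)
      p <- g * r3^(1 / 3)
      if (protocol$emitter_R > 0) {
        d2 <- colSums((t(p) - protocol$emitter_center)^2)
        p <- p[d2 >= protocol$emitter_R^2, , drop = FALSE]
      }
      take <- min(nrow(p), n - i)
      if (take > 0) {
        out[(i + 1):(i + take), ] <- p[seq_len(take), , drop = FALSE]
        i <- i + take
      }
    }
    out
  })
  colnames(pos) <- c("x", "y", "z")
  structure(
    list(
      t = state$t,
      species = c(state$species, rep("Pheromone", n)),
      pos = rbind(state$pos, pos),
      geometry = state$geometry
    ),
    class = "polar_state"
  )
}

#' Poisson emission events per step
#'
#' The number of pheromone molecules released from the point source within
#' one time step is Poisson with mean `rate * dt`.
#'
#' @param rate Emission rate, molecules/s.
#' @param dt Time step, s.
#' @param n Number of steps to sample.
#' @param seed Optional seed.
#' @return Integer vector of event counts.
#' @export
emit_events <- function(rate, dt, n = 1L, seed = NULL) {
  stopifnot(rate >= 0, dt > 0)
  with_seed(seed, rpois(n, rate * dt))
}

#' Simulate the extracellular pheromone field alone
#'
#' Runs only pheromone molecules (no receiver-cell reactions) between the
#' receiver and emitter cells: Poisson point-source emission, diffusion at
#' 150 um^2/s, reflection off both membranes, absorption at the outer
#' shell, and optional bath maintenance. Used to measure the concentration
#' profile a receiver experiences under a given emission rate.
#'
#' @param protocol A [pheromone_protocol()].
#' @param t_end Simulated duration, s.
#' @param seed Integer seed.
#' @param record_every Snapshot interval, s.
#' @param geometry Receiver geometry (default 2.5-um sphere).
#' @param dt Time step, s.
#' @return A `polar_trajectory` containing only pheromone particles.
#' @export
simulate_pheromone_field <- function(protocol, t_end, seed = 1L,
                                     record_every = 1,
                                     geometry = sphere_geometry(), dt = 1e-4) {
  params <- pheromone_only_params(geometry, dt)
  run_simulation(
    params, initial_condition("uniform"),
    t_end = t_end, seed = seed,
    record_every = record_every, pheromone = protocol
  )
}

# Minimal parameter set holding only the pheromone species.
pheromone_only_params <- function(geometry, dt = 1e-4) {
  species <- polar_species_table()
  species <- species[species$name == "Pheromone", , drop = FALSE]
  species$D <- species$D_3d
  species$mobile <- TRUE
  rownames(species) <- NULL
  reactions <- data.frame(
    label = character(0), kind = character(0),
    r1 = character(0), r2 = character(0),
    p1 = character(0), p2 = character(0),
    rate = numeric(0), unit = character(0), rho = numeric(0),
    description = character(0), stringsAsFactors = FALSE
  )
  structure(
    list(
      circuit = "pheromone_only", geometry = geometry, dt = dt,
      species = species, reactions = reactions,
      abundances = list(), init_species = character(0), groups = list()
    ),
    class = "polar_params"
  )
}

#' Ring-resolved pheromone concentrations at the receiver surface
#'
#' Averages pheromone molecule counts in sampling shells above rings of the
#' receiver membrane (bands of polar angle measured from the source-facing
#' pole) over the snapshots of a trajectory, and converts to nM.
#'
#' @param traj A `polar_trajectory` containing pheromone particles.
#' @param n_rings Number of equal-angle rings from the source-facing pole
#'   to the opposite pole.
#' @param shell Sampling-shell thickness above the membrane, um.
#' @param t_min Discard snapshots before this time (equilibration), s.
#' @param axis Pole axis (default +z, the emitter direction).
#' @param add_background Add the protocol's uniform background concentration
#'   to every ring (default). Point-source runs simulate only the emitted
#'   molecules explicitly; a uniform background is a superposed equilibrium
#'   component and enters the profile as a constant.
#' @return A `polar_ring_profile` data frame: `ring`, `theta_center` (rad),
#'   `mean_nM`, `sd_nM`, `n_snapshots`.
#' @export
ring_concentrations <- function(traj, n_rings = 16, shell = 0.15,
                                t_min = 0, axis = c(0, 0, 1),
                                add_background = TRUE) {
  stopifnot(inherits(traj, "polar_trajectory"))
  geometry <- traj$params$geometry
  if (!is_sphere(geometry)) stop("ring profile requires a sphere geometry")
  use <- which(traj$times >= t_min)
  if (!length(use)) stop("empty trajectory window")
  axis <- axis / sqrt(sum(axis^2))
  R <- geometry$R
  edges <- seq(0, pi, length.out = n_rings + 1L)
  # volume of each ring's sampling shell: R < r < R + shell, theta band
  vol <- (2 * pi / 3) * ((R + shell)^3 - R^3) *
    (cos(edges[-length(edges)]) - cos(edges[-1]))
  pher_code <- match("Pheromone", traj$species_names) - 1L
  counts <- matrix(0, length(use), n_rings)
  for (k in seq_along(use)) {
    s <- traj$snapshots[[use[k]]]
    keep <- s$species == pher_code
    if (!any(keep)) next
    p <- s$pos[keep, , drop = FALSE]
    r <- sqrt(rowSums(p^2))
    inshell <- r > R & r <= R + shell
    if (!any(inshell)) next
    ct <- pmin(1, pmax(-1, (p[inshell, , drop = FALSE] %*% axis) / r[inshell]))
    th <- acos(ct)
    bin <- pmin(n_rings, findInterval(th, edges, rightmost.closed = TRUE))
    tb <- tabulate(bin, nbins = n_rings)
    counts[k, ] <- tb
  }
  # molecules per um^3 -> nM (1 nM = N_A * 1e-9 * 1e-15 molecules/um^3)
  conc <- sweep(counts, 2, vol, "/") / (.N_AVOGADRO * 1e-15 * 1e-9)
  if (add_background && !is.null(traj$pheromone) &&
    traj$pheromone$mode == "point_source") {
    conc <- conc + traj$pheromone$background_nM
  }
  out <- data.frame(
    ring = seq_len(n_rings),
    theta_center = (edges[-1] + edges[-length(edges)]) / 2,
    mean_nM = colMeans(conc),
    sd_nM = apply(conc, 2, sd),
    n_snapshots = length(use)
  )
  class(out) <- c("polar_ring_profile", "data.frame")
  out
}

#' Time-averaged pheromone concentration in a radial shell
#'
#' Counts pheromone molecules with radius inside `r_range` (um from the
#' receiver center) over the snapshots after `t_min` and converts to nM.
#' Useful for checking bulk bath concentrations away from the boundaries,
#' where the discretized reflection carries a small bias.
#'
#' @param traj A `polar_trajectory` containing pheromone particles.
#' @param r_range Radial interval, um.
#' @param t_min Discard snapshots before this time, s.
#' @return Concentration in nM.
#' @export
bulk_concentration <- function(traj, r_range = c(3.5, 6), t_min = 0) {
  stopifnot(inherits(traj, "polar_trajectory"), r_range[2] > r_range[1])
  use <- which(traj$times >= t_min)
  if (!length(use)) stop("empty trajectory window")
  pher_code <- match("Pheromone", traj$species_names) - 1L
  vol <- (4 / 3) * pi * (r_range[2]^3 - r_range[1]^3)
  counts <- vapply(use, function(k) {
    s <- traj$snapshots[[k]]
    keep <- s$species == pher_code
    if (!any(keep)) return(0)
    r2 <- rowSums(s$pos[keep, , drop = FALSE]^2)
    sum(r2 > r_range[1]^2 & r2 <= r_range[2]^2)
  }, numeric(1))
  mean(counts) / vol / (.N_AVOGADRO * 1e-15 * 1e-9)
}

#' Frozen pheromone gradient field
#'
#' Replaces explicit pheromone particles by a static position-dependent
#' receptor-activation rate derived from a measured ring profile: a
#' membrane-bound inactive receptor at polar angle `theta` from the source
#' axis activates with first-order hazard
#' `lambda11 * c(theta) * (2/3) pi rho^3 * N_A`, the well-mixed expectation
#' of the explicit bimolecular binding at local concentration `c(theta)`.
#' This approximation makes scaled-down gradient runs affordable; outputs
#' carry the field so runs are flagged as frozen-field.
#'
#' @param profile A `polar_ring_profile` (or data frame with `theta_center`
#'   and `mean_nM`).
#' @param lambda11 Pheromone-binding probability rate, 1/s.
#' @param rho Reactive radius, um.
#' @param axis Source axis (default +z).
#' @return A `polar_field` usable as the `field` argument of
#'   [run_simulation()].
#' @export
frozen_gradient_field <- function(profile, lambda11 = 1.8, rho = 0.05,
                                  axis = c(0, 0, 1)) {
  stopifnot(all(c("theta_center", "mean_nM") %in% names(profile)))
  axis <- axis / sqrt(sum(axis^2))
  # molecules per um^3 at 1 nM
  per_um3 <- 1e-9 * .N_AVOGADRO * 1e-15
  rate <- lambda11 * profile$mean_nM * per_um3 * (2 / 3) * pi * rho^3
  ord <- order(cos(profile$theta_center))
  structure(
    list(
      species = "Ri_m", product = "Ra_m", axis = axis,
      cos = cos(profile$theta_center)[ord], rate = rate[ord],
      profile = profile
    ),
    class = "polar_field"
  )
}

#' @export
print.polar_field <- function(x, ...) {
  cat(sprintf(
    "<polar_field> frozen gradient: %d rings, rates %.3g .. %.3g /s\n",
    length(x$rate), min(x$rate), max(x$rate)
  ))
  invisible(x)
}
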