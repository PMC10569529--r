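#' Initial conditions
#'
#' Describes how the molecule populations of a circuit are laid out at time
#' zero. The default places every group according to its compartment:
#' cytosolic species uniformly over the domain, membrane species uniformly
#' over the membrane. The named kinds override the placement of one group:
#'
#' * `"uniform"`: everything uniform.
#' * `"prepolarized_cdc42"`: all Cdc42 starts as active Cdc42-GTP in a
#'   Gaussian cluster of standard deviation `sigma` (default 0.2 um) at
#'   `center`; other groups uniform.
#' * `"polarized_receptors"`: receptors start in a Gaussian cluster of
#'   standard deviation `sigma` (default 0.2 um); other groups uniform.
#' * `"dispersed_receptors"`: as `"polarized_receptors"` but intended for
#'   dispersion scans (`sigma` is the scanned dispersion; `sigma = Inf`
#'   means uniform).
#' * `"fixed_far1_seeds"`: immobile Far1-GEF seeds at `seed_positions`
#'   (default: an evenly spaced layout from [fixed_seed_layout()]).
#'
#' @param kind Initial-condition kind, see Details.
#' @param sigma Gaussian dispersion, um.
#' @param center Cluster center (defaults to the domain center / north pole).
#' @param seed_positions Explicit coordinates for fixed seeds.
#' @return An `polar_init` object.
#' @export
initial_condition <- function(kind = c(
                                "uniform", "prepolarized_cdc42",
                                "polarized_receptors", "dispersed_receptors",
                                "fixed_far1_seeds"
                              ),
                              sigma = 0.2, center = NULL,
                              seed_positions = NULL) {
  kind <- match.arg(kind)
  structure(
    list(
      kind = kind, sigma = sigma, center = center,
      seed_positions = seed_positions
    ),
    class = "polar_init"
  )
}

#' Build the particle state at time zero
#'
#' @param params A [build_circuit()] parameter set.
#' @param init An [initial_condition()].
#' @param seed RNG seed for the placement.
#' @return A `polar_state`: time, species vector, coordinate matrix, geometry.
#' @export
initial_state <- function(params, init = initial_condition(), seed = NULL) {
  stopifnot(inherits(params, "polar_params"), inherits(init, "polar_init"))
  geometry <- params$geometry
  comp <- stats::setNames(params$species$compartment, params$species$name)
  species <- character(0)
  rows <- list()

  place_uniform <- function(s, n) {
    uniform_pattern(n, geometry,
      compartment = if (comp[[s]] == "cytosol") "cytosol" else "membrane"
    )
  }

  with_seed(seed, {
    for (g in names(params$abundances)) {
      n <- params$abundances[[g]]
      if (n == 0) next
      s <- params$init_species[[g]]
      pos <- NULL
      if (g == "Cdc42" && init$kind == "prepolarized_cdc42") {
        s <- "Cdc42T" # pre-polarized cluster of active Cdc42
        pos <- gaussian_cluster_pattern(n, init$center, init$sigma, geometry)
      } else if (g == "R" &&
        init$kind %in% c("polarized_receptors", "dispersed_receptors")) {
        pos <- if (is.infinite(init$sigma)) {
          uniform_pattern(n, geometry, compartment = "membrane")
        } else {
          gaussian_cluster_pattern(n, init$center, init$sigma, geometry)
        }
      } else if (g == "Far1GEF_s") {
        pos <- if (!is.null(init$seed_positions)) {
          init$seed_positions
        } else {
          fixed_seed_layout(n, geometry)
        }
        stopifnot(nrow(pos) == n)
      }
      if (is.null(pos)) pos <- place_uniform(s, n)
      species <- c(species, rep(s, n))
      rows[[length(rows) + 1L]] <- pos
    }
  })

  pos <- do.call(rbind, rows)
  if (is.null(pos)) pos <- matrix(numeric(0), ncol = geometry$dim)
  structure(
    list(t = 0, species = species, pos = pos, geometry = geometry),
    class = "polar_state"
  )
}

#' @export
print.polar_state <- function(x, ...) {
  cat(sprintf(
    "<polar_state> t = %g s, %d particles on %s\n",
    x$t, length(x$species), x$geometry$mode
  ))
  print(table(x$species))
  invisible(x)
}

# ---- engine configuration -------------------------------------------------

# Assemble the flat reaction/species encoding passed to the C++ engine.
engine_config <- function(params, pheromone = NULL, field = NULL,
                          well_mixed = FALSE) {
  sp <- params$species
  nsp <- nrow(sp)
  idx <- function(name) match(name, sp$name) - 1L
  comp_code <- c(cytosol = 0L, membrane = 1L, extracellular = 2L)
  dt <- params$dt
  rx <- params$reactions
  rho_max <- max(c(rx$rho, 0.05), na.rm = TRUE)

  fo <- rx[rx$kind %in% c("first_order", "surface_association"), , drop = FALSE]
  fo_rate <- ifelse(
    fo$kind == "surface_association",
    # um/s surface rate as an equivalent well-mixed first-order rate;
    # placement projects the particle radially onto the membrane
    fo$rate * params$geometry$A_m / params$geometry$V_c,
    fo$rate
  )
  fo_sp <- idx(fo$r1)
  fo_p1 <- idx(fo$p1)
  fo_p2 <- ifelse(is.na(fo$p2), -1L, idx(fo$p2))
  fo_prob <- 1 - exp(-fo_rate * dt)
  fo_field <- rep(FALSE, nrow(fo))

  field_cfg <- NULL
  if (!is.null(field)) {
    stopifnot(inherits(field, "polar_field"))
    fo_sp <- c(fo_sp, idx(field$species))
    fo_p1 <- c(fo_p1, idx(field$product))
    fo_p2 <- c(fo_p2, -1L)
    fo_prob <- c(fo_prob, 0)
    fo_field <- c(fo_field, TRUE)
    field_cfg <- list(
      axis = field$axis,
      cos = field$cos,
      prob = 1 - exp(-field$rate * dt)
    )
  }

  so <- rx[rx$kind == "second_order", , drop = FALSE]
  so_anchor <- integer(nrow(so))
  so_pb <- integer(nrow(so))
  for (i in seq_len(nrow(so))) {
    if (is.na(so$p2[i])) {
      so_pb[i] <- -1L
      comps <- comp_code[c(
        sp$compartment[idx(so$r1[i]) + 1L],
        sp$compartment[idx(so$r2[i]) + 1L]
      )]
      # binding product sits at the membrane-anchored reactant
      so_anchor[i] <- if (comps[1] == 1L) 0L else if (comps[2] == 1L) 1L else 0L
    } else {
      so_pb[i] <- idx(so$p2[i])
      so_anchor[i] <- -1L
    }
  }

  pher_cfg <- list(
    emitter = NULL, emission = NULL, bath_target = -1L, absorb_on = TRUE,
    R_absorb = 0
  )
  if (!is.null(pheromone)) pher_cfg <- pheromone_engine_config(pheromone, params$geometry)

  list(
    mode = params$geometry$mode,
    L = if (is_plane(params$geometry)) params$geometry$L else 0,
    R = if (is_sphere(params$geometry)) params$geometry$R else 0,
    R_absorb = pher_cfg$R_absorb,
    dt = dt,
    offset = rho_max + 1e-5,
    nsp = nsp,
    D = sp$D,
    comp = unname(comp_code[sp$compartment]),
    fo_sp = as.integer(fo_sp), fo_p1 = as.integer(fo_p1),
    fo_p2 = as.integer(fo_p2), fo_prob = as.numeric(fo_prob),
    fo_field = fo_field,
    so_r1 = idx(so$r1), so_r2 = idx(so$r2),
    so_pa = idx(so$p1), so_pb = as.integer(so_pb),
    so_anchor = as.integer(so_anchor),
    so_prob = 1 - exp(-so$rate * dt),
    so_rho = ifelse(is.na(so$rho), 0.05, so$rho),
    well_mixed = isTRUE(well_mixed),
    pher_sp = if ("Pheromone" %in% sp$name) idx("Pheromone") else -1L,
    emitter = pher_cfg$emitter,
    emission = pher_cfg$emission,
    bath_target = as.integer(pher_cfg$bath_target),
    absorb_on = isTRUE(pher_cfg$absorb_on),
    field = field_cfg
  )
}

# ---- running --------------------------------------------------------------

#' Run a particle-based simulation
#'
#' Advances the particle system by Brownian dynamics with stochastic
#' reactions at fixed time step `params$dt`, recording a snapshot of all
#' particle positions every `record_every` seconds (10 s default, the
#' recording interval used throughout the analyses).
#'
#' @param params A [build_circuit()] parameter set.
#' @param init An [initial_condition()], or a ready-made `polar_state` to
#'   continue from.
#' @param t_end Simulated duration, s.
#' @param seed Integer seed; the run is fully reproducible given
#'   (`params`, `init`, `t_end`, `seed`).
#' @param record_every Snapshot interval, s.
#' @param pheromone Optional [pheromone_protocol()] (sphere geometry only).
#' @param field Optional frozen pheromone gradient from
#'   [frozen_gradient_field()], replacing explicit pheromone particles by a
#'   position-dependent receptor-activation rate.
#' @param well_mixed Remove the spatial gate on bimolecular reactions and
#'   fire them as mass-action events at the matched effective rate (plane
#'   geometry; used to validate reaction bookkeeping against an ODE solution).
#' @return A `polar_trajectory`: snapshot list, per-species count series,
#'   and run metadata.
#' @examples
#' \donttest{
#' p <- build_circuit("core", plane_geometry(), c(Cdc42 = 500, Bem1GEF = 20))
#' tr <- run_simulation(p, t_end = 1, seed = 1, record_every = 0.5)
#' species_counts(tr)
#' }
#' @export
run_simulation <- function(params, init = initial_condition(), t_end,
                           seed = 1L, record_every = 10,
                           pheromone = NULL, field = NULL,
                           well_mixed = FALSE) {
  stopifnot(inherits(params, "polar_params"), t_end > 0)
  if (inherits(init, "polar_init")) {
    state <- initial_state(params, init, seed = seed)
  } else if (inherits(init, "polar_state")) {
    state <- init
  } else {
    stop("`init` must be an initial_condition() or a polar_state")
  }
  if (!is.null(pheromone)) {
    state <- add_pheromone_particles(state, pheromone, params, seed = seed)
  }
  cfg <- engine_config(params, pheromone = pheromone, field = field,
    well_mixed = well_mixed)
  sp_idx <- match(state$species, params$species$name) - 1L
  if (anyNA(sp_idx)) {
    stop("state contains species absent from the parameter set: ",
      paste(unique(state$species[is.na(sp_idx)]), collapse = ", "))
  }
  pos <- state$pos
  if (is_plane(params$geometry) && ncol(pos) < 2L) {
    stop("plane state needs x, y coordinates")
  }
  res <- .ps_run(
    cfg, list(species = as.integer(sp_idx), pos = pos),
    t_end, record_every, as.numeric(seed)
  )
  nsp <- nrow(params$species)
  counts <- matrix(
    vapply(
      res$snapshots,
      function(s) tabulate(s$species + 1L, nbins = nsp),
      integer(nsp)
    ),
    ncol = nsp, byrow = TRUE
  )
  colnames(counts) <- params$species$name
  structure(
    list(
      times = res$times + state$t,
      snapshots = res$snapshots,
      species_names = params$species$name,
      counts = counts,
      params = params, init = init, seed = seed, t_end = t_end,
      record_every = record_every,
      pheromone = pheromone, field = field
    ),
    class = "polar_trajectory"
  )
}

#' @export
print.polar_trajectory <- function(x, ...) {
  cat(sprintf(
    "<polar_trajectory> circuit '%s' on %s: %g s, %d snapshots, seed %s\n",
    x$params$circuit, x$params$geometry$mode,
    max(x$times) - min(x$times), length(x$times), format(x$seed)
  ))
  invisible(x)
}

#' Extract positions of selected species from a trajectory snapshot
#'
#' @param traj A `polar_trajectory`.
#' @param i Snapshot index (1-based), or use `t` to select by time.
#' @param species Character vector of species names; defaults to the active
#'   Cdc42 species (`Cdc42T` and the Cdc42T-Bem1-GEF complex).
#' @param t Snapshot time, s (nearest snapshot).
#' @return Coordinate matrix of the selected particles.
#' @export
get_positions <- function(traj, i = NULL, species = ACTIVE_CDC42_SPECIES,
                          t = NULL) {
  stopifnot(inherits(traj, "polar_trajectory"))
  if (is.null(i)) {
    i <- if (is.null(t)) length(traj$times) else which.min(abs(traj$times - t))
  }
  snap <- traj$snapshots[[i]]
  keep <- snap$species %in% (match(species, traj$species_names) - 1L)
  snap$pos[keep, , drop = FALSE]
}

#' Per-species molecule-count series of a trajectory
#'
#' @param traj A `polar_trajectory`.
#' @return Data frame: `t` plus one column per species.
#' @export
species_counts <- function(traj) {
  stopifnot(inherits(traj, "polar_trajectory"))
  data.frame(t = traj$times, traj$counts, check.names = FALSE)
}

#' Check conservation-group totals along a trajectory
#'
#' Sums the member species of every conservation group (total Cdc42, total
#' Bem1-GEF, total Far1-GEF, total receptors) at each snapshot and verifies
#' the totals never change.
#'
#' @param traj A `polar_trajectory`.
#' @return Invisibly `TRUE`; errors if any group total drifts.
#' @export
check_conservation <- function(traj) {
  groups <- traj$params$groups
  for (g in names(groups)) {
    members <- intersect(groups[[g]], colnames(traj$counts))
    if (!length(members)) next
    tot <- rowSums(traj$counts[, members, drop = FALSE])
    if (length(unique(tot)) != 1L) {
      stop(sprintf(
        "conservation violated for group %s: totals range %d..%d",
        g, min(tot), max(tot)
      ))
    }
  }
  invisible(TRUE)
}

# ---- elementary operations, exposed for direct use and testing -----------

#' Reaction probability within one time step
#'
#' A reaction with rate constant `rate` (first-order) or probability rate
#' `rate` (second-order, partners within the reactive radius) fires within a
#' step of length `dt` with probability `1 - exp(-rate * dt)`.
#'
#' @param rate Rate, 1/s.
#' @param dt Time step, s.
#' @return Firing probability.
#' @examples
#' reaction_probability(0.35, 1e-4) # 3.49994e-5
#' @export
reaction_probability <- function(rate, dt) {
  stopifnot(all(rate >= 0), all(dt > 0))
  1 - exp(-rate * dt)
}

#' One Brownian step (reference implementation)
#'
#' Displaces points by independent Gaussian increments with per-axis
#' standard deviation `sqrt(2 * D * dt)` (the Euler-Maruyama update),
#' applying the geometry's boundary rule: periodic wrapping on the plane;
#' on the sphere, membrane points move in the local tangent plane and are
#' re-projected to radius `R`, cytosolic points reflect at the membrane.
#' This is the plain-R reference for the compiled engine's diffusion step.
#'
#' @param pos Coordinate matrix.
#' @param D Diffusion coefficient, um^2/s (scalar or per-point).
#' @param dt Time step, s.
#' @param geometry A geometry object.
#' @param compartment `"membrane"` or `"cytosol"` (sphere only).
#' @return Displaced coordinate matrix.
#' @export
brownian_step <- function(pos, D, dt, geometry = plane_geometry(),
                          compartment = "membrane") {
  assert_geometry(geometry)
  stopifnot(dt > 0, all(D >= 0))
  n <- nrow(pos)
  if (n == 0) return(pos)
  s <- sqrt(2 * D * dt)
  if (is_plane(geometry)) {
    out <- pos + matrix(rnorm(2 * n), ncol = 2) * s
    out %% geometry$L
  } else if (compartment == "membrane") {
    R <- geometry$R
    u <- pos / R
    g <- matrix(rnorm(3 * n), ncol = 3)
    g <- g - u * rowSums(g * u) # project onto the tangent plane
    out <- pos + g * s
    out / sqrt(rowSums(out^2)) * R
  } else {
    R <- geometry$R
    out <- pos + matrix(rnorm(3 * n), ncol = 3) * s
    r <- sqrt(rowSums(out^2))
    refl <- r > R
    if (any(refl)) {
      f <- pmax(0, (2 * R - r[refl]) / r[refl])
      out[refl, ] <- out[refl, , drop = FALSE] * f
    }
    out
  }
}

#' Placement of dissociation products
#'
#' When a complex dissociates, one product keeps the parent position and the
#' other is placed at `rho + 1e-5` um in a random direction, just beyond the
#' binding radius so the pair cannot instantly re-associate. On the sphere
#' the direction is tangent and the product is re-projected to radius `R`.
#'
#' @param parent Parent position (length 2 or 3).
#' @param rho Binding radius, um.
#' @param geometry A geometry object.
#' @param direction Optional fixed direction (unit vector) instead of a
#'   random draw.
#' @return Position of the displaced product.
#' @export
place_dissociated <- function(parent, rho = 0.05,
                              geometry = plane_geometry(),
                              direction = NULL) {
  assert_geometry(geometry)
  offset <- rho + 1e-5
  if (is_plane(geometry)) {
    if (is.null(direction)) {
      a <- runif(1, 0, 2 * pi)
      direction <- c(cos(a), sin(a))
    }
    (parent + offset * direction) %% geometry$L
  } else {
    R <- geometry$R
    u <- parent / sqrt(sum(parent^2))
    if (is.null(direction)) {
      g <- rnorm(3)
      g <- g - sum(g * u) * u
      direction <- g / sqrt(sum(g^2))
    } else {
      direction <- direction - sum(direction * u) * u
      direction <- direction / sqrt(sum(direction^2))
    }
    out <- parent + offset * direction
    out / sqrt(sum(out^2)) * R
  }
}

#' Advance a particle state by a fixed number of steps
#'
#' @param state A `polar_state`.
#' @param params The matching parameter set.
#' @param n Number of time steps.
#' @param seed Integer seed.
#' @return The advanced `polar_state`.
#' @export
step_state <- function(state, params, n = 1L, seed = 1L) {
  stopifnot(inherits(state, "polar_state"), n >= 1)
  tr <- run_simulation(
    params, state,
    t_end = n * params$dt, seed = seed,
    record_every = n * params$dt
  )
  snap <- tr$snapshots[[length(tr$snapshots)]]
  structure(
    list(
      t = state$t + n * params$dt,
      species = params$species$name[snap$species + 1L],
      pos = snap$pos, geometry = params$geometry
    ),
    class = "polar_state"
  )
}

#' Write trajectory snapshots and counts as tabular text
#'
#' @param traj A `polar_trajectory`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_trajectory <- function(traj, dir) {
  stopifnot(inherits(traj, "polar_trajectory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(traj$times), function(i) {
    s <- traj$snapshots[[i]]
    if (length(s$species) == 0) return(NULL)
    data.frame(
      t = traj$times[i],
      species = traj$species_names[s$species + 1L],
      s$pos
    )
  })
  snap_df <- do.call(rbind, rows)
  names(snap_df)[-(1:2)] <- c("x", "y", "z")[seq_len(ncol(snap_df) - 2L)]
  f1 <- file.path(dir, "snapshots.tsv")
  write.table(snap_df, f1, sep = "\t", row.names = FALSE, quote = FALSE)
  f2 <- file.path(dir, "counts.tsv")
  write.table(species_counts(traj), f2, sep = "\t", row.names = FALSE, quote = FALSE)
  f3 <- file.path(dir, "meta.txt")
  meta <- c(
    sprintf("circuit\t%s", traj$params$circuit),
    sprintf("geometry\t%s", traj$params$geometry$mode),
    sprintf("dt\t%g", traj$params$dt),
    sprintf("seed\t%s", format(traj$seed)),
    sprintf("t_end\t%g", traj$t_end),
    sprintf("record_every\t%g", traj$record_every),
    sprintf("abundance_%s\t%d", names(traj$params$abundances),
      unlist(traj$params$abundances))
  )
  writeLines(meta, f3)
  invisible(c(f1, f2, f3))
}
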