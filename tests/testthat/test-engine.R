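test_that("reaction probabilities follow 1 - exp(-rate dt)", {
  expect_equal(reaction_probability(0.35, 1e-4), 3.49994e-5, tolerance = 1e-6)
  expect_equal(reaction_probability(180, 1e-4), 0.0178390, tolerance = 1e-5)
  expect_equal(reaction_probability(0, 1e-4), 0)
  # Monte-Carlo firing rate of a first-order channel matches the closed form
  p <- diffusion_only_params("Bem1GEF_m", n = 1000)
  p$reactions <- data.frame(
    label = "decay", kind = "first_order", r1 = "Bem1GEF_m", r2 = NA,
    p1 = "Bem1GEF_c", p2 = NA, rate = 100, unit = "s-1", rho = NA,
    description = "test", stringsAsFactors = FALSE
  )
  p$species <- polarsim::polar_species_table()
  p$species <- p$species[p$species$name %in% c("Bem1GEF_m", "Bem1GEF_c"), ]
  p$species$D <- p$species$D_2d
  p$groups <- list(Bem1GEF = c("Bem1GEF_m", "Bem1GEF_c"))
  tr <- run_simulation(p, t_end = 0.01, seed = 1, record_every = 0.01)
  # survival over 100 steps: N exp(-k t)
  expected <- 1000 * exp(-100 * 0.01)
  surv <- tr$counts[2, "Bem1GEF_m"]
  expect_lt(abs(surv - expected), 3 * sqrt(1000 * 0.368 * 0.632))
})

test_that("brownian_step realizes the Euler-Maruyama displacement law", {
  g <- plane_geometry()
  pos <- matrix(4, nrow = 4000, ncol = 2)
  set.seed(1)
  out <- brownian_step(pos, D = 0.0025, dt = 1e-4, g)
  d <- out - pos
  expect_equal(sd(d), 7.0711e-4, tolerance = 0.03) # sqrt(2 D dt)
  expect_identical(brownian_step(pos, D = 0, dt = 1e-4, g), pos)

  # periodic wrap: stepping past L lands near 0
  p2 <- matrix(c(g$L - 1e-9, 1), 1)
  set.seed(2)
  w <- brownian_step(p2, D = 15, dt = 1e-4, g)
  expect_true(all(w >= 0 & w < g$L))

  # sphere membrane points stay on the sphere
  g3 <- sphere_geometry()
  m <- uniform_pattern(500, g3, seed = 3)
  out3 <- brownian_step(m, D = 0.0025, dt = 1e-4, g3, "membrane")
  expect_equal(sqrt(rowSums(out3^2)), rep(g3$R, 500), tolerance = 1e-9)

  # cytosolic points never leave the ball
  cyt <- uniform_pattern(500, g3, compartment = "cytosol", seed = 4)
  outc <- brownian_step(cyt, D = 15, dt = 1e-4, g3, "cytosol")
  expect_true(all(rowSums(outc^2) <= g3$R^2 + 1e-12))
})

test_that("dissociation products are placed just beyond the binding radius", {
  g <- plane_geometry()
  set.seed(1)
  q <- place_dissociated(c(4, 4), 0.05, g)
  expect_equal(sqrt(sum((q - c(4, 4))^2)), 0.05001, tolerance = 1e-9)

  g3 <- sphere_geometry()
  parent <- c(0, 0, g3$R)
  q3 <- place_dissociated(parent, 0.05, g3)
  expect_equal(sqrt(sum(q3^2)), g3$R, tolerance = 1e-9)

  # directions uniform on the circle: resultant length small (Rayleigh)
  set.seed(2)
  dirs <- t(vapply(
    1:2000,
    function(i) place_dissociated(c(4, 4), 0.05, g) - c(4, 4),
    numeric(2)
  ))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rbar <- sqrt(sum(colMeans(dirs)^2))
  expect_lt(2000 * rbar^2, qchisq(0.999, 2) / 2) # Rayleigh statistic
})

test_that("pure-diffusion mean squared displacement follows 4 D t", {
  g <- plane_geometry()
  p <- diffusion_only_params("Cdc42D_m", n = 400, geometry = g)
  tr <- run_simulation(p, t_end = 4, seed = 5, record_every = 0.5)
  # track displacements between consecutive snapshots via minimum image
  id_pos <- lapply(tr$snapshots, function(s) s$pos[order(s$id), ])
  msd_step <- vapply(2:length(id_pos), function(i) {
    d <- id_pos[[i]] - id_pos[[i - 1]]
    d <- (d + g$L / 2) %% g$L - g$L / 2
    mean(rowSums(d^2))
  }, numeric(1))
  expect_equal(mean(msd_step), 4 * 0.0025 * 0.5, tolerance = 0.05)

  # sphere surface: small-time MSD matches the planar law
  g3 <- sphere_geometry()
  p3 <- diffusion_only_params("Cdc42D_m", n = 400, geometry = g3)
  tr3 <- run_simulation(p3, t_end = 2, seed = 6, record_every = 0.5)
  pos_a <- tr3$snapshots[[1]]$pos[order(tr3$snapshots[[1]]$id), ]
  pos_b <- tr3$snapshots[[2]]$pos[order(tr3$snapshots[[2]]$id), ]
  cosd <- rowSums(pos_a * pos_b) / g3$R^2
  geo <- g3$R * acos(pmin(1, pmax(-1, cosd)))
  expect_equal(mean(geo^2), 4 * 0.0025 * 0.5, tolerance = 0.08)
})

test_that("trajectories are deterministic given a seed", {
  p <- small_core()
  a <- run_simulation(p, t_end = 0.5, seed = 77, record_every = 0.1)
  b <- run_simulation(p, t_end = 0.5, seed = 77, record_every = 0.1)
  expect_identical(a$counts, b$counts)
  expect_identical(
    a$snapshots[[length(a$snapshots)]]$pos,
    b$snapshots[[length(b$snapshots)]]$pos
  )
  c2 <- run_simulation(p, t_end = 0.5, seed = 78, record_every = 0.1)
  expect_false(identical(a$counts, c2$counts))
})

test_that("conservation groups hold over every circuit and geometry", {
  cases <- list(
    list(circ = "core", g = plane_geometry()),
    list(circ = "receptor_far1", g = plane_geometry()),
    list(circ = "combined", g = plane_geometry()),
    list(circ = "combined", g = sphere_geometry())
  )
  ab <- c(Cdc42 = 400, Bem1GEF = 40, Far1GEF = 10, R = 200)
  for (cs in cases) {
    p <- build_circuit(cs$circ, cs$g, ab[names(ab) %in% names(
      build_circuit(cs$circ, cs$g)$abundances
    )])
    tr <- run_simulation(p, t_end = 2, seed = 3, record_every = 0.5)
    expect_true(check_conservation(tr), info = cs$circ)
  }
  # fixed seeds stay immobile and conserved
  pf <- build_circuit(
    "core_fixed_far1", plane_geometry(),
    c(Cdc42 = 300, Bem1GEF = 20, Far1GEF_s = 5)
  )
  init <- initial_condition("fixed_far1_seeds")
  trf <- run_simulation(pf, init, t_end = 1, seed = 4, record_every = 0.5)
  expect_true(check_conservation(trf))
  seed_code <- match("Far1GEF_s", trf$species_names) - 1L
  first <- trf$snapshots[[1]]
  last <- trf$snapshots[[length(trf$snapshots)]]
  sel_f <- which(first$species == seed_code)
  sel_l <- which(last$species == seed_code)
  expect_equal(
    first$pos[sel_f[order(first$id[sel_f])], ],
    last$pos[sel_l[order(last$id[sel_l])], ]
  )
})

test_that("membrane exchange equilibrates to k_5a / (k_5a + k_5b)", {
  # single inactive Cdc42 molecule cycling on/off the membrane: the fraction
  # of time membrane-bound is the two-state Markov equilibrium 36/49
  p <- small_core(n_cdc42 = 1, n_bem1 = 0)
  tr <- run_simulation(p, t_end = 60, seed = 10, record_every = 0.05)
  occ <- mean(tr$counts[, "Cdc42D_m"] +
    tr$counts[, "Cdc42T"] + tr$counts[, "Cdc42T_Bem1GEF"])
  expected <- 36 / 49
  # autocorrelated samples: allow a generous band around the equilibrium
  expect_lt(abs(occ - expected), 0.08)

  # many-molecule version tightens the estimate
  p2 <- small_core(n_cdc42 = 2000, n_bem1 = 0)
  tr2 <- run_simulation(p2, t_end = 2, seed = 11, record_every = 0.25)
  frac <- (tr2$counts[-(1:4), "Cdc42D_m"]) / 2000
  expect_lt(abs(mean(frac) - expected), 0.02)
})

test_that("well-mixed reaction bookkeeping matches the ODE solution", {
  skip_if_not_installed("deSolve")
  g <- plane_geometry()
  p <- build_circuit("core", g, c(Cdc42 = 150, Bem1GEF = 50))
  rhs <- function(t, y, parms) {
    rx <- p$reactions
    dy <- stats::setNames(numeric(length(y)), names(y))
    for (i in seq_len(nrow(rx))) {
      flux <- if (rx$kind[i] == "second_order") {
        rx$rate[i] * pi * rx$rho[i]^2 / g$A_m * y[rx$r1[i]] * y[rx$r2[i]]
      } else {
        rx$rate[i] * y[rx$r1[i]]
      }
      dy[rx$r1[i]] <- dy[rx$r1[i]] - flux
      if (!is.na(rx$r2[i])) dy[rx$r2[i]] <- dy[rx$r2[i]] - flux
      dy[rx$p1[i]] <- dy[rx$p1[i]] + flux
      if (!is.na(rx$p2[i])) dy[rx$p2[i]] <- dy[rx$p2[i]] + flux
    }
    list(dy)
  }
  y0 <- stats::setNames(numeric(nrow(p$species)), p$species$name)
  y0["Cdc42D_c"] <- 150
  y0["Bem1GEF_c"] <- 50
  times <- seq(0, 20, 2)
  sol <- deSolve::ode(y0, times, rhs, NULL)
  reps <- lapply(1:8, function(s) {
    run_simulation(p,
      t_end = 20, seed = s, record_every = 2,
      well_mixed = TRUE
    )$counts
  })
  mc <- Reduce("+", reps) / length(reps)
  for (sp in c("Cdc42D_m", "Cdc42D_c", "Cdc42T", "Bem1GEF_m")) {
    resid <- mc[-1, sp] - sol[-1, sp]
    # Monte-Carlo error: binomial-scale spread over 8 replicates
    tol <- 3 * pmax(sqrt(pmax(sol[-1, sp], 1)) / sqrt(8), 1.5)
    expect_true(all(abs(resid) < tol), info = sp)
  }
})

test_that("step_state advances time and preserves particle totals", {
  p <- small_core(n_cdc42 = 100, n_bem1 = 10)
  st <- initial_state(p, seed = 2)
  st2 <- step_state(st, p, n = 10, seed = 3)
  expect_equal(st2$t, 10 * p$dt)
  cdc <- c("Cdc42D_c", "Cdc42D_m", "Cdc42T", "Cdc42T_Bem1GEF")
  expect_equal(sum(st2$species %in% cdc), 100)
})

test_that("trajectory text output round-trips through tabular files", {
  p <- small_core(n_cdc42 = 50, n_bem1 = 5)
  tr <- run_simulation(p, t_end = 0.2, seed = 1, record_every = 0.1)
  d <- withr::local_tempdir()
  paths <- write_trajectory(tr, d)
  expect_true(all(file.exists(paths)))
  snaps <- read.delim(paths[1])
  expect_equal(nrow(snaps), 3 * 55)
  expect_true(all(c("t", "species", "x", "y") %in% names(snaps)))
  counts <- read.delim(paths[2], check.names = FALSE)
  expect_equal(counts$Cdc42D_c + counts$Cdc42D_m + counts$Cdc42T +
    counts$Cdc42T_Bem1GEF, rep(50, 3))
})
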