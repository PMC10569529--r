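test_that("geometry invariants hold", {
  g2 <- plane_geometry()
  expect_equal(g2$A_m, 78.540, tolerance = 1e-4)
  expect_equal(g2$L, 8.8623, tolerance = 1e-4)
  expect_equal(g2$A_m, g2$L^2)

  g3 <- sphere_geometry(R = 2.5)
  expect_equal(g3$A_m, 4 * pi * 2.5^2)
  expect_equal(g3$V_c, (4 / 3) * pi * 2.5^3)
  expect_error(sphere_geometry(R = 2.5, R_absorb = 2), "exceed")
})

test_that("molecule counts convert to the tabulated concentrations", {
  g <- sphere_geometry(R = 2.5)
  expect_equal(molecules_to_concentration(3000, g), 76.1, tolerance = 1e-3)
  expect_equal(molecules_to_concentration(170, g), 4.3, tolerance = 1e-2)
  expect_equal(molecules_to_concentration(30, g), 0.76, tolerance = 1e-2)
  expect_equal(molecules_to_concentration(0, g), 0)
  expect_error(molecules_to_concentration(-1, g), "non-negative")
  expect_error(molecules_to_concentration(10, plane_geometry()), "sphere")
  # round trip
  expect_equal(concentration_to_molecules(76.1, g), 3000, tolerance = 1e-3)
})

test_that("first-order membrane-association rates convert as V_c/A_m", {
  g <- sphere_geometry(R = 2.5)
  expect_equal(convert_rate_first_order_to_3d(10, g), 8.333, tolerance = 1e-4)
  expect_equal(convert_rate_first_order_to_3d(36, g), 30)
  expect_equal(convert_rate_first_order_to_3d(0, g), 0)
  expect_error(convert_rate_first_order_to_3d(10, plane_geometry()), "sphere")
})

test_that("second-order cytosol-membrane rates convert with the half-ball volume", {
  g <- sphere_geometry(R = 2.5)
  expect_equal(convert_rate_second_order_to_3d(256, 0.05, g), 6400)
  expect_equal(convert_rate_second_order_to_3d(300, 0.05, g), 7500)
  expect_equal(convert_rate_second_order_to_3d(0.025, 0.05, g), 0.625)
  expect_error(convert_rate_second_order_to_3d(1, 0, g), "rho")
})

test_that("applying the conversion rules reproduces the printed 3D column", {
  v <- validate_rate_conversions()
  # every convertible entry agrees to printed precision
  expect_true(all(v$matches[v$convertible]))
  # the one tuned entry is the membrane-membrane complex-formation rate
  expect_identical(v$label[!v$convertible], "lambda_4a")
})

test_that("build_circuit assembles the tabulated reaction sets", {
  p <- build_circuit("core", plane_geometry(), c(Cdc42 = 3000, Bem1GEF = 102))
  expect_equal(nrow(p$reactions), 10)
  expect_equal(p$reactions$rate[p$reactions$label == "k_1a"], 10)
  expect_equal(p$reactions$rate[p$reactions$label == "lambda_3"], 180)
  expect_true(all(p$reactions$rho[p$reactions$kind == "second_order"] == 0.05))

  p3 <- build_circuit("combined", sphere_geometry(),
    c(Cdc42 = 3000, Bem1GEF = 170, Far1GEF = 30, R = 2500))
  expect_equal(p3$reactions$rate[p3$reactions$label == "lambda_8a"], 7500)
  expect_equal(p3$reactions$rate[p3$reactions$label == "lambda_9"], 0.625)
  expect_equal(p3$reactions$kind[p3$reactions$label == "k_1a"], "surface_association")

  # every lambda row is second order, every k row first order or surface
  for (circ in c("core", "receptor_far1", "combined")) {
    pp <- build_circuit(circ, plane_geometry())
    lam <- grepl("^lambda", pp$reactions$label)
    expect_true(all(pp$reactions$kind[lam] == "second_order"))
    expect_true(all(pp$reactions$kind[!lam] %in%
      c("first_order", "surface_association")))
  }

  # empty population is a valid no-op system
  p0 <- build_circuit("core", plane_geometry(), c(Cdc42 = 0, Bem1GEF = 0))
  st <- initial_state(p0, seed = 1)
  expect_equal(length(st$species), 0)

  expect_error(build_circuit("nonsense"), "arg")
  expect_error(
    build_circuit("core", abundances = c(Cdc42 = -5)), "non-negative"
  )
})

test_that("reaction stoichiometry conserves every registered group", {
  for (circ in c("core", "receptor_far1", "combined", "core_fixed_far1")) {
    p <- build_circuit(circ, plane_geometry())
    for (gname in names(p$groups)) {
      members <- p$groups[[gname]]
      for (i in seq_len(nrow(p$reactions))) {
        rx <- p$reactions[i, ]
        balance <- sum(c(rx$p1, rx$p2) %in% members, na.rm = TRUE) -
          sum(c(rx$r1, rx$r2) %in% members, na.rm = TRUE)
        expect_equal(balance, 0,
          info = sprintf("%s: %s unbalanced for %s", circ, rx$label, gname)
        )
      }
    }
  }
  # pheromone variant conserves receptors (pheromone itself is open)
  p <- build_circuit("combined_pheromone", sphere_geometry())
  for (i in seq_len(nrow(p$reactions))) {
    rx <- p$reactions[i, ]
    members <- p$groups$R
    balance <- sum(c(rx$p1, rx$p2) %in% members, na.rm = TRUE) -
      sum(c(rx$r1, rx$r2) %in% members, na.rm = TRUE)
    expect_equal(balance, 0, info = rx$label)
  }
})

test_that("pheromone circuit is sphere-only and receptor residence is ~8 min", {
  expect_error(build_circuit("combined_pheromone", plane_geometry()), "sphere")
  expect_equal(receptor_residence_minutes(), 8.33, tolerance = 1e-2)
})
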