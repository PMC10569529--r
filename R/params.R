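#' Species and reaction tables
#'
#' The model's species and rate constants are shipped as plain-text tables
#' under `inst/extdata/` and are the single source of truth for every
#' circuit: [build_circuit()] assembles parameter sets from them and never
#' hard-codes a rate.
#'
#' @param circuit One of `"core"`, `"receptor_far1"`, `"combined"`,
#'   `"combined_pheromone"`, `"core_fixed_far1"`.
#' @return `polar_species_table()`: a data frame of species (name,
#'   compartment, diffusion coefficients, conservation group).
#'   `polar_reaction_table()`: a data frame of reactions with both the 2D and
#'   3D rate columns verbatim.
#' @export
polar_species_table <- function() {
  read.delim(
    system.file("extdata", "species.tsv", package = "polarsim"),
    stringsAsFactors = FALSE
  )
}

.CIRCUITS <- c(
  "core", "receptor_far1", "combined", "combined_pheromone", "core_fixed_far1"
)

#' @rdname polar_species_table
#' @export
polar_reaction_table <- function(circuit = "combined") {
  circuit <- match.arg(circuit, .CIRCUITS)
  rd <- function(f) {
    read.delim(
      system.file("extdata", f, package = "polarsim"),
      stringsAsFactors = FALSE
    )
  }
  core <- rd("reactions_core.tsv")
  rf <- rd("reactions_receptor_far1.tsv")
  phero <- rd("reactions_pheromone.tsv")
  seed <- rd("reactions_fixed_seed.tsv")
  switch(circuit,
    core = core,
    # Standalone receptor-Far1 circuit: receptor pathway plus the basal
    # Cdc42 membrane cycling and hydrolysis it acts on (no Bem1-GEF).
    receptor_far1 = rbind(rf, core[core$label %in% c("k_2b", "k_5a", "k_5b"), ]),
    combined = rbind(core, rf),
    # Pheromone-binding variant: constitutive receptor activation/delivery
    # (lambda_9, k_10) replaced by explicit pheromone binding and the
    # inactive-membrane-receptor pathway.
    combined_pheromone = rbind(
      core, rf[!rf$label %in% c("lambda_9", "k_10"), ], phero
    ),
    core_fixed_far1 = rbind(core, seed)
  )
}

#' Convert a first-order membrane-association rate from 2D to 3D
#'
#' In the planar model a cytosolic molecule associates with the membrane as a
#' first-order reaction with rate `k2d` (1/s). On the sphere the same process
#' is a surface association with rate `k3d = (V_c / A_m) * k2d` (um/s), where
#' `V_c` is the cytosolic volume and `A_m` the membrane area. Rates of
#' membrane-to-cytosol and membrane-bound first-order reactions are unchanged
#' between geometries.
#'
#' @param k2d First-order rate, 1/s.
#' @param geometry A [sphere_geometry()].
#' @return Surface-association rate, um/s.
#' @examples
#' convert_rate_first_order_to_3d(10, sphere_geometry())  # 8.333 um/s
#' @export
convert_rate_first_order_to_3d <- function(k2d, geometry = sphere_geometry()) {
  assert_geometry(geometry)
  if (!is_sphere(geometry)) stop("3D conversion requires a sphere geometry")
  if (any(k2d < 0)) stop("rate must be non-negative")
  (geometry$V_c / geometry$A_m) * k2d
}

#' Convert a second-order cytosol-membrane rate from 2D to 3D
#'
#' A bimolecular reaction between a cytosolic and a membrane-bound partner
#' fires when the pair is within the reactive radius `rho`. The 2D reaction
#' area is `pi * rho^2`; in 3D the reaction volume is the half-ball
#' `(1/2)(4/3) pi rho^3` (half, because one reactant is confined to the
#' membrane). The probability rate converts as
#' `lambda3d = (V_c / A_m) * (pi rho^2) / ((2/3) pi rho^3) * lambda2d`.
#' Membrane-membrane second-order rates are unchanged between geometries.
#'
#' @param lambda2d Second-order probability rate, 1/s.
#' @param rho Reactive radius, um.
#' @param geometry A [sphere_geometry()].
#' @return Second-order probability rate in 3D, 1/s.
#' @examples
#' convert_rate_second_order_to_3d(256, 0.05, sphere_geometry())  # 6400
#' @export
convert_rate_second_order_to_3d <- function(lambda2d, rho = 0.05,
                                            geometry = sphere_geometry()) {
  assert_geometry(geometry)
  if (!is_sphere(geometry)) stop("3D conversion requires a sphere geometry")
  if (any(rho <= 0)) stop("rho must be positive")
  if (any(lambda2d < 0)) stop("rate must be non-negative")
  v2d <- pi * rho^2
  v3d <- 0.5 * (4 / 3) * pi * rho^3
  (geometry$V_c / geometry$A_m) * (v2d / v3d) * lambda2d
}

#' Assemble a parameter set for one circuit variant in one geometry
#'
#' Builds the full parameter set (species, reactions with the
#' geometry-appropriate rate column, abundances, conservation groups) for a
#' circuit variant. Rates are taken verbatim from the shipped tables; the
#' conversion helpers ([convert_rate_first_order_to_3d()],
#' [convert_rate_second_order_to_3d()]) are used for validation, not to
#' populate entries, because a few 3D rates were tuned independently.
#'
#' @param circuit Circuit name; see [polar_reaction_table()].
#' @param geometry A [plane_geometry()] or [sphere_geometry()].
#' @param abundances Named integer vector/list of total copy numbers. Names
#'   among `Cdc42`, `Bem1GEF`, `Far1GEF`, `R` (receptors), `Far1GEF_s`
#'   (immobile seeds). Unnamed groups default to the modeled cell's values
#'   (3000 Cdc42, 170 Bem1-GEF, 30 Far1-GEF, 2500 receptors).
#' @param dt Time step, s.
#' @return A `polar_params` object.
#' @examples
#' p <- build_circuit("core", plane_geometry(), c(Cdc42 = 3000, Bem1GEF = 102))
#' nrow(p$reactions)  # 10
#' @export
build_circuit <- function(circuit = "combined",
                          geometry = plane_geometry(),
                          abundances = NULL,
                          dt = 1e-4) {
  circuit <- match.arg(circuit, .CIRCUITS)
  assert_geometry(geometry)
  stopifnot(dt > 0)
  tab <- polar_reaction_table(circuit)
  species <- polar_species_table()

  plane <- is_plane(geometry)
  if (plane && anyNA(tab$rate_2d)) {
    stop("circuit '", circuit, "' is defined only for the sphere geometry")
  }

  rate <- if (plane) tab$rate_2d else tab$rate_3d
  unit <- if (plane) tab$unit_2d else tab$unit_3d
  kind <- ifelse(tab$order == 2L, "second_order",
    ifelse(!plane & unit == "um s-1", "surface_association", "first_order")
  )

  split2 <- function(s) {
    parts <- strsplit(s, "+", fixed = TRUE)
    list(
      first = vapply(parts, `[`, "", 1L),
      second = vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, "")
    )
  }
  rx <- split2(tab$reactants)
  px <- split2(tab$products)

  reactions <- data.frame(
    label = tab$label, kind = kind,
    r1 = rx$first, r2 = rx$second, p1 = px$first, p2 = px$second,
    rate = rate, unit = unit, rho = tab$rho,
    description = tab$description,
    stringsAsFactors = FALSE
  )

  used <- unique(c(
    reactions$r1, reactions$r2, reactions$p1, reactions$p2
  ))
  used <- used[!is.na(used)]
  bad <- setdiff(used, species$name)
  if (length(bad)) stop("unknown species in reaction table: ", paste(bad, collapse = ", "))
  species <- species[species$name %in% used, , drop = FALSE]
  species$D <- if (plane) species$D_2d else species$D_3d
  species$mobile <- species$D > 0
  rownames(species) <- NULL

  defaults <- c(Cdc42 = 3000, Bem1GEF = 170, Far1GEF = 30, R = 2500, Far1GEF_s = 0)
  ab <- defaults
  if (!is.null(abundances)) {
    abundances <- unlist(abundances)
    if (is.null(names(abundances)) || any(!nzchar(names(abundances)))) {
      stop("abundances must be named")
    }
    bad <- setdiff(names(abundances), names(defaults))
    if (length(bad)) stop("unknown abundance group: ", paste(bad, collapse = ", "))
    if (any(abundances < 0)) stop("abundances must be non-negative")
    if (any(abundances != round(abundances))) stop("abundances must be integers")
    ab[names(abundances)] <- abundances
  }
  # Species each abundance group starts out as (placement done by the
  # initial-condition builder). Receptors start active in the
  # constitutive circuits, inactive in the pheromone-binding variant.
  init_species <- c(
    Cdc42 = "Cdc42D_c", Bem1GEF = "Bem1GEF_c", Far1GEF = "Far1GEF_c",
    R = if (circuit == "combined_pheromone") "Ri_m" else "Ra_m",
    Far1GEF_s = "Far1GEF_s"
  )
  keep <- init_species[names(ab)] %in% species$name
  ab <- ab[keep]
  init_species <- init_species[names(ab)]

  groups <- conservation_groups(species)

  structure(
    list(
      circuit = circuit, geometry = geometry, dt = dt,
      species = species, reactions = reactions,
      abundances = as.list(ab), init_species = init_species,
      groups = groups
    ),
    class = "polar_params"
  )
}

# Conservation groups from the species table's group annotations. A species
# annotated "A+B" (a complex) counts once in group A and once in group B.
conservation_groups <- function(species) {
  map <- list(
    Cdc42 = "Cdc42", Bem1GEF = "Bem1GEF",
    Far1GEF = "Far1GEF", R = "Receptor"
  )
  out <- lapply(map, function(tag) {
    hits <- vapply(
      strsplit(species$group, "+", fixed = TRUE),
      function(g) tag %in% g, logical(1)
    )
    species$name[hits]
  })
  out[vapply(out, length, 0L) > 0L]
}

#' @export
print.polar_params <- function(x, ...) {
  cat(sprintf(
    "<polar_params> circuit '%s' on %s\n", x$circuit, x$geometry$mode
  ))
  cat(sprintf(
    "  %d species, %d reactions, dt = %g s\n",
    nrow(x$species), nrow(x$reactions), x$dt
  ))
  ab <- unlist(x$abundances)
  cat("  abundances:", paste(names(ab), ab, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Validate the 3D rate column against the conversion formulas
#'
#' Applies the 2D-to-3D conversion rules to every reaction of the core and
#' receptor-Far1 tables and compares with the shipped 3D column. All entries
#' agree to printed precision except `lambda_4a`, whose 3D value was tuned
#' independently rather than converted.
#'
#' @param geometry A [sphere_geometry()].
#' @return Data frame with columns `label`, `rate_2d`, `rate_3d_printed`,
#'   `rate_3d_converted`, `convertible` (whether the conversion rule applies),
#'   `matches` (agreement to printed precision, NA where not convertible).
#' @export
validate_rate_conversions <- function(geometry = sphere_geometry()) {
  tab <- rbind(
    polar_reaction_table("core"),
    polar_reaction_table("receptor_far1")[1:6, ]
  )
  tab <- tab[!duplicated(tab$label), ]
  species <- polar_species_table()
  comp <- stats::setNames(species$compartment, species$name)
  first_sp <- vapply(strsplit(tab$reactants, "+", fixed = TRUE), `[`, "", 1L)
  second_sp <- vapply(
    strsplit(tab$reactants, "+", fixed = TRUE),
    function(p) if (length(p) > 1L) p[2L] else NA_character_, ""
  )

  conv <- rep(NA_real_, nrow(tab))
  convertible <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (tab$order[i] == 1L) {
      if (comp[[first_sp[i]]] == "cytosol") {
        # cytosol -> membrane association picks up the V_c/A_m length factor
        conv[i] <- convert_rate_first_order_to_3d(tab$rate_2d[i], geometry)
        convertible[i] <- TRUE
      } else {
        conv[i] <- tab$rate_2d[i] # membrane first-order rates pass through
        convertible[i] <- TRUE
      }
    } else {
      comps <- c(comp[[first_sp[i]]], comp[[second_sp[i]]])
      if (any(comps == "cytosol")) {
        conv[i] <- convert_rate_second_order_to_3d(
          tab$rate_2d[i], tab$rho[i], geometry
        )
        convertible[i] <- TRUE
      } else {
        conv[i] <- tab$rate_2d[i] # membrane-membrane rates pass through
        # lambda_4a is membrane-membrane yet differs between columns: tuned.
        convertible[i] <- tab$rate_2d[i] == tab$rate_3d[i]
      }
    }
  }
  digits <- nchar(sub("^[^.]*\\.?", "", as.character(tab$rate_3d)))
  matches <- ifelse(convertible, round(conv, digits) == tab$rate_3d, NA)
  data.frame(
    label = tab$label, rate_2d = tab$rate_2d,
    rate_3d_printed = tab$rate_3d, rate_3d_converted = conv,
    convertible = convertible, matches = matches,
    stringsAsFactors = FALSE
  )
}

#' Mean receptor membrane residence time
#'
#' Reciprocal of the receptor internalization rate `k_10`, in minutes. With
#' the endocytosis rate 0.002/s this is about 8 minutes, the mismatch that
#' prevents the receptor-Far1 loop from polarizing on its own.
#'
#' @param k10 Internalization rate, 1/s.
#' @return Residence time in minutes.
#' @export
receptor_residence_minutes <- function(k10 = NULL) {
  if (is.null(k10)) {
    tab <- polar_reaction_table("receptor_far1")
    k10 <- tab$rate_2d[tab$label == "k_10"]
  }
  stopifnot(k10 > 0)
  1 / k10 / 60
}
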