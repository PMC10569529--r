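#' Configure a named simulation experiment
#'
#' Bundles everything that determines a set of replicate runs: circuit,
#' geometry, abundances, initial condition, optional pheromone protocol or
#' frozen gradient field, duration and seeds. A `scale` factor divides the
#' duration and replicate count for desk-scale runs; it never changes the
#' time step, reactive radius or any rate (which would change the physics),
#' and scaled outputs are labeled as such.
#'
#' @param name Experiment name (used in reports and output files).
#' @param circuit Circuit variant, see [build_circuit()].
#' @param geometry A geometry object.
#' @param abundances Named abundances, see [build_circuit()].
#' @param init An [initial_condition()].
#' @param pheromone Optional [pheromone_protocol()].
#' @param field Optional [frozen_gradient_field()].
#' @param t_end Full-scale duration, s.
#' @param n_replicates Full-scale replicate count.
#' @param seeds Explicit seeds (defaults to `seed_base + 1:n`).
#' @param seed_base Base for default seeds.
#' @param scale Scale divisor for desk runs.
#' @param record_every Snapshot interval, s.
#' @return A `polar_experiment` configuration.
#' @export
experiment_config <- function(name, circuit = "combined",
                              geometry = plane_geometry(),
                              abundances = NULL,
                              init = initial_condition(),
                              pheromone = NULL, field = NULL,
                              t_end = 4000, n_replicates = 10,
                              seeds = NULL, seed_base = 0L,
                              scale = 1, record_every = 10) {
  stopifnot(scale >= 1, t_end > 0, n_replicates >= 1)
  t_run <- t_end / scale
  n_run <- max(1L, floor(n_replicates / scale))
  if (is.null(seeds)) seeds <- seed_base + seq_len(n_run)
  structure(
    list(
      name = name, circuit = circuit, geometry = geometry,
      abundances = abundances, init = init,
      pheromone = pheromone, field = field,
      t_end = t_run, n_replicates = n_run, seeds = seeds[seq_len(n_run)],
      scale = scale, record_every = record_every
    ),
    class = "polar_experiment"
  )
}

#' @export
print.polar_experiment <- function(x, ...) {
  cat(sprintf(
    "<polar_experiment> '%s': %s on %s, %g s x %d replicates%s\n",
    x$name, x$circuit, x$geometry$mode, x$t_end, x$n_replicates,
    if (x$scale > 1) sprintf(" (scaled 1/%g)", x$scale) else ""
  ))
  invisible(x)
}

#' Run all replicates of an experiment
#'
#' Runs each replicate, computes its K-value series and final state, and
#' optionally the cluster-count series. Trajectories are dropped by default
#' to keep memory bounded; pass `keep_trajectories = TRUE` to retain them.
#'
#' @param config A [experiment_config()].
#' @param params Optional pre-built parameter set (built from the config
#'   otherwise); lets scans modify rates between runs.
#' @param clusters Also compute cluster-count series per replicate.
#' @param keep_trajectories Retain the full trajectories in the result.
#' @param progress Print one line per replicate to stderr.
#' @return A `polar_experiment_result`: per-replicate K series (list),
#'   summary data frame (final K, fraction of window polarized, delta), and
#'   optionally cluster series / trajectories.
#' @export
run_experiment <- function(config, params = NULL, clusters = FALSE,
                           keep_trajectories = FALSE, progress = FALSE) {
  stopifnot(inherits(config, "polar_experiment"))
  if (is.null(params)) {
    params <- build_circuit(config$circuit, config$geometry, config$abundances)
  }
  thr <- polarity_thresholds(config$geometry$mode)[["polarized"]]
  ks <- list()
  cs <- list()
  trajs <- list()
  rows <- list()
  for (i in seq_along(config$seeds)) {
    seed <- config$seeds[i]
    tr <- run_simulation(
      params, config$init,
      t_end = config$t_end, seed = seed,
      record_every = config$record_every,
      pheromone = config$pheromone, field = config$field
    )
    kser <- k_series(tr)
    ks[[i]] <- kser
    d <- delta_statistic(kser, threshold = thr)
    rows[[i]] <- data.frame(
      replicate = i, seed = seed,
      K_final = kser$K[nrow(kser)],
      frac_polarized = mean(
        kser$K[kser$t >= max(kser$t) / 2] >= thr
      ),
      delta = d$delta, n_samples = d$n, delta_frac = d$delta_frac
    )
    if (clusters) cs[[i]] <- cluster_series(tr)
    if (keep_trajectories) trajs[[i]] <- tr
    if (progress) {
      message(sprintf(
        "[%s] replicate %d/%d (seed %d): K_final = %.2f",
        config$name, i, length(config$seeds), seed, kser$K[nrow(kser)]
      ))
    }
  }
  structure(
    list(
      config = config, k_series = ks,
      summary = do.call(rbind, rows),
      cluster_series = if (clusters) cs else NULL,
      trajectories = if (keep_trajectories) trajs else NULL,
      threshold = thr
    ),
    class = "polar_experiment_result"
  )
}

#' @export
print.polar_experiment_result <- function(x, ...) {
  cat(sprintf("<polar_experiment_result> '%s'\n", x$config$name))
  s <- x$summary
  cat(sprintf(
    "  K_final: %.2f +/- %.2f over %d replicates; mean frac polarized %.2f\n",
    mean(s$K_final), sd(s$K_final), nrow(s), mean(s$frac_polarized)
  ))
  invisible(x)
}

#' Scan one parameter of an experiment
#'
#' Repeats an experiment over a grid of values of one knob:
#'
#' * `"bem1_abundance"`, `"far1_abundance"`, `"cdc42_abundance"`,
#'   `"receptor_abundance"`, `"n_seeds"`: copy-number scans.
#' * `"dispersion_sigma"`: dispersion of the initial receptor Gaussian
#'   (`Inf` = uniform).
#' * `"receptor_residence"`: receptor membrane residence time in minutes;
#'   the internalization rates (`k_10`) and the delivery rate (`lambda_9`)
#'   are scaled jointly by the same factor so the steady-state surface
#'   receptor number stays approximately fixed while trafficking speeds up.
#'
#' @param config A [experiment_config()] (the template).
#' @param parameter Scanned knob, see Details.
#' @param values Numeric grid.
#' @param ... Passed to [run_experiment()].
#' @return A `polar_scan`: per-value [run_experiment()] results plus a
#'   summary data frame (`value`, mean/sd of final K, mean delta fraction).
#' @export
scan_parameter <- function(config,
                           parameter = c(
                             "bem1_abundance", "far1_abundance",
                             "cdc42_abundance", "receptor_abundance",
                             "n_seeds", "dispersion_sigma",
                             "receptor_residence"
                           ),
                           values, ...) {
  parameter <- match.arg(parameter)
  results <- vector("list", length(values))
  for (j in seq_along(values)) {
    v <- values[j]
    cfg <- config
    params <- NULL
    ab <- cfg$abundances
    if (parameter == "bem1_abundance") {
      ab[["Bem1GEF"]] <- v
    } else if (parameter == "far1_abundance") {
      ab[["Far1GEF"]] <- v
    } else if (parameter == "cdc42_abundance") {
      ab[["Cdc42"]] <- v
    } else if (parameter == "receptor_abundance") {
      ab[["R"]] <- v
    } else if (parameter == "n_seeds") {
      ab[["Far1GEF_s"]] <- v
    } else if (parameter == "dispersion_sigma") {
      cfg$init <- initial_condition("dispersed_receptors", sigma = v)
    } else if (parameter == "receptor_residence") {
      params <- build_circuit(cfg$circuit, cfg$geometry, ab)
      base_res <- receptor_residence_minutes()
      f <- base_res / v # speed-up factor relative to the table rates
      speed <- params$reactions$label %in% c("k_10", "k_10b", "lambda_9")
      params$reactions$rate[speed] <- params$reactions$rate[speed] * f
    }
    cfg$abundances <- ab
    cfg$name <- sprintf("%s[%s=%g]", config$name, parameter, v)
    results[[j]] <- run_experiment(cfg, params = params, ...)
  }
  summaries <- do.call(rbind, lapply(seq_along(values), function(j) {
    s <- results[[j]]$summary
    data.frame(
      value = values[j],
      K_final_mean = mean(s$K_final), K_final_sd = sd(s$K_final),
      frac_polarized = mean(s$frac_polarized),
      delta_frac = mean(s$delta_frac)
    )
  }))
  structure(
    list(parameter = parameter, values = values, results = results,
      summary = summaries),
    class = "polar_scan"
  )
}

#' @export
print.polar_scan <- function(x, ...) {
  cat(sprintf("<polar_scan> over %s\n", x$parameter))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write an experiment result as tabular text
#'
#' @param result A `polar_experiment_result`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_experiment <- function(result, dir) {
  stopifnot(inherits(result, "polar_experiment_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  f <- file.path(dir, "summary.tsv")
  write.table(result$summary, f, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, f)
  kall <- do.call(rbind, lapply(seq_along(result$k_series), function(i) {
    cbind(replicate = i, result$k_series[[i]])
  }))
  f <- file.path(dir, "k_series.tsv")
  write.table(kall, f, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, f)
  if (!is.null(result$cluster_series)) {
    call_ <- do.call(rbind, lapply(seq_along(result$cluster_series), function(i) {
      cbind(replicate = i, as.data.frame(result$cluster_series[[i]]))
    }))
    f <- file.path(dir, "cluster_series.tsv")
    write.table(call_, f, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, f)
  }
  cfg <- result$config
  f <- file.path(dir, "config.txt")
  writeLines(c(
    sprintf("name\t%s", cfg$name),
    sprintf("circuit\t%s", cfg$circuit),
    sprintf("geometry\t%s", cfg$geometry$mode),
    sprintf("t_end\t%g", cfg$t_end),
    sprintf("n_replicates\t%d", cfg$n_replicates),
    sprintf("scale\t%g", cfg$scale),
    sprintf("seeds\t%s", paste(cfg$seeds, collapse = ",")),
    sprintf("init\t%s", cfg$init$kind)
  ), f)
  invisible(c(paths, f))
}
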