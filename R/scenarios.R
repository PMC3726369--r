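# Scenario presets reproducing each figure-level computation, the ensemble
# robustness analysis, and the YAML configuration interface.

.scenario_registry <- function() {
  list(
    fig3_timecourses = list(variant = "antrum",
                            obs = "expression"),
    fig4_growing = list(variant = "two_compartment", obs = "gonadotropins",
                        scaled = FALSE),
    fig4_scaled = list(variant = "two_compartment", obs = "gonadotropins",
                       scaled = TRUE),
    fig4_antrum = list(variant = "antrum", obs = "gonadotropins",
                       scaled = TRUE),
    fig4_mixed = list(variant = "antrum_mixed", obs = "gonadotropins",
                      scaled = TRUE),
    fig5_steroids = list(variant = "antrum", obs = "steroids"),
    fig6_receptors = list(variant = "antrum", obs = "receptors"),
    supp_thick_theca = list(variant = "antrum", obs = "steroids",
                            theca_scale = 1.2)
  )
}

#' Registered scenario names
#' @return character vector of scenario names accepted by
#'   [run_scenario()].
#' @export
scenario_names <- function() names(.scenario_registry())

# scalar time-series observables summarising a scenario (used both for the
# CSV outputs and as the quantities tracked by the robustness bands)
.scenario_series <- function(sim, spec) {
  if (spec$obs == "expression") {
    expression_timecourses(sim)
  } else if (spec$obs == "steroids") {
    a <- compartment_average(sim, "A", "fluid"); a$name <- "A_fluid_nM"
    e <- compartment_average(sim, "E", "fluid"); e$name <- "E_fluid_nM"
    list(A_fluid = a, E_fluid = e)
  } else if (spec$obs == "gonadotropins") {
    comp <- if (sim$geometry$variant == "two_compartment") "granulosa" else "fluid"
    f <- compartment_average(sim, "F", comp)
    l <- compartment_average(sim, "L", comp)
    f$name <- paste0("F_", comp, "_nM"); l$name <- paste0("L_", comp, "_nM")
    list(F_avg = f, L_avg = l)
  } else { # receptors
    tc <- expression_timecourses(sim)
    er <- compartment_average(sim, sim$conc[, "Re", ] + sim$conc[, "Ce", ],
                              "granulosa")
    er$name <- "total_ER_granulosa"; er$units <- "nM"
    c(tc, list(er_granulosa = er))
  }
}

#' Run a figure-level scenario
#'
#' Runs the geometry / observable combination behind one of the reported
#' figures, with daily outputs over 5 days by default:
#' \describe{
#'   \item{fig3_timecourses}{antrum geometry; the four expression time
#'     courses (LHR theca and granulosa, FSHR granulosa, aromatase proxy).}
#'   \item{fig4_growing / fig4_scaled}{two-compartment geometry; F and L
#'     profiles on the growing or scaled domain.}
#'   \item{fig4_antrum / fig4_mixed}{antrum geometry (with and without
#'     rapid fluid mixing); F and L profiles.}
#'   \item{fig5_steroids}{antrum geometry; steroid production fields,
#'     profiles, and fluid-averaged A and E.}
#'   \item{fig6_receptors}{antrum geometry; receptor production, free,
#'     bound and activity fields.}
#'   \item{supp_thick_theca}{as fig5_steroids but with a 20% thicker
#'     theca, the same parameter values otherwise.}
#' }
#'
#' If `out_dir` is given, the scenario writes a long-form solution CSV,
#' one CSV of its summary time series, and a JSON manifest recording the
#' resolved configuration.
#'
#' @param name scenario name, see [scenario_names()].
#' @param out_dir optional output directory (created if needed).
#' @param config optional list with entries `parameters` (named
#'   overrides), `geometry` (overrides passed to [follicle_geometry()]),
#'   and `solver` (`refine`, `rtol`, `atol`, `mix_interval`,
#'   `days`, `outputs_per_day`), e.g. from [read_follicle_config()].
#' @return (invisibly) list with `sim` (the `follicle_sim`), `series`
#'   (summary time courses), and `files` (paths written).
#' @export
run_scenario <- function(name, out_dir = NULL, config = list()) {
  reg <- .scenario_registry()
  if (!name %in% names(reg)) {
    stop("unknown scenario '", name, "'; see scenario_names()")
  }
  spec <- reg[[name]]
  params <- do.call(follicle_parameters, as.list(config$parameters))
  gargs <- as.list(config$geometry)
  gargs$variant <- spec$variant
  if (!is.null(spec$theca_scale) && is.null(gargs$theca_scale)) {
    gargs$theca_scale <- spec$theca_scale
  }
  geometry <- do.call(follicle_geometry, gargs)
  sol <- as.list(config$solver)
  days <- if (is.null(sol$days)) 5 else sol$days
  opd <- if (is.null(sol$outputs_per_day)) 1 else sol$outputs_per_day
  times <- seq(0, days * 86400, by = 86400 / opd)
  mesh <- follicle_mesh(geometry,
                        refine = if (is.null(sol$refine)) 1 else sol$refine)
  sim <- simulate_follicle(
    params, geometry, times = times, mesh = mesh,
    rtol = if (is.null(sol$rtol)) 1e-6 else sol$rtol,
    atol = if (is.null(sol$atol)) 1e-8 else sol$atol,
    mix_interval = if (is.null(sol$mix_interval)) 600 else sol$mix_interval)
  series <- .scenario_series(sim, spec)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(out_dir, paste0(name, "_solution.csv"))
    export_solution_csv(sim, f1)
    f2 <- file.path(out_dir, paste0(name, "_series.csv"))
    export_series_csv(series, f2)
    f3 <- file.path(out_dir, paste0(name, "_manifest.json"))
    manifest <- list(scenario = name,
                     parameters = unclass(params),
                     geometry = unclass(geometry),
                     solver = sim$diagnostics,
                     times_s = times)
    jsonlite::write_json(manifest, f3, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(f1, f2, f3)
  }
  invisible(list(sim = sim, series = series, files = files))
}

#' Ensemble robustness bands under parameter noise
#'
#' Re-runs a scenario `n_runs` times with all kinetic parameters jointly
#' perturbed by multiplicative Gaussian noise (each run one draw, constant
#' in time) and returns the per-time mean and standard deviation of each
#' of the scenario's summary time courses. Runs that fail to integrate
#' are excluded and counted; more than 20% failures is an error. A fixed
#' seed reproduces the ensemble exactly.
#'
#' @param name scenario name.
#' @param noise a [noise_spec()].
#' @param config optional configuration list as in [run_scenario()].
#' @return object of class `robustness_result`: list with `times`,
#'   `mean` and `sd` (times x observables matrices), `n_ok`, `n_failed`,
#'   and the `noise` spec used.
#' @export
robustness_bands <- function(name, noise = noise_spec(), config = list()) {
  reg <- .scenario_registry()
  if (!name %in% names(reg)) stop("unknown scenario '", name, "'")
  base <- do.call(follicle_parameters, as.list(config$parameters))
  draws <- sample_noisy_parameters(base, noise)
  runs <- vector("list", noise$n_runs)
  failed <- 0L
  for (i in seq_len(noise$n_runs)) {
    cfg <- config
    cfg$parameters <- unclass(draws[[i]])
    runs[[i]] <- tryCatch(run_scenario(name, config = cfg)$series,
                          error = function(e) NULL)
    if (is.null(runs[[i]])) failed <- failed + 1L
  }
  if (failed > 0.2 * noise$n_runs) {
    stop(failed, " of ", noise$n_runs, " ensemble runs failed to integrate")
  }
  ok <- runs[!vapply(runs, is.null, logical(1))]
  obs_names <- vapply(ok[[1]], `[[`, "", "name")
  times <- ok[[1]][[1]]$times
  arr <- vapply(ok, function(r) {
    vapply(r, `[[`, numeric(length(times)), "values")
  }, matrix(0, length(times), length(obs_names)))
  mu <- apply(arr, c(1, 2), mean)
  sd <- apply(arr, c(1, 2), stats::sd)
  if (length(ok) == 1L) sd[] <- 0
  colnames(mu) <- colnames(sd) <- obs_names
  structure(list(times = times, mean = mu, sd = sd,
                 n_ok = length(ok), n_failed = failed, noise = noise,
                 scenario = name),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf(
    "Robustness ensemble '%s': %d runs (%d failed), relative sd %.2f\n",
    x$scenario, x$n_ok + x$n_failed, x$n_failed, x$noise$relative_sd))
  cat("final-time mean +/- sd:\n")
  last <- nrow(x$mean)
  print(data.frame(mean = signif(x$mean[last, ], 4),
                   sd = signif(x$sd[last, ], 4)))
  invisible(x)
}

#' Read a YAML configuration file
#'
#' Accepts a structured configuration with optional sections
#' `parameters` (field names exactly as in [follicle_parameters()],
#' values in internal units), `geometry` (arguments of
#' [follicle_geometry()]), `solver` and `noise`. Unknown parameter names
#' are rejected when the configuration is applied.
#'
#' @param path path to a YAML file.
#' @return a configuration list for [run_scenario()] /
#'   [robustness_bands()].
#' @export
read_follicle_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("parameters", "geometry", "solver", "noise")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "))
  }
  cfg
}
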