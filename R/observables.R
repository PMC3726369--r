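# Reductions of the space-time solution to the reported quantities:
# compartment-averaged time courses, steroid production fields, and the
# receptor production / free / bound / activity field sets.

#' Observable time course
#'
#' Light-weight container for a named scalar time course: values at the
#' simulation's output times with units and provenance recorded.
#'
#' @param name observable name.
#' @param times times, s.
#' @param values values (same length as `times`).
#' @param units unit string.
#' @param compartment compartment the series was reduced over.
#' @param normalized whether values are scaled to their own maximum.
#' @return object of class `observable_series`.
#' @export
observable_series <- function(name, times, values, units,
                              compartment = NA_character_,
                              normalized = FALSE) {
  stopifnot(length(times) == length(values))
  structure(list(name = name, times = times, values = values, units = units,
                 compartment = compartment, normalized = normalized),
            class = "observable_series")
}

#' @export
print.observable_series <- function(x, ...) {
  cat(sprintf("%s [%s]%s over '%s':\n", x$name, x$units,
              if (x$normalized) " (normalized)" else "", x$compartment))
  print(stats::setNames(signif(x$values, 4),
                        sprintf("%.1fd", x$times / 86400)))
  invisible(x)
}

#' Normalise a series to its own maximum
#'
#' @param series an `observable_series` with a positive maximum.
#' @return the series scaled so its maximum is 1.
#' @export
normalize_series <- function(series) {
  m <- max(series$values)
  if (m <= 0) stop("series has no positive maximum to normalise by")
  series$values <- series$values / m
  series$units <- "relative"
  series$normalized <- TRUE
  series
}

#' Length-weighted compartment average
#'
#' Averages a species concentration (or an arbitrary field given as a
#' time x node matrix) over the nodes of one compartment at each output
#' time, weighting by the node control volumes within the compartment.
#'
#' @param sim a `follicle_sim`.
#' @param species a species code, or a numeric matrix
#'   (times x nodes) to average.
#' @param compartment `"theca"`, `"granulosa"`, `"coc"`, `"fluid"`, or
#'   `"cells"` (granulosa plus COC).
#' @return an [observable_series()].
#' @export
compartment_average <- function(sim, species, compartment) {
  cn <- .comp_nodes(sim$mesh, compartment)
  if (is.character(species)) {
    M <- sim$conc[, species, , drop = FALSE]
    dim(M) <- dim(sim$conc)[c(1, 3)]
    nm <- species
    units <- "nM"
  } else {
    M <- species
    nm <- "field"
    units <- ""
  }
  vals <- as.vector(M[, cn$idx, drop = FALSE] %*% cn$weights) / sum(cn$weights)
  observable_series(paste0(nm, "_", compartment), sim$times, vals, units,
                    compartment)
}

# regulatory activities over the whole solution: list of time x node
# matrices sigma_F, sigma_L, sigma_E, sigma_I, sigma_G; stored states may
# carry negatives within the solver tolerance, clipped here
.sigma_fields <- function(sim) {
  p <- sim$params
  regulatory_state(pmax(sim$conc[, "Cf", ], 0), pmax(sim$conc[, "Cl", ], 0),
                   pmax(sim$conc[, "Ce", ], 0), pmax(sim$conc[, "I", ], 0), p)
}

#' Aromatase activity proxy field
#'
#' The model carries no explicit aromatase species; the plotted
#' "aromatase" quantity is the dimensionless regulation factor of the
#' estradiol production term, `sigma_I (1 + sigma_E sigma_G)(1 + sigma_G)`,
#' evaluated pointwise. Using `sigma_I` rather than the IGF complex
#' concentration itself makes the proxy comparable across compartments.
#'
#' @param sim a `follicle_sim`.
#' @return times x nodes matrix (dimensionless).
#' @export
aromatase_proxy <- function(sim) {
  s <- .sigma_fields(sim)
  s$sigma_I * (1 + s$sigma_E * s$sigma_G) * (1 + s$sigma_G)
}

#' Steroid production-rate fields
#'
#' Returns the androgen production field (blood delivery
#' `rho_A (1 + sigma_G) Delta` on the theca) and the estradiol production
#' field (the aromatase Michaelis-Menten term on the cell block), each as
#' a times x nodes matrix in nM/s.
#'
#' @param sim a `follicle_sim`.
#' @return list with elements `A` and `E`.
#' @export
steroid_production_fields <- function(sim) {
  p <- sim$params
  ind <- indicators(sim$mesh$xi, sim$geometry)
  s <- .sigma_fields(sim)
  A <- pmax(sim$conc[, "A", ], 0)
  I <- pmax(sim$conc[, "I", ], 0)
  prodA <- sweep(p$rho_A * (1 + s$sigma_G) * p$Delta, 2, ind$Theta, `*`)
  prodE <- sweep(p$rho_E * (A / (A + p$K_M)) * I *
                   (1 + s$sigma_E * s$sigma_G) * (1 + s$sigma_G),
                 2, ind$Gamma, `*`)
  list(A = prodA, E = prodE)
}

#' Expression time courses of the measured genes
#'
#' The four compartment-averaged series whose kinetics the model is
#' calibrated against: total LH receptor (free + bound, `Rl + Cl`) in the
#' theca and in the granulosa, total FSH receptor (`Rf + Cf`) in the
#' granulosa, and the aromatase activity proxy in the granulosa. Total
#' (free + bound) receptor is used because ligand-bound LH receptors are
#' heavily internalised, so free receptor alone would understate thecal
#' expression. The measured data are relative, so set `normalize = TRUE`
#' to compare shapes.
#'
#' @param sim a `follicle_sim`.
#' @param normalize scale each series to its own maximum.
#' @return named list of four [observable_series()]:
#'   `lhr_theca`, `lhr_granulosa`, `fshr_granulosa`,
#'   `aromatase_granulosa`.
#' @export
expression_timecourses <- function(sim, normalize = FALSE) {
  tot_lhr <- sim$conc[, "Rl", ] + sim$conc[, "Cl", ]
  tot_fshr <- sim$conc[, "Rf", ] + sim$conc[, "Cf", ]
  out <- list(
    lhr_theca = compartment_average(sim, tot_lhr, "theca"),
    lhr_granulosa = compartment_average(sim, tot_lhr, "granulosa"),
    fshr_granulosa = compartment_average(sim, tot_fshr, "granulosa"),
    aromatase_granulosa = compartment_average(sim, aromatase_proxy(sim),
                                              "granulosa")
  )
  nm <- c("total_LHR_theca", "total_LHR_granulosa", "total_FSHR_granulosa",
          "aromatase_proxy_granulosa")
  un <- c("nM", "nM", "nM", "dimensionless")
  for (k in seq_along(out)) {
    out[[k]]$name <- nm[k]
    out[[k]]$units <- un[k]
  }
  if (normalize) out <- lapply(out, normalize_series)
  out
}

#' Receptor field sets
#'
#' For each receptor system (FSH, LH, estrogen) returns the four spatial
#' field families reported for the receptor figures: the production-rate
#' field (the regulated rho term of the receptor equation, nM/s), the
#' free-receptor field, the bound-complex field (both nM), and the
#' receptor activity field (the Hill activity of the bound complex,
#' dimensionless in `[0, 1)`). All fields are times x nodes matrices.
#'
#' @param sim a `follicle_sim`.
#' @return nested list `list(fsh, lh, estrogen)`, each with elements
#'   `production`, `free`, `bound`, `activity`.
#' @export
receptor_fields <- function(sim) {
  p <- sim$params
  ind <- indicators(sim$mesh$xi, sim$geometry)
  s <- .sigma_fields(sim)
  gam <- matrix(ind$Gamma, nrow = length(sim$times),
                ncol = length(sim$mesh$xi), byrow = TRUE)
  list(
    fsh = list(
      production = p$rho_RF * (gam * p$theta + s$sigma_I * (1 + s$sigma_E)),
      free = sim$conc[, "Rf", ], bound = sim$conc[, "Cf", ],
      activity = s$sigma_F),
    lh = list(
      production = p$rho_RL * s$sigma_I * (1 + s$sigma_E),
      free = sim$conc[, "Rl", ], bound = sim$conc[, "Cl", ],
      activity = s$sigma_L),
    estrogen = list(
      production = p$rho_RE * (1 + s$sigma_E) * (1 - s$sigma_I),
      free = sim$conc[, "Re", ], bound = sim$conc[, "Ce", ],
      activity = s$sigma_E)
  )
}

#' Export observable series to CSV
#'
#' Writes one or more series sharing the same time grid to a CSV file
#' with a `time_s` column followed by one column per series, preceded by
#' comment lines recording the units. Deterministic column order (the
#' order given). Reading the file back reproduces the values exactly.
#'
#' @param series a single [observable_series()] or a list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_series_csv <- function(series, path) {
  if (inherits(series, "observable_series")) series <- list(series)
  if (length(series)) {
    tt <- series[[1]]$times
    for (s in series) stopifnot(identical(s$times, tt))
    df <- data.frame(time_s = tt)
    for (s in series) df[[s$name]] <- s$values
    meta <- sprintf("# %s: %s", vapply(series, `[[`, "", "name"),
                    vapply(series, `[[`, "", "units"))
  } else {
    df <- data.frame(time_s = numeric(0))
    meta <- character(0)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Export the full solution in long form
#'
#' Writes columns `time_s, xi, x_mm, species, conc_nM` for every stored
#' output time, node and species.
#'
#' @param sim a `follicle_sim`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_solution_csv <- function(sim, path) {
  nt <- length(sim$times); nx <- length(sim$mesh$xi)
  xmat <- t(vapply(sim$times, function(t) {
    physical_coordinate(sim$mesh$xi, t, sim$geometry, sim$params)
  }, numeric(nx)))                     # nt x nx
  idx <- expand.grid(t = seq_len(nt), sp = seq_len(11L), node = seq_len(nx))
  df <- data.frame(
    time_s = sim$times[idx$t],
    xi = sim$mesh$xi[idx$node],
    x_mm = xmat[cbind(idx$t, idx$node)],
    species = species_names()[idx$sp],
    conc_nM = as.vector(sim$conc)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
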