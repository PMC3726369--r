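# Reductions: compartment averages, expression time courses, receptor
# fields and CSV export.

test_that("compartment averages are exact for uniform and initial fields", {
  sim <- default_antrum_sim()
  nt <- length(sim$times); nx <- length(sim$mesh$xi)
  uni <- matrix(4.2, nt, nx)
  for (comp in c("theca", "granulosa", "coc", "fluid", "cells")) {
    expect_equal(compartment_average(sim, uni, comp)$values, rep(4.2, nt))
  }
  # initial IGF complex: 1500 nM over the theca, zero elsewhere
  expect_equal(compartment_average(sim, "I", "theca")$values[1], 1500)
  expect_equal(compartment_average(sim, "I", "granulosa")$values[1], 0)
  expect_equal(compartment_average(sim, "I", "fluid")$values[1], 0)
})

test_that("compartment averaging is linear and bounded by the field range", {
  sim <- default_antrum_sim()
  set.seed(4)
  nt <- length(sim$times); nx <- length(sim$mesh$xi)
  A <- matrix(runif(nt * nx), nt, nx)
  B <- matrix(runif(nt * nx), nt, nx)
  for (comp in c("theca", "fluid")) {
    va <- compartment_average(sim, A, comp)$values
    vb <- compartment_average(sim, B, comp)$values
    vab <- compartment_average(sim, 2 * A + 3 * B, comp)$values
    expect_equal(vab, 2 * va + 3 * vb)
    idx <- follicleRD:::.comp_nodes(sim$mesh, comp)$idx
    expect_true(all(va >= apply(A[, idx, drop = FALSE], 1, min) - 1e-12))
    expect_true(all(va <= apply(A[, idx, drop = FALSE], 1, max) + 1e-12))
  }
})

test_that("normalised series are invariant under uniform field rescaling", {
  sim <- default_antrum_sim()
  s1 <- normalize_series(compartment_average(sim, "E", "fluid"))
  scaled <- compartment_average(sim, 57.3 * sim$conc[, "E", ], "fluid")
  s2 <- normalize_series(scaled)
  expect_equal(s1$values, s2$values)
  expect_error(normalize_series(observable_series("z", 0:2, rep(0, 3), "nM")),
               "positive maximum")
})

test_that("expression time courses start from the imposed initial pattern", {
  sim <- default_antrum_sim()
  tc <- expression_timecourses(sim)
  # no receptors anywhere at t = 0
  expect_equal(tc$lhr_theca$values[1], 0)
  expect_equal(tc$lhr_granulosa$values[1], 0)
  expect_equal(tc$fshr_granulosa$values[1], 0)
  # the aromatase proxy is zero in the granulosa but positive in the theca
  expect_equal(tc$aromatase_granulosa$values[1], 0)
  prox <- aromatase_proxy(sim)
  th0 <- compartment_average(sim, prox, "theca")$values[1]
  expect_gt(th0, 0)
  # sigma_I(0.3 K_I) enters the t=0 theca proxy
  expect_equal(th0, 0.09 / 1.09, tolerance = 1e-6)
  norm <- expression_timecourses(sim, normalize = TRUE)
  expect_equal(max(norm$lhr_theca$values), 1)
})

test_that("receptor fields respect their analytic bounds", {
  sim <- default_antrum_sim()
  rf <- receptor_fields(sim)
  for (sys in rf) {
    expect_true(all(sys$activity >= 0 & sys$activity < 1))
    expect_true(all(sys$production >= 0))
  }
  # the theta term is a production floor for FSHR in the cell block
  ind <- indicators(sim$mesh$xi, sim$geometry)
  p <- sim$params
  floor_g <- p$rho_RF * p$theta
  cells <- ind$Gamma == 1
  expect_true(all(rf$fsh$production[, cells] >= floor_g - 1e-12))
})

test_that("CSV export round-trips exactly and keeps the declared columns", {
  sim <- default_antrum_sim()
  a <- compartment_average(sim, "A", "fluid"); a$name <- "A_fluid_nM"
  e <- compartment_average(sim, "E", "fluid"); e$name <- "E_fluid_nM"
  f <- tempfile(fileext = ".csv")
  export_series_csv(list(a, e), f)
  df <- utils::read.csv(f, comment.char = "#")
  expect_identical(names(df), c("time_s", "A_fluid_nM", "E_fluid_nM"))
  expect_equal(df$A_fluid_nM, a$values, tolerance = 1e-12)
  expect_equal(df$E_fluid_nM, e$values, tolerance = 1e-12)
  # empty export: header-only file
  f2 <- tempfile(fileext = ".csv")
  export_series_csv(list(), f2)
  expect_equal(nrow(utils::read.csv(f2)), 0)

  f3 <- tempfile(fileext = ".csv")
  export_solution_csv(sim, f3)
  sol <- utils::read.csv(f3)
  expect_identical(names(sol), c("time_s", "xi", "x_mm", "species", "conc_nM"))
  expect_equal(nrow(sol), length(sim$times) * 11 * length(sim$mesh$xi))
  # spot-check one cell against the array
  row <- sol[sol$time_s == 0 & sol$species == "I", ]
  expect_equal(row$conc_nM[order(row$xi)], sim$conc[1, "I", ],
               tolerance = 1e-12)
  unlink(c(f, f2, f3))
})

test_that("field extraction matches the stored array", {
  sim <- default_antrum_sim()
  expect_equal(field_at(sim, "I", 0), sim$conc[1, "I", ])
  expect_error(field_at(sim, "I", 12345), "output times")
})
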