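# Mesh construction, initial conditions, and the integrator's analytic
# limit behaviours.

test_that("mesh is boundary-fitted and resolves every layer", {
  for (g in list(follicle_geometry("antrum"),
                 follicle_geometry("two_compartment"),
                 follicle_geometry("antrum", theca_scale = 1.2))) {
    m <- follicle_mesh(g)
    expect_true(all(diff(m$xi) > 0))
    expect_true(all(c(-1, 1, -g$xi_theta, g$xi_theta) %in% m$xi))
    if (g$variant != "two_compartment") {
      expect_true(all(c(g$xi_phi1, g$xi_phi2) %in% m$xi))
    }
    expect_true(all(table(m$label) >= 8))
    expect_equal(sum(m$weights), 2)  # control volumes tile [-1, 1]
    m2 <- follicle_mesh(g, refine = 2)
    expect_gt(length(m2$xi), 1.8 * length(m$xi))
  }
})

test_that("initial state is zero except the thecal IGF complex", {
  p <- follicle_parameters()
  g <- follicle_geometry("antrum")
  m <- follicle_mesh(g)
  S <- initial_state(p, m)
  th <- m$label == "theca"
  expect_true(all(S[, !th] == 0))
  expect_true(all(S["I", th] == 0.3 * p$K_I))
  expect_equal(unique(S["I", th]), 1500)
  expect_true(all(S[setdiff(species_names(), "I"), ] == 0))
  # the theca exists at both ends, so I(0) is nonzero at both
  expect_true(any(S["I", m$xi < 0] > 0) && any(S["I", m$xi > 0] > 0))
})

test_that("zero sources give the identically zero solution", {
  p <- limit_params()   # everything off, I0_frac = 0
  g <- follicle_geometry("antrum")
  sim <- simulate_follicle(p, g, times = c(0, 43200, 86400))
  expect_equal(max(abs(sim$conc)), 0)
})

test_that("pure growth dilutes every species by Lambda(0)/Lambda(t)", {
  p <- limit_params(keep = "v")  # growth only: D = 0, R = 0
  g <- follicle_geometry("antrum")
  m <- follicle_mesh(g)
  set.seed(1)
  S0 <- matrix(runif(11 * length(m$xi), 0, 10), nrow = 11,
               dimnames = list(species_names(), NULL))
  times <- c(0, 86400, 432000)
  sim <- simulate_follicle(p, g, times = times, mesh = m, init = S0)
  for (k in 2:3) {
    fac <- p$Lambda0 / domain_length(times[k], p)
    expect_equal(sim$conc[k, , ], S0 * fac, tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("a uniform profile is a fixed point without growth or reactions", {
  p <- limit_params()
  for (f in c("D_H", "D_S", "D_R", "D_CL", "D_I")) p[[f]] <- follicle_parameters()[[f]]
  g <- follicle_geometry("antrum")
  m <- follicle_mesh(g)
  S0 <- matrix(3.7, nrow = 11, ncol = length(m$xi),
               dimnames = list(species_names(), NULL))
  sim <- simulate_follicle(p, g, times = c(0, 86400), mesh = m, init = S0)
  expect_equal(sim$conc[2, , ], S0, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("binding conserves ligand plus complex when sources are off", {
  # v = 0, decay/production/exchange off, binding on: the spatial integral
  # of F+Cf, L+Cl and E+Ce is constant to quadrature accuracy
  p <- limit_params(keep = c("D_H", "D_S", "D_R", "D_CL", "D_I",
                             "k_on", "k_off_F", "k_off_L", "k_off_E"))
  g <- follicle_geometry("antrum")
  m <- follicle_mesh(g)
  set.seed(3)
  S0 <- matrix(0, nrow = 11, ncol = length(m$xi),
               dimnames = list(species_names(), NULL))
  for (sp in c("F", "L", "E", "Rf", "Rl", "Re")) {
    S0[sp, ] <- runif(length(m$xi), 0, 5)
  }
  sim <- simulate_follicle(p, g, times = c(0, 43200, 86400), mesh = m,
                           rtol = 1e-9, atol = 1e-10)
  total <- function(k, a, b) {
    sum((sim$conc[k, a, ] + sim$conc[k, b, ]) * m$weights)
  }
  for (pair in list(c("F", "Cf"), c("L", "Cl"), c("E", "Ce"))) {
    t0 <- total(1, pair[1], pair[2])
    expect_equal(total(2, pair[1], pair[2]), t0, tolerance = 1e-8)
    expect_equal(total(3, pair[1], pair[2]), t0, tolerance = 1e-8)
  }
})

test_that("two-compartment solutions stay even in xi", {
  sim <- default_two_comp_sim()
  n <- length(sim$mesh$xi)
  expect_equal(sim$mesh$xi, -rev(sim$mesh$xi))  # symmetric mesh
  for (k in seq_along(sim$times)) {
    S <- sim$conc[k, , ]
    scale <- pmax(apply(abs(S), 1, max), 1e-12)
    expect_lt(max(abs(S - S[, n:1]) / scale), 1e-4)
  }
})

test_that("stored output begins with the initial condition and stays near-positive", {
  sim <- default_antrum_sim()
  expect_equal(sim$conc[1, , ],
               initial_state(sim$params, sim$mesh), ignore_attr = TRUE)
  expect_gt(min(sim$conc), -100 * sim$diagnostics$atol)
  expect_true(all(diff(sim$times) > 0))
})

test_that("fluid mixing is averaging, conservative and idempotent", {
  g <- follicle_geometry("antrum_mixed")
  m <- follicle_mesh(g)
  S <- initial_state(follicle_parameters(), m)
  fl <- m$label == "fluid"
  S["F", ] <- seq(0, 10, length.out = length(m$xi))   # linear profile
  w <- follicleRD:::.comp_nodes(m, "fluid")$weights
  before <- sum(S["F", fl] * w)
  M <- mix_fluid(S, m)
  expect_equal(length(unique(M["F", fl])), 1L)
  expect_equal(sum(M["F", fl] * w), before)           # mass conserved
  expect_equal(mix_fluid(M, m), M)                    # idempotent
  expect_equal(M["I", ], S["I", ])                    # receptors untouched
  expect_equal(M["F", !fl], S["F", !fl])
})

test_that("well-mixed antrum runs keep the fluid homogeneous in solubles", {
  g <- follicle_geometry("antrum_mixed")
  sim <- cached_sim("mixed_short", simulate_follicle(
    follicle_parameters(), g, times = c(0, 43200, 86400)))
  fl <- sim$mesh$label == "fluid"
  for (sp in c("F", "L", "A", "E")) {
    v <- sim$conc[3, sp, fl]
    expect_lt(diff(range(v)), 1e-6 * max(max(v), 1e-9) + 1e-9)
  }
})

test_that("simulation inputs are validated", {
  p <- follicle_parameters()
  g <- follicle_geometry("antrum")
  expect_error(simulate_follicle(p, g, times = c(100, 200)), "start at 0")
  expect_error(simulate_follicle(p, g, times = c(0, 5, 5)), "increase")
})
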