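# Hill regulation and the reaction network.

test_that("hill function has the standard half-saturation behaviour", {
  for (K in c(0.01, 5, 1500)) {
    expect_equal(hill(K, K, 2), 0.5)
    expect_equal(hill(0, K, 2), 0)
    expect_equal(hill(3 * K, K, 2), 0.9)
  }
  expect_error(hill(-1, 5, 2), "negative")
  expect_error(hill(1, 0, 2), "positive")
  expect_error(hill(1, 5, 0.5), ">= 1")
})

test_that("regulatory activities combine as sigma_G = sigma_F + sigma_L", {
  p <- follicle_parameters()
  r0 <- regulatory_state(0, 0, 0, 0, p)
  expect_equal(unlist(r0), c(sigma_F = 0, sigma_L = 0, sigma_E = 0,
                             sigma_I = 0, sigma_G = 0))
  r1 <- regulatory_state(p$K_F, p$K_L, 0, 0, p)
  expect_equal(r1$sigma_G, 1)
  # the initial theca IGF level 0.3 K_I gives sigma_I = 0.09/1.09
  r2 <- regulatory_state(0, 0, 0, 0.3 * p$K_I, p)
  expect_equal(r2$sigma_I, 0.09 / 1.09)
  # sigma_G can exceed 1 but never 2; the others stay below 1
  rbig <- regulatory_state(1e9, 1e9, 1e9, 1e9, p)
  expect_lt(rbig$sigma_G, 2)
  expect_gt(rbig$sigma_G, 1.99)
  expect_lt(rbig$sigma_E, 1)
})

test_that("reaction terms reproduce closed-form point values", {
  p <- follicle_parameters()
  th <- data.frame(Theta = 1, Gamma = 0, Phi = 0)
  fl <- data.frame(Theta = 0, Gamma = 0, Phi = 1)
  s <- stats::setNames(numeric(11), species_names())

  # theca point with F at the delivery level: exchange cancels, decay remains
  s1 <- s; s1["F"] <- p$rho_F
  expect_equal(reaction_rates(s1, th, p)[["F"]], -p$delta_F * p$rho_F)
  expect_equal(reaction_rates(s1, th, p)[["F"]], -2e-5)

  # fluid point: no exchange, no receptors, no degradation of solubles
  s2 <- s; s2[c("F", "L", "A", "E")] <- c(1.3, 0.4, 50, 120)
  r2 <- reaction_rates(s2, fl, p)
  expect_equal(unname(r2[c("F", "L", "A", "E")]), c(0, 0, 0, 0))

  # theca point with sigma_G = 1: IGF complex steady state at 2.8 K_I
  s3 <- s; s3["Cf"] <- p$K_F; s3["Cl"] <- p$K_L; s3["I"] <- 2.8 * p$K_I
  expect_equal(reaction_rates(s3, th, p)[["I"]], 0)
  expect_equal(2.8 * p$K_I, 14000)

  expect_error(reaction_rates(s - 1, th, p), "negative")
})

test_that("binding fluxes are stoichiometrically consistent", {
  # with decay, production and exchange off, each ligand + its complex is
  # conserved pointwise, and equilibrium satisfies C/(L*R) = k_on/k_off
  p <- follicle_parameters()
  zero <- c("delta_F", "delta_L", "delta_A", "delta_E", "delta_RF",
            "delta_RL", "delta_RE", "delta_CF", "delta_CL", "delta_CE",
            "delta_I", "rho_RF", "rho_RL", "rho_RE", "rho_I", "rho_E",
            "Delta")
  for (f in zero) p[[f]] <- 0
  p <- validate_parameters(p)
  set.seed(7)
  for (i in 1:25) {
    s <- stats::setNames(runif(11, 0, 200), species_names())
    ind <- data.frame(Theta = sample(0:1, 1), Gamma = 0, Phi = 0)
    ind$Gamma <- ifelse(ind$Theta == 1, 0, 1)
    r <- reaction_rates(s, ind, p)
    expect_equal(r[["F"]] + r[["Cf"]], 0)
    expect_equal(r[["L"]] + r[["Cl"]], 0)
    expect_equal(r[["E"]] + r[["Ce"]], 0)
  }
  # equilibrium of one pair
  s <- stats::setNames(numeric(11), species_names())
  s["F"] <- 2; s["Rf"] <- 30
  s["Cf"] <- p$k_on * s["F"] * s["Rf"] / p$k_off_F
  r <- reaction_rates(s, data.frame(Theta = 0, Gamma = 1, Phi = 0), p)
  expect_equal(r[["Cf"]], 0)
  expect_equal(s[["Cf"]] / (s[["F"]] * s[["Rf"]]), p$k_on / p$k_off_F)
})

test_that("reactions never drive a zero concentration negative", {
  p <- follicle_parameters()
  set.seed(13)
  inds <- list(data.frame(Theta = 1, Gamma = 0, Phi = 0),
               data.frame(Theta = 0, Gamma = 1, Phi = 0),
               data.frame(Theta = 0, Gamma = 0, Phi = 1))
  for (i in 1:50) {
    s <- stats::setNames(runif(11, 0, 500), species_names())
    z <- sample(11, sample(1:6, 1))
    s[z] <- 0
    r <- reaction_rates(s, inds[[sample(3, 1)]], p)
    expect_true(all(r[z] >= 0))
  }
})

test_that("aromatase catalysis follows the gated Michaelis-Menten law", {
  p <- follicle_parameters()
  # half-saturation at A = K_M = 44 nM
  expect_equal(catalysis_rate(p$K_M, 100, 0, 0, 1, p),
               p$rho_E * 0.5 * 100)
  expect_equal(catalysis_rate(50, 100, 0.3, 1.2, 0, p), 0)
  # saturated limit: rate -> k_cat * I = 0.06 I
  expect_equal(catalysis_rate(1e9, 7, 0, 0, 1, p), 0.06 * 7,
               tolerance = 1e-6)
  # regulation factors multiply in
  expect_equal(catalysis_rate(p$K_M, 10, 0.5, 1, 1, p),
               p$rho_E * 0.5 * 10 * (1 + 0.5) * 2)
})
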