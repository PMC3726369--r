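# Method-of-lines integration of the growing-domain reaction-diffusion
# system. The uniform dilation x = l(t) * xi turns the moving-boundary
# problem into a fixed-domain system with a time-dependent diffusion
# scaling D / l(t)^2 and a dilution term (v / Lambda) * c; zero-flux
# boundaries are imposed at xi = +/- 1.

#' Initial field state
#'
#' All species start at zero except the IGF-receptor complex, which is
#' present in the theca at a fraction `I0_frac` of its half-saturation
#' constant (`0.3 * K_I` by default). The patterns in the interior then
#' emerge entirely from the regulatory interactions.
#'
#' @param params a `follicle_params` object.
#' @param mesh a `follicle_mesh`.
#' @return 11 x n_nodes matrix (nM) with rownames [species_names()].
#' @export
initial_state <- function(params, mesh) {
  S <- matrix(0, nrow = 11L, ncol = length(mesh$xi),
              dimnames = list(species_names(), NULL))
  S["I", mesh$label == "theca"] <- params$I0_frac * params$K_I
  S
}

#' Homogenise the soluble species over the follicular fluid
#'
#' Replaces F, L, A and E on the fluid nodes by their length-weighted
#' mean over the fluid, leaving receptors, complexes and the IGF complex
#' untouched. The total amount over the fluid (with the mesh's quadrature
#' weights) is conserved exactly; the operation is idempotent. This is
#' the well-mixed-antrum assumption: the aqueous fluid is stirred as the
#' animal moves, so no gradient can persist there.
#'
#' @param state 11 x n_nodes concentration matrix.
#' @param mesh a `follicle_mesh` whose geometry has a fluid compartment.
#' @return the mixed state matrix.
#' @export
mix_fluid <- function(state, mesh) {
  fl <- .comp_nodes(mesh, "fluid")
  for (sp in c("F", "L", "A", "E")) {
    state[sp, fl$idx] <- sum(state[sp, fl$idx] * fl$weights) / sum(fl$weights)
  }
  state
}

# Laplacian stencil weights on the nonuniform grid; zero-flux ends via
# the reflected-ghost second-order one-sided form
.laplacian_weights <- function(xi) {
  n <- length(xi)
  h <- diff(xi)
  wl <- wc <- wr <- numeric(n)
  i <- 2:(n - 1)
  wl[i] <- 2 / (h[i - 1] * (h[i - 1] + h[i]))
  wr[i] <- 2 / (h[i] * (h[i - 1] + h[i]))
  wc[i] <- -(wl[i] + wr[i])
  wr[1] <- 2 / h[1]^2;       wc[1] <- -wr[1]
  wl[n] <- 2 / h[n - 1]^2;   wc[n] <- -wl[n]
  list(wl = wl, wc = wc, wr = wr)
}

#' Simulate follicle development
#'
#' Integrates the 11-species reaction-diffusion system over the growing
#' follicle cross-section and returns a classed result holding the full
#' space-time solution. The stiff system (receptor binding and the blood
#' exchange act on the 1 s scale, the horizon is days) is advanced by an
#' implicit adaptive multistep method (`deSolve::lsoda`) with a banded
#' numeric Jacobian; the species-fastest state ordering keeps the
#' half-bandwidth at the number of species.
#'
#' For the `antrum_mixed` geometry the well-mixed fluid is applied by
#' operator splitting: the PDE step is interrupted every `mix_interval`
#' seconds and the soluble species are homogenised over the fluid (mass
#' conservative and unconditionally stable).
#'
#' @param params a `follicle_params` object.
#' @param geometry a `follicle_geometry`.
#' @param times output times in seconds (default: daily over 5 days).
#'   Must start at 0 and be strictly increasing.
#' @param mesh optional `follicle_mesh`; built from `geometry` if absent.
#' @param rtol,atol relative / absolute (nM) integration tolerances.
#' @param mix_interval operator-splitting substep for the well-mixed
#'   fluid, seconds.
#' @param init optional initial state matrix (defaults to
#'   [initial_state()]).
#' @return object of class `follicle_sim`: list with `times`, `conc`
#'   (array time x species x node, nM), `mesh`, `geometry`, `params`,
#'   and `diagnostics`.
#' @examples
#' \donttest{
#' sim <- simulate_follicle(follicle_parameters(),
#'                          follicle_geometry("antrum"))
#' summary(sim)
#' }
#' @export
simulate_follicle <- function(params = follicle_parameters(),
                              geometry = follicle_geometry("antrum"),
                              times = seq(0, 5 * 86400, by = 86400),
                              mesh = NULL, rtol = 1e-6, atol = 1e-8,
                              mix_interval = 600, init = NULL) {
  params <- validate_parameters(params)
  if (is.null(mesh)) mesh <- follicle_mesh(geometry)
  if (times[1] != 0 || any(diff(times) <= 0)) {
    stop("times must start at 0 and increase strictly")
  }
  n <- length(mesh$xi)
  ind <- indicators(mesh$xi, geometry)
  Th <- ind$Theta; Ga <- ind$Gamma; Ph <- ind$Phi
  W <- .laplacian_weights(mesh$xi)
  WL <- matrix(rep(W$wl, each = 11L), 11L)
  WC <- matrix(rep(W$wc, each = 11L), 11L)
  WR <- matrix(rep(W$wr, each = 11L), 11L)
  iL <- c(1L, seq_len(n - 1L))
  iR <- c(seq_len(n - 1L) + 1L, n)
  Dvec <- species_diffusion(params)
  half <- geometry$length_convention == "half_length"

  rhs <- function(t, y, parms) {
    S <- matrix(y, nrow = 11L)
    Sc <- S
    Sc[Sc < 0] <- 0                      # clip only inside the reactions
    R <- .reaction_core(Sc, Th, Ga, Ph, params)
    L <- params$Lambda0 + params$v * t
    ell <- if (half) L / 2 else L
    lap <- S[, iL, drop = FALSE] * WL + S * WC + S[, iR, drop = FALSE] * WR
    dS <- lap * (Dvec / ell^2) - (params$v / L) * S + R
    list(as.vector(dS))
  }

  S0 <- if (is.null(init)) initial_state(params, mesh) else init
  stopifnot(identical(dim(S0), c(11L, n)))
  y0 <- as.vector(S0)

  mix <- geometry$variant == "antrum_mixed"
  solve_piece <- function(y, tt) {
    out <- deSolve::lsoda(y, tt, rhs, parms = NULL, rtol = rtol, atol = atol,
                          jactype = "bandint", bandup = 11L, banddown = 11L,
                          maxsteps = 100000)
    if (attr(out, "istate")[1] < 0) {
      ylast <- out[nrow(out), -1]
      worst <- which.min(ylast)
      stop(sprintf(
        "integration failed near t = %.0f s (species %s, node %d)",
        out[nrow(out), 1], species_names()[(worst - 1) %% 11 + 1],
        (worst - 1) %/% 11 + 1))
    }
    out
  }

  steps <- 0L
  if (!mix) {
    out <- solve_piece(y0, times)
    steps <- attr(out, "istate")[3]
    conc <- out[, -1, drop = FALSE]
  } else {
    grid <- sort(unique(c(times, seq(0, max(times), by = mix_interval))))
    conc <- matrix(NA_real_, length(times), 11L * n)
    mix_fluid_vec <- function(yv) {
      as.vector(mix_fluid(matrix(yv, nrow = 11L,
                                 dimnames = list(species_names(), NULL)),
                          mesh))
    }
    conc[1, ] <- y0                    # first state is the initial condition
    y <- mix_fluid_vec(y0)
    for (k in seq_len(length(grid) - 1L)) {
      out <- solve_piece(y, grid[k:(k + 1L)])
      steps <- steps + attr(out, "istate")[3]
      y <- mix_fluid_vec(out[2, -1])
      hit <- match(grid[k + 1L], times)
      if (!is.na(hit)) conc[hit, ] <- y
    }
  }

  if (min(conc) < -100 * atol) {
    stop(sprintf("solver produced concentrations below -100*atol (min %.3g nM)",
                 min(conc)))
  }
  arr <- array(conc, dim = c(length(times), 11L, n),
               dimnames = list(NULL, species_names(), NULL))
  structure(list(times = times, conc = arr, mesh = mesh,
                 geometry = geometry, params = params,
                 diagnostics = list(steps = steps, rtol = rtol, atol = atol,
                                    n_nodes = n)),
            class = "follicle_sim")
}

#' Extract the concentration field of one species at one time
#'
#' @param sim a `follicle_sim`.
#' @param species one of [species_names()].
#' @param time an element of `sim$times` (seconds).
#' @return numeric vector over the mesh nodes, nM.
#' @export
field_at <- function(sim, species, time) {
  it <- match(time, sim$times)
  if (is.na(it)) stop("time not among the stored output times")
  sim$conc[it, species, ]
}

#' @export
print.follicle_sim <- function(x, ...) {
  cat("Follicle simulation:", x$geometry$variant, "geometry,",
      length(x$mesh$xi), "nodes,", length(x$times), "output times ",
      sprintf("(%.1f d horizon)\n", max(x$times) / 86400))
  invisible(x)
}

#' @export
summary.follicle_sim <- function(object, ...) {
  tend <- max(object$times)
  comps <- if (object$geometry$variant == "two_compartment") {
    c("theca", "granulosa")
  } else c("theca", "granulosa", "coc", "fluid")
  cat("Follicle simulation summary\n")
  cat(sprintf("  geometry: %s   horizon: %.1f d   follicle: %.1f -> %.1f mm\n",
              object$geometry$variant, tend / 86400,
              domain_length(0, object$params),
              domain_length(tend, object$params)))
  cat("  final compartment-averaged concentrations (nM):\n")
  m <- sapply(comps, function(cp) {
    sapply(species_names(), function(sp) {
      utils::tail(compartment_average(object, sp, cp)$values, 1)
    })
  })
  print(round(m, 3))
  invisible(m)
}

#' Plot concentration profiles
#'
#' Draws the spatial profile of one species at each stored output day on
#' the scaled domain, with compartment shading (granulosa/COC grey, fluid
#' blue).
#'
#' @param x a `follicle_sim`.
#' @param species species code (default `"F"`).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.follicle_sim <- function(x, species = "F", ...) {
  prof <- t(x$conc[, species, ])
  graphics::matplot(x$mesh$xi, prof, type = "l", lty = 1,
                    xlab = expression(xi), ylab = paste(species, "(nM)"),
                    main = paste(species, "profiles (one line per output time)"),
                    ...)
  g <- x$geometry
  usr <- graphics::par("usr")
  shade <- function(a, b, col) graphics::rect(a, usr[3], b, usr[4],
                                              col = col, border = NA)
  if (g$variant != "two_compartment") {
    shade(-g$xi_theta, g$xi_phi2, grDevices::adjustcolor("grey40", 0.15))
    shade(g$xi_phi2, g$xi_theta, grDevices::adjustcolor("steelblue", 0.12))
  }
  graphics::abline(v = c(-g$xi_theta, g$xi_theta), col = "grey60", lty = 3)
  graphics::matlines(x$mesh$xi, prof, lty = 1)
  invisible(x)
}
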