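# Hill regulation and the reaction terms of the 11-species network:
# gonadotropins F and L, steroids A and E, free receptors Rf/Rl/Re, bound
# complexes Cf/Cl/Ce, and the lumped IGF-receptor complex I.

#' Species identifiers in canonical order
#'
#' @return character vector of the 11 species codes.
#' @export
species_names <- function() {
  c("F", "L", "A", "E", "Rf", "Rl", "Re", "Cf", "Cl", "Ce", "I")
}

#' Per-species diffusion coefficients
#'
#' Assigns each species its diffusion coefficient: gonadotropins `D_H`,
#' steroids `D_S`, the LH-bound complex its measured (slow) `D_CL`, the
#' IGF complex `D_I`, and all other receptors and complexes the membrane
#' value `D_R`.
#'
#' @param params a `follicle_params` object.
#' @return named numeric vector over [species_names()], mm^2 s^-1.
#' @export
species_diffusion <- function(params) {
  c(F = params$D_H, L = params$D_H, A = params$D_S, E = params$D_S,
    Rf = params$D_R, Rl = params$D_R, Re = params$D_R,
    Cf = params$D_R, Cl = params$D_CL, Ce = params$D_R, I = params$D_I)
}

#' Hill activation function
#'
#' `hill(c, K, n) = c^n / (c^n + K^n)`: half-maximal at `c = K`, bounded
#' in `[0, 1)`. Inhibitory influences are modelled as `1 - hill(...)`.
#'
#' @param c concentration, nM (>= 0); vectorised.
#' @param K half-saturation constant, nM (> 0).
#' @param n Hill coefficient (>= 1).
#' @return activity in `[0, 1)`.
#' @export
hill <- function(c, K, n) {
  if (any(c < 0)) stop("negative concentration")
  if (any(K <= 0)) stop("K must be positive")
  if (any(n < 1)) stop("n must be >= 1")
  cn <- c^n
  cn / (cn + K^n)
}

#' Regulatory activities of the bound complexes
#'
#' Computes the Hill activities sigma_F, sigma_L, sigma_E, sigma_I of the
#' FSH-, LH-, estrogen- and IGF-receptor complexes, and the combined
#' gonadotropin activity `sigma_G = sigma_F + sigma_L` (the model treats
#' FSH and LH signalling as interchangeable downstream of their
#' receptors).
#'
#' @param Cf,Cl,Ce,I complex concentrations, nM; vectorised.
#' @param params a `follicle_params` object.
#' @return list with components `sigma_F`, `sigma_L`, `sigma_E`,
#'   `sigma_I`, `sigma_G`.
#' @export
regulatory_state <- function(Cf, Cl, Ce, I, params) {
  n <- params$n_hill
  sF <- hill(Cf, params$K_F, n)
  sL <- hill(Cl, params$K_L, n)
  sE <- hill(Ce, params$K_E, n)
  sI <- hill(I, params$K_I, n)
  list(sigma_F = sF, sigma_L = sL, sigma_E = sE, sigma_I = sI,
       sigma_G = sF + sL)
}

#' Aromatase (estradiol production) rate
#'
#' Michaelis-Menten conversion of androgens to estradiol, gated by the
#' IGF-receptor complex and enhanced by estrogen and gonadotropin
#' signalling:
#' `rho_E * Gamma * A/(A + K_M) * I * (1 + sigma_E sigma_G) * (1 + sigma_G)`.
#' The Gamma factor restricts the aromatase to the cellular compartment
#' (granulosa and cumulus cells).
#'
#' @param A androgen concentration, nM.
#' @param I IGF-complex concentration, nM.
#' @param sigma_E,sigma_G regulatory activities.
#' @param Gamma cell-compartment indicator (0/1).
#' @param params a `follicle_params` object.
#' @return rate in nM s^-1.
#' @export
catalysis_rate <- function(A, I, sigma_E, sigma_G, Gamma, params) {
  stopifnot(all(A >= 0), all(I >= 0))
  params$rho_E * Gamma * (A / (A + params$K_M)) * I *
    (1 + sigma_E * sigma_G) * (1 + sigma_G)
}

#' Reaction terms of the signalling network
#'
#' Evaluates the full reaction rate vector R(c) at one or more spatial
#' locations. The terms implement: blood exchange at rate `Delta` in the
#' theca (delivery of F, L and A at their serum-set concentrations,
#' removal of all four soluble species); mass-action receptor binding and
#' unbinding; linear decay, suppressed for the soluble species in the
#' follicular fluid where no cells are present (`1 - Phi` factor);
#' regulated receptor production; aromatase catalysis A -> E in the cell
#' block; and production of the IGF complex under gonadotropin signalling.
#'
#' @param state numeric matrix (11 x n locations) with rownames
#'   [species_names()], or a named numeric vector for a single location;
#'   nM. Negative entries are an error.
#' @param ind indicator values at the same locations, as returned by
#'   [indicators()] (columns `Theta`, `Gamma`, `Phi`).
#' @param params a `follicle_params` object.
#' @return matrix (or named vector) of rates, nM s^-1, same shape as
#'   `state`.
#' @examples
#' p <- follicle_parameters()
#' s <- setNames(numeric(11), species_names())
#' s["F"] <- p$rho_F   # delivery balanced -> only decay remains
#' reaction_rates(s, data.frame(Theta = 1, Gamma = 0, Phi = 0), p)["F"]
#' @export
reaction_rates <- function(state, ind, params) {
  vec <- is.null(dim(state))
  if (vec) state <- matrix(state, ncol = 1, dimnames = list(names(state)))
  if (is.null(rownames(state)) ||
      !all(species_names() %in% rownames(state))) {
    stop("state must be named with the 11 species codes")
  }
  if (any(state < 0)) stop("negative state")
  state <- state[species_names(), , drop = FALSE]
  Th <- ind$Theta; Ga <- ind$Gamma; Ph <- ind$Phi
  R <- .reaction_core(state, Th, Ga, Ph, params)
  if (vec) R[, 1] else R
}

# internal: no validation/clipping decisions, used by the ODE right-hand
# side on every evaluation; state is an 11 x n matrix in canonical order
.reaction_core <- function(S, Th, Ga, Ph, p) {
  F <- S[1, ]; L <- S[2, ]; A <- S[3, ]; E <- S[4, ]
  Rf <- S[5, ]; Rl <- S[6, ]; Re <- S[7, ]
  Cf <- S[8, ]; Cl <- S[9, ]; Ce <- S[10, ]; I <- S[11, ]

  n <- p$n_hill
  sF <- Cf^n / (Cf^n + p$K_F^n)
  sL <- Cl^n / (Cl^n + p$K_L^n)
  sE <- Ce^n / (Ce^n + p$K_E^n)
  sI <- I^n / (I^n + p$K_I^n)
  sG <- sF + sL

  bindF <- p$k_on * F * Rf; unbF <- p$k_off_F * Cf
  bindL <- p$k_on * L * Rl; unbL <- p$k_off_L * Cl
  bindE <- p$k_on * E * Re; unbE <- p$k_off_E * Ce
  DTh <- p$Delta * Th
  cell <- 1 - Ph                      # decay only where cells are present
  cat <- p$rho_E * Ga * (A / (A + p$K_M)) * I * (1 + sE * sG) * (1 + sG)

  rbind(
    F  = (p$rho_F - F) * DTh - bindF + unbF - p$delta_F * F * cell,
    L  = (p$rho_L - L) * DTh - bindL + unbL - p$delta_L * L * cell,
    A  = (p$rho_A * (1 + sG) - A) * DTh - p$delta_A * A * cell - cat,
    E  = -E * DTh - bindE + unbE - p$delta_E * E * cell + cat,
    Rf = p$rho_RF * (Ga * p$theta + sI * (1 + sE)) - bindF + unbF -
         p$delta_RF * Rf,
    Rl = p$rho_RL * sI * (1 + sE) - bindL + unbL - p$delta_RL * Rl,
    Re = p$rho_RE * (1 + sE) * (1 - sI) - bindE + unbE - p$delta_RE * Re,
    Cf = bindF - unbF - p$delta_CF * Cf,
    Cl = bindL - unbL - p$delta_CL * Cl,
    Ce = bindE - unbE - p$delta_CE * Ce,
    I  = p$rho_I * sG - p$delta_I * I
  )
}
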