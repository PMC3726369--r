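# The literature-derived parameter set (internal units: nM, s, mm) and the
# multiplicative Gaussian noise sampler for the robustness analysis.

# fields that may legitimately be zero in analytic limit configurations
.rate_fields <- c(
  "v", "D_H", "D_S", "D_CL", "D_R", "D_I",
  "k_on", "k_off_F", "k_off_L", "k_off_E",
  "delta_F", "delta_L", "delta_RF", "delta_RL", "delta_RE",
  "delta_CF", "delta_CL", "delta_CE", "delta_A", "delta_E", "delta_I",
  "rho_RF", "rho_RL", "rho_RE", "rho_F", "rho_L", "rho_A", "rho_E", "rho_I",
  "theta", "Delta", "I0_frac"
)
# fields that must stay strictly positive (half-saturation points, volumes)
.positive_fields <- c("Lambda0", "K_M", "K_F", "K_L", "K_E", "K_I",
                      "n_hill", "membrane_factor")

# Table-defaults perturbed by the noise analysis: every rate, affinity,
# diffusion, production/delivery parameter plus theta, Delta, Lambda0, v.
.default_noise_fields <- c(
  "Lambda0", "v", "D_H", "D_S", "D_CL", "D_R", "D_I",
  "k_on", "k_off_F", "k_off_L", "k_off_E",
  "delta_F", "delta_L", "delta_RF", "delta_RL", "delta_RE",
  "delta_CF", "delta_CL", "delta_CE", "delta_A", "delta_E", "delta_I",
  "rho_RF", "rho_RL", "rho_RE", "rho_F", "rho_L", "rho_A", "rho_E", "rho_I",
  "K_M", "K_F", "K_L", "K_E", "K_I", "theta", "Delta"
)

#' Default model parameters
#'
#' Returns the complete parameter set of the follicle model in internal
#' units (concentrations nM, time s, length mm). Values are the
#' literature-derived set: measured diffusion coefficients, binding and
#' decay rates, serum-calibrated delivery concentrations, and the
#' half-saturation constants inferred from the receptor expression
#' kinetics. Membrane receptors carry the 500-fold reaction-volume factor
#' where stated (production rates `rho_RF`, `rho_RL` and the Hill constants
#' `K_F`, `K_L`).
#'
#' Selected entries and their origin:
#' \describe{
#'   \item{Lambda0, v}{initial follicle diameter 5 mm, linear growth
#'     2.3e-5 mm s^-1 (about 10 mm in 5 days).}
#'   \item{D_H, D_S, D_CL, D_R, D_I}{diffusion coefficients of the
#'     gonadotropins, steroids, LH-bound receptor complex, other receptors,
#'     and the IGF-receptor complex, mm^2 s^-1.}
#'   \item{k_on, k_off_F, k_off_L, k_off_E}{binding kinetics; the implied
#'     dissociation constants are 0.5 nM (FSH), 10 nM (LH), 0.1 nM (E2).}
#'   \item{rho_F, rho_L, rho_A}{serum-set delivery concentrations, with
#'     rho_L = 0.4 rho_F.}
#'   \item{rho_I}{IGF-complex production rate, 2.8 * K_I * delta_I.}
#'   \item{theta}{gonadotropin-independent FSH-receptor drive (0.2).}
#'   \item{Delta}{blood exchange rate in the theca, 1 s^-1.}
#' }
#'
#' @param ... named overrides in internal units; unknown names are an
#'   error.
#' @return an object of class `follicle_params` (a named list).
#' @examples
#' p <- follicle_parameters()
#' p$D_H                       # 6.7e-5 mm^2 s^-1
#' follicle_parameters(Delta = 2)$Delta
#' @export
follicle_parameters <- function(...) {
  K_I <- 5000          # nM (5 uM)
  delta_I <- 1.2e-6    # s^-1 (half-life ~10 h)
  p <- list(
    # geometry / growth
    Lambda0 = 5,                 # mm
    v       = 2.3e-5,            # mm s^-1
    # diffusion, mm^2 s^-1
    D_H  = 6.7e-5,               # FSH/LH
    D_S  = 1e-4,                 # steroids
    D_CL = 2e-8,                 # LH-bound receptor complex
    D_R  = 1e-7,                 # all other receptors and complexes
    D_I  = 4e-9,                 # IGF-receptor complex
    # binding, s^-1 (k_on: nM^-1 s^-1)
    k_on    = 1e-3,
    k_off_F = 5e-4,
    k_off_L = 1e-2,
    k_off_E = 1e-4,
    # decay, s^-1
    delta_F  = 1e-5,
    delta_L  = 5e-4,
    delta_RF = 3e-5,
    delta_RL = 3e-5,
    delta_RE = 6.4e-5,           # grouped with the 3-h half-life species
    delta_CF = 6.4e-5,
    delta_CL = 7.5e-4,
    delta_CE = 6.4e-5,
    delta_A  = 6.4e-5,
    delta_E  = 6.4e-5,
    delta_I  = delta_I,
    # production / delivery
    rho_RF = 500 * 0.5e-3,       # nM s^-1 (membrane factor applied)
    rho_RL = 500 * 0.5e-3,       # nM s^-1
    rho_RE = 1.25e-3,            # nM s^-1
    rho_F  = 2,                  # nM
    rho_L  = 0.4 * 2,            # nM
    rho_A  = 100,                # nM
    rho_E  = 0.06,               # s^-1 (aromatase k_cat)
    rho_I  = 2.8 * K_I * delta_I,  # nM s^-1
    K_M    = 44,                 # nM
    # regulation
    K_F    = 500 * 3,            # nM (membrane factor applied)
    K_L    = 500 * 10e-3,        # nM (membrane factor applied)
    K_E    = 35,                 # nM
    K_I    = K_I,                # nM
    n_hill = 2,
    theta  = 0.2,
    # exchange and initial condition
    Delta   = 1,                 # s^-1
    I0_frac = 0.3,               # I(0) = I0_frac * K_I on the theca
    membrane_factor = 500
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over)))) {
      stop("parameter overrides must be named")
    }
    unknown <- setdiff(names(over), names(p))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    }
    p[names(over)] <- over
  }
  validate_parameters(structure(p, class = "follicle_params"))
}

#' Validate a parameter set
#'
#' Checks that every field is a finite scalar, that rates, diffusion
#' coefficients and production terms are non-negative (zero is allowed so
#' that analytic limit configurations can be expressed), and that
#' half-saturation constants, volumes and the Hill coefficient are strictly
#' positive with `n_hill >= 1`.
#'
#' @param p a `follicle_params` object.
#' @return `p`, invisibly classed, after validation.
#' @export
validate_parameters <- function(p) {
  stopifnot(is.list(p))
  for (f in c(.rate_fields, .positive_fields)) {
    if (is.null(p[[f]])) stop("missing parameter: ", f)
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter ", f, " must be a finite numeric scalar")
    }
  }
  neg <- .rate_fields[vapply(.rate_fields, function(f) p[[f]] < 0, logical(1))]
  if (length(neg)) stop("negative parameter(s): ", paste(neg, collapse = ", "))
  nonpos <- .positive_fields[vapply(.positive_fields, function(f) p[[f]] <= 0,
                                    logical(1))]
  if (length(nonpos)) {
    stop("parameter(s) must be strictly positive: ",
         paste(nonpos, collapse = ", "))
  }
  if (p$n_hill < 1) stop("n_hill must be >= 1")
  if (p$I0_frac > 1) stop("I0_frac above 1 is outside the intended range")
  structure(p, class = "follicle_params")
}

#' @export
print.follicle_params <- function(x, ...) {
  cat("Follicle model parameters (nM, s, mm)\n")
  df <- data.frame(value = unlist(x))
  print(format(df, digits = 4))
  invisible(x)
}

#' Noise specification for the robustness analysis
#'
#' Describes the multiplicative Gaussian perturbation applied to the
#' parameter set in the ensemble robustness analysis: each perturbed field
#' is multiplied by an independent draw from Normal(1, relative_sd),
#' redrawn until positive.
#'
#' @param relative_sd relative standard deviation (default 0.2, i.e. 20%
#'   noise); must lie in `[0, 1)` — values at or above 1 would make the
#'   positivity truncation degenerate.
#' @param n_runs ensemble size (default 100).
#' @param seed integer seed for reproducibility.
#' @param perturbed_fields parameter names to perturb; defaults to every
#'   rate, affinity, diffusion and production parameter (geometry
#'   boundaries, the Hill coefficient and the initial-condition fraction
#'   are excluded).
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(relative_sd = 0.2, n_runs = 100, seed = 1L,
                       perturbed_fields = .default_noise_fields) {
  if (relative_sd < 0) stop("relative_sd must be >= 0")
  if (relative_sd >= 1) stop("relative_sd >= 1 makes truncation degenerate")
  if (n_runs < 1) stop("n_runs must be >= 1")
  unknown <- setdiff(perturbed_fields, names(follicle_parameters()))
  if (length(unknown)) {
    stop("unknown perturbed field(s): ", paste(unknown, collapse = ", "))
  }
  structure(list(relative_sd = relative_sd, n_runs = as.integer(n_runs),
                 seed = as.integer(seed),
                 perturbed_fields = perturbed_fields),
            class = "noise_spec")
}

#' Sample noisy parameter sets
#'
#' Draws `spec$n_runs` perturbed copies of `base`: each field named in
#' `spec$perturbed_fields` is multiplied by an independent factor from
#' Normal(mean 1, sd `spec$relative_sd`), redrawn until positive; all other
#' fields are unchanged. A fixed seed reproduces the ensemble exactly.
#'
#' @param base a `follicle_params` object.
#' @param spec a `noise_spec`.
#' @return a list of `follicle_params` objects of length `n_runs`.
#' @examples
#' ens <- sample_noisy_parameters(follicle_parameters(),
#'                                noise_spec(n_runs = 3, seed = 7))
#' @export
sample_noisy_parameters <- function(base, spec) {
  base <- validate_parameters(base)
  stopifnot(inherits(spec, "noise_spec"))
  fields <- spec$perturbed_fields
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  draw_pos <- function(n) {
    f <- stats::rnorm(n, mean = 1, sd = spec$relative_sd)
    while (any(bad <- f <= 0)) {
      f[bad] <- stats::rnorm(sum(bad), mean = 1, sd = spec$relative_sd)
    }
    f
  }
  lapply(seq_len(spec$n_runs), function(i) {
    fac <- draw_pos(length(fields))
    p <- base
    p[fields] <- unlist(p[fields]) * fac
    validate_parameters(p)
  })
}
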