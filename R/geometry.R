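# Growing 1D cross-section of the follicle: linear growth law, compartment
# boundaries on the stationary coordinate xi in [-1, 1], and the indicator
# functions restricting reactions to theca / cell block / fluid.

#' Follicle cross-section geometry
#'
#' Defines the compartment layout on the stationary coordinate
#' \eqn{\xi \in [-1, 1]}. The theca occupies both outer slabs
#' \eqn{|\xi| \ge \xi_\theta}. In the `two_compartment` variant everything
#' inside the theca is granulosa. In the `antrum` variants the cellular
#' block sits on one side: the thin mural granulosa
#' \eqn{[-\xi_\theta, \xi_{\phi 1}]}, then the cumulus-oocyte complex
#' \eqn{[\xi_{\phi 1}, \xi_{\phi 2}]}, and follicular fluid filling the
#' rest up to the far theca. `antrum_mixed` additionally treats the fluid
#' as well mixed (soluble species homogenised, see
#' [simulate_follicle()]).
#'
#' By default the boundaries are tied together: \eqn{\xi_\theta = 1 -
#' 0.01\,\mathrm{theca\_scale}}, \eqn{\xi_{\phi 1} = -\xi_\theta + 0.005}
#' (granulosa width 0.005, i.e. 12.5 um at the initial 5 mm follicle) and
#' \eqn{\xi_{\phi 2} = \xi_{\phi 1} + 0.15} (COC spanning 3 mm of a 20 mm
#' follicle). Thickening the theca therefore shifts the cell block inward
#' without changing granulosa or COC widths. Explicit `xi_*` values
#' override the defaults.
#'
#' @param variant `"two_compartment"`, `"antrum"`, or `"antrum_mixed"`.
#' @param theca_scale multiplier on theca thickness (1.2 reproduces the
#'   thickened-theca sensitivity variant).
#' @param xi_theta,xi_phi1,xi_phi2 optional boundary overrides on the
#'   stationary coordinate.
#' @param length_convention `"half_length"` (default): the domain length
#'   `Lambda(t)` is the follicle diameter spanned by `xi` in `[-1,1]`, so
#'   physical positions and the diffusion scaling use the half-length
#'   `Lambda/2`. `"as_printed"` uses `Lambda` itself (coarser gradients by
#'   a factor 2 in length).
#' @param as_printed_phi2 restore the uncorrected sign of the cell-block
#'   end (`+0.835` instead of `-0.835`) for comparison runs.
#' @return an object of class `follicle_geometry`.
#' @examples
#' g <- follicle_geometry("antrum")
#' indicators(c(-0.995, -0.9, 0), g)
#' @export
follicle_geometry <- function(variant = c("antrum", "two_compartment", "antrum_mixed"),
                              theca_scale = 1,
                              xi_theta = NULL, xi_phi1 = NULL, xi_phi2 = NULL,
                              length_convention = c("half_length", "as_printed"),
                              as_printed_phi2 = FALSE) {
  variant <- match.arg(variant)
  length_convention <- match.arg(length_convention)
  if (theca_scale <= 0) stop("theca_scale must be positive")
  xt <- if (is.null(xi_theta)) 1 - 0.01 * theca_scale else xi_theta
  x1 <- if (is.null(xi_phi1)) -xt + 0.005 else xi_phi1
  x2 <- if (is.null(xi_phi2)) {
    if (as_printed_phi2) -x1 - 0.15 else x1 + 0.15
  } else xi_phi2
  if (!(xt > 0 && xt < 1)) stop("xi_theta must lie in (0, 1)")
  if (variant != "two_compartment") {
    if (!(-1 < -xt && -xt < x1 && x1 < x2 && x2 < xt)) {
      stop("boundaries must satisfy -1 < -xi_theta < xi_phi1 < xi_phi2 < xi_theta")
    }
  }
  structure(list(variant = variant, theca_scale = theca_scale,
                 xi_theta = xt, xi_phi1 = x1, xi_phi2 = x2,
                 length_convention = length_convention),
            class = "follicle_geometry")
}

#' @export
print.follicle_geometry <- function(x, ...) {
  cat("Follicle geometry:", x$variant, "\n")
  cat(sprintf("  xi_theta = %.4g  xi_phi1 = %.4g  xi_phi2 = %.4g\n",
              x$xi_theta, x$xi_phi1, x$xi_phi2))
  cat("  length convention:", x$length_convention,
      " theca scale:", x$theca_scale, "\n")
  invisible(x)
}

#' Domain length under linear growth
#'
#' The follicle diameter grows linearly, `Lambda(t) = Lambda0 + v t`:
#' about 10 mm of growth over the 5-day simulation horizon at the default
#' speed.
#'
#' @param t time in seconds (>= 0); vectorised.
#' @param params a `follicle_params` object supplying `Lambda0` and `v`.
#' @return length in mm.
#' @export
domain_length <- function(t, params = follicle_parameters()) {
  if (any(t < 0)) stop("t must be non-negative")
  params$Lambda0 + params$v * t
}

# half-length (or full length under as_printed) used for physical scaling
.length_scale <- function(t, params, geom) {
  L <- domain_length(t, params)
  if (geom$length_convention == "half_length") L / 2 else L
}

#' Compartment label of stationary coordinates
#'
#' Nodes exactly on a boundary are assigned to the compartment on their
#' theca (outer) side, which removes the Heaviside ambiguity at H(0).
#'
#' @param xi stationary coordinate(s) in `[-1, 1]`.
#' @param geom a `follicle_geometry`.
#' @return character vector: `"theca"`, `"granulosa"`, `"coc"` or
#'   `"fluid"` (`two_compartment` uses only theca/granulosa).
#' @export
compartment_label <- function(xi, geom) {
  if (any(xi < -1 | xi > 1)) stop("xi must lie in [-1, 1]")
  xt <- geom$xi_theta
  lab <- rep("theca", length(xi))
  inner <- abs(xi) < xt
  if (geom$variant == "two_compartment") {
    lab[inner] <- "granulosa"
  } else {
    lab[inner & xi <= geom$xi_phi1] <- "granulosa"
    lab[inner & xi > geom$xi_phi1 & xi <= geom$xi_phi2] <- "coc"
    lab[inner & xi > geom$xi_phi2] <- "fluid"
  }
  lab
}

#' Compartment indicator functions
#'
#' Evaluates the indicators restricting reactions in space: Theta (theca,
#' blood exchange), Gamma (cellular compartment: granulosa plus COC in the
#' antrum variants, the whole interior in `two_compartment`), and Phi
#' (follicular fluid, where nothing is degraded). Exactly one indicator
#' equals 1 at every point.
#'
#' @inheritParams compartment_label
#' @return a data.frame with columns `Theta`, `Gamma`, `Phi` (0/1).
#' @export
indicators <- function(xi, geom) {
  lab <- compartment_label(xi, geom)
  data.frame(Theta = as.numeric(lab == "theca"),
             Gamma = as.numeric(lab %in% c("granulosa", "coc")),
             Phi   = as.numeric(lab == "fluid"))
}

# xi-interval of a named layer; 'theca' is the width of one slab (the
# follicle has two, one at each end of the cross-section)
.layer_xi_width <- function(geom, layer) {
  xt <- geom$xi_theta
  two <- geom$variant == "two_compartment"
  switch(layer,
    theca = 1 - xt,
    granulosa = if (two) 2 * xt else geom$xi_phi1 - (-xt),
    cell_block = if (two) 0 else geom$xi_phi2 - geom$xi_phi1,
    fluid = if (two) 0 else xt - geom$xi_phi2,
    stop("unknown layer: ", layer)
  )
}

#' Physical thickness of a named layer
#'
#' Converts the stationary xi-width of a layer into millimetres at time
#' `t`. Under the default `half_length` convention the xi-interval
#' `[-1, 1]` spans the diameter `Lambda(t)`, so a xi-width `w` corresponds
#' to `w * Lambda(t) / 2`. At the initial 5 mm follicle the granulosa
#' (xi-width 0.005) is 12.5 um thick. `theca` reports one slab (the
#' cross-section has one at each end), so the layer thicknesses satisfy
#' `2 * theca + granulosa + cell_block + fluid = Lambda(t)`.
#'
#' @param geom a `follicle_geometry`.
#' @param layer one of `"theca"`, `"granulosa"`, `"cell_block"`,
#'   `"fluid"`.
#' @param t time in seconds.
#' @param params parameter set supplying the growth law.
#' @return thickness in mm.
#' @examples
#' layer_thickness(follicle_geometry("antrum"), "granulosa", 0) * 1000  # um
#' @export
layer_thickness <- function(geom, layer, t = 0, params = follicle_parameters()) {
  .layer_xi_width(geom, layer) * .length_scale(t, params, geom)
}

#' Physical position of a stationary coordinate
#'
#' @inheritParams layer_thickness
#' @param xi stationary coordinate(s) in `[-1, 1]`.
#' @return position in mm (signed; the centre is 0).
#' @export
physical_coordinate <- function(xi, t, geom, params = follicle_parameters()) {
  if (any(xi < -1 | xi > 1)) stop("xi must lie in [-1, 1]")
  xi * .length_scale(t, params, geom)
}
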