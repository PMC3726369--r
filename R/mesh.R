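# Nonuniform spatial mesh on the stationary coordinate, boundary-fitted to
# the compartment layout so that the thin theca and granulosa layers are
# resolved without a huge uniform grid.

# end-clustered node distribution on [a, b] (Chebyshev-extrema spacing)
.graded_nodes <- function(a, b, n) {
  t <- (1 - cos(pi * seq(0, 1, length.out = n))) / 2
  a + (b - a) * t
}

#' Build a boundary-fitted mesh
#'
#' Places nodes on the stationary coordinate `[-1, 1]`, including both
#' domain ends and every compartment boundary exactly. Thin layers (theca,
#' granulosa) receive uniformly spaced nodes; wide layers (interior, COC,
#' fluid) receive end-clustered nodes so the steep profiles next to the
#' compartment boundaries are resolved. Each node carries the compartment
#' label of its position (boundary nodes belong to the compartment on
#' their theca side).
#'
#' @param geom a `follicle_geometry`.
#' @param refine integer grid-refinement factor; `refine = 2` doubles the
#'   node count of every layer (used for grid-convergence checks).
#' @param n_thin,n_coc,n_wide nodes per thin layer (theca, granulosa), per
#'   COC block, and per wide layer (fluid, or the whole interior in the
#'   two-compartment variant).
#' @return object of class `follicle_mesh`: list with `xi` (sorted
#'   nodes), `label` (compartment per node), `weights` (control-volume
#'   quadrature weights on xi), and `geom`.
#' @export
follicle_mesh <- function(geom, refine = 1, n_thin = 11, n_coc = 19,
                          n_wide = 91) {
  stopifnot(refine >= 1)
  r <- function(n) as.integer(ceiling((n - 1) * refine) + 1)
  xt <- geom$xi_theta
  if (geom$variant == "two_compartment") {
    pieces <- list(
      seq(-1, -xt, length.out = r(n_thin)),
      .graded_nodes(-xt, xt, r(n_wide)),
      seq(xt, 1, length.out = r(n_thin))
    )
  } else {
    pieces <- list(
      seq(-1, -xt, length.out = r(n_thin)),
      seq(-xt, geom$xi_phi1, length.out = r(n_thin)),
      .graded_nodes(geom$xi_phi1, geom$xi_phi2, r(n_coc)),
      .graded_nodes(geom$xi_phi2, xt, r(n_wide)),
      seq(xt, 1, length.out = r(n_thin))
    )
  }
  xi <- sort(unique(unlist(pieces)))
  h <- diff(xi)
  n <- length(xi)
  w <- c(h[1] / 2, (h[-1] + h[-(n - 1)]) / 2, h[n - 1] / 2)
  structure(list(xi = xi, label = compartment_label(xi, geom),
                 weights = w, geom = geom),
            class = "follicle_mesh")
}

#' @export
print.follicle_mesh <- function(x, ...) {
  cat("Follicle mesh:", length(x$xi), "nodes on [-1, 1] (",
      x$geom$variant, ")\n")
  print(table(x$label))
  invisible(x)
}

# indices and within-compartment quadrature weights of one compartment
# ('cells' selects granulosa + coc, i.e. the Gamma block)
.comp_nodes <- function(mesh, compartment) {
  labs <- switch(compartment,
                 cells = c("granulosa", "coc"),
                 compartment)
  idx <- which(mesh$label %in% labs)
  if (!length(idx)) stop("empty compartment: ", compartment)
  # the theca occupies two disjoint slabs: weight each contiguous run
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  w <- unlist(lapply(runs, function(ii) {
    xi <- mesh$xi[ii]
    k <- length(xi)
    if (k == 1L) return(1)
    h <- diff(xi)
    if (k == 2L) return(c(h / 2, h / 2))
    c(h[1] / 2, (h[-1] + h[-(k - 1)]) / 2, h[k - 1] / 2)
  }), use.names = FALSE)
  list(idx = idx, weights = w)
}
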