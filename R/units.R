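# Unit-conversion arithmetic used to derive the default parameter values.
# Internal unit system: concentrations in nM, time in s, length in mm;
# cell volumes enter in um^3 at the conversion boundary only.

#' Avogadro constant (mol^-1)
#' @noRd
.avogadro <- 6.02214076e23

#' Convert a per-cell receptor count to a nanomolar concentration
#'
#' Distributes `count` molecules over the cell volume and expresses the
#' result as a concentration. With the granulosa cell volume of 1140 um^3,
#' 1500 receptors per cell correspond to about 2.2 nM.
#'
#' @param count molecules per cell (>= 0).
#' @param cell_volume cell volume in um^3 (> 0); default is the measured
#'   granulosa cell volume.
#' @return concentration in nM.
#' @examples
#' receptors_per_cell_to_nM(1500)  # ~2.2 nM
#' @export
receptors_per_cell_to_nM <- function(count, cell_volume = 1140) {
  stopifnot(all(count >= 0))
  if (any(cell_volume <= 0)) stop("cell_volume must be positive")
  litres <- cell_volume * 1e-15       # um^3 -> l
  count / (litres * .avogadro) * 1e9  # mol/l -> nmol/l
}

#' Convert a per-cell production rate to nM per second
#'
#' @param rate molecules per cell per minute (>= 0).
#' @param cell_volume cell volume in um^3 (> 0).
#' @return rate in nM s^-1. 21 receptors/cell/min in a 1140 um^3 cell is
#'   about 0.5 pM s^-1.
#' @export
per_cell_rate_to_nM_per_s <- function(rate, cell_volume = 1140) {
  stopifnot(all(rate >= 0))
  receptors_per_cell_to_nM(rate, cell_volume) / 60
}

#' Convert an international-unit hormone titre to nanomolar
#'
#' @param iu titre in IU l^-1 (> 0).
#' @param ug_per_iu protein mass equivalent of one IU, in ug (FSH ~46,
#'   LH ~23).
#' @param mw molecular weight in kDa (gonadotropins 30-35).
#' @return concentration in nM.
#' @examples
#' iu_per_l_to_nM(1, 46, 30)  # 1 IU/l FSH ~ 1.5 nM
#' @export
iu_per_l_to_nM <- function(iu, ug_per_iu, mw) {
  if (any(iu <= 0) || any(ug_per_iu <= 0) || any(mw <= 0)) {
    stop("all arguments must be positive")
  }
  # ug/l divided by kDa is directly nmol/l
  iu * ug_per_iu / mw
}

#' Convert a mass concentration to nanomolar
#'
#' @param conc concentration in ng ml^-1 (>= 0); ng/ml is numerically ug/l.
#' @param mw molecular weight in kDa (> 0).
#' @return concentration in nM.
#' @export
mass_conc_to_nM <- function(conc, mw) {
  stopifnot(all(conc >= 0))
  if (any(mw <= 0)) stop("mw must be positive")
  conc / mw
}

#' Characteristic length of a diffusion-degradation gradient
#'
#' For a ligand with diffusion coefficient D and first-order removal rate
#' k = ln(2)/half_life, a steady gradient decays over the length
#' lambda = sqrt(D/k). For IGF (D = 2.6e-5 mm^2 s^-1, half-life ~2 min)
#' this is below 70 um; a 100-fold longer half-life widens the gradient
#' 10-fold.
#'
#' @param D diffusion coefficient, mm^2 s^-1 (> 0).
#' @param half_life ligand half-life, s (> 0).
#' @return gradient length in mm.
#' @export
gradient_length <- function(D, half_life) {
  if (any(D <= 0) || any(half_life <= 0)) stop("D and half_life must be positive")
  sqrt(D * half_life / log(2))
}
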