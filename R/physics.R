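#' @useDynLib smmds, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx dnorm pnorm qnorm rnorm runif rpois rmultinom
#'   optim optimize nls coef vcov median mad sd var quantile rbinom setNames
#'   logLik complete.cases
#' @importFrom utils head tail modifyList write.csv read.csv
#' @importFrom graphics lines legend
NULL

## Boltzmann constant, exact SI value
.kB <- 1.380649e-23

#' Solvent conditions for Stokes--Einstein conversions
#'
#' Container for the temperature and dynamic viscosity that enter the
#' Stokes--Einstein relationship \eqn{D = k_B T / (6 \pi \eta R_H)}.
#' Defaults correspond to aqueous buffer at room temperature (25 degrees C).
#'
#' @param temperature Absolute temperature in kelvin.
#' @param viscosity Dynamic viscosity in pascal-seconds.
#' @return An object of class `solvent_conditions`.
#' @examples
#' cond <- solvent_conditions()          # water at 25 C
#' diffusion_coefficient(3.73e-9, cond)  # HSA-sized sphere
#' @export
solvent_conditions <- function(temperature = 298.15, viscosity = 8.9e-4) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive number (kelvin)")
  }
  if (!is.numeric(viscosity) || length(viscosity) != 1L ||
      !is.finite(viscosity) || viscosity <= 0) {
    stop("`viscosity` must be a single positive number (Pa s)")
  }
  structure(list(temperature = temperature, viscosity = viscosity),
            class = "solvent_conditions")
}

#' @export
print.solvent_conditions <- function(x, ...) {
  cat(sprintf("Solvent conditions: T = %.2f K, eta = %.3g Pa s\n",
              x$temperature, x$viscosity))
  invisible(x)
}

.check_cond <- function(cond) {
  if (!inherits(cond, "solvent_conditions")) {
    cond <- do.call(solvent_conditions, as.list(cond))
  }
  cond
}

#' Diffusion coefficient of a sphere from its hydrodynamic radius
#'
#' Stokes--Einstein relationship \eqn{D = k_B T / (6 \pi \eta R_H)}.
#'
#' @param r_h Hydrodynamic radius in meters (vectorised).
#' @param cond A [solvent_conditions()] object.
#' @return Diffusion coefficient(s) in m^2/s.
#' @seealso [hydrodynamic_radius()] for the exact inverse.
#' @export
diffusion_coefficient <- function(r_h, cond = solvent_conditions()) {
  cond <- .check_cond(cond)
  if (!is.numeric(r_h) || length(r_h) < 1L || any(!is.finite(r_h)) ||
      any(r_h <= 0)) {
    stop("`r_h` must be positive and finite (meters)")
  }
  .kB * cond$temperature / (6 * pi * cond$viscosity * r_h)
}

#' Hydrodynamic radius from a diffusion coefficient
#'
#' Exact inverse of [diffusion_coefficient()].
#'
#' @param d Diffusion coefficient in m^2/s (vectorised).
#' @param cond A [solvent_conditions()] object.
#' @return Hydrodynamic radius (meters).
#' @export
hydrodynamic_radius <- function(d, cond = solvent_conditions()) {
  cond <- .check_cond(cond)
  if (!is.numeric(d) || length(d) < 1L || any(!is.finite(d)) || any(d <= 0)) {
    stop("`d` must be positive and finite (m^2/s)")
  }
  .kB * cond$temperature / (6 * pi * cond$viscosity * d)
}

#' Molecular weight from hydrodynamic radius via empirical scaling laws
#'
#' Globular (folded) proteins follow \eqn{R_H \propto M_W^{1/3}}, intrinsically
#' disordered proteins \eqn{R_H \propto M_W^{0.6}}. The scaling prefactor is a
#' calibration constant that must be supplied explicitly (for example, pin a
#' known protein's radius to its known mass with [mw_prefactor()]); no default
#' is assumed.
#'
#' @param r_h Hydrodynamic radius in nm.
#' @param protein_class `"globular"` or `"disordered"`.
#' @param prefactor Calibration prefactor in nm/kDa^exponent, with exponent
#'   1/3 (globular) or 0.6 (disordered); must be positive.
#' @return Molecular weight in kDa.
#' @export
mw_from_rh <- function(r_h, protein_class = c("globular", "disordered"),
                       prefactor) {
  protein_class <- match.arg(protein_class)
  if (missing(prefactor) || !is.numeric(prefactor) || length(prefactor) != 1L ||
      !is.finite(prefactor) || prefactor <= 0) {
    stop("`prefactor` must be a single positive calibration constant")
  }
  if (!is.numeric(r_h) || any(!is.finite(r_h)) || any(r_h <= 0)) {
    stop("`r_h` must be positive (nm)")
  }
  nu <- switch(protein_class, globular = 1 / 3, disordered = 0.6)
  (r_h / prefactor)^(1 / nu)
}

#' Calibrate the radius--mass scaling prefactor from a reference protein
#'
#' @param r_h_ref Reference hydrodynamic radius (nm).
#' @param mw_ref Reference molecular weight (kDa).
#' @param protein_class `"globular"` or `"disordered"`.
#' @return The prefactor such that `mw_from_rh(r_h_ref, protein_class, pf)`
#'   returns `mw_ref`.
#' @export
mw_prefactor <- function(r_h_ref, mw_ref,
                         protein_class = c("globular", "disordered")) {
  protein_class <- match.arg(protein_class)
  if (r_h_ref <= 0 || mw_ref <= 0) stop("reference values must be positive")
  nu <- switch(protein_class, globular = 1 / 3, disordered = 0.6)
  r_h_ref / mw_ref^nu
}
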