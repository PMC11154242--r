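#' Optical properties of a tissue at one wavelength
#'
#' Bundles the absorption coefficient, reduced scattering coefficient,
#' refractive index and scattering anisotropy that drive the photon
#' transport simulation. The literature values used throughout the package
#' report only the reduced scattering coefficient \eqn{\mu_s'}, so the
#' default simulation works in the similarity regime with isotropic
#' scattering (`g = 0`, \eqn{\mu_s = \mu_s'}); a non-zero `g` switches to a
#' Henyey-Greenstein phase function with \eqn{\mu_s = \mu_s'/(1-g)}.
#'
#' @param mu_a Absorption coefficient, mm^-1.
#' @param mu_s_reduced Reduced scattering coefficient \eqn{\mu_s' =
#'   \mu_s (1 - g)}, mm^-1.
#' @param n Refractive index of the tissue (>= 1).
#' @param g Scattering anisotropy, in (-1, 1). Default 0 (similarity
#'   regime).
#' @return An object of class `optical_properties`.
#' @examples
#' optical_properties(mu_a = 0.92, mu_s_reduced = 1.29, n = 1.4)
#' @export
optical_properties <- function(mu_a, mu_s_reduced, n = 1.4, g = 0) {
  if (!is.numeric(mu_a) || length(mu_a) != 1L || is.na(mu_a) || mu_a < 0)
    .pdt_validation_error("`mu_a` must be a single non-negative number (mm^-1)")
  if (!is.numeric(mu_s_reduced) || length(mu_s_reduced) != 1L ||
      is.na(mu_s_reduced) || mu_s_reduced < 0)
    .pdt_validation_error("`mu_s_reduced` must be a single non-negative number (mm^-1)")
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    .pdt_validation_error("`n` must be a single number >= 1")
  if (!is.numeric(g) || length(g) != 1L || is.na(g) || g <= -1 || g >= 1)
    .pdt_validation_error("`g` must be in (-1, 1)")
  structure(
    list(mu_a = as.numeric(mu_a), mu_s_reduced = as.numeric(mu_s_reduced),
         n = as.numeric(n), g = as.numeric(g)),
    class = "optical_properties"
  )
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "<optical_properties> mu_a = %g mm^-1, mu_s' = %g mm^-1, n = %g, g = %g\n",
    x$mu_a, x$mu_s_reduced, x$n, x$g))
  invisible(x)
}

#' Tissue model: optical properties keyed by wavelength
#'
#' @param label Tissue name, e.g. `"tumor"` or `"muscle"`.
#' @param properties_by_wavelength Named list mapping wavelength in nm
#'   (as names, e.g. `"405"`) to [optical_properties()] objects.
#' @param ambient_n Refractive index of the medium above the cut surface
#'   (default 1.0, air).
#' @return An object of class `tissue_model`.
#' @seealso [default_tissue_models()] for the tumor and muscle models used
#'   in the reference simulations.
#' @export
tissue_model <- function(label, properties_by_wavelength, ambient_n = 1.0) {
  if (!is.character(label) || length(label) != 1L)
    .pdt_validation_error("`label` must be a single string")
  if (!is.list(properties_by_wavelength) ||
      is.null(names(properties_by_wavelength)) ||
      any(names(properties_by_wavelength) == ""))
    .pdt_validation_error(
      "`properties_by_wavelength` must be a named list keyed by wavelength (nm)")
  ok <- vapply(properties_by_wavelength, inherits, logical(1), "optical_properties")
  if (!all(ok))
    .pdt_validation_error("every entry must be an `optical_properties` object")
  if (!is.numeric(ambient_n) || length(ambient_n) != 1L || ambient_n < 1)
    .pdt_validation_error("`ambient_n` must be a single number >= 1")
  structure(
    list(label = label,
         properties_by_wavelength = properties_by_wavelength,
         ambient_n = as.numeric(ambient_n)),
    class = "tissue_model"
  )
}

#' Look up the optical properties of a tissue model at a wavelength
#'
#' @param model A [tissue_model()].
#' @param wavelength Wavelength in nm.
#' @return The matching [optical_properties()] object. A missing entry is a
#'   configuration error.
#' @export
tissue_properties <- function(model, wavelength) {
  stopifnot(inherits(model, "tissue_model"))
  key <- as.character(wavelength)
  props <- model$properties_by_wavelength[[key]]
  if (is.null(props))
    .pdt_config_error(sprintf(
      "tissue model '%s' has no optical properties at %s nm (available: %s)",
      model$label, key,
      paste(names(model$properties_by_wavelength), collapse = ", ")))
  props
}

#' Reference tumor and muscle tissue models
#'
#' Mouse tumor (CT-26 adenocarcinoma) and muscle optical properties at the
#' two chlorin-e6 activation wavelengths, 405 and 660 nm, as used by the
#' reference absorbed-dose simulations. Tumor tissue attenuates faster than
#' muscle at both wavelengths owing to its higher blood content.
#'
#' @return Named list with `tumor` and `muscle` [tissue_model()] objects.
#' @examples
#' default_tissue_models()$tumor
#' @export
default_tissue_models <- function() {
  list(
    tumor = tissue_model("tumor", list(
      "405" = optical_properties(mu_a = 0.92, mu_s_reduced = 1.29, n = 1.4),
      "660" = optical_properties(mu_a = 0.18, mu_s_reduced = 0.67, n = 1.4)
    )),
    muscle = tissue_model("muscle", list(
      "405" = optical_properties(mu_a = 0.57, mu_s_reduced = 1.17, n = 1.4),
      "660" = optical_properties(mu_a = 0.07, mu_s_reduced = 0.58, n = 1.4)
    ))
  )
}

#' Irradiation plan for a PDT or irradiation-only procedure
#'
#' @param dose_J_cm2 Total light dose at the surface, J/cm^2.
#' @param fluence_rate_mW_cm2 Fluence rate at the tissue surface, mW/cm^2.
#' @param spot_diameter_mm Diameter of the irradiation spot, mm.
#' @param wavelength_nm Wavelength, nm.
#' @return An object of class `irradiation_plan`.
#' @examples
#' # the two reference regimes: 405 nm at 125 mW/cm^2, 660 nm at 260 mW/cm^2
#' irradiation_plan(150, 125, 9, 405)
#' @export
irradiation_plan <- function(dose_J_cm2, fluence_rate_mW_cm2,
                             spot_diameter_mm = 9, wavelength_nm = NA_real_) {
  if (!is.numeric(dose_J_cm2) || length(dose_J_cm2) != 1L || dose_J_cm2 < 0)
    .pdt_validation_error("`dose_J_cm2` must be a single non-negative number")
  if (!is.numeric(fluence_rate_mW_cm2) || length(fluence_rate_mW_cm2) != 1L ||
      fluence_rate_mW_cm2 < 0)
    .pdt_validation_error("`fluence_rate_mW_cm2` must be a single non-negative number")
  structure(
    list(dose_J_cm2 = as.numeric(dose_J_cm2),
         fluence_rate_mW_cm2 = as.numeric(fluence_rate_mW_cm2),
         spot_diameter_mm = as.numeric(spot_diameter_mm),
         wavelength_nm = as.numeric(wavelength_nm)),
    class = "irradiation_plan"
  )
}

#' Default irradiation plans at 405 and 660 nm
#'
#' 150 J/cm^2 total dose over a 9-mm spot; 125 mW/cm^2 at 405 nm and
#' 260 mW/cm^2 at 660 nm (the blue fluence rate is kept lower to avoid
#' heating the tissue surface while staying within a half-hour session).
#'
#' @return Named list of [irradiation_plan()] objects keyed `"405"`, `"660"`.
#' @export
default_irradiation_plans <- function() {
  list(
    "405" = irradiation_plan(150, 125, 9, 405),
    "660" = irradiation_plan(150, 260, 9, 660)
  )
}

#' Exposure time required to deliver the planned dose
#'
#' `time = dose / fluence rate`, with units handled (J/cm^2 over mW/cm^2
#' gives seconds after the mW -> W conversion).
#'
#' @param plan An [irradiation_plan()].
#' @return Exposure time in seconds.
#' @examples
#' exposure_time(irradiation_plan(150, 260))  # ~577 s
#' exposure_time(irradiation_plan(150, 125))  # 1200 s = 20 min
#' @export
exposure_time <- function(plan) {
  stopifnot(inherits(plan, "irradiation_plan"))
  if (plan$dose_J_cm2 == 0) return(0)
  if (plan$fluence_rate_mW_cm2 <= 0)
    .pdt_validation_error("fluence rate must be > 0 to compute an exposure time")
  plan$dose_J_cm2 / (plan$fluence_rate_mW_cm2 / 1000)
}
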