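#' Combine a light depth-dose profile with a photosensitizer depth fit
#'
#' Interpretive model: the PDT effect at depth requires both light and
#' photosensitizer (PS), so a pointwise product of the absorbed-light
#' density and the normalized PS concentration serves as a relative proxy
#' for the treatment intensity versus depth. No absolute singlet-oxygen
#' dosimetry is attempted -- the proxy supports ordinal statements only
#' (deeper/shallower, larger/smaller), which is how it should be read.
#'
#' @param light A `depth_dose_profile` (depth in mm).
#' @param ps A converged `decay_fit` (decay length in micrometers; the
#'   micrometer-to-millimeter conversion is handled here). A negative
#'   fitted background is clipped to zero with a warning.
#' @return A `combined_dose_profile` with `z_mm`, `light_density` (mm^-1),
#'   `ps_relative` (normalized so the surface value is 1) and
#'   `pdt_proxy = light_density * ps_relative`.
#' @export
combine_profiles <- function(light, ps) {
  stopifnot(inherits(light, "depth_dose_profile"))
  if (!inherits(ps, "decay_fit") || !isTRUE(ps$converged))
    .pdt_validation_error("`ps` must be a converged `decay_fit`")
  bg <- ps$background
  if (is.na(bg) || bg < 0) {
    if (!is.na(bg) && bg < 0)
      warning("negative fitted background clipped to 0")
    bg <- 0
  }
  z_mm <- light$z_centers
  z_um <- z_mm * 1000
  ps_abs <- ps$I0 * exp(-z_um / ps$delta_um) + bg
  ps_rel <- ps_abs / (ps$I0 + bg)  # surface value -> 1
  structure(
    list(z_mm = z_mm,
         light_density = light$density,
         ps_relative = ps_rel,
         pdt_proxy = light$density * ps_rel,
         wavelength = light$wavelength,
         resection_label = NA_character_),
    class = "combined_dose_profile")
}

#' Effective treatment depth and PS-free light zone
#'
#' The treatment depth is the first depth at which the PDT proxy falls
#' below `threshold_fraction` of its surface value. The PS-free light zone
#' is the depth interval in which the PS has essentially vanished
#' (`ps_relative < ps_threshold`) while light is still present
#' (`light_density` above `threshold_fraction` of its own surface value) --
#' the zone where light reaches tissue that carries no photosensitizer,
#' the hypothesized substrate of recurrence stimulation by low-dose light.
#'
#' @param profile A `combined_dose_profile`.
#' @param threshold_fraction Light/proxy cutoff as a fraction of the
#'   surface value, in (0, 1); default 0.01.
#' @param ps_threshold PS cutoff on the normalized concentration; default
#'   0.05.
#' @return List with `treatment_depth_mm` (`NA` with `degenerate = TRUE`
#'   when the proxy never exceeds the threshold), and
#'   `ps_free_light_zone` -- `c(start_mm, end_mm)` or `NULL` when empty.
#' @export
treatment_depth <- function(profile, threshold_fraction = 0.01,
                            ps_threshold = 0.05) {
  stopifnot(inherits(profile, "combined_dose_profile"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    .pdt_validation_error("`threshold_fraction` must be in (0, 1)")
  z <- profile$z_mm
  proxy <- profile$pdt_proxy

  if (max(proxy) <= 0)
    return(list(treatment_depth_mm = NA_real_, degenerate = TRUE,
                ps_free_light_zone = NULL))
  cutoff <- threshold_fraction * proxy[1]
  below <- which(proxy < cutoff)
  depth <- if (length(below) == 0L) {
    NA_real_  # still above threshold at the bottom of the grid
  } else {
    k <- below[1]
    if (k == 1L) z[1]
    else z[k - 1] + (proxy[k - 1] - cutoff) * (z[k] - z[k - 1]) /
      (proxy[k - 1] - proxy[k])
  }

  light_cut <- threshold_fraction * profile$light_density[1]
  in_zone <- profile$ps_relative < ps_threshold &
    profile$light_density > light_cut
  zone <- if (any(in_zone)) range(z[in_zone]) else NULL

  list(treatment_depth_mm = depth, degenerate = FALSE,
       ps_free_light_zone = zone)
}
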