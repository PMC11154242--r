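#' Serial fluorescence tile scan from a cut tissue surface
#'
#' A tile scan is an ordered stack of confocal fields of view along the
#' depth axis, the first tile at the cut surface. Within a tile the pixel
#' row maps to depth; the tile index sets the coarse depth bin.
#'
#' @param tiles List of non-negative numeric matrices, all the same shape,
#'   ordered surface-first. Rows run along the depth axis.
#' @param tile_height_um Depth spanned by one tile, micrometers.
#' @param pixel_size_um Pixel pitch, micrometers.
#' @param sample_id Sample identifier.
#' @param group_label `"cold_knife"` or `"laser_scalpel"`.
#' @return An object of class `fluor_tile_scan`.
#' @export
fluor_tile_scan <- function(tiles, tile_height_um = 212, pixel_size_um = 1,
                            sample_id = NA_character_,
                            group_label = c("cold_knife", "laser_scalpel")) {
  group_label <- match.arg(group_label)
  if (!is.list(tiles) || length(tiles) < 1L)
    .pdt_validation_error("`tiles` must be a non-empty list of matrices")
  if (!all(vapply(tiles, is.matrix, logical(1))))
    .pdt_validation_error("every tile must be a numeric matrix")
  shapes <- vapply(tiles, function(t) paste(dim(t), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1L)
    .pdt_validation_error("all tiles must have the same shape")
  if (any(vapply(tiles, function(t) any(t < 0), logical(1))))
    .pdt_validation_error("tile intensities must be non-negative")
  if (!is.numeric(tile_height_um) || tile_height_um <= 0)
    .pdt_validation_error("`tile_height_um` must be positive")
  structure(
    list(tiles = tiles, tile_height_um = as.numeric(tile_height_um),
         pixel_size_um = as.numeric(pixel_size_um),
         sample_id = as.character(sample_id), group_label = group_label),
    class = "fluor_tile_scan")
}

#' Integrate a tile scan into an intensity-versus-depth profile
#'
#' One value per tile: the sum of all pixel intensities. The representative
#' depth of tile `t` (0-based) is the tile center,
#' `(t + 0.5) * tile_height_um`.
#'
#' @param scan A [fluor_tile_scan()].
#' @return A `depth_fluor_profile` with `depth_um`, `integral_intensity`,
#'   `sample_id` and `group_label`.
#' @export
integrate_tiles <- function(scan) {
  if (!inherits(scan, "fluor_tile_scan"))
    .pdt_validation_error("`scan` must be a `fluor_tile_scan`")
  n <- length(scan$tiles)
  structure(
    list(depth_um = (seq_len(n) - 0.5) * scan$tile_height_um,
         integral_intensity = vapply(scan$tiles, sum, numeric(1)),
         sample_id = scan$sample_id, group_label = scan$group_label),
    class = "depth_fluor_profile")
}

#' Construct a depth-fluorescence profile from vectors
#'
#' @param depth_um Depths of the tile centers, micrometers.
#' @param integral_intensity Integrated intensity per tile, arbitrary units.
#' @param sample_id,group_label Metadata carried along.
#' @return A `depth_fluor_profile`.
#' @export
depth_fluor_profile <- function(depth_um, integral_intensity,
                                sample_id = NA_character_,
                                group_label = NA_character_) {
  if (length(depth_um) != length(integral_intensity))
    .pdt_validation_error("`depth_um` and `integral_intensity` lengths differ")
  if (any(integral_intensity < 0))
    .pdt_validation_error("intensities must be non-negative")
  structure(
    list(depth_um = as.numeric(depth_um),
         integral_intensity = as.numeric(integral_intensity),
         sample_id = as.character(sample_id),
         group_label = as.character(group_label)),
    class = "depth_fluor_profile")
}

#' Average depth profiles across samples of one group
#'
#' Per-depth mean and sample standard deviation of the integrated
#' intensities (averaging is done on intensities, not on their logs, as in
#' standard reporting of mean +/- SD on a semi-log axis).
#'
#' @param profiles Non-empty list of `depth_fluor_profile`s sharing one
#'   depth grid.
#' @return A `group_depth_profile` with `depth_um`, `mean_intensity`,
#'   `sd_intensity` (0 when `n_samples == 1`) and `n_samples`.
#' @export
aggregate_group <- function(profiles) {
  if (!is.list(profiles) || length(profiles) == 0L)
    .pdt_validation_error("`profiles` must be a non-empty list")
  if (!all(vapply(profiles, inherits, logical(1), "depth_fluor_profile")))
    .pdt_validation_error("every element must be a `depth_fluor_profile`")
  depth <- profiles[[1]]$depth_um
  same <- vapply(profiles, function(p)
    length(p$depth_um) == length(depth) && all(abs(p$depth_um - depth) < 1e-9),
    logical(1))
  if (!all(same))
    .pdt_validation_error("profiles use different depth grids")
  mat <- do.call(rbind, lapply(profiles, `[[`, "integral_intensity"))
  n <- nrow(mat)
  structure(
    list(depth_um = depth,
         mean_intensity = colMeans(mat),
         sd_intensity = if (n == 1L) rep(0, ncol(mat)) else apply(mat, 2, sd),
         n_samples = n,
         group_label = profiles[[1]]$group_label),
    class = "group_depth_profile")
}

.profile_values <- function(profile) {
  if (inherits(profile, "depth_fluor_profile"))
    list(depth = profile$depth_um, intensity = profile$integral_intensity)
  else if (inherits(profile, "group_depth_profile"))
    list(depth = profile$depth_um, intensity = profile$mean_intensity)
  else .pdt_validation_error(
    "expected a `depth_fluor_profile` or `group_depth_profile`")
}

#' Fit an exponential decay with background to a depth profile
#'
#' Fits `I(z) = I0 * exp(-z / delta) + background` by nonlinear least
#' squares, initialized from a log-linear fit of the background-subtracted
#' upper part of the profile. The additive background captures the
#' asymptotic plateau the signal reaches at about 1 mm depth. A pure
#' log-linear fit (no background) is available via `background = FALSE`.
#'
#' @param profile A `depth_fluor_profile` or `group_depth_profile` with at
#'   least 3 depth points.
#' @param background Fit an additive offset (default `TRUE`).
#' @return A `decay_fit` with `I0` (a.u.), `delta_um` (decay length,
#'   micrometers), `background` (a.u.), `r_squared` and `converged`. When
#'   the decay is unidentifiable (e.g. a constant profile) the fit is
#'   returned with `converged = FALSE` and diagnostic message.
#' @examples
#' z <- (1:6 - 0.5) * 212
#' fit <- fit_decay(depth_fluor_profile(z, 100 * exp(-z / 200) + 5))
#' fit$delta_um
#' @export
fit_decay <- function(profile, background = TRUE) {
  v <- .profile_values(profile)
  z <- v$depth; y <- v$intensity
  if (length(z) < 3L)
    .pdt_validation_error("need at least 3 depth points to fit a decay")
  if (all(y <= 0))
    .pdt_validation_error("profile has no positive intensities")

  flag <- function(msg) structure(
    list(I0 = NA_real_, delta_um = NA_real_, background = NA_real_,
         r_squared = NA_real_, converged = FALSE, diagnostics = msg),
    class = "decay_fit")

  if (max(y) - min(y) <= 1e-12 * max(abs(y)))
    return(flag("constant profile: decay length unidentifiable"))

  # log-linear initialization on the background-subtracted signal
  bg0 <- if (background) min(y) * 0.5 else 0
  ypos <- pmax(y - bg0, max(y) * 1e-6)
  lf <- stats::lm.fit(cbind(1, z), log(ypos))
  slope <- lf$coefficients[2]
  delta0 <- if (is.finite(slope) && slope < 0) -1 / slope else diff(range(z))
  I00 <- exp(lf$coefficients[1])

  df <- data.frame(z = z, y = y)
  fit <- tryCatch({
    if (background) {
      nls(y ~ I0 * exp(-z / delta) + bg, data = df,
          start = list(I0 = I00, delta = delta0, bg = bg0),
          lower = c(I0 = 0, delta = 1e-6, bg = 0),
          algorithm = "port",
          control = list(maxiter = 200, warnOnly = FALSE))
    } else {
      nls(y ~ I0 * exp(-z / delta), data = df,
          start = list(I0 = I00, delta = delta0),
          lower = c(I0 = 0, delta = 1e-6),
          algorithm = "port",
          control = list(maxiter = 200, warnOnly = FALSE))
    }
  }, error = function(e) e)
  if (inherits(fit, "error"))
    return(flag(paste("fit did not converge:", conditionMessage(fit))))

  cf <- coef(fit)
  resid <- y - predict(fit)
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(I0 = unname(cf["I0"]),
         delta_um = unname(cf["delta"]),
         background = if (background) unname(cf["bg"]) else 0,
         r_squared = 1 - ss_res / ss_tot,
         converged = TRUE, diagnostics = NA_character_),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<decay_fit> NOT CONVERGED:", x$diagnostics, "\n")
  } else {
    cat(sprintf(
      "<decay_fit> I0 = %.4g, delta = %.1f um, background = %.4g, R^2 = %.4f\n",
      x$I0, x$delta_um, x$background, x$r_squared))
  }
  invisible(x)
}

#' Surface-to-depth fluorescence attenuation ratio
#'
#' Ratio of the superficial (first-tile) signal to the signal at a
#' reference depth, by default 636 um -- a depth safely below the
#' 300-400 um caramelization layer formed by laser-scalpel cutting. The
#' reference-depth signal is interpolated log-linearly between the
#' neighbouring tile centers (exact for exponentially decaying samples).
#' An attenuation ratio above ~20 is the laser-scalpel regime; below ~7 is
#' the cold-knife regime.
#'
#' The superficial signal is the first tile's value and the reference
#' depth is measured from that first sampling plane, so that for a pure
#' exponential the ratio equals `exp(reference_depth_um / delta)` exactly,
#' independent of whether tile depths are labelled by centers or edges.
#'
#' @param profile A `depth_fluor_profile` or `group_depth_profile`.
#' @param reference_depth_um Reference depth below the superficial
#'   (first-tile) plane, micrometers (default 636 = three tile heights at
#'   the default 212-um tile).
#' @return The dimensionless ratio; `Inf` (with a warning) when the
#'   interpolated reference intensity is zero.
#' @examples
#' z <- (1:6 - 0.5) * 212
#' attenuation_ratio(depth_fluor_profile(z, exp(-z / 200)))  # ~ exp(636/200)
#' @export
attenuation_ratio <- function(profile, reference_depth_um = 636) {
  v <- .profile_values(profile)
  z <- v$depth; y <- v$intensity
  z_ref <- z[1] + reference_depth_um
  if (z_ref < min(z) || z_ref > max(z))
    .pdt_validation_error(sprintf(
      "reference plane %g um below the first tile falls outside the sampled range [%g, %g] um",
      reference_depth_um, min(z), max(z)))
  surface <- y[1]
  ref <- if (all(y > 0)) {
    exp(approx(z, log(y), xout = z_ref)$y)
  } else {
    approx(z, y, xout = z_ref)$y  # linear fallback near zeros
  }
  if (ref <= 0) {
    warning("zero intensity at the reference depth; ratio is infinite")
    return(Inf)
  }
  surface / ref
}
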