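#' Write / read a depth-dose profile as CSV
#'
#' Columns: `z_mm`, `density_per_mm`, `wavelength_nm`, `tissue`.
#'
#' @param profile A `depth_dose_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "depth_dose_profile"))
  df <- data.frame(z_mm = profile$z_centers,
                   density_per_mm = profile$density,
                   wavelength_nm = profile$wavelength,
                   tissue = profile$tissue_label)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- read.csv(path)
  depth_profile(df$z_mm, df$density_per_mm,
                wavelength = df$wavelength_nm[1],
                tissue_label = df$tissue[1])
}

#' Write / read a fluorescence tile scan as plain text
#'
#' Each tile is stored as a headerless CSV matrix (`tile_01.csv`, ...)
#' plus a JSON sidecar (`scan.json`) holding the geometry, metadata and,
#' when present, the generator's ground truth. Plain-text storage keeps
#' fixtures portable; real acquisitions arriving as multi-page TIFF should
#' be converted tile-by-tile to this layout.
#'
#' @param scan A [fluor_tile_scan()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fluor_stack <- function(scan, dir) {
  stopifnot(inherits(scan, "fluor_tile_scan"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(scan$tiles)) {
    utils::write.table(scan$tiles[[i]],
                       file.path(dir, sprintf("tile_%02d.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  meta <- list(tile_height_um = scan$tile_height_um,
               pixel_size_um = scan$pixel_size_um,
               sample_id = scan$sample_id, group_label = scan$group_label,
               n_tiles = length(scan$tiles))
  gt <- attr(scan, "ground_truth")
  if (!is.null(gt)) meta$ground_truth <- gt
  jsonlite::write_json(meta, file.path(dir, "scan.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_fluor_stack
#' @export
read_fluor_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scan.json"), simplifyVector = TRUE)
  tiles <- lapply(seq_len(meta$n_tiles), function(i) {
    as.matrix(read.csv(file.path(dir, sprintf("tile_%02d.csv", i)),
                       header = FALSE))
  })
  tiles <- lapply(tiles, function(m) { dimnames(m) <- NULL; m })
  scan <- fluor_tile_scan(tiles, tile_height_um = meta$tile_height_um,
                          pixel_size_um = meta$pixel_size_um,
                          sample_id = meta$sample_id,
                          group_label = meta$group_label)
  if (!is.null(meta$ground_truth))
    attr(scan, "ground_truth") <- meta$ground_truth
  scan
}

#' Write / read a trial ledger CSV
#'
#' @param ledger A [trial_ledger()].
#' @param path CSV path.
#' @return `path` (write) or the validated ledger (read).
#' @export
write_ledger_csv <- function(ledger, path) {
  stopifnot(inherits(ledger, "trial_ledger"))
  write.csv(as.data.frame(ledger), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ledger_csv
#' @export
read_ledger_csv <- function(path) {
  trial_ledger(read.csv(path))
}

#' Pipeline configuration
#'
#' Single validated configuration object for a full run. Unknown keys are
#' rejected. Embedded defaults: the reference tumor/muscle optical
#' properties, the 405/660-nm irradiation plans (150 J/cm^2, 125 and
#' 260 mW/cm^2, 9-mm spot) and the two fluorescence presets.
#'
#' @param rng_seed Root seed; each stage derives its own stream from it.
#' @param n_photons Photon packets per transport run.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "fluor", "trial_stats", "dose_model")`.
#' @param n_samples_per_group Animals per resection group in the
#'   fluorescence stage (default 5).
#' @param out_dir Output directory for [run_pipeline()].
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(rng_seed = 1L,
                            n_photons = 1e5,
                            stages = c("simulate", "fluor", "trial_stats",
                                       "dose_model"),
                            n_samples_per_group = 5L,
                            out_dir = tempfile("pdt_run_")) {
  allowed <- c("simulate", "fluor", "trial_stats", "dose_model")
  if (length(setdiff(stages, allowed)))
    .pdt_config_error(paste("unknown stages:",
                            paste(setdiff(stages, allowed), collapse = ", ")))
  structure(
    list(rng_seed = as.integer(rng_seed), n_photons = n_photons,
         stages = stages, n_samples_per_group = as.integer(n_samples_per_group),
         out_dir = out_dir,
         tissues = default_tissue_models(),
         plans = default_irradiation_plans()),
    class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' Only the scalar fields are serialized; tissue models and irradiation
#' plans are re-embedded from package defaults unless overridden in the
#' JSON under `optical_properties` (`tissue -> wavelength -> {mu_a,
#' mu_s_reduced, n}`).
#'
#' @param config A [pipeline_config()].
#' @param path JSON path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_config_json <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  # out_dir is deliberately not serialized: the resolved config written
  # into a run directory must be byte-identical across runs with one seed
  scalars <- config[c("rng_seed", "n_photons", "stages",
                      "n_samples_per_group")]
  jsonlite::write_json(scalars, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("rng_seed", "n_photons", "stages", "n_samples_per_group",
               "out_dir", "optical_properties")
  extra <- setdiff(names(raw), allowed)
  if (length(extra))
    .pdt_config_error(paste("unknown config keys:", paste(extra, collapse = ", ")))
  cfg <- pipeline_config(
    rng_seed = raw$rng_seed %||% 1L,
    n_photons = raw$n_photons %||% 1e5,
    stages = raw$stages %||% c("simulate", "fluor", "trial_stats", "dose_model"),
    n_samples_per_group = raw$n_samples_per_group %||% 5L,
    out_dir = raw$out_dir %||% tempfile("pdt_run_"))
  if (!is.null(raw$optical_properties)) {
    for (tis in names(raw$optical_properties)) {
      props <- lapply(raw$optical_properties[[tis]], function(p)
        optical_properties(p$mu_a, p$mu_s_reduced,
                           n = p$n %||% 1.4, g = p$g %||% 0))
      cfg$tissues[[tis]] <- tissue_model(tis, props)
    }
  }
  cfg
}
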