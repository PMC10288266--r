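#' Pipeline run configuration
#'
#' Bundles every numeric protocol constant so that runs are reproducible
#' from the configuration alone. Defaults follow the acquisition protocol:
#' a 6 x 3 x 2 mm crop of the central colon, a 5480 x 1600 x 520 µm
#' TAG-anchored analysis volume, a ±18° angular sector about the guide
#' axis, and seven segments for the thickness measurement.
#'
#' @param crop_extent_um central crop extent (X, Y, Z), µm.
#' @param analysis_extent_um analysis volume extent (X, Y, Z), µm; must not
#'   exceed the crop extent per axis.
#' @param sector_half_angle_deg angular sector half-angle, degrees, (0, 90].
#' @param n_segments segments along X for the thickness measurement.
#' @param tag_polymer_wall_um transparent polymer wall of the guide, µm.
#' @param tag_outer_diameter_um outer diameter of the guide, µm.
#' @param overlay_gap_um vessel-free gap marking the colon/peritoneum
#'   boundary in the automatic overlay separation, µm.
#' @param thickness_half_width half-width (columns) of the centerline band
#'   used by the thickness measurement.
#' @param rotation_tol_deg tilt below which rotation resampling is skipped
#'   (the chain's own alignment tolerance).
#' @param bend_tol_vox maximum traced deviation from straight (voxels) below
#'   which bend correction is skipped; corrections under the trace noise
#'   floor only resample without straightening anything.
#' @return a list of class `run_config`.
#' @export
run_config <- function(crop_extent_um = c(6000, 3000, 2000),
                       analysis_extent_um = c(5480, 1600, 520),
                       sector_half_angle_deg = 18,
                       n_segments = 7,
                       tag_polymer_wall_um = 150,
                       tag_outer_diameter_um = 3000,
                       overlay_gap_um = 120,
                       thickness_half_width = 5,
                       rotation_tol_deg = 0.2,
                       bend_tol_vox = 0.25) {
  cfg <- list(crop_extent_um = as.numeric(crop_extent_um),
              analysis_extent_um = as.numeric(analysis_extent_um),
              sector_half_angle_deg = sector_half_angle_deg,
              n_segments = as.integer(n_segments),
              tag_polymer_wall_um = tag_polymer_wall_um,
              tag_outer_diameter_um = tag_outer_diameter_um,
              overlay_gap_um = overlay_gap_um,
              thickness_half_width = as.integer(thickness_half_width),
              rotation_tol_deg = rotation_tol_deg,
              bend_tol_vox = bend_tol_vox)
  if (any(cfg$analysis_extent_um > cfg$crop_extent_um))
    stop("analysis extent must not exceed crop extent on any axis")
  if (cfg$sector_half_angle_deg <= 0 || cfg$sector_half_angle_deg > 90)
    stop("sector half-angle must be in (0, 90]")
  if (cfg$n_segments < 1)
    stop("n_segments must be >= 1")
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' Keys missing from the file fall back to the protocol defaults; unknown
#' keys are an error so typos do not silently reconfigure a run.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}
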