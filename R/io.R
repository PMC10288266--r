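#' Write a volume as a multi-page TIFF with a JSON sidecar
#'
#' Pages are Z slices in increasing Z; each page is a (Y, X) matrix (TIFF
#' row/column convention), bridging to the in-memory (X, Y, Z) convention.
#' Samples are stored as 16-bit grayscale; intensities are normalized by the
#' volume's `intensity_scale` (its maximum, or 1 for an all-zero volume),
#' which is recorded in the sidecar and restored on read. Integer data up to
#' 65535 round-trip bit-exactly; other data to 1/65535 of the scale.
#'
#' @param vol an [rsom_volume].
#' @param path output path of the TIFF; the sidecar is written next to it
#'   with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  d <- dim(vol$data)
  scale <- max(vol$data)
  if (scale <= 0) scale <- 1
  q <- round(vol$data / scale * 65535) / 65535
  pages <- lapply(seq_len(d[3]), function(z) t(q[, , z]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  sidecar <- list(voxel_spacing_um = vol$spacing,
                  contrast_state = vol$contrast,
                  axes = "XYZ",
                  intensity_scale = scale,
                  shape = d)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Read a volume written by [write_volume()]
#'
#' @param path path to the multi-page TIFF; the JSON sidecar (same name,
#'   `.json` extension) must be present and carry `voxel_spacing_um` and
#'   `contrast_state`.
#' @return an [rsom_volume].
#' @export
read_volume <- function(path) {
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path))
    stop("missing sidecar ", sc_path,
         " (required keys: voxel_spacing_um, contrast_state, intensity_scale)")
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  need <- c("voxel_spacing_um", "contrast_state")
  miss <- setdiff(need, names(sc))
  if (length(miss) > 0)
    stop("sidecar is missing required keys: ", paste(miss, collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  a <- array(0, c(nx, ny, nz))
  for (z in seq_len(nz)) a[, , z] <- t(pages[[z]])
  scale <- if (!is.null(sc$intensity_scale)) sc$intensity_scale else 1
  rsom_volume(a * scale, sc$voxel_spacing_um, sc$contrast_state)
}

#' Write / read a boolean mask as a single-bit-per-sample style TIFF
#'
#' Masks are stored as 8-bit multi-page TIFF congruent with the analysis
#' volume (0 = excluded, 255 = included).
#'
#' @param mask logical 3D array.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  d <- dim(mask)
  pages <- lapply(seq_len(d[3]), function(z) t(mask[, , z]) * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  a <- array(FALSE, c(nx, ny, nz))
  for (z in seq_len(nz)) a[, , z] <- t(pages[[z]]) > 0.5
  a
}

#' Append a biomarker row to a tidy results table
#'
#' One row per (subject, timepoint), with all protocol constants echoed so
#' every result is reproducible from the table alone.
#'
#' @param set a `biomarker_set` from [compute_biomarkers()].
#' @param subject,group,day identifiers of the measurement.
#' @param config the [run_config()] used.
#' @return a one-row data.frame.
#' @export
biomarker_row <- function(set, subject, group = NA_character_, day = NA_real_,
                          config = run_config()) {
  data.frame(subject = subject, group = group, day = day,
             thickness_um = set$thickness_um,
             thickness_per_segment = paste(
               signif(set$thickness_per_segment, 6), collapse = ";"),
             intensity_au = set$intensity_au,
             blood_volume_ul = set$blood_volume_ul,
             threshold_8bit = set$threshold_8bit,
             voxel_volume_ul = set$voxel_volume_ul,
             sector_half_angle_deg = config$sector_half_angle_deg,
             n_segments = config$n_segments,
             tag_polymer_wall_um = config$tag_polymer_wall_um,
             stringsAsFactors = FALSE)
}
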