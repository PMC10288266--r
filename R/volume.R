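#' RSOM volume container
#'
#' A reconstructed optoacoustic mesoscopy volume: a non-negative 3D scalar
#' grid indexed `(X, Y, Z)`, where X is the TAG/scan axis, Y the lateral
#' scan axis, and Z is depth with `Z = 0` at the skin-facing surface and
#' increasing downward. Voxel centers sit at `(i - 0.5) * spacing` along each
#' axis.
#'
#' @param data 3D numeric array, finite and >= 0, indexed `[x, y, z]`.
#' @param spacing numeric length-3 voxel spacing in micrometres `(x, y, z)`.
#' @param contrast contrast state of the TAG lumen, `"ink"` or `"water"`.
#'
#' @return An object of class `rsom_volume`: a list with elements `data`,
#'   `spacing` and `contrast`.
#' @export
rsom_volume <- function(data, spacing, contrast = c("ink", "water")) {
  contrast <- match.arg(contrast)
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  if (!all(is.finite(data)))
    stop("volume data must be finite")
  if (min(data) < 0)
    stop("volume data must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive values (x, y, z) in µm")
  structure(list(data = data, spacing = spacing, contrast = contrast),
            class = "rsom_volume")
}

#' Physical extent of a volume in micrometres
#'
#' @param vol an [rsom_volume].
#' @return numeric length-3: extent along (X, Y, Z) in micrometres.
#' @export
volume_extent <- function(vol) {
  dim(vol$data) * vol$spacing
}

#' @export
print.rsom_volume <- function(x, ...) {
  d <- dim(x$data)
  e <- volume_extent(x)
  cat(sprintf(
    "<rsom_volume> %d x %d x %d voxels (%g x %g x %g µm), spacing (%g, %g, %g) µm, %s-TAG\n",
    d[1], d[2], d[3], e[1], e[2], e[3],
    x$spacing[1], x$spacing[2], x$spacing[3], x$contrast))
  invisible(x)
}

# Replace the data array, keeping metadata.
with_data <- function(vol, data) {
  vol$data <- data
  vol
}
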