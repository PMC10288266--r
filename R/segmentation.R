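#' Angular sector mask about the TAG axis
#'
#' Keeps voxels whose azimuth about the traced TAG centerline, measured from
#' the vertical pointing toward the skin (-Z), is within `half_angle_deg`,
#' and which lie radially outside the guide's outer cylinder. Structures
#' outside this sector are acoustic artifacts of the guide itself and are
#' discarded (protocol default: ±18°).
#'
#' @param dims integer length-3 grid dimensions of the analysis volume.
#' @param trace [trace_tag()] result in the analysis frame.
#' @param half_angle_deg sector half-angle in degrees, in (0, 90].
#' @param spacing voxel spacing (X, Y, Z) µm.
#' @return logical array of `dims`.
#' @export
angular_sector_mask <- function(dims, trace, half_angle_deg = 18,
                                spacing = attr(trace, "spacing")) {
  if (half_angle_deg <= 0 || half_angle_deg > 90)
    stop("half angle must be in (0, 90] degrees")
  Rv <- attr(trace, "tag_radius_um")
  y_um <- (seq_len(dims[2]) - 0.5) * spacing[2]
  z_um <- (seq_len(dims[3]) - 0.5) * spacing[3]
  cosmin <- cos(half_angle_deg * pi / 180)
  out <- array(FALSE, dims)
  yc_all <- (trace$y_lumen - 0.5) * spacing[2]
  zc_all <- (trace$z_outer - 0.5) * spacing[3] + Rv
  for (x in seq_len(dims[1])) {
    dy <- y_um - yc_all[x]
    dz <- z_um - zc_all[x]                 # negative above the axis
    r2 <- outer(dy^2, dz^2, `+`)
    r <- sqrt(r2)
    up <- outer(rep(1, dims[2]), -dz)      # height above axis, µm
    out[x, , ] <- r > Rv & up / pmax(r, .Machine$double.eps) >= cosmin
  }
  out
}

#' Separate the colon-wall vasculature from overlying tissue
#'
#' Builds the colon mask on which all biomarkers are computed. If a manual
#' overlay mask is supplied it is intersected with the angular sector and
#' the TAG exclusion. Otherwise an automatic band heuristic is used: within
#' the sector, each (X, Y) column is scanned upward from the guide's outer
#' surface and kept until the first vessel-free gap of at least `gap_um` of
#' sub-threshold signal, taken as the colon/peritoneum boundary. The
#' threshold is the iterative-intermeans (IsoData) threshold of the
#' in-sector analysis volume.
#'
#' @param vol the analysis [rsom_volume].
#' @param trace [trace_tag()] in the analysis frame.
#' @param sector_mask logical array from [angular_sector_mask()].
#' @param manual_mask optional logical array congruent with the volume
#'   (manual colon/overlay separation).
#' @param gap_um minimum vessel-free gap marking the boundary, µm.
#' @return logical array (the colon mask) with a `provenance` attribute.
#' @export
separate_colon_wall <- function(vol, trace, sector_mask, manual_mask = NULL,
                                gap_um = 120) {
  d <- dim(vol$data)
  if (!all(dim(sector_mask) == d))
    stop("sector mask grid mismatch")
  if (!is.null(manual_mask)) {
    if (!all(dim(manual_mask) == d))
      stop("manual mask grid mismatch")
    out <- manual_mask & sector_mask
    attr(out, "provenance") <- list(method = "manual", gap_um = NA_real_)
    return(out)
  }
  out <- array(FALSE, d)
  insect <- vol$data[sector_mask]
  if (length(insect) == 0 || max(insect) == 0) {
    attr(out, "provenance") <- list(method = "auto", gap_um = gap_um,
                                    threshold_8bit = NA_real_)
    return(out)
  }
  vmax <- max(vol$data)
  h <- tabulate(pmin(pmax(as.integer(floor(insect / vmax * 255 + 0.5)), 0L),
                     255L) + 1L, 256L)
  t8 <- tryCatch(isodata_threshold(h), error = function(e) 0L)
  thr <- t8 / 255 * vmax
  g <- max(1L, as.integer(round(gap_um / vol$spacing[3])))
  for (x in seq_len(d[1])) {
    sm <- sector_mask[x, , ]
    cols <- which(rowSums(sm) > 0)         # y columns with sector voxels
    if (length(cols) == 0) next
    fr <- vol$data[x, , ]
    for (y in cols) {
      zs <- which(sm[y, ])
      if (length(zs) == 0) next
      z_bot <- max(zs)                     # just above the outer surface
      prof <- fr[y, z_bot:1]               # upward from the surface
      sub <- prof <= thr
      rl <- rle(sub)
      ends <- cumsum(rl$lengths)
      gap <- which(rl$values & rl$lengths >= g)
      stop_at <- if (length(gap) > 0) ends[gap[1]] - rl$lengths[gap[1]] else length(prof)
      if (stop_at >= 1) {
        keep_z <- z_bot - seq_len(stop_at) + 1L
        keep_z <- keep_z[keep_z %in% zs]
        out[x, y, keep_z] <- TRUE
      }
    }
  }
  out <- out & sector_mask
  attr(out, "provenance") <- list(method = "auto", gap_um = gap_um,
                                  threshold_8bit = t8)
  out
}
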