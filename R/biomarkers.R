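#' Split a masked volume into per-segment maximum-intensity projections
#'
#' Divides the X range into `n_segments` contiguous blocks whose sizes
#' differ by at most one voxel (the remainder is distributed from the low-X
#' end) and projects each block onto the YZ plane by the voxelwise maximum
#' of the masked volume. Segments whose mask is empty are flagged and later
#' excluded from averaged read-outs.
#'
#' @param vol the analysis [rsom_volume].
#' @param mask logical colon mask congruent with the volume.
#' @param n_segments number of segments along X (protocol default 7).
#' @return list with `mips` (list of YZ matrices), `blocks` (list of X index
#'   ranges) and `flagged` (logical; empty-mask segments).
#' @export
segment_mips <- function(vol, mask, n_segments = 7) {
  d <- dim(vol$data)
  if (n_segments < 1 || n_segments > d[1])
    stop("n_segments must be between 1 and the X extent in voxels")
  base <- d[1] %/% n_segments
  extra <- d[1] %% n_segments
  sizes <- rep(base, n_segments) + c(rep(1L, extra), rep(0L, n_segments - extra))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  masked <- vol$data * mask
  mips <- vector("list", n_segments)
  flagged <- logical(n_segments)
  for (s in seq_len(n_segments)) {
    blk <- starts[s]:ends[s]
    flagged[s] <- !any(mask[blk, , ])
    mips[[s]] <- apply(masked[blk, , , drop = FALSE], c(2, 3), max)
  }
  list(mips = mips, blocks = Map(`:`, starts, ends), flagged = flagged)
}

#' Measure colon-wall thickness from segment MIPs
#'
#' Per segment, thickness is the axial distance between the traced TAG
#' lumen interface (segment-median apex) and the upper boundary of the
#' colon-wall vessel signal, minus the transparent polymer wall of the
#' guide. The vessel boundary is read at the TAG-centerline Y band
#' (±`half_width` columns): per column, the minimum Z whose MIP value
#' exceeds the segment's iterative-intermeans threshold; the median over
#' columns. Negative values are clamped to zero with a warning. The mean is
#' taken over unflagged segments.
#'
#' @param segs a [segment_mips()] result.
#' @param trace [trace_tag()] in the analysis frame.
#' @param polymer_wall_um TAG polymer wall thickness to subtract, µm.
#' @param half_width half-width of the centerline Y band, columns.
#' @return list with `per_segment` (µm; `NA` for flagged segments),
#'   `mean_um`, and `thresholds` (per-segment 8-bit thresholds).
#' @export
measure_wall_thickness <- function(segs, trace,
                                   polymer_wall_um = 150, half_width = 5) {
  sp <- attr(trace, "spacing")
  n <- length(segs$mips)
  per <- rep(NA_real_, n)
  thr8 <- rep(NA_real_, n)
  clamped <- FALSE
  gmax <- max(unlist(lapply(segs$mips, max)), 0)
  for (s in seq_len(n)) {
    if (segs$flagged[s]) next
    blk <- segs$blocks[[s]]
    z_lum <- stats::median(trace$z_lumen[blk])
    y_c <- round(stats::median(trace$y_lumen[blk]))
    M <- segs$mips[[s]]
    if (gmax == 0) next
    m8 <- floor(M / gmax * 255 + 0.5)
    h <- tabulate(m8 + 1L, 256L)
    t8 <- tryCatch(isodata_threshold(h), error = function(e) NA_integer_)
    if (is.na(t8)) { segs$flagged[s] <- TRUE; next }
    thr8[s] <- t8
    ys <- max(1, y_c - half_width):min(nrow(M), y_c + half_width)
    ztop <- rep(NA_real_, length(ys))
    for (i in seq_along(ys)) {
      zi <- which(m8[ys[i], ] > t8)
      if (length(zi) > 0) ztop[i] <- min(zi)
    }
    if (all(is.na(ztop))) { segs$flagged[s] <- TRUE; next }
    z_top <- stats::median(ztop, na.rm = TRUE)
    th <- (z_lum - z_top) * sp[3] - polymer_wall_um
    if (th < 0) { th <- 0; clamped <- TRUE }
    per[s] <- th
  }
  if (clamped)
    warning("negative thickness clamped to 0")
  if (all(is.na(per)))
    warning("no segment contained supra-threshold colon signal")
  list(per_segment = per,
       mean_um = mean(per, na.rm = TRUE),
       thresholds = thr8)
}

#' Convert a masked volume to 8-bit depth
#'
#' Out-of-mask voxels are set to zero; in-mask values are linearly rescaled
#' from `[0, global max of the analysis volume]` to `[0, 255]` and rounded
#' half-up (the ImageJ conversion convention). The per-volume normalization
#' is recorded in the `scale_max` attribute since it affects cross-subject
#' comparability.
#'
#' @param vol the analysis [rsom_volume].
#' @param mask logical colon mask.
#' @return integer array of 8-bit values.
#' @export
to_8bit <- function(vol, mask) {
  gmax <- max(vol$data)
  out <- array(0L, dim(vol$data))
  if (gmax > 0) {
    v <- vol$data[mask]
    out[mask] <- as.integer(floor(v / gmax * 255 + 0.5))
  }
  attr(out, "scale_max") <- gmax
  out
}

#' Total optoacoustic signal intensity
#'
#' Exact integer sum of all voxel values of an 8-bit masked volume.
#'
#' @param vol8 8-bit array from [to_8bit()].
#' @return numeric scalar (a whole number).
#' @export
total_signal_intensity <- function(vol8) {
  sum(as.numeric(vol8))
}

#' Iterative-intermeans (IsoData) threshold of an 8-bit histogram
#'
#' The "Default" auto-threshold variant: starting from t = 127, iterate
#' `t <- round((mean of bins <= t + mean of bins > t) / 2)` (round half up)
#' until the fixed point `t = round((mu_low + mu_high) / 2)` is reached.
#' Bin 0 is disregarded when `ignore_zeros` (masked-out voxels carry no
#' information about tissue).
#'
#' @param histogram256 numeric length-256 histogram of the 8-bit values
#'   (bin 1 holds value 0).
#' @param ignore_zeros drop bin 0 before thresholding.
#' @return integer threshold in `[0, 255]`.
#' @export
isodata_threshold <- function(histogram256, ignore_zeros = TRUE) {
  if (length(histogram256) != 256L)
    stop("expected a 256-bin histogram")
  h <- as.numeric(histogram256)
  if (ignore_zeros) h[1] <- 0
  if (sum(h) == 0)
    stop("nothing to threshold: histogram empty after zero removal")
  occ <- which(h > 0) - 1L
  if (length(occ) == 1L) return(occ)
  vals <- 0:255
  intermean <- function(t) {
    lo <- h[vals <= t]; vlo <- vals[vals <= t]
    hi <- h[vals > t];  vhi <- vals[vals > t]
    slo <- sum(lo); shi <- sum(hi)
    if (slo == 0) return(floor(sum(vhi * hi) / shi + 0.5))
    if (shi == 0) return(floor(sum(vlo * lo) / slo + 0.5))
    mlo <- sum(vlo * lo) / slo
    mhi <- sum(vhi * hi) / shi
    floor((mlo + mhi) / 2 + 0.5)
  }
  t <- 127L
  for (i in 1:256) {
    t_new <- as.integer(intermean(t))
    if (t_new == t) break
    t <- t_new
  }
  # adjacent thresholds can satisfy the fixed-point equation simultaneously
  # (moving t across a sparse bin leaves both means unchanged); ties are
  # resolved toward the smallest fixed point
  while (t > 1L && as.integer(intermean(t - 1L)) == t - 1L) t <- t - 1L
  t
}

#' Blood volume from a thresholded 8-bit volume
#'
#' Counts in-mask voxels strictly above the threshold and converts to
#' microlitres via the voxel volume.
#'
#' @param vol8 8-bit array from [to_8bit()] (out-of-mask voxels are 0).
#' @param threshold 8-bit threshold; voxels `> threshold` count as blood.
#' @param spacing voxel spacing (X, Y, Z), µm.
#' @return blood volume in µL.
#' @export
blood_volume <- function(vol8, threshold, spacing) {
  sum(vol8 > threshold) * prod(spacing) * 1e-9
}

#' Compute all colon-wall biomarkers for one analysis volume
#'
#' Runs the angular-sector and overlay separation, per-segment MIP
#' thickness measurement, 8-bit conversion, total signal intensity, and
#' blood-volume thresholding. `measure_on` selects which member of the pair
#' the intensity-based read-outs are evaluated on; the colon mask and trace
#' always come from the ink-derived geometry.
#'
#' @param vol the analysis [rsom_volume] to measure (ink or water member).
#' @param trace ink-derived [trace_tag()] in the analysis frame.
#' @param config a [run_config()].
#' @param mask optional precomputed colon mask; computed when `NULL`.
#' @param manual_mask optional manual overlay mask passed through to
#'   [separate_colon_wall()].
#' @return a `biomarker_set`: list with `thickness_um`,
#'   `thickness_per_segment`, `intensity_au`, `blood_volume_ul`,
#'   `threshold_8bit`, `voxel_volume_ul` and the mask provenance.
#' @export
compute_biomarkers <- function(vol, trace, config = run_config(),
                               mask = NULL, manual_mask = NULL) {
  d <- dim(vol$data)
  if (is.null(mask)) {
    sector <- angular_sector_mask(d, trace, config$sector_half_angle_deg,
                                  vol$spacing)
    mask <- separate_colon_wall(vol, trace, sector, manual_mask,
                                config$overlay_gap_um)
  }
  segs <- segment_mips(vol, mask, config$n_segments)
  th <- measure_wall_thickness(segs, trace, config$tag_polymer_wall_um,
                               config$thickness_half_width)
  vol8 <- to_8bit(vol, mask)
  intensity <- total_signal_intensity(vol8)
  h <- tabulate(as.integer(vol8[mask]) + 1L, 256L)
  t8 <- tryCatch(isodata_threshold(h), error = function(e) NA_integer_)
  bv <- if (is.na(t8)) 0 else blood_volume(vol8, t8, vol$spacing)
  structure(list(thickness_um = th$mean_um,
                 thickness_per_segment = th$per_segment,
                 intensity_au = intensity,
                 blood_volume_ul = bv,
                 threshold_8bit = t8,
                 voxel_volume_ul = prod(vol$spacing) * 1e-9,
                 mask_provenance = attr(mask, "provenance"),
                 scale_max = attr(vol8, "scale_max")),
            class = "biomarker_set")
}
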