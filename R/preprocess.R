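#' Crop the central part of a volume
#'
#' Cuts a centered window of the requested physical extent. When the margin
#' is odd it is split with the extra voxel on the high-index side.
#'
#' @param vol an [rsom_volume].
#' @param extent_um numeric length-3 target extent (X, Y, Z) in µm.
#' @return the cropped [rsom_volume]; the voxel window is recorded in the
#'   `crop_window` attribute (list of index ranges into the input).
#' @export
crop_central <- function(vol, extent_um) {
  d <- dim(vol$data)
  n <- as.integer(round(extent_um / vol$spacing))
  if (any(n > d))
    stop("crop extent exceeds volume extent on axis ",
         paste(c("X", "Y", "Z")[n > d], collapse = ", "))
  lo <- (d - n) %/% 2L + 1L
  win <- lapply(1:3, function(k) lo[k]:(lo[k] + n[k] - 1L))
  out <- with_data(vol, vol$data[win[[1]], win[[2]], win[[3]], drop = FALSE])
  attr(out, "crop_window") <- win
  out
}

#' Trace the TAG fiducial through an ink-contrast volume
#'
#' Per X frame, thresholds the volume at half its global maximum (the ink
#' lumen is by far the strongest absorber), keeps the largest connected
#' component of the YZ frame, and records the lumen-interface apex: the
#' minimum-Z voxel of that component, with Y taken as the median Y at that
#' row. The outer-cylinder apex is the lumen apex minus the (transparent)
#' polymer wall. Frames where no sufficiently large component exists are
#' flagged invalid and interpolated from their neighbours.
#'
#' @param vol an [rsom_volume] in the ink contrast state.
#' @param polymer_wall_um thickness of the TAG's outer polymer wall, µm.
#' @param tag_outer_diameter_um outer diameter of the TAG, µm (carried as
#'   metadata for downstream geometry).
#' @param min_area_vox minimum connected-component area (voxels) for a
#'   candidate lumen component to count as the fiducial; vessel
#'   cross-sections stay well below this.
#' @return a `tag_trace`: data.frame with per-frame columns `x`, `y_lumen`,
#'   `z_lumen`, `z_outer` (voxel indices; fractional where interpolated) and
#'   `valid`; spacing and TAG geometry in attributes.
#' @export
trace_tag <- function(vol, polymer_wall_um = 150,
                      tag_outer_diameter_um = 3000,
                      min_area_vox = 120) {
  if (vol$contrast != "ink")
    stop("TAG not found: tracing requires the ink contrast state")
  d <- dim(vol$data)
  thr <- 0.5 * max(vol$data)
  min_area <- min_area_vox
  y_l <- z_l <- rep(NA_real_, d[1])
  valid <- logical(d[1])
  for (x in seq_len(d[1])) {
    bw <- vol$data[x, , ] >= thr
    if (!any(bw)) next
    lab <- EBImage::bwlabel(bw)
    tab <- tabulate(lab[lab > 0L])
    if (length(tab) == 0L || max(tab) < min_area) next
    big <- which.max(tab)
    idx <- which(lab == big, arr.ind = TRUE)
    zmin <- min(idx[, 2])
    # subvoxel apex: the lumen cross-section is symmetric about the axis, so
    # the Y centroid of its top rows estimates the axis laterally; the Z
    # position interpolates the threshold crossing along the axis column.
    toprows <- idx[idx[, 2] <= zmin + 3L, , drop = FALSE]
    yc <- mean(toprows[, 1])
    y_int <- as.integer(round(yc))
    p <- vol$data[x, y_int, ]
    zc <- zmin
    if (zmin > 1L && p[zmin] > p[zmin - 1L] && p[zmin] >= thr && p[zmin - 1L] < thr)
      zc <- (zmin - 1L) + (thr - p[zmin - 1L]) / (p[zmin] - p[zmin - 1L])
    y_l[x] <- yc
    z_l[x] <- zc
    valid[x] <- TRUE
  }
  if (sum(valid) < 0.5 * d[1])
    stop("TAG not found: fewer than half of the frames contain the ink fiducial")
  xs <- seq_len(d[1])
  if (!all(valid)) {
    y_l <- stats::approx(xs[valid], y_l[valid], xs, rule = 2)$y
    z_l <- stats::approx(xs[valid], z_l[valid], xs, rule = 2)$y
  }
  z_o <- z_l - polymer_wall_um / vol$spacing[3]
  tr <- data.frame(x = xs, y_lumen = y_l, z_lumen = z_l, z_outer = z_o,
                   valid = valid)
  attr(tr, "spacing") <- vol$spacing
  attr(tr, "polymer_wall_um") <- polymer_wall_um
  attr(tr, "tag_radius_um") <- tag_outer_diameter_um / 2
  class(tr) <- c("tag_trace", "data.frame")
  tr
}

#' Estimate the TAG tilt angle by triangulation
#'
#' Takes the two valid frames with extreme X and triangulates the tilt of
#' the traced lumen interface against the scan axis:
#' `atan(dz / dx)` in physical units. Positive angles mean the guide runs
#' deeper at high X.
#'
#' @param trace a [trace_tag()] result.
#' @return tilt angle in degrees.
#' @export
estimate_rotation <- function(trace) {
  v <- which(trace$valid)
  if (length(v) < 2L)
    stop("rotation is undefined: need at least two valid trace frames")
  sp <- attr(trace, "spacing")
  i <- v[1]; j <- v[length(v)]
  dz <- (trace$z_lumen[j] - trace$z_lumen[i]) * sp[3]
  dx <- (trace$x[j] - trace$x[i]) * sp[1]
  atan2(dz, dx) * 180 / pi
}

# Build the 36-tap sampling plan for an XZ-plane rotation of a (nx, nz)
# lattice about its physical center. Returns per-tap padded linear indices
# and weights, shared by every Y slice.
rotation_plan <- function(nx, nz, angle_deg, spacing) {
  th <- angle_deg * pi / 180
  cx <- (nx + 1) / 2; cz <- (nz + 1) / 2
  gx <- matrix(seq_len(nx), nx, nz)
  gz <- matrix(seq_len(nz), nx, nz, byrow = TRUE)
  dxp <- (gx - cx) * spacing[1]
  dzp <- (gz - cz) * spacing[3]
  sx <- cx + (cos(th) * dxp - sin(th) * dzp) / spacing[1]
  sz <- cz + (sin(th) * dxp + cos(th) * dzp) / spacing[3]
  inside <- sx > -2 & sx < nx + 3 & sz > -2 & sz < nz + 3
  ix <- floor(sx); iz <- floor(sz)
  npx <- nx + 6L; npz <- nz + 6L
  taps <- vector("list", 36)
  k_ <- 0L
  for (k in -2:3) {
    wx <- bspline5(sx - (ix + k))
    px <- pmin(pmax(ix + k + 3L, 1L), npx)
    for (l in -2:3) {
      wz <- bspline5(sz - (iz + l))
      pz <- pmin(pmax(iz + l + 3L, 1L), npz)
      k_ <- k_ + 1L
      w <- as.vector(wx * wz)
      w[!inside] <- 0
      taps[[k_]] <- list(idx = as.vector(px + (pz - 1L) * npx), w = w)
    }
  }
  list(taps = taps, npx = npx, npz = npz)
}

#' Rotate a volume in the XZ plane with quintic B-spline interpolation
#'
#' Resamples the volume on a grid rotated by `-angle_deg` about the volume
#' center in the physical XZ plane, so that a structure tilted by
#' `angle_deg` (as estimated by [estimate_rotation()]) ends up parallel to
#' the X axis. Uses a 5th-order B-spline interpolant (recursive prefilter
#' plus 6x6 kernel evaluation per target sample); voxels sampled outside the
#' input grid are zero-filled.
#'
#' @param vol an [rsom_volume].
#' @param angle_deg tilt to remove, degrees; `|angle_deg| < 45`.
#' @return the resampled [rsom_volume].
#' @export
resample_rotated <- function(vol, angle_deg) {
  if (abs(angle_deg) >= 45) stop("|angle| must be < 45 degrees")
  if (angle_deg == 0) return(vol)
  d <- dim(vol$data)
  a <- bspline_prefilter_axis(vol$data, 1L)
  a <- bspline_prefilter_axis(a, 3L)
  plan <- rotation_plan(d[1], d[3], angle_deg, vol$spacing)
  out <- array(0, d)
  # padded coefficient slab per Y slice, laid out [xpad, zpad]
  for (y in seq_len(d[2])) {
    cpad <- matrix(0, plan$npx, plan$npz)
    cpad[4:(d[1] + 3L), 4:(d[3] + 3L)] <- a[, y, ]
    acc <- numeric(d[1] * d[3])
    for (tp in plan$taps) acc <- acc + tp$w * cpad[tp$idx]
    out[, y, ] <- acc
  }
  out[out < 0] <- 0
  with_data(vol, out)
}

#' Rigidly co-register a water volume to its ink counterpart
#'
#' Estimates the in-plane (Y, Z) translation that maps the water acquisition
#' into the ink frame by maximizing the cross-correlation of the
#' X-maximum-intensity YZ projections (vessels are sparse along the scan
#' axis, so the maximum preserves them where the mean would wash them out),
#' excluding the guide and its blurred halo, which differ between the two
#' contrast states by design. If the correlation at the peak is below 0.2
#' the volumes share no usable structure and the identity transform is
#' returned with a warning.
#'
#' @param ink,water co-acquired [rsom_volume]s on the same grid.
#' @param trace optional [trace_tag()] of the ink volume, used to mask the
#'   guide out of the similarity measure.
#' @param max_shift_vox maximum shift considered, voxels; co-acquired
#'   scans share the animal position, so the true offset is small.
#' @return list with `dy`, `dz` (voxels; apply to the water volume to map it
#'   into the ink frame) and `peak_corr`.
#' @export
coregister <- function(ink, water, trace = NULL, max_shift_vox = 6) {
  d <- dim(ink$data)
  if (!all(d == dim(water$data)))
    stop("co-registration requires volumes on the same grid")
  A <- xmax_project(ink$data)
  B <- xmax_project(water$data)
  if (!is.null(trace)) {
    sp <- attr(trace, "spacing")
    Rv <- attr(trace, "tag_radius_um")
    yc <- stats::median(trace$y_lumen)
    zc <- stats::median(trace$z_outer) + Rv / sp[3]
    dy <- ((seq_len(d[2]) - 0.5) - yc) * sp[2]
    dz <- ((seq_len(d[3]) - 0.5) - zc) * sp[3]
    tagmask <- outer(dy^2, dz^2, `+`) <= (Rv + 4 * sp[1])^2
    A[tagmask] <- 0
    B[tagmask] <- 0
  }
  # exhaustive search over the physically plausible shift window with
  # overlap-normalized correlation (an unnormalized FFT score is biased
  # toward large-overlap lags)
  res <- ncc_search(A, B, as.integer(max_shift_vox))
  dy_hat <- res[1]
  dz_hat <- res[2]
  peak <- if (res[3] > -2) res[3] else 0
  if (!is.finite(peak) || peak < 0.2) {
    warning("co-registration peak correlation below 0.2; returning identity")
    return(list(dy = 0, dz = 0, peak_corr = peak))
  }
  list(dy = dy_hat, dz = dz_hat, peak_corr = peak)
}

# X-axis maximum-intensity projection as a (Y, Z) matrix.
xmax_project <- function(a) {
  d <- dim(a)
  m <- matrix(a[1, , ], d[2], d[3])
  for (x in seq_len(d[1])[-1]) m <- pmax(m, a[x, , ])
  m
}

#' Apply a rigid in-plane (Y, Z) shift to a volume
#'
#' @param vol an [rsom_volume].
#' @param dy,dz translation in voxels (may be fractional).
#' @return the translated [rsom_volume] (bilinear, zero fill).
#' @export
apply_rigid <- function(vol, dy, dz) {
  d <- dim(vol$data)
  off <- matrix(rep(c(dy, dz), each = d[1]), ncol = 2)
  out <- shift_frames(vol$data, off)
  out[out < 0] <- 0
  with_data(vol, out)
}

#' Straighten a bent TAG by per-frame translation
#'
#' Translates every YZ frame so the traced lumen apex comes to lie on a
#' common line parallel to X (its median Y and Z position), undoing the
#' deformation a bent guide imprints on the acquisition. Offsets at invalid
#' frames come from the linear interpolation already present in the trace.
#'
#' @param vol an [rsom_volume].
#' @param trace [trace_tag()] result for the co-registered ink volume.
#' @return the straightened [rsom_volume]; per-frame voxel offsets are
#'   recorded in the `bend_offsets` attribute.
#' @export
correct_bend <- function(vol, trace) {
  if (nrow(trace) != dim(vol$data)[1])
    stop("trace does not match the volume's X extent")
  ref <- smooth_trace_ref(trace)
  off <- cbind(stats::median(ref$y) - ref$y,
               stats::median(ref$z) - ref$z)
  shifted <- shift_frames(vol$data, off)
  shifted[shifted < 0] <- 0
  out <- with_data(vol, shifted)
  attr(out, "bend_offsets") <- off
  out
}

# The physical deformation is smooth along the scan axis, so the per-frame
# traced reference is smoothed (locally weighted regression) before offsets
# are derived; this keeps voxel-level trace jitter out of the correction.
smooth_trace_ref <- function(trace, f = 0.15) {
  n <- nrow(trace)
  if (n < 10) return(list(y = trace$y_lumen, z = trace$z_lumen))
  list(y = stats::lowess(trace$x, trace$y_lumen, f = f)$y,
       z = stats::lowess(trace$x, trace$z_lumen, f = f)$y)
}

# Apply previously computed per-frame voxel offsets (e.g. to the water
# member of a pair).
apply_frame_offsets <- function(vol, offsets) {
  out <- shift_frames(vol$data, offsets)
  out[out < 0] <- 0
  with_data(vol, out)
}

#' Trim the TAG-anchored analysis volume
#'
#' Cuts the canonical analysis window: centered on the scan axis in X
#' (odd margins drop toward low indices, extra voxel at the high side),
#' centered on the traced TAG axis in Y, and anchored in Z so the window
#' ends one voxel below the traced outer-cylinder apex and extends toward
#' the skin. With the default protocol constants the result is
#' 5480 x 1600 x 520 µm, i.e. (274, 80, 130) voxels at (20, 20, 4) µm.
#'
#' @param vol an [rsom_volume] in the TAG-aligned frame.
#' @param trace [trace_tag()] result in the same frame.
#' @param extent_um analysis extent (X, Y, Z), µm.
#' @return list with `volume` (the trimmed [rsom_volume]), `trace` (the
#'   trace re-indexed into the trimmed frame) and `window` (index ranges
#'   into the input).
#' @export
trim_analysis <- function(vol, trace, extent_um = c(5480, 1600, 520)) {
  d <- dim(vol$data)
  n <- as.integer(round(extent_um / vol$spacing))
  if (any(n > d))
    stop("insufficient margin on axis ",
         paste(c("X", "Y", "Z")[n > d], collapse = ", "))
  x_lo <- (d[1] - n[1]) %/% 2L + 1L
  if (n[2] == d[2]) {
    y_lo <- 1L                            # degenerate: full extent
  } else {
    y_c <- as.integer(round(stats::median(trace$y_lumen)))
    y_lo <- y_c - (n[2] %/% 2L) + 1L
    if (y_lo < 1L || y_lo + n[2] - 1L > d[2])
      stop("insufficient margin on axis Y")
  }
  if (n[3] == d[3]) {
    z_lo <- 1L
  } else {
    z_hi <- min(as.integer(round(stats::median(trace$z_outer))) + 1L, d[3])
    z_lo <- z_hi - n[3] + 1L
    if (z_lo < 1L)
      stop("insufficient margin on axis Z")
  }
  win <- list(x = x_lo:(x_lo + n[1] - 1L),
              y = y_lo:(y_lo + n[2] - 1L),
              z = z_lo:(z_lo + n[3] - 1L))
  out <- with_data(vol, vol$data[win$x, win$y, win$z, drop = FALSE])
  tr <- trace[win$x, , drop = FALSE]
  tr$x <- seq_len(n[1])
  tr$y_lumen <- tr$y_lumen - (y_lo - 1L)
  tr$z_lumen <- tr$z_lumen - (z_lo - 1L)
  tr$z_outer <- tr$z_outer - (z_lo - 1L)
  attributes(tr)[c("spacing", "polymer_wall_um", "tag_radius_um")] <-
    attributes(trace)[c("spacing", "polymer_wall_um", "tag_radius_um")]
  class(tr) <- class(trace)
  list(volume = out, trace = tr, window = win)
}

#' Run the full preprocessing chain on an ink/water pair
#'
#' Crop to the protocol window, trace the ink fiducial, remove the TAG tilt
#' by quintic-spline resampling, co-register the water volume into the ink
#' frame, straighten the residual bend, and trim the TAG-anchored analysis
#' volume. All transforms are estimated on the ink volume and transferred to
#' the water volume.
#'
#' @param ink,water co-acquired [rsom_volume]s.
#' @param config a [run_config()].
#' @return list with the trimmed `ink` and `water` volumes, the analysis
#'   `trace`, and `record`: the serializable alignment record (rotation,
#'   rigid shift, bend offsets, crop and trim windows, config echo).
#' @export
preprocess_pair <- function(ink, water, config = run_config()) {
  if (!all(dim(ink$data) == dim(water$data)) ||
      !all(ink$spacing == water$spacing))
    stop("ink/water pair is inconsistent (grid or spacing mismatch)")
  ink_c <- crop_central(ink, pmin(config$crop_extent_um, volume_extent(ink)))
  water_c <- crop_central(water, pmin(config$crop_extent_um, volume_extent(water)))
  crop_win <- attr(ink_c, "crop_window")

  tr <- trace_tag(ink_c, config$tag_polymer_wall_um, config$tag_outer_diameter_um)
  angle <- estimate_rotation(tr)
  if (abs(angle) > config$rotation_tol_deg) {
    ink_c <- resample_rotated(ink_c, angle)
    water_c <- resample_rotated(water_c, angle)
    tr <- trace_tag(ink_c, config$tag_polymer_wall_um, config$tag_outer_diameter_um)
  }

  rig <- coregister(ink_c, water_c, tr)
  if (rig$dy != 0 || rig$dz != 0)
    water_c <- apply_rigid(water_c, rig$dy, rig$dz)

  ref <- smooth_trace_ref(tr)
  dev <- max(abs(c(ref$y - stats::median(ref$y),
                   ref$z - stats::median(ref$z))))
  if (dev > config$bend_tol_vox) {
    ink_b <- correct_bend(ink_c, tr)
    off <- attr(ink_b, "bend_offsets")
    water_b <- apply_frame_offsets(water_c, off)
    tr_b <- trace_tag(ink_b, config$tag_polymer_wall_um, config$tag_outer_diameter_um)
  } else {
    # the guide is already straight to within the trace noise floor
    ink_b <- ink_c
    water_b <- water_c
    off <- matrix(0, nrow(tr), 2)
    tr_b <- tr
  }

  trim <- trim_analysis(ink_b, tr_b, config$analysis_extent_um)
  trim_w <- with_data(water_b,
                      water_b$data[trim$window$x, trim$window$y, trim$window$z,
                                   drop = FALSE])
  record <- list(rotation_deg = angle,
                 rigid_shift_vox = c(dy = rig$dy, dz = rig$dz),
                 coreg_peak_corr = rig$peak_corr,
                 bend_offsets_vox = unname(off),
                 crop_window = lapply(crop_win, range),
                 trim_window = lapply(trim$window, range),
                 config = unclass(config))
  list(ink = trim$volume, water = trim_w, trace = trim$trace, record = record)
}
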