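#' Phantom specification for synthetic TAG-RSOM volume pairs
#'
#' Describes a synthetic acquisition: a rigid absorber-guide cylinder (TAG)
#' running along X with a switchable lumen (ink = strong absorber, water =
#' transparent), a colon-wall vascular band resting on the cylinder's outer
#' surface, overlying peritoneal and skin vessel layers, anisotropic
#' resolution, slight TAG bending, a small rigid offset between the two
#' contrast acquisitions, and additive noise. All lengths are micrometres.
#'
#' @param grid_extent physical size (X, Y, Z) of the simulated grid, µm.
#' @param voxel_spacing voxel spacing (X, Y, Z), µm; the reconstruction
#'   default is 20 x 20 x 4 µm.
#' @param tag_outer_diameter outer diameter of the TAG cylinder, µm (3 mm).
#' @param tag_polymer_wall thickness of the transparent outer polymer wall,
#'   µm. The lumen diameter is `tag_outer_diameter - 2 * tag_polymer_wall`.
#' @param tag_depth depth of the outer-cylinder apex below the skin surface,
#'   µm.
#' @param tag_lumen_ink_intensity,tag_lumen_water_intensity lumen intensity
#'   (a.u.) in the ink and water contrast states.
#' @param tag_polymer_intensity residual intensity of the polymer wall (a.u.,
#'   near zero: the wall is transparent).
#' @param vessel_intensity optoacoustic intensity of blood vessels (a.u.).
#' @param wall_thickness_true true thickness of the colon-wall vascular band,
#'   µm (the ground truth the thickness biomarker must recover).
#' @param vessel_density expected vessel centerline length per unit volume of
#'   the colon-wall band, µm per µm^3.
#' @param vessel_radius_range min/max vessel radius, µm (per-vessel radii are
#'   drawn uniformly; capped at half the band thickness so vessels fit).
#' @param skin_depth,skin_thickness,skin_vessel_density skin vessel layer:
#'   start depth, thickness (µm) and centerline density.
#' @param peritoneum_depth,peritoneum_thickness,peritoneum_vessel_density
#'   peritoneal vessel layer parameters.
#' @param psf_lateral_fwhm,psf_axial_fwhm point-spread-function full width at
#'   half maximum, µm (lateral 40, axial 10).
#' @param bend_amplitude amplitude of the smooth TAG bend along X, µm (the
#'   colon uplifts the guide toward the skin at mid-scan).
#' @param rotation_deg tilt of the TAG axis against X in the XZ plane,
#'   degrees; positive means the guide runs deeper at high X.
#' @param rigid_shift rigid (Y, Z) offset of the water acquisition relative
#'   to the ink acquisition, µm.
#' @param noise_sigma standard deviation of additive Gaussian noise (a.u.),
#'   clipped at zero.
#' @param seed integer seed; `(spec, seed)` reproduces the pair bit-exactly.
#' @param keep_labels if `TRUE`, pre-blur binary label arrays (colon, skin,
#'   peritoneum vessels, lumen) are attached to the returned truth.
#'
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_extent = c(6000, 3000, 2000),
                         voxel_spacing = c(20, 20, 4),
                         tag_outer_diameter = 3000,
                         tag_polymer_wall = 150,
                         tag_depth = 700,
                         tag_lumen_ink_intensity = 1.0,
                         tag_lumen_water_intensity = 0.02,
                         tag_polymer_intensity = 0.01,
                         vessel_intensity = 0.5,
                         wall_thickness_true = 100,
                         vessel_density = 1e-4,
                         vessel_radius_range = c(15, 30),
                         skin_depth = 30, skin_thickness = 120,
                         skin_vessel_density = 8e-5,
                         peritoneum_depth = 250, peritoneum_thickness = 100,
                         peritoneum_vessel_density = 8e-5,
                         psf_lateral_fwhm = 40, psf_axial_fwhm = 10,
                         bend_amplitude = 40,
                         rotation_deg = 2,
                         rigid_shift = c(40, 12),
                         noise_sigma = 0.02,
                         seed = 1L,
                         keep_labels = FALSE) {
  spec <- list(grid_extent = as.numeric(grid_extent),
               voxel_spacing = as.numeric(voxel_spacing),
               tag_outer_diameter = tag_outer_diameter,
               tag_polymer_wall = tag_polymer_wall,
               tag_depth = tag_depth,
               tag_lumen_ink_intensity = tag_lumen_ink_intensity,
               tag_lumen_water_intensity = tag_lumen_water_intensity,
               tag_polymer_intensity = tag_polymer_intensity,
               vessel_intensity = vessel_intensity,
               wall_thickness_true = wall_thickness_true,
               vessel_density = vessel_density,
               vessel_radius_range = as.numeric(vessel_radius_range),
               skin_depth = skin_depth, skin_thickness = skin_thickness,
               skin_vessel_density = skin_vessel_density,
               peritoneum_depth = peritoneum_depth,
               peritoneum_thickness = peritoneum_thickness,
               peritoneum_vessel_density = peritoneum_vessel_density,
               psf_lateral_fwhm = psf_lateral_fwhm,
               psf_axial_fwhm = psf_axial_fwhm,
               bend_amplitude = bend_amplitude,
               rotation_deg = rotation_deg,
               rigid_shift = as.numeric(rigid_shift),
               noise_sigma = noise_sigma,
               seed = as.integer(seed),
               keep_labels = isTRUE(keep_labels))
  validate_phantom_spec(spec)
  class(spec) <- "phantom_spec"
  spec
}

validate_phantom_spec <- function(s) {
  if (any(s$grid_extent <= 0) || any(s$voxel_spacing <= 0))
    stop("grid extent and voxel spacing must be positive")
  if (any(abs(s$grid_extent / s$voxel_spacing -
              round(s$grid_extent / s$voxel_spacing)) > 1e-9))
    stop("grid extent must be divisible by voxel spacing on every axis")
  if (s$tag_outer_diameter <= 0 || s$tag_polymer_wall <= 0 ||
      s$tag_polymer_wall >= s$tag_outer_diameter / 2)
    stop("invalid TAG geometry")
  if (s$wall_thickness_true < s$voxel_spacing[3])
    stop("wall thickness must be at least one axial voxel")
  if (abs(s$rotation_deg) >= 15)
    stop("|rotation_deg| must be < 15")
  if (s$vessel_density < 0 || s$skin_vessel_density < 0 ||
      s$peritoneum_vessel_density < 0)
    stop("vessel densities must be >= 0")
  if (s$tag_depth - s$wall_thickness_true < 0)
    stop("phantom does not fit grid: wall band exceeds grid depth")
  invisible(s)
}

# Smooth per-frame bend profile of the TAG in µm: a single uplift arch in Z
# (toward the skin at mid-scan, hence negative) plus a smaller lateral sway.
bend_profile <- function(n_frames, amplitude) {
  xh <- (seq_len(n_frames) - 0.5) / n_frames
  cbind(by = amplitude / 3 * sin(2 * pi * xh),
        bz = -amplitude * sin(pi * xh))
}

#' Grow a stochastic vessel network inside a tissue layer
#'
#' Vessels are random-walk tubes: each starts at a uniform point of the
#' layer, takes fixed-length steps with a slowly wandering direction, and is
#' kept inside the layer by reflecting the within-layer height coordinate.
#' Growth stops when the summed centerline length reaches
#' `density * layer volume`.
#'
#' @param layer a layer geometry as returned by the internal constructors:
#'   a list with `x_range`, `y_range` (µm), a surface function
#'   `z_of(x, y, h)` mapping a height `h` above the layer floor to depth,
#'   the layer `thickness` (µm) and its `volume` (µm^3).
#' @param density expected centerline length per unit layer volume
#'   (µm / µm^3); `0` yields an empty network.
#' @param radius_range per-vessel radius range, µm; capped at half the layer
#'   thickness.
#' @param step step length of the random walk, µm.
#' @param mean_length mean vessel length, µm.
#'
#' @return a matrix with one row per centerline segment and columns
#'   `x0, y0, z0, x1, y1, z1, r` (µm). Uses the current RNG state.
#' @export
grow_vessel_network <- function(layer, density, radius_range,
                                step = 30, mean_length = 300) {
  if (density < 0) stop("density must be >= 0")
  target <- density * layer$volume
  if (target <= 0) {
    return(matrix(numeric(0), ncol = 7,
                  dimnames = list(NULL, c("x0", "y0", "z0", "x1", "y1", "z1", "r"))))
  }
  rmax_eff <- min(radius_range[2], layer$thickness / 2)
  rmin_eff <- min(radius_range[1], rmax_eff)
  segs <- vector("list", 256)
  nseg <- 0L
  total <- 0
  while (total < target) {
    r <- stats::runif(1, rmin_eff, rmax_eff)
    hmin <- min(r, layer$thickness / 2)
    hmax <- max(layer$thickness - r, layer$thickness / 2)
    x <- stats::runif(1, layer$x_range[1], layer$x_range[2])
    y <- stats::runif(1, layer$y_range[1], layer$y_range[2])
    h <- stats::runif(1, hmin, hmax)
    # mostly in-plane direction with a small vertical component
    phi <- stats::runif(1, 0, 2 * pi)
    dir <- c(cos(phi), sin(phi), stats::runif(1, -0.2, 0.2))
    dir <- dir / sqrt(sum(dir^2))
    len <- stats::rexp(1, 1 / mean_length) + step
    n_steps <- max(1L, as.integer(round(len / step)))
    p0 <- c(x, y, h)
    for (i in seq_len(n_steps)) {
      # wander the direction slightly
      dir <- dir + c(stats::rnorm(2, 0, 0.25), stats::rnorm(1, 0, 0.1))
      dir <- dir / sqrt(sum(dir^2))
      p1 <- p0 + step * dir
      # keep inside the layer: clamp laterally, reflect in height
      p1[1] <- min(max(p1[1], layer$x_range[1]), layer$x_range[2])
      p1[2] <- min(max(p1[2], layer$y_range[1]), layer$y_range[2])
      if (p1[3] < hmin) p1[3] <- hmin + (hmin - p1[3])
      if (p1[3] > hmax) p1[3] <- hmax - (p1[3] - hmax)
      p1[3] <- min(max(p1[3], hmin), hmax)
      seglen <- sqrt(sum((p1 - p0)^2))
      if (seglen > 0) {
        nseg <- nseg + 1L
        if (nseg > length(segs)) segs <- c(segs, vector("list", length(segs)))
        z0 <- layer$z_of(p0[1], p0[2], p0[3])
        z1 <- layer$z_of(p1[1], p1[2], p1[3])
        segs[[nseg]] <- c(p0[1], p0[2], z0, p1[1], p1[2], z1, r)
        total <- total + seglen
      }
      p0 <- p1
      if (total >= target) break
    }
  }
  out <- do.call(rbind, segs[seq_len(nseg)])
  colnames(out) <- c("x0", "y0", "z0", "x1", "y1", "z1", "r")
  attr(out, "total_length") <- total
  out
}

# Flat slab layer: depth z in [z0, z0 + thickness]; h measured downward from
# z0 so z = z0 + h.
slab_layer <- function(x_range, y_range, z0, thickness) {
  force(z0)
  list(x_range = x_range, y_range = y_range, thickness = thickness,
       z_of = function(x, y, h) z0 + h,
       volume = diff(x_range) * diff(y_range) * thickness)
}

# Curved band draped on the upper surface of the (possibly tilted/bent) TAG
# cylinder: h is height above the outer surface, z = z_surf(x, y) - h.
# z_axis_fun(x): depth of the cylinder axis at scan position x (µm).
# y_axis_fun(x): lateral position of the axis at x (µm).
shell_layer <- function(x_range, y_range, z_axis_fun, y_axis_fun, radius,
                        thickness, z_max, spacing) {
  z_surf <- function(x, y) {
    dy <- y - y_axis_fun(x)
    s2 <- radius^2 - dy^2
    ifelse(s2 > 0, z_axis_fun(x) - sqrt(pmax(s2, 0)), NA_real_)
  }
  # numeric layer volume on a coarse lattice, clipping to the grid depth
  xs <- seq(x_range[1], x_range[2], by = max(spacing[1], 40))
  ys <- seq(y_range[1], y_range[2], by = max(spacing[2], 40))
  zs <- outer(xs, ys, z_surf)
  lo <- pmax(zs - thickness, 0)
  hi <- pmin(zs, z_max)
  depth <- pmax(hi - lo, 0)
  depth[is.na(depth)] <- 0
  vol <- mean(depth) * diff(x_range) * diff(y_range)
  list(x_range = x_range, y_range = y_range, thickness = thickness,
       z_of = function(x, y, h) {
         zs <- z_surf(x, y)
         ifelse(is.na(zs), NA_real_, zs - h)
       },
       surface = z_surf,
       volume = vol)
}

# Rasterize centerline segments as solid tubes into a logical array.
# Segments in µm; voxel centers at (i - 0.5) * spacing.
rasterize_segments <- function(segs, dims, spacing) {
  if (is.null(segs) || nrow(segs) == 0) return(array(FALSE, dims))
  array(raster_tubes(as.integer(dims), as.numeric(spacing),
                     segs[, 1:7, drop = FALSE]) > 0L, dims)
}

#' Generate a synthetic ink/water TAG-RSOM volume pair with ground truth
#'
#' Rasterizes the four strata of a transabdominal TAG-RSOM acquisition --
#' skin vessels, peritoneal vessels, the colon-wall vascular band draped on
#' the absorber guide, and the guide itself -- then applies the anisotropic
#' point-spread function and additive noise. The two volumes differ only in
#' the lumen intensity (ink versus water) and a small rigid (Y, Z) offset
#' between the acquisitions. Ground truth is recorded on the pre-blur binary
#' rasterization.
#'
#' @param spec a [phantom_spec].
#' @return a list with elements `ink`, `water` (both [rsom_volume]) and
#'   `truth`: a list with `wall_thickness_true`, `vessel_voxel_count`
#'   (colon-band vessels, pre-blur), `vessel_volume_ul`, `rotation_deg`,
#'   `rigid_shift`, the per-frame `bend` profile (µm), `tag_depth`,
#'   `tag_axis_y`, and `seed`; plus `labels` when `spec$keep_labels`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  sp <- spec$voxel_spacing
  dims <- as.integer(round(spec$grid_extent / sp))
  ext <- spec$grid_extent
  R <- spec$tag_outer_diameter / 2
  R_in <- R - spec$tag_polymer_wall
  w <- spec$wall_thickness_true

  bend <- bend_profile(dims[1], spec$bend_amplitude)
  x_um <- (seq_len(dims[1]) - 0.5) * sp[1]
  tilt <- tan(spec$rotation_deg * pi / 180)
  y_axis <- ext[2] / 2 + bend[, "by"]
  z_apex <- spec$tag_depth + tilt * (x_um - ext[1] / 2) + bend[, "bz"]
  if (any(z_apex - w < 0) || any(z_apex < 0))
    stop("phantom does not fit grid: wall band exceeds grid depth")
  z_axis <- z_apex + R
  y_axis_fun <- stats::approxfun(x_um, y_axis, rule = 2)
  z_axis_fun <- stats::approxfun(x_um, z_axis, rule = 2)

  # --- TAG lumen and polymer wall masks (per-frame circles) ---
  y_um <- (seq_len(dims[2]) - 0.5) * sp[2]
  z_um <- (seq_len(dims[3]) - 0.5) * sp[3]
  dy2 <- (matrix(y_um, dims[1], dims[2], byrow = TRUE) - y_axis)^2   # [x, y]
  dz2 <- (matrix(z_um, dims[1], dims[3], byrow = TRUE) - z_axis)^2   # [x, z]
  r2 <- array(0, dims)
  for (z in seq_len(dims[3])) r2[, , z] <- dy2 + dz2[, z]
  lumen <- r2 <= R_in^2
  polymer <- r2 <= R^2 & !lumen
  rm(r2)

  # --- vessel layers ---
  colon_layer <- shell_layer(c(0, ext[1]), c(0, ext[2]), z_axis_fun,
                             y_axis_fun, R, w, ext[3], sp)
  skin_layer_g <- slab_layer(c(0, ext[1]), c(0, ext[2]),
                             spec$skin_depth, spec$skin_thickness)
  perit_layer_g <- slab_layer(c(0, ext[1]), c(0, ext[2]),
                              spec$peritoneum_depth, spec$peritoneum_thickness)
  segs_colon <- grow_vessel_network(colon_layer, spec$vessel_density,
                                    spec$vessel_radius_range)
  if (spec$vessel_density > 0) {
    # Superficial plexus: the outer boundary of the colon wall is a
    # continuous vascularized surface, so a few vessels run along the top of
    # the band for the whole scan length. This gives the band a sharply
    # defined upper edge (the quantity the thickness biomarker measures).
    rp <- min(max(spec$vessel_radius_range[1], w / 5),
              spec$vessel_radius_range[2], w / 2)
    offs <- seq(-0.3 * R, 0.3 * R, by = 50)
    plex <- lapply(offs, function(o) {
      xs <- seq(0, ext[1], by = 100)
      yj <- cumsum(stats::rnorm(length(xs), 0, 15))
      yj <- yj - mean(yj)
      ys <- pmin(pmax(ext[2] / 2 + o + yj, 0), ext[2])
      zs <- vapply(seq_along(xs), function(i) {
        dy <- ys[i] - y_axis_fun(xs[i])
        s2 <- R^2 - dy^2
        if (s2 <= 0) return(NA_real_)
        z_axis_fun(xs[i]) - sqrt(s2) - (w - rp)
      }, numeric(1))
      cbind(x0 = xs[-length(xs)], y0 = ys[-length(ys)], z0 = zs[-length(zs)],
            x1 = xs[-1], y1 = ys[-1], z1 = zs[-1], r = rp)
    })
    segs_colon <- rbind(segs_colon, do.call(rbind, plex))
  }
  segs_skin <- grow_vessel_network(skin_layer_g, spec$skin_vessel_density,
                                   spec$vessel_radius_range)
  segs_perit <- grow_vessel_network(perit_layer_g, spec$peritoneum_vessel_density,
                                    spec$vessel_radius_range)
  colon_v <- rasterize_segments(segs_colon, dims, sp)
  # colon vessels cannot penetrate the guide
  colon_v <- colon_v & !lumen & !polymer
  skin_v <- rasterize_segments(segs_skin, dims, sp)
  perit_v <- rasterize_segments(segs_perit, dims, sp)

  structure_img <- spec$vessel_intensity * (colon_v | skin_v | perit_v) +
    spec$tag_polymer_intensity * polymer

  truth <- list(wall_thickness_true = w,
                vessel_voxel_count = sum(colon_v),
                vessel_volume_ul = sum(colon_v) * prod(sp) * 1e-9,
                rotation_deg = spec$rotation_deg,
                rigid_shift = spec$rigid_shift,
                bend = bend,
                tag_depth = spec$tag_depth,
                tag_axis_y = ext[2] / 2,
                seed = spec$seed)
  if (spec$keep_labels) {
    truth$labels <- list(colon = colon_v, skin = skin_v, peritoneum = perit_v,
                         lumen = lumen, polymer = polymer)
  }

  fwhm <- c(spec$psf_lateral_fwhm, spec$psf_lateral_fwhm, spec$psf_axial_fwhm)
  bS <- gauss_blur3d(structure_img, fwhm, sp)
  bL <- gauss_blur3d(lumen * 1.0, fwhm, sp)
  rm(structure_img)

  ink_data <- bS + spec$tag_lumen_ink_intensity * bL
  water_data <- bS + spec$tag_lumen_water_intensity * bL
  rm(bS, bL)
  if (any(spec$rigid_shift != 0)) {
    off <- matrix(rep(spec$rigid_shift / sp[2:3], each = dims[1]), ncol = 2)
    water_data <- shift_frames(water_data, off)
  }
  if (spec$noise_sigma > 0) {
    ink_data <- ink_data + stats::rnorm(length(ink_data), 0, spec$noise_sigma)
    water_data <- water_data + stats::rnorm(length(water_data), 0, spec$noise_sigma)
  }
  ink_data[ink_data < 0] <- 0
  water_data[water_data < 0] <- 0

  list(ink = rsom_volume(ink_data, sp, "ink"),
       water = rsom_volume(water_data, sp, "water"),
       truth = truth)
}

#' Apply a per-frame bend to a volume
#'
#' Translates every YZ frame by its (Y, Z) offset with bilinear resampling
#' and zero fill, emulating the deformation a bent absorber guide imprints
#' on the acquisition. The inverse of [correct_bend()] up to interpolation
#' error; a constant profile is a rigid in-plane shift.
#'
#' @param vol an [rsom_volume].
#' @param profile_um matrix with one row per X frame and columns (Y, Z)
#'   offsets in µm.
#' @return the bent [rsom_volume]; warns if content is pushed outside the
#'   grid (lost voxels are zero-filled).
#' @export
apply_bend <- function(vol, profile_um) {
  d <- dim(vol$data)
  if (nrow(profile_um) != d[1])
    stop("bend profile must have one row per X frame")
  off <- cbind(profile_um[, 1] / vol$spacing[2],
               profile_um[, 2] / vol$spacing[3])
  max_off <- apply(abs(off), 2, max)
  if (any(max_off >= d[2:3] / 2))
    warning("bend offsets push content outside the grid; zero-filled")
  out <- shift_frames(vol$data, off)
  out[out < 0] <- 0
  with_data(vol, out)
}
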