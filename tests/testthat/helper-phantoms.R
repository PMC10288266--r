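# Shared fixtures: phantoms are expensive, so builders are memoized for the
# duration of the test run. Everything is generated in code from fixed seeds.

.phantom_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .phantom_cache))
    assign(key, builder(), envir = .phantom_cache)
  get(key, envir = .phantom_cache)
}

# A clean compact pair: straight guide, no shift, no bend, no noise.
clean_pair <- function() {
  cached("clean_pair", function() {
    sp <- cohort_phantom_spec(wall_thickness_true = 100, seed = 5,
                              noise_sigma = 0)
    sp$rotation_deg <- 0
    sp$rigid_shift <- c(0, 0)
    sp$bend_amplitude <- 0
    generate_phantom(sp)
  })
}

# Same geometry but with the guide placed shallower so the lumen stays
# visible under large applied bends.
shallow_clean_ink <- function() {
  cached("shallow_clean_ink", function() {
    sp <- cohort_phantom_spec(wall_thickness_true = 100, seed = 5,
                              noise_sigma = 0)
    sp$rotation_deg <- 0
    sp$rigid_shift <- c(0, 0)
    sp$bend_amplitude <- 0
    sp$tag_depth <- 400
    generate_phantom(sp)$ink
  })
}

# A labelled noiseless pair for segmentation/volumetry truth comparisons.
labelled_pair <- function() {
  cached("labelled_pair", function() {
    generate_phantom(cohort_phantom_spec(wall_thickness_true = 100, seed = 3,
                                         noise_sigma = 0, keep_labels = TRUE))
  })
}

# Independent geometric region oracle for the compact phantom: colon-band
# voxels inside the ±half_angle wedge (computed from the known cylinder
# geometry, not from pipeline code) and the reported analysis window.
# Valid for straight, unrotated phantoms, where the analysis window indexes
# the original grid directly.
cohort_region_truth_vox <- function(ph, window, spec, half_angle = 18) {
  d <- dim(ph$ink$data)
  spx <- ph$ink$spacing
  yc <- spec$grid_extent[2] / 2                  # guide axis, µm
  zc <- spec$tag_depth + spec$tag_outer_diameter / 2
  y_um <- (seq_len(d[2]) - 0.5) * spx[2]
  z_um <- (seq_len(d[3]) - 0.5) * spx[3]
  DY <- matrix(y_um - yc, d[2], d[3])
  DZ <- matrix(z_um - zc, d[2], d[3], byrow = TRUE)
  r <- sqrt(DY^2 + DZ^2)
  phi <- acos(pmax(pmin(-DZ / r, 1), -1)) * 180 / pi
  wedge <- r > spec$tag_outer_diameter / 2 & phi <= half_angle
  win <- lapply(window, function(rg) rg[1]:rg[2])
  keep <- array(FALSE, d)
  for (x in win$x) keep[x, win$y, win$z] <- wedge[win$y, win$z]
  sum(ph$truth$labels$colon & keep)
}
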