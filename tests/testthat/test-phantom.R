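test_that("generation is bit-deterministic given (spec, seed)", {
  sp <- cohort_phantom_spec(wall_thickness_true = 60, seed = 17)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$ink$data, b$ink$data)
  expect_identical(a$water$data, b$water$data)
  expect_identical(a$truth, b$truth)
})

test_that("empty densities yield the expected strata only", {
  sp <- cohort_phantom_spec(seed = 1, noise_sigma = 0,
                            vessel_density = 0,
                            skin_vessel_density = 0,
                            peritoneum_vessel_density = 0,
                            tag_polymer_intensity = 0)
  ph <- generate_phantom(sp)
  # water volume: no vessels, no polymer, lumen at water intensity only
  expect_lt(max(ph$water$data), 1.2 * sp$tag_lumen_water_intensity)
  expect_identical(ph$truth$vessel_voxel_count, 0L)
  # skin layer alone reappears when its density is restored
  sp2 <- cohort_phantom_spec(seed = 1, noise_sigma = 0,
                             vessel_density = 0,
                             peritoneum_vessel_density = 0,
                             tag_polymer_intensity = 0,
                             tag_lumen_water_intensity = 0)
  ph2 <- generate_phantom(sp2)
  nz <- which(ph2$water$data > 0.01, arr.ind = TRUE)
  depth <- nz[, 3] * ph2$water$spacing[3]
  expect_true(all(depth < sp2$skin_depth + sp2$skin_thickness + 60))
})

test_that("truth volume equals voxel count times voxel volume and is pre-blur", {
  ph <- labelled_pair()
  expect_identical(ph$truth$vessel_voxel_count, sum(ph$truth$labels$colon))
  expect_equal(ph$truth$vessel_volume_ul,
               ph$truth$vessel_voxel_count * prod(ph$ink$spacing) * 1e-9)
})

test_that("the wall band's pre-blur gap to the lumen equals thickness plus polymer wall", {
  sp <- cohort_phantom_spec(wall_thickness_true = 100, seed = 9,
                            noise_sigma = 0, keep_labels = TRUE,
                            vessel_density = 4e-4,
                            vessel_radius_range = c(10, 20))
  sp$rotation_deg <- 0
  sp$bend_amplitude <- 0
  ph <- generate_phantom(sp)
  lum_top <- apply(ph$truth$labels$lumen, 1,
                   function(m) min(which(apply(m, 2, any))))
  ves_top <- apply(ph$truth$labels$colon, 1,
                   function(m) min(which(apply(m, 2, any))))
  gap_um <- (lum_top - ves_top) * ph$ink$spacing[3]
  expected <- sp$wall_thickness_true + sp$tag_polymer_wall
  expect_true(all(abs(gap_um - expected) <= 2 * ph$ink$spacing[3]))
})

test_that("ink and water differ only in the lumen plus the rigid shift", {
  sp <- cohort_phantom_spec(wall_thickness_true = 100, seed = 21,
                            noise_sigma = 0)
  sp$rigid_shift <- c(40, 8)  # (2, 2) voxels: exact integer translation
  ph <- generate_phantom(sp)
  back <- apply_rigid(ph$water, -2, -2)
  d <- dim(ph$ink$data)
  # outside the lumen's blurred halo and away from shift borders
  zmax <- floor((sp$tag_depth + sp$tag_polymer_wall) / 4) - 5
  diffs <- abs(ph$ink$data[3:(d[1]), 5:(d[2] - 4), 5:zmax] -
               back$data[3:(d[1]), 5:(d[2] - 4), 5:zmax])
  expect_lt(max(diffs), 1e-6)
})

test_that("vessel growth matches the requested density and is reproducible", {
  layer <- tagrsom:::slab_layer(c(0, 2000), c(0, 2000), 100, 150)
  set.seed(4)
  empty <- grow_vessel_network(layer, 0, c(10, 25))
  expect_identical(nrow(empty), 0L)
  set.seed(4)
  a <- grow_vessel_network(layer, 2e-4, c(10, 25))
  set.seed(4)
  b <- grow_vessel_network(layer, 2e-4, c(10, 25))
  expect_identical(a, b)
  target <- 2e-4 * layer$volume
  expect_gt(nrow(a), 50)
  expect_lt(abs(attr(a, "total_length") - target) / target, 0.1)
  # doubling density doubles mean total length (20 replicates)
  ratios <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    l1 <- attr(grow_vessel_network(layer, 1e-4, c(10, 25)), "total_length")
    set.seed(2000 + s)
    l2 <- attr(grow_vessel_network(layer, 2e-4, c(10, 25)), "total_length")
    l2 / l1
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2) / 2, 0.1)
})

test_that("segments stay inside their layer", {
  layer <- tagrsom:::slab_layer(c(0, 1500), c(0, 1500), 200, 120)
  set.seed(8)
  segs <- grow_vessel_network(layer, 3e-4, c(10, 25))
  expect_true(all(segs[, c("z0", "z1")] >= 200 - 1e-9))
  expect_true(all(segs[, c("z0", "z1")] <= 320 + 1e-9))
  expect_true(all(segs[, c("x0", "x1")] >= 0 & segs[, c("x0", "x1")] <= 1500))
})

test_that("bend application: zero profile is identity, constant profile is rigid", {
  ph <- clean_pair()
  v <- ph$ink
  n <- dim(v$data)[1]
  expect_identical(apply_bend(v, cbind(rep(0, n), rep(0, n)))$data, v$data)
  vs <- apply_bend(v, cbind(rep(5 * 20, n), rep(10 * 4, n)))
  vr <- apply_rigid(v, 5, 10)
  expect_equal(vs$data, vr$data)
  expect_warning(apply_bend(v, cbind(rep(0, n), rep(400 * 4, n))),
                 "outside the grid")
})

test_that("oversized wall bands are rejected", {
  expect_error(phantom_spec(tag_depth = 80, wall_thickness_true = 100),
               "does not fit grid")
})

test_that("blur conserves interior intensity and matches the plain-R kernel", {
  set.seed(2)
  a <- array(0, c(48, 40, 60))
  a[15:34, 12:30, 20:42] <- runif(20 * 19 * 23)
  b <- tagrsom:::gauss_blur3d(a, c(40, 40, 10), c(20, 20, 4))
  expect_lt(abs(sum(b) - sum(a)) / sum(a), 0.01)
  ref <- a
  sig <- c(40, 40, 10) / (2 * sqrt(2 * log(2))) / c(20, 20, 4)
  for (ax in 1:3) ref <- tagrsom:::blur_axis(ref, sig[ax], ax)
  expect_equal(b, ref, tolerance = 1e-12)
})

test_that("tube rasterization marks exactly the voxels within radius", {
  dims <- c(30, 30, 60)
  spacing <- c(20, 20, 4)
  segs <- rbind(c(100, 300, 120, 500, 300, 120, 30))
  m <- tagrsom:::rasterize_segments(segs, dims, spacing)
  # brute-force oracle over all voxel centers
  oracle <- array(FALSE, dims)
  for (i in 1:30) for (j in 1:30) for (k in 1:60) {
    p <- (c(i, j, k) - 0.5) * spacing
    t <- min(max((p[1] - 100) / 400, 0), 1)
    q <- c(100 + 400 * t, 300, 120)
    oracle[i, j, k] <- sum((p - q)^2) <= 30^2
  }
  expect_identical(m, oracle)
})
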