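make_trace <- function(x, y, z, spacing = c(20, 20, 4), wall = 150) {
  tr <- data.frame(x = x, y_lumen = y, z_lumen = z,
                   z_outer = z - wall / spacing[3], valid = TRUE)
  attr(tr, "spacing") <- spacing
  attr(tr, "polymer_wall_um") <- wall
  attr(tr, "tag_radius_um") <- 1500
  class(tr) <- c("tag_trace", "data.frame")
  tr
}

test_that("central crop honors extent, identity and parity conventions", {
  set.seed(3)
  v <- rsom_volume(array(runif(40 * 30 * 50), c(40, 30, 50)), c(20, 20, 4), "ink")
  expect_identical(crop_central(v, volume_extent(v))$data, v$data)
  c1 <- crop_central(v, c(400, 400, 120))
  expect_equal(dim(c1$data), c(20L, 20L, 30L))
  # odd margin: 40 - 19 = 21 -> low margin 10, high margin 11
  c2 <- crop_central(v, c(19 * 20, 30 * 20, 50 * 4))
  expect_identical(c2$data[1, , ], v$data[11, , ])
  expect_identical(c2$data[19, , ], v$data[29, , ])
  expect_error(crop_central(v, c(2000, 400, 120)), "axis X")
})

test_that("a 12 x 12 x 3 mm acquisition crops to the protocol window", {
  v <- rsom_volume(array(0, c(600, 600, 750)), c(20, 20, 4), "ink")
  cc <- crop_central(v, c(6000, 3000, 2000))
  expect_equal(dim(cc$data), c(300L, 150L, 500L))
})

test_that("the traced lumen apex matches phantom geometry frame by frame", {
  ph <- clean_pair()
  tr <- trace_tag(ph$ink, 150, 3000)
  # apex depth = tag_depth + polymer wall = 630 µm -> voxel 158 boundary
  expect_true(all(abs(tr$z_lumen - 630 / 4) <= 1.5))
  expect_true(all(abs(tr$y_lumen - 15.5) <= 1))
  expect_true(all(tr$valid))
})

test_that("tracing a water volume reports a missing fiducial", {
  ph <- clean_pair()
  expect_error(trace_tag(ph$water), "TAG not found")
})

test_that("an applied bend is recovered by the trace after detrending", {
  v <- shallow_clean_ink()
  n <- dim(v$data)[1]
  prof <- cbind(rep(0, n), 40 * sin(2 * pi * (1:n) / n))
  vb <- apply_bend(v, prof)
  tr <- trace_tag(vb, 150, 3000)
  rec <- (tr$z_lumen - mean(tr$z_lumen)) * 4
  expect_true(max(abs(rec - (prof[, 2] - mean(prof[, 2])))) <= 4)
})

test_that("rotation estimation is the closed-form triangulation", {
  flat <- make_trace(1:100, rep(20, 100), rep(150, 100))
  expect_equal(estimate_rotation(flat), 0)
  # dz = 100 µm over dx = 5720 µm -> atan(100/5720)
  tr <- make_trace(c(1, 287), c(20, 20), c(150, 150 + 100 / 4))
  expect_equal(estimate_rotation(tr), atan(100 / 5720) * 180 / pi,
               tolerance = 1e-10)
  expect_equal(round(estimate_rotation(tr), 4), 1.0016)
  one <- make_trace(1, 20, 150)
  expect_error(estimate_rotation(one), "at least two valid")
})

test_that("rotation recovery from tilted phantoms is within tolerance", {
  for (th in c(-10, -1, 5)) {
    sp <- cohort_phantom_spec(wall_thickness_true = 100, seed = 5,
                              noise_sigma = 0)
    sp$rotation_deg <- th
    sp$rigid_shift <- c(0, 0)
    sp$bend_amplitude <- 0
    ph <- generate_phantom(sp)
    tr <- trace_tag(ph$ink, 150, 3000)
    est <- estimate_rotation(tr)
    expect_lt(abs(est - th), 0.5)
    v2 <- resample_rotated(ph$ink, est)
    expect_lt(abs(estimate_rotation(trace_tag(v2, 150, 3000))), 0.2)
  }
})

test_that("rotation resampling: identity at zero, invertible on smooth content", {
  ph <- clean_pair()
  v <- ph$ink
  expect_identical(resample_rotated(v, 0)$data, v$data)
  r1 <- resample_rotated(v, 4)
  r2 <- resample_rotated(r1, -4)
  d <- dim(v$data)
  # interior, clear of zero-filled corners
  ix <- 15:(d[1] - 14); iz <- 30:(d[3] - 29)
  err <- max(abs(r2$data[ix, , iz] - v$data[ix, , iz]))
  expect_lt(err, 0.01 * diff(range(v$data)))
})

test_that("co-registration recovers rigid offsets and degrades gracefully", {
  sp <- cohort_phantom_spec(100, seed = 6, noise_sigma = 0)
  sp$rotation_deg <- 0; sp$bend_amplitude <- 0
  sp$rigid_shift <- c(3 * 20, 5 * 4)
  ph <- generate_phantom(sp)
  tr <- trace_tag(ph$ink, 150, 3000)
  rg <- coregister(ph$ink, ph$water, tr)
  expect_lte(abs(rg$dy - (-3)), 1)
  expect_lte(abs(rg$dz - (-5)), 1)
  expect_gt(rg$peak_corr, 0.5)
  # identical volumes: identity
  rg0 <- coregister(ph$ink, ph$ink, tr)
  expect_identical(c(rg0$dy, rg0$dz), c(0, 0))
  # pure noise: identity with a warning
  set.seed(1)
  n1 <- rsom_volume(array(abs(rnorm(30 * 20 * 40)), c(30, 20, 40)), c(20, 20, 4), "ink")
  n2 <- rsom_volume(array(abs(rnorm(30 * 20 * 40)), c(30, 20, 40)), c(20, 20, 4), "water")
  expect_warning(rgn <- coregister(n1, n2), "below 0.2")
  expect_identical(c(rgn$dy, rgn$dz), c(0, 0))
})

test_that("bend correction straightens and inverts an applied bend", {
  v <- shallow_clean_ink()
  n <- dim(v$data)[1]
  d <- dim(v$data)
  # straight guide: correction is the identity within interpolation error
  tr0 <- trace_tag(v, 150, 3000)
  v0 <- correct_bend(v, tr0)
  expect_gt(cor(as.vector(v0$data), as.vector(v$data)), 0.99)
  tr0b <- trace_tag(v0, 150, 3000)
  expect_lt(sqrt(mean((tr0b$z_lumen - mean(tr0b$z_lumen))^2)), 0.3)
  # sinusoidal bend, 10 voxels peak in Z, zero-median
  prof <- cbind(40 * sin(2 * pi * (1:n) / n), 40 * sin(2 * pi * (1:n) / n))
  vb <- apply_bend(v, prof)
  tr <- trace_tag(vb, 150, 3000)
  vc <- correct_bend(vb, tr)
  tr2 <- trace_tag(vc, 150, 3000)
  expect_lt(sqrt(mean((tr2$z_lumen - mean(tr2$z_lumen))^2)), 1)
  expect_lt(sqrt(mean((tr2$y_lumen - mean(tr2$y_lumen))^2)), 1)
  iy <- 5:(d[2] - 4); iz <- 13:(d[3] - 12)
  cc <- cor(as.vector(v$data[, iy, iz]), as.vector(vc$data[, iy, iz]))
  expect_gte(cc, 0.99)
})

test_that("analysis trim yields the canonical shape and tracks the guide", {
  ph <- clean_pair()
  tr <- trace_tag(ph$ink, 150, 3000)
  t1 <- trim_analysis(ph$ink, tr, c(800, 440, 400))
  expect_equal(dim(t1$volume$data), c(40L, 22L, 100L))
  expect_equal(volume_extent(t1$volume), c(800, 440, 400))
  # identity when the extent equals the input extent
  d <- dim(ph$ink$data)
  t2 <- trim_analysis(ph$ink, tr, volume_extent(ph$ink))
  expect_identical(t2$volume$data, ph$ink$data)
  # the Y window follows an off-centre guide
  tr_off <- tr
  tr_off$y_lumen <- tr$y_lumen + 4
  t3 <- trim_analysis(ph$ink, tr_off, c(800, 200, 400))
  t4 <- trim_analysis(ph$ink, tr, c(800, 200, 400))
  expect_equal(t3$window$y[1] - t4$window$y[1], 4L)
  expect_error(trim_analysis(ph$ink, tr, c(800, 440, 600)), "axis Z")
  expect_error(trim_analysis(ph$ink, tr, c(2000, 440, 400)), "axis X")
})

test_that("the full chain is deterministic and transfers ink transforms to water", {
  sp <- cohort_phantom_spec(100, seed = 12)
  ph <- generate_phantom(sp)
  cfg <- cohort_run_config()
  a <- preprocess_pair(ph$ink, ph$water, cfg)
  b <- preprocess_pair(ph$ink, ph$water, cfg)
  expect_identical(a$ink$data, b$ink$data)
  expect_identical(a$water$data, b$water$data)
  expect_equal(dim(a$ink$data), dim(a$water$data))
  # residual ink/water misalignment after transfer is at most one voxel:
  # the brightest in-sector structures coincide
  sec <- angular_sector_mask(dim(a$ink$data), a$trace, 18, a$ink$spacing)
  ci <- cor(a$ink$data[sec], a$water$data[sec])
  expect_gt(ci, 0.9)
})
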