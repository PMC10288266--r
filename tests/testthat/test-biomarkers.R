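test_that("segment blocks split the X range with the stated convention", {
  v <- rsom_volume(array(1, c(274, 4, 5)), c(20, 20, 4), "ink")
  mask <- array(TRUE, c(274, 4, 5))
  s <- segment_mips(v, mask, 7)
  sizes <- vapply(s$blocks, length, 1L)
  expect_equal(sizes, c(40L, rep(39L, 6)))      # 274 = 7*39 + 1, extra at low X
  expect_equal(unlist(s$blocks), 1:274)
  # constant volume: every MIP is constant
  expect_true(all(vapply(s$mips, function(m) all(m == 1), logical(1))))
  # single segment = global MIP
  v2 <- rsom_volume(array(runif(200), c(10, 4, 5)), c(20, 20, 4), "ink")
  g <- segment_mips(v2, array(TRUE, c(10, 4, 5)), 1)
  expect_equal(g$mips[[1]], apply(v2$data, c(2, 3), max))
  expect_error(segment_mips(v2, array(TRUE, c(10, 4, 5)), 11), "n_segments")
  # empty-mask segments are flagged
  m3 <- array(TRUE, c(10, 4, 5)); m3[6:10, , ] <- FALSE
  f <- segment_mips(v2, m3, 2)
  expect_equal(f$flagged, c(FALSE, TRUE))
})

test_that("8-bit conversion follows the ImageJ convention with half-up rounding", {
  a <- array(0, c(4, 3, 2))
  a[1, 1, 1] <- 10                # global max
  a[2, 1, 1] <- 5                 # exactly half -> 127.5 -> 128
  a[3, 1, 1] <- 10                # masked out
  mask <- array(TRUE, dim(a)); mask[3, 1, 1] <- FALSE
  v8 <- to_8bit(rsom_volume(a, c(20, 20, 4), "ink"), mask)
  expect_identical(v8[1, 1, 1], 255L)
  expect_identical(v8[2, 1, 1], 128L)
  expect_identical(v8[3, 1, 1], 0L)
  expect_equal(attr(v8, "scale_max"), 10)
  expect_identical(total_signal_intensity(v8), 255 + 128)
  zero <- to_8bit(rsom_volume(array(0, dim(a)), c(20, 20, 4), "ink"), mask)
  expect_true(all(zero == 0L))
})

test_that("iterative intermeans matches its closed forms", {
  h <- numeric(256)
  h[10 + 1] <- 500; h[200 + 1] <- 500
  expect_identical(isodata_threshold(h), 105L)   # intermean of 10 and 200
  h1 <- numeric(256); h1[77 + 1] <- 12
  expect_identical(isodata_threshold(h1), 77L)
  empty <- numeric(256); empty[1] <- 99
  expect_error(isodata_threshold(empty), "nothing to threshold")
  # ignore_zeros: bin 0 must not drag the lower mean down
  h2 <- numeric(256); h2[1] <- 1e6; h2[10 + 1] <- 100; h2[200 + 1] <- 100
  expect_identical(isodata_threshold(h2), 105L)
  expect_identical(isodata_threshold(h2, ignore_zeros = FALSE), 100L)
})

test_that("iterative intermeans agrees with the exhaustive fixed-point oracle", {
  oracle <- function(h) {
    h <- as.numeric(h); h[1] <- 0
    vals <- 0:255
    for (t in 1:254) {
      lo <- vals <= t
      slo <- sum(h[lo]); shi <- sum(h[!lo])
      if (slo == 0 || shi == 0) next
      mlo <- sum(vals[lo] * h[lo]) / slo
      mhi <- sum(vals[!lo] * h[!lo]) / shi
      if (t == floor((mlo + mhi) / 2 + 0.5)) return(t)
    }
    NA_integer_
  }
  # random histograms: bimodal background/foreground mixtures with Poisson
  # counts, the shape the in-mask 8-bit volumes produce
  set.seed(99)
  n_checked <- 0
  for (i in 1:1000) {
    m1 <- runif(1, 20, 90); s1 <- runif(1, 10, 30)
    m2 <- runif(1, 120, 230); s2 <- runif(1, 10, 40)
    w <- runif(1, 0.3, 0.9)
    dens <- w * dnorm(0:255, m1, s1) + (1 - w) * dnorm(0:255, m2, s2)
    h <- rpois(256, dens / sum(dens) * 5000)
    ref <- oracle(h)
    if (is.na(ref)) next
    expect_identical(isodata_threshold(h), ref)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 950)
})

test_that("blood volume is the supra-threshold count times voxel volume", {
  v8 <- array(0L, c(50, 50, 25))
  v8[seq_len(62500)] <- 100L
  expect_equal(blood_volume(v8, 50L, c(20, 20, 4)), 0.1)   # 62500 voxels -> 0.1 µL
  expect_equal(blood_volume(v8, 255L, c(20, 20, 4)), 0)
  # strict inequality at the threshold
  expect_equal(blood_volume(v8, 100L, c(20, 20, 4)), 0)
  # non-increasing in the threshold
  set.seed(1)
  r8 <- array(sample(0:255, 4000, TRUE), c(20, 20, 10))
  bv <- vapply(c(0, 50, 100, 200, 255), function(t) blood_volume(r8, t, c(20, 20, 4)), numeric(1))
  expect_true(all(diff(bv) <= 0))
})

test_that("thickness responds linearly to the polymer wall and clamps at zero", {
  ph <- clean_pair()
  cfg <- cohort_run_config()
  pp <- preprocess_pair(ph$ink, ph$water, cfg)
  sec <- angular_sector_mask(dim(pp$ink$data), pp$trace, 18, pp$ink$spacing)
  mask <- separate_colon_wall(pp$ink, pp$trace, sec)
  segs <- segment_mips(pp$ink, mask, 7)
  t150 <- measure_wall_thickness(segs, pp$trace, 150)
  t170 <- measure_wall_thickness(segs, pp$trace, 170)
  expect_equal(t150$mean_um - t170$mean_um, 20)
  expect_equal(t150$per_segment - t170$per_segment, rep(20, 7))
  # a wall so thick the subtraction goes negative is clamped with a warning
  expect_warning(t_big <- measure_wall_thickness(segs, pp$trace, 5000),
                 "clamped")
  expect_true(all(t_big$per_segment[!is.na(t_big$per_segment)] == 0))
})

test_that("biomarkers rise with inflammation severity across seeds", {
  healthy <- inflamed <- vector("list", 4)
  cfg <- cohort_run_config()
  for (i in 1:4) {
    g1 <- generate_phantom(cohort_phantom_spec(60, 1, seed = 300 + i))
    g2 <- generate_phantom(cohort_phantom_spec(130, 2, seed = 400 + i))
    healthy[[i]] <- quantify_pair(g1$ink, g1$water, cfg)$ink_set
    inflamed[[i]] <- quantify_pair(g2$ink, g2$water, cfg)$ink_set
  }
  med <- function(l, f) median(vapply(l, function(x) x[[f]], numeric(1)))
  expect_gt(med(inflamed, "thickness_um"), med(healthy, "thickness_um"))
  expect_gt(med(inflamed, "intensity_au"), med(healthy, "intensity_au"))
  expect_gt(med(inflamed, "blood_volume_ul"), med(healthy, "blood_volume_ul"))
})

test_that("widening the sector never decreases intensity or blood volume", {
  ph <- clean_pair()
  cfg18 <- cohort_run_config()
  cfg90 <- cohort_run_config(sector_half_angle_deg = 90)
  q18 <- quantify_pair(ph$ink, ph$water, cfg18)
  q90 <- quantify_pair(ph$ink, ph$water, cfg90)
  expect_gte(q90$ink_set$blood_volume_ul, q18$ink_set$blood_volume_ul)
  expect_gte(q90$ink_set$intensity_au, q18$ink_set$intensity_au)
})
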