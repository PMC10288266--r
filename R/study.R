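#' Compact phantom specification for cohort studies
#'
#' A reduced-field-of-view phantom (1000 x 600 x 720 µm at the standard
#' 20 x 20 x 4 µm voxel spacing) carrying the same four strata as the full
#' acquisition geometry -- skin vessels, peritoneal vessels, colon-wall band
#' on the guide, guide lumen -- but small enough that whole simulated
#' cohorts can be generated and quantified quickly. The guide apex sits at
#' 480 µm depth so the scaled analysis window (see [cohort_run_config()])
#' spans the colon band and the lower peritoneal layer.
#'
#' @param wall_thickness_true true colon-wall thickness, µm.
#' @param vessel_density_scale multiplier on the baseline colon vessel
#'   density (1 = healthy, 2 = inflamed-style densification).
#' @param seed integer seed.
#' @param noise_sigma additive noise level (a.u.).
#' @param ... further overrides passed to [phantom_spec()].
#' @return a [phantom_spec()].
#' @export
cohort_phantom_spec <- function(wall_thickness_true = 100,
                                vessel_density_scale = 1,
                                seed = 1L, noise_sigma = 0.02, ...) {
  args <- list(grid_extent = c(1000, 600, 720),
               voxel_spacing = c(20, 20, 4),
               tag_depth = 480,
               wall_thickness_true = wall_thickness_true,
               vessel_density = 1e-4 * vessel_density_scale,
               skin_depth = 20, skin_thickness = 40,
               skin_vessel_density = 6e-5,
               peritoneum_depth = 80, peritoneum_thickness = 50,
               peritoneum_vessel_density = 6e-5,
               bend_amplitude = 0, rotation_deg = 0,
               rigid_shift = c(20, 8),
               noise_sigma = noise_sigma,
               seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(phantom_spec, args)
}

#' Run configuration matched to [cohort_phantom_spec()]
#'
#' Same protocol constants as [run_config()], with the crop and analysis
#' windows scaled to the compact cohort grid.
#'
#' @param ... overrides passed to [run_config()].
#' @return a [run_config()].
#' @export
cohort_run_config <- function(...) {
  run_config(crop_extent_um = c(1000, 600, 720),
             analysis_extent_um = c(800, 440, 400), ...)
}

#' Preprocess and quantify one phantom (or acquisition) pair
#'
#' Convenience wrapper: runs [preprocess_pair()] and [compute_biomarkers()]
#' on the ink member (and optionally, using the identical ink-derived mask
#' and trace, on the co-registered water member).
#'
#' @param ink,water the volume pair.
#' @param config a [run_config()].
#' @param measure_water also quantify the water member with the ink-derived
#'   geometry.
#' @param manual_mask optional manual overlay mask in the analysis frame.
#' @return list with `ink_set` (and `water_set`), the analysis `trace`,
#'   `mask` and alignment `record`.
#' @export
quantify_pair <- function(ink, water, config = run_config(),
                          measure_water = FALSE, manual_mask = NULL) {
  pp <- preprocess_pair(ink, water, config)
  d <- dim(pp$ink$data)
  sector <- angular_sector_mask(d, pp$trace, config$sector_half_angle_deg,
                                pp$ink$spacing)
  mask <- separate_colon_wall(pp$ink, pp$trace, sector, manual_mask,
                              config$overlay_gap_um)
  out <- list(ink_set = compute_biomarkers(pp$ink, pp$trace, config, mask = mask),
              trace = pp$trace, mask = mask, record = pp$record)
  if (measure_water)
    out$water_set <- compute_biomarkers(pp$water, pp$trace, config, mask = mask)
  out
}

#' Generate and quantify a phantom cohort
#'
#' Maps a table of phantom conditions through the full pipeline --
#' generation, preprocessing, segmentation, biomarkers -- and returns one
#' tidy row per phantom with ground truth next to the measured read-outs.
#'
#' @param conditions data.frame with columns `wall_um`, `density_scale`,
#'   `seed` and optionally `group`, `noise_sigma`.
#' @param config a [run_config()]; defaults to [cohort_run_config()].
#' @param measure_water also record water-member biomarkers.
#' @return data.frame with truth columns (`wall_true_um`,
#'   `vessel_volume_true_ul`) and measured biomarkers.
#' @export
run_phantom_cohort <- function(conditions, config = cohort_run_config(),
                               measure_water = FALSE) {
  rows <- lapply(seq_len(nrow(conditions)), function(i) {
    cond <- conditions[i, ]
    ns <- if ("noise_sigma" %in% names(cond)) cond$noise_sigma else 0.02
    spec <- cohort_phantom_spec(wall_thickness_true = cond$wall_um,
                                vessel_density_scale = cond$density_scale,
                                seed = cond$seed, noise_sigma = ns)
    ph <- generate_phantom(spec)
    q <- quantify_pair(ph$ink, ph$water, config, measure_water = measure_water)
    row <- data.frame(
      subject = i,
      group = if ("group" %in% names(cond)) cond$group else NA_character_,
      seed = cond$seed,
      wall_true_um = ph$truth$wall_thickness_true,
      vessel_volume_true_ul = ph$truth$vessel_volume_ul,
      thickness_um = q$ink_set$thickness_um,
      intensity_au = q$ink_set$intensity_au,
      blood_volume_ul = q$ink_set$blood_volume_ul,
      threshold_8bit = q$ink_set$threshold_8bit,
      stringsAsFactors = FALSE)
    if (measure_water) {
      row$water_thickness_um <- q$water_set$thickness_um
      row$water_intensity_au <- q$water_set$intensity_au
      row$water_blood_volume_ul <- q$water_set$blood_volume_ul
    }
    row
  })
  do.call(rbind, rows)
}

#' Simulate a two-arm colitis cohort of phantoms
#'
#' Healthy and inflamed arms with subject-level variation in true wall
#' thickness (normal, truncated to a physiological range) and the inflamed
#' arm's vessel densification, mirroring the contrast between control and
#' dextran-sulfate-sodium colitis animals.
#'
#' @param n_healthy,n_inflamed arm sizes.
#' @param healthy_mean,healthy_sd,inflamed_mean,inflamed_sd true-thickness
#'   distributions, µm.
#' @param inflamed_density_scale colon vessel densification of the inflamed
#'   arm.
#' @param seed cohort seed (subject seeds are derived from it).
#' @param config a [run_config()].
#' @return cohort data.frame as from [run_phantom_cohort()], with `group`
#'   set to `"healthy"`/`"inflamed"`.
#' @export
simulate_colitis_cohort <- function(n_healthy = 10, n_inflamed = 10,
                                    healthy_mean = 60, healthy_sd = 20.67,
                                    inflamed_mean = 130, inflamed_sd = 53.65,
                                    inflamed_density_scale = 2,
                                    seed = 1L,
                                    config = cohort_run_config()) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  rtrunc <- function(n, mean, sd, lo = 24, hi = 220) {
    x <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        v <- stats::rnorm(1, mean, sd)
        if (v >= lo && v <= hi) break
      }
      x[i] <- v
    }
    x
  }
  walls <- c(rtrunc(n_healthy, healthy_mean, healthy_sd),
             rtrunc(n_inflamed, inflamed_mean, inflamed_sd))
  conditions <- data.frame(
    wall_um = walls,
    density_scale = rep(c(1, inflamed_density_scale), c(n_healthy, n_inflamed)),
    seed = sample.int(.Machine$integer.max, n_healthy + n_inflamed),
    group = rep(c("healthy", "inflamed"), c(n_healthy, n_inflamed)),
    stringsAsFactors = FALSE)
  run_phantom_cohort(conditions, config)
}
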