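#!/usr/bin/env Rscript

# Step 1: define the synthetic colitis study and materialize one example
# acquisition pair.
#
# The study compares a healthy arm (true wall thickness ~ N(60, 20.7) µm,
# baseline vessel density) against an inflamed arm (~ N(130, 53.7) µm,
# doubled vessel density), n = 10 per arm — the magnitudes of a
# dextran-sulfate-sodium colitis contrast. Subject-level phantoms are
# regenerated from their seeds downstream; this step freezes the design
# table and writes one ink/water pair to disk so the file-based interface
# is exercised end to end.

suppressPackageStartupMessages(library(tagrsom))

dir.create("results/volumes", showWarnings = FALSE, recursive = TRUE)
study_seed <- 20260
set.seed(study_seed)

rtrunc <- function(n, mean, sd, lo = 24, hi = 220) {
  x <- numeric(n)
  for (i in seq_len(n)) repeat { v <- rnorm(1, mean, sd)
    if (v >= lo && v <= hi) { x[i] <- v; break } }
  x
}

design <- data.frame(
  subject = sprintf("m%02d", 1:20),
  group = rep(c("healthy", "inflamed"), each = 10),
  wall_um = c(rtrunc(10, 60, 20.67), rtrunc(10, 130, 53.65)),
  density_scale = rep(c(1, 2), each = 10),
  seed = sample.int(1e6, 20)
)
write.csv(design, "results/cohort_design.csv", row.names = FALSE)
cat("Design: 10 healthy (wall", round(mean(design$wall_um[1:10])),
    "µm mean) vs 10 inflamed (wall", round(mean(design$wall_um[11:20])),
    "µm mean, 2x vessel density)\n")

# materialize the first subject of each arm as multi-page TIFF + sidecar
for (i in c(1, 11)) {
  sp <- cohort_phantom_spec(design$wall_um[i], design$density_scale[i],
                            seed = design$seed[i])
  ph <- generate_phantom(sp)
  base <- file.path("results/volumes", design$subject[i])
  write_volume(ph$ink, paste0(base, "_ink.tif"))
  write_volume(ph$water, paste0(base, "_water.tif"))
  jsonlite::write_json(ph$truth[c("wall_thickness_true", "vessel_voxel_count",
                                  "vessel_volume_ul", "rotation_deg", "seed")],
                       paste0(base, "_truth.json"), auto_unbox = TRUE)
  cat("Wrote", base, "_{ink,water}.tif (", paste(dim(ph$ink$data), collapse = "x"),
      "voxels )\n")
}
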