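#!/usr/bin/env Rscript
# Generate the synthetic study data sets with known ground truth.
#
# Two data sets mirror the two experimental settings the pipeline targets:
#   - a liquid-culture-style set ("invitro_like"): an induced condition and
#     a no-inducer control, 3 biological replicates at 3 timepoints;
#   - a leaf-style set ("inplanta_like"): one condition, 8 replicates at
#     3 timepoints, baselined on time zero.
# Micrographs (TIFF) and ground truth land under scratch/ (bulky,
# regenerable); the design tables are copied to results/ for reference.

suppressMessages(library(popfluor))

seed <- 1L
dir.create("results", showWarnings = FALSE)

for (preset in c("tiny", "invitro_like", "inplanta_like")) {
  out <- file.path("scratch", "fixtures", preset)
  design <- make_fixtures(preset, seed = seed, out_dir = out)
  gt <- read.csv(file.path(out, "ground_truth.csv"))
  message(sprintf("%-14s %3d images, %4d objects (%d cells, %d debris)",
                  preset, length(unique(gt$image_id)), nrow(gt),
                  sum(gt$is_cell), sum(!gt$is_cell)))
  write.csv(design, file.path("results", paste0("design_", preset, ".csv")),
            row.names = FALSE)
}
message("fixtures written under scratch/fixtures/")
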