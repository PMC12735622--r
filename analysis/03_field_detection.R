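#!/usr/bin/env Rscript
# 1.7 mT field detection: bulk diamond (double-Lorentzian branch) versus a
# randomly oriented nanodiamond powder (spline + dip detection branch), and
# the broadening comparison between the two.

suppressPackageStartupMessages(library(nvodmr))

seed <- 20260920
dir.create("results", showWarnings = FALSE)

bulk <- run_pipeline(list(preset = "field_1p7mT_bulk", branch = "bulk",
                          convention = "bulk_tetrahedral", seed = seed))
cat(sprintf("bulk diamond:  separation %.1f MHz, per-dip shift %.1f MHz -> B = %.3f +/- %.3f mT\n",
            bulk$separation_MHz, bulk$per_dip_shift_MHz,
            bulk$field_mT, bulk$uncertainty_mT))

nd <- run_pipeline(list(preset = "field_1p7mT_nd", branch = "nd",
                        convention = "powder_edge", seed = seed))
if (nd$status == "ok") {
  cat(sprintf("nanodiamonds:  band-edge estimate B = %.3f mT (dip pair separation %.1f MHz)\n",
              nd$field_mT, nd$separation_MHz))
} else {
  cat("nanodiamonds: ", nd$message,
      "- broad orientation-averaged band, as expected for a powder\n")
}

# lineshape comparison at identical field and total NV weight
mb <- ensemble_spectrum(c(0, 0, 1.7), bulk_ensemble(), mode = "secular")
mp <- ensemble_spectrum(c(0, 0, 1.7), powder_ensemble(2000, seed = seed),
                        mode = "full")
db <- 1 - mb$relative_pl
dp <- 1 - mp$relative_pl
cmp <- data.frame(
  ensemble = c("bulk_tetrahedral", "powder"),
  max_depth = c(max(db), max(dp)),
  half_depth_width_MHz = c(sum(db >= max(db) / 2), sum(dp >= max(dp) / 2))
)
utils::write.csv(cmp, file.path("results", "lineshape_comparison.csv"),
                 row.names = FALSE)
cat(sprintf("broadening: bulk half-depth width %d MHz vs powder %d MHz; bulk dips %.1fx deeper\n",
            cmp$half_depth_width_MHz[1], cmp$half_depth_width_MHz[2],
            cmp$max_depth[1] / cmp$max_depth[2]))

est <- data.frame(
  sample = c("bulk", "nanodiamond"),
  branch = c("bulk", "nd"),
  convention = c("bulk_tetrahedral", "powder_edge"),
  field_mT = c(bulk$field_mT,
               if (nd$status == "ok") nd$field_mT else NA_real_),
  true_field_mT = 1.7
)
utils::write.csv(est, file.path("results", "field_estimates.csv"),
                 row.names = FALSE)
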