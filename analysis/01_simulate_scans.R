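#!/usr/bin/env Rscript
# Simulate the three measurement conditions (zero-field nanodiamond powder,
# powder and bulk diamond in a 1.7 mT field) as replicate CCD scans on the
# 2800-3000 MHz, 1 MHz sweep, and write them as spectra files.

suppressPackageStartupMessages(library(nvodmr))

seed <- 20260920
out <- file.path("results", "spectra")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (preset in c("zero_field_nd", "field_1p7mT_nd", "field_1p7mT_bulk")) {
  scans <- fixture_presets(preset, seed = seed)
  for (i in seq_along(scans))
    write_spectrum(scans[[i]], file.path(out, sprintf("%s_scan%d.tsv", preset, i)))
  write_spectrum(attr(scans, "dark_frame"),
                 file.path(out, sprintf("%s_dark.tsv", preset)))
  avg <- average_scans(scans)
  cat(sprintf("%-18s %d replicate scans + dark frame; averaged minimum at %g MHz\n",
              preset, length(scans),
              avg$frequencies[which.min(avg$counts)]))
}
cat("spectra written under", out, "\n")
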