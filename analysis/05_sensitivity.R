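#!/usr/bin/env Rscript
# Sweep-resolution planning: what frequency resolution is needed to resolve
# a given field at the first-order Zeeman slope, and is the current 1 MHz
# step enough?

suppressPackageStartupMessages(library(nvodmr))

targets <- data.frame(
  case = c("Helmholtz coil (applied)", "typical lab stray field",
           "neuron action potential (4 nT)"),
  field_mT = c(1.7, 0.05, 4e-6)
)
plan <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i) {
  r <- required_frequency_resolution(targets$field_mT[i])
  data.frame(case = targets$case[i], field_mT = r$target_field,
             required_resolution_MHz = r$required_resolution,
             required_resolution_Hz = r$required_resolution * 1e6,
             feasible_at_1MHz_step = r$feasible)
}))

dir.create("results", showWarnings = FALSE)
utils::write.csv(plan, file.path("results", "resolution_plan.csv"),
                 row.names = FALSE)
print(plan, row.names = FALSE)
cat("\nresolving nanotesla cellular fields needs ~100 Hz sweep resolution,\n")
cat("four orders of magnitude below the 1 MHz step used for mT-scale fields.\n")
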