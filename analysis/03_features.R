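#!/usr/bin/env Rscript
# Step 3 -- 3-month lead-time index features.
#
# For each lead time 1..6 (windows Jun-Aug back to Jan-Mar, anchored to a
# September harvest), average each index over its window to get one
# feature per index per year. Years with any missing window month would
# be dropped; the synthetic panel is complete, so all 39 years survive.

suppressPackageStartupMessages(library(frugalcast))

indices <- read_climate_indices("results/demo/data/indices.csv")
for (ld in 1:6) {
  f <- compute_lead_features(indices, ld)
  win <- lead_window(ld)
  write_lead_features(f, sprintf("results/demo/features_ld%d.csv", ld))
  message(sprintf("lead %d (%s): %d years x %d indices", ld,
                  paste(month.abb[win$months], collapse = "-"),
                  nrow(f), ncol(f) - 1))
}
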