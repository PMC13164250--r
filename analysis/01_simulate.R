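#!/usr/bin/env Rscript
# Simulate the study-scale synthetic cohort and write it as CSV fixtures.
#
# The default spec emulates the study design: 142 individuals with severe
# obesity (69 noDM / 25 PreDM / 48 T2DM), a 92-assay inflammation panel
# with 18 low-detectability assays above the 20% missingness bar, two
# plates bridged by 35 technical replicates, seven planted inflammatory
# phenotypes, planted T2DM shifts on IL8/FLT3L/CDCP1 and planted age/FPG
# slopes. Ground truth (cluster labels, offsets, slopes) is written next
# to the data so downstream steps can be scored.

library(inflamapper)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 42

spec <- cohort_spec(seed = seed)
paths <- write_fixture(spec, "results/cohort")
co <- generate_cohort(spec)

print(co)
cat(sprintf("bridge samples: %d; planted batch offset range: %.2f to %.2f NPX\n",
            spec$n_bridge, min(co$truth$batch_offsets), max(co$truth$batch_offsets)))
cat("planted group shifts (NPX, vs noDM):\n")
print(co$truth$group_shift_table, row.names = FALSE)
cat("planted covariate slopes:\n")
print(co$truth$effect_table, row.names = FALSE)
cat("fixtures written:\n"); print(unname(paths))
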