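#!/usr/bin/env Rscript
# Partition the sample set into 25 calibration and 10 validation samples by
# bootstrap-stabilized Kennard-Stone selection in PCA score space. Per-PC
# score extremes are forced into calibration, so every validation sample is
# an interpolation.
#
# Reads:  results/spectra.csv
# Writes: results/split.csv

library(nmrcal)

sm <- read_matrix_csv("results/spectra.csv")
sp <- pca_coverage_split(sm, n_val = 10L, n_boot = 200L, k_pcs = 5L, seed = 1L)
write_split(sp, "results/split.csv")

print(sp)
message("validation: ", paste(sp$validation_ids, collapse = ", "))
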