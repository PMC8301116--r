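#!/usr/bin/env Rscript
# Exploratory PCA of the simulated spectra: how much structure the first
# components carry, and the score/loading tables used for plotting.
#
# Reads:  results/spectra.csv (from 01_simulate.R)
# Writes: results/pca_scores.csv, results/pca_loadings.csv,
#         results/pca_variance.csv

library(nmrcal)

sm <- read_matrix_csv("results/spectra.csv")
k <- 5L
m <- fit_pca(sm, k)

sc <- data.frame(sample_id = sm$sample_ids, m$scores)
names(sc)[-1] <- paste0("PC", 1:k)
utils::write.csv(sc, "results/pca_scores.csv", row.names = FALSE)

ld <- data.frame(ppm = sm$grid, m$loadings)
names(ld)[-1] <- paste0("PC", 1:k)
utils::write.csv(ld, "results/pca_loadings.csv", row.names = FALSE)

ev <- data.frame(component = seq_along(m$explained_variance_pct),
                 explained_variance_pct = m$explained_variance_pct)
utils::write.csv(ev, "results/pca_variance.csv", row.names = FALSE)

message(sprintf("first five PCs explain %.1f%% of total variance",
                sum(m$explained_variance_pct[1:k])))
message("per-component %: ",
        paste(sprintf("%.1f", m$explained_variance_pct[1:k]), collapse = ", "))
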