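#!/usr/bin/env Rscript
# Step 3 — essential dynamics and free-energy landscapes.
#
# Builds the mass-unweighted Cartesian covariance per state (iterative
# superposition onto the ensemble mean), diagonalizes it, checks sampling
# convergence via the cosine content of the leading principal components,
# and bins the projections on the first two converged PCs into a
# free-energy landscape G = -kT ln(P / Pmax).
#
# Requires: analysis/01_build_systems.R
# Outputs:  analysis/results/<state>/{scree.csv,projections.csv,fel.txt}

suppressPackageStartupMessages(library(allodyn))

cfg <- pipeline_config(file.path("analysis", "data", "config.yaml"))
cfg$stages <- "pca"
cfg$output_dir <- file.path("analysis", "results")
run_pipeline(cfg)

for (st in names(cfg$states)) {
  scree <- read.csv(file.path(cfg$output_dir, st, "scree.csv"))
  cat(sprintf("%-10s PC1 %.1f%% | PC2 %.1f%% | first 20 PCs %.1f%%\n", st,
              100 * scree$fraction[1], 100 * scree$fraction[2],
              100 * scree$cumulative[20]))
}
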