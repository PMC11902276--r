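#!/usr/bin/env Rscript
# Step 5 — elastic-network modes and perturbation response scanning.
#
# Per state, builds an anisotropic network model on evenly spaced
# representative frames, forms the mode-truncated covariance over the
# slowest non-zero modes, applies the perturbation-response scan (unit
# forces at every node, isotropically averaged), and averages the
# row-normalized response maps. Effector/sensor profiles and their
# perturbed-minus-reference differences identify nodes that transmit or
# receive the mechanical signal.
#
# Requires: analysis/01_build_systems.R
# Outputs:  analysis/results/<state>/{prs_map.txt,prs_profiles.csv},
#           analysis/results/perturbed_vs_reference/delta_prs_profiles.csv

suppressPackageStartupMessages(library(allodyn))

cfg <- pipeline_config(file.path("analysis", "data", "config.yaml"))
cfg$stages <- "prs"
cfg$output_dir <- file.path("analysis", "results")
run_pipeline(cfg)

for (st in names(cfg$states)) {
  prof <- read.csv(file.path(cfg$output_dir, st, "prs_profiles.csv"))
  cat(sprintf("%-10s top effector node %d | top sensor node %d\n", st,
              prof$node[which.max(prof$effector)],
              prof$node[which.max(prof$sensor)]))
}
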