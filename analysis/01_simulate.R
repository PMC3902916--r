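#!/usr/bin/env Rscript

# Stage 1: generate the synthetic germination study.
#
# Five sigma-factor regulators drive regulons of 20 targets each through the
# sigmoid transcription model; 150 dim noisy background genes emulate the
# unregulated majority of the array. Replicated two-channel arrays (13 time
# points x 6 pooled replicate values) with multiplicative noise, gross
# outliers and per-gene channel bias are written together with all
# ground-truth tables.

library(sigmakin)

fixture_dir <- "results/fixture"
spec <- synthetic_spec()
dataset <- generate_fixture(spec, seed = 20240901)
write_fixture(dataset, fixture_dir)

cat(sprintf("fixture: %d genes (%d regulators, %d targets, %d decoys)\n",
            nrow(dataset$profiles), spec$n_regulators,
            spec$n_regulators * spec$targets_per_regulator, spec$n_decoys))
cat(sprintf("arrays: %d (%d time points x %d replicate values)\n",
            ncol(dataset$arrays$log2ratio), spec$n_time_points,
            spec$replicates_per_point))
cat(sprintf("injected outliers: %d\n", dataset$arrays$n_outliers))
cat("written to ", fixture_dir, "\n")
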