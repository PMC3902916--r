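#!/usr/bin/env Rscript

# Stage 2: per-array normalization and profile inference.
#
# Each array's Log2Ratio distribution is centered to median 0 / MAD 1, its
# 2% most extreme values per tail are masked, and values return to the
# ratio scale. Replicates are screened for outliers (Dixon Q for 3-9
# values, Peirce beyond) and averaged; interior gaps are interpolated.

library(sigmakin)

fx <- read_fixture("results/fixture")
ratios <- normalize_arrays(fx$arrays$log2ratio, trim_q = 0.02)
profiles <- average_replicates(ratios, fx$arrays$meta, fx$grid)
profiles <- fill_internal_gaps(profiles)

write_profiles(profiles, "results/profiles")
cat(sprintf("profiles: %d genes x %d time points; %d incomplete\n",
            nrow(profiles$values), ncol(profiles$values),
            sum(profiles$incomplete)))
cat(sprintf("masked ratio values: %d of %d\n",
            sum(is.na(ratios)), length(ratios)))
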