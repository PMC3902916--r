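#!/usr/bin/env Rscript

# Stage 3: gene selection.
#
# The overall expression level (median sample-channel intensity) splits the
# genes at the quartiles; category I (below Q1) is dropped unless a profile
# carries a significant peak. The low-variance gate keeps genes whose
# replicate CV stays below 0.47 at eight or more of the 13 time points.

library(sigmakin)

fx <- read_fixture("results/fixture")
profiles <- local({
  v <- read_matrix_tsv("results/profiles.tsv")
  cv <- read_matrix_tsv("results/profiles_cv.tsv")
  n <- read_matrix_tsv("results/profiles_n.tsv")
  profile_set(v, cv = cv, n_used = n, grid = fx$grid)
})

signal_by_time <- sapply(fx$grid$label, function(tl) {
  cols <- fx$arrays$meta$array_id[fx$arrays$meta$time_label == tl]
  apply(fx$arrays$sample_signal[, cols, drop = FALSE], 1, function(v)
    mean(remove_outliers(v)))
})
common <- intersect(rownames(profiles$values), rownames(signal_by_time))
summary_df <- select_highly_expressed(
  signal_by_time[common, , drop = FALSE],
  fx$arrays$sample_signal[common, , drop = FALSE])
low_cv <- select_low_cv(profiles)

write.table(summary_df, "results/expression_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(summary_df$gene_id[summary_df$highly_expressed],
           "results/highly_expressed.txt")
writeLines(low_cv, "results/low_cv.txt")

cat(sprintf("quartiles: %s\n",
            paste(round(attr(summary_df, "thresholds")), collapse = " / ")))
cat(sprintf("highly expressed: %d of %d (%d rescued by peak)\n",
            sum(summary_df$highly_expressed), nrow(summary_df),
            sum(summary_df$rescued_by_peak)))
cat(sprintf("low-CV set: %d genes\n", length(low_cv)))
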