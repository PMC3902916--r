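#!/usr/bin/env Rscript

# Stage 6: functional-class enrichment of the kinetic clusters and linkage
# of sigma factors to enriched classes through their accepted cluster edges.
#
# One-sided Fisher exact tests compare each class's frequency inside a
# cluster (core members plus assigned genes) with the highly expressed
# universe; a class is significant at P < 0.05, fold change > 2 and more
# than 7 member genes in the cluster.

library(sigmakin)

fx <- read_fixture("results/fixture")
membership <- read.delim("results/cluster_membership.tsv")
summary_df <- read.delim("results/expression_summary.tsv")
universe <- summary_df$gene_id[summary_df$highly_expressed]

enrichment <- do.call(rbind, lapply(split(membership, membership$core_id),
  function(mm) {
    members <- intersect(unique(mm$gene_id), universe)
    res <- fisher_enrichment(members, fx$annotation, universe)
    if (is.null(res)) return(NULL)
    cbind(cluster_id = mm$core_id[1], res)
  }))
sig <- significant_classes(enrichment)
write.table(enrichment, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sig, "results/enrichment_significant.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("enrichment records: %d; significant: %d\n",
            nrow(enrichment), nrow(sig)))

edges_clusters <- read.delim("results/edges_clusters.tsv")
links <- link_sigma_functions(edges_clusters, sig)
write.table(links, "results/sigma_function_links.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("sigma-function associations: %d\n", nrow(links)))
if (nrow(links))
  print(links, row.names = FALSE)

# planted-truth comparison
planted <- fx$planted_enrichment
hits <- 0
for (i in seq_len(nrow(planted))) {
  grp_genes <- names(fx$cluster_labels)[
    !is.na(fx$cluster_labels) & fx$cluster_labels == planted$cluster_id[i]]
  overlap <- vapply(split(membership$gene_id, membership$core_id),
                    function(g) length(intersect(g, grp_genes)), integer(1))
  cl <- names(which.max(overlap))
  if (any(sig$cluster_id == cl & sig$class == planted$class[i]))
    hits <- hits + 1
}
cat(sprintf("planted enrichments recovered: %d of %d\n", hits,
            nrow(planted)))
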