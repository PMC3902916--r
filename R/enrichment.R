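#' Functional-class enrichment of a gene cluster
#'
#' One-sided (over-representation) Fisher exact test of each functional
#' class against the gene universe: for a cluster of size m containing k
#' genes of a class with K members among N universe genes, the test is on
#' the 2x2 table `[[k, m-k], [K-k, N-m-(K-k)]]`. Genes without annotation
#' form an implicit `"unclassified"` class. The fold change is
#' `(k/m) / (K/N)`.
#'
#' @param cluster_members Character vector of gene ids (subset of the
#'   universe).
#' @param annotation Data frame with columns `gene_id`, `class`; repeated
#'   rows allow multi-class genes.
#' @param universe Character vector of all gene ids under consideration.
#' @param p_max,fc_min,k_min_exclusive Significance rule: a class is
#'   significant when `p < p_max`, `fold_change > fc_min` and
#'   `k > k_min_exclusive` (defaults 0.05, 2, 7).
#' @return Data frame, one row per class in the universe: `cluster_size`,
#'   `k`, `K`, `N`, `p_value`, `p_adjust` (Benjamini-Hochberg,
#'   supplementary), `fold_change`, `significant`.
#' @export
fisher_enrichment <- function(cluster_members, annotation, universe,
                              p_max = 0.05, fc_min = 2,
                              k_min_exclusive = 7) {
  if (!all(cluster_members %in% universe))
    stop("cluster members must be a subset of the universe")
  if (!length(cluster_members)) return(NULL)
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  unannotated <- setdiff(universe, ann$gene_id)
  if (length(unannotated))
    ann <- rbind(ann[, c("gene_id", "class")],
                 data.frame(gene_id = unannotated, class = "unclassified",
                            stringsAsFactors = FALSE))
  ann <- unique(ann[, c("gene_id", "class")])
  N <- length(universe)
  m <- length(unique(cluster_members))
  classes <- sort(unique(ann$class))
  res <- lapply(classes, function(cl) {
    class_genes <- ann$gene_id[ann$class == cl]
    K <- length(class_genes)
    k <- sum(cluster_members %in% class_genes)
    tab <- matrix(c(k, m - k, K - k, N - m - (K - k)), 2, 2)
    p <- fisher.test(tab, alternative = "greater")$p.value
    fc <- if (K > 0) (k / m) / (K / N) else 0
    data.frame(class = cl, cluster_size = m, k = k, K = K, N = N,
               p_value = p, fold_change = fc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjust <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < p_max & out$fold_change > fc_min &
    out$k > k_min_exclusive
  out
}

#' Filter enrichment results to the significant classes
#'
#' Keeps records with `p < p_max`, `fold_change > fc_min` and
#' `k > k_min_exclusive` (all strict).
#'
#' @param results Data frame from [fisher_enrichment()] (possibly several
#'   clusters row-bound with a `cluster_id` column).
#' @inheritParams fisher_enrichment
#' @return The filtered data frame.
#' @export
significant_classes <- function(results, p_max = 0.05, fc_min = 2,
                                k_min_exclusive = 7) {
  results[results$p_value < p_max & results$fold_change > fc_min &
            results$k > k_min_exclusive, , drop = FALSE]
}

#' Link sigma factors to enriched functional classes
#'
#' A sigma factor is associated with a functional class when it has an
#' accepted kinetic edge to a cluster in which the class is significantly
#' enriched; the mediating cluster is recorded and alternative regulators
#' of one class are all kept.
#'
#' @param edges Accepted sigma-to-cluster edge data frame (columns
#'   `regulator_id`, `target_id`).
#' @param enriched Significant enrichment records carrying a `cluster_id`
#'   column matching the edges' `target_id`.
#' @return Data frame with `sigma_id`, `class`, `cluster_id`.
#' @export
link_sigma_functions <- function(edges, enriched) {
  if (!nrow(edges) || is.null(enriched) || !nrow(enriched))
    return(data.frame(sigma_id = character(), class = character(),
                      cluster_id = character(), stringsAsFactors = FALSE))
  if ("accepted" %in% names(edges))
    edges <- edges[edges$accepted, , drop = FALSE]
  out <- merge(edges[, c("regulator_id", "target_id")],
               enriched[, c("cluster_id", "class")],
               by.x = "target_id", by.y = "cluster_id")
  res <- data.frame(sigma_id = out$regulator_id, class = out$class,
                    cluster_id = out$target_id, stringsAsFactors = FALSE)
  unique(res[order(res$sigma_id, res$class, res$cluster_id), ])
}
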