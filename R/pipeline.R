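#' Run the full inference pipeline on one data set
#'
#' Normalization, profile inference, expression and CV filters, consensus
#' kinetic clustering, sigma-factor screening against cluster cores (and
#' optionally against individual genes), and functional enrichment, in the
#' order the stages feed each other. Intended for synthetic fixtures and
#' real expression tables alike; every stage is also callable on its own.
#'
#' @param arrays List with `log2ratio`, `sample_signal` (genes x arrays) and
#'   `meta` (array_id, time_label, replicate), e.g. the `arrays` field of a
#'   [generate_fixture()] data set or matrices read with
#'   [read_matrix_tsv()].
#' @param sigma_ids Character vector of sigma-factor gene ids.
#' @param annotation Optional gene/class annotation data frame.
#' @param priors Optional prior-interaction table.
#' @param grid A [time_grid()].
#' @param trim_q Per-tail quantile trim during normalization.
#' @param cv_max,min_points CV-filter thresholds.
#' @param n_clusters Cluster count; when NULL a jackknife scan over
#'   `scan_range` picks the elbow.
#' @param scan_range Candidate cluster counts for the scan.
#' @param default_n Fallback when the scan shows no elbow.
#' @param cluster_runs Repeated k-means runs for the consensus.
#' @param assign_r_min Correlation gate for post-hoc cluster assignment.
#' @param fit_cfg Annealing configuration for the screens.
#' @param r_accept,r_accept_prior,r_trivial Edge acceptance and trivial
#'   thresholds.
#' @param screen_genes Also screen sigma factors against individual gene
#'   profiles (needed for gene-level edge recovery).
#' @param seed Integer seed covering every stochastic stage.
#' @return List with `profiles` (filled `profile_set`), `expression_summary`,
#'   `low_cv_ids`, `clustered_ids`, `scan`, `n_clusters`, `cores`,
#'   `edges_clusters`, `edges_genes`, `edges_sigma`, `enrichment`,
#'   `significant`, `sigma_links`.
#' @export
run_pipeline <- function(arrays, sigma_ids, annotation = NULL, priors = NULL,
                         grid = time_grid(), trim_q = 0.02, cv_max = 0.47,
                         min_points = 8, n_clusters = NULL,
                         scan_range = 2:10, default_n = 42,
                         cluster_runs = 100, assign_r_min = 0.8,
                         fit_cfg = screening_config(), r_accept = 0.8,
                         r_accept_prior = 0.65, r_trivial = 0.9,
                         screen_genes = TRUE, seed = 1) {
  set.seed(seed)

  ratios <- normalize_arrays(arrays$log2ratio, trim_q)
  profiles <- average_replicates(ratios, arrays$meta, grid)
  profiles <- fill_internal_gaps(profiles)

  signal_by_time <- .signal_by_time(arrays$sample_signal, arrays$meta, grid)
  common <- intersect(rownames(profiles$values), rownames(signal_by_time))
  summary_df <- select_highly_expressed(
    signal_by_time[common, , drop = FALSE],
    arrays$sample_signal[common, , drop = FALSE])
  highly <- summary_df$gene_id[summary_df$highly_expressed]

  low_cv <- select_low_cv(profiles, cv_max, min_points)
  complete <- rownames(profiles$values)[!profiles$incomplete]
  nonconst <- rownames(profiles$values)[
    apply(profiles$values, 1, function(v) length(unique(v[!is.na(v)])) > 1)]
  clusterable <- Reduce(intersect, list(highly, low_cv, complete, nonconst))
  values <- profiles$values[clusterable, , drop = FALSE]

  scan <- NULL
  if (is.null(n_clusters)) {
    cfg0 <- clustering_config(n_clusters = max(2, min(scan_range)),
                              n_range = scan_range,
                              scan_runs = 15, scan_n_init = 8)
    scan <- jackknife_scan(values, cfg0)
    n_clusters <- select_n(scan, default_n = default_n)
  }
  cfg <- clustering_config(n_clusters = n_clusters, n_runs = cluster_runs,
                           assign_r_min = assign_r_min)
  clust <- cluster_profiles(values, cfg, assign = FALSE)
  assignable <- intersect(intersect(highly, complete), nonconst)
  clust$cores <- assign_to_cores(
    profiles$values[assignable, , drop = FALSE], clust$cores, assign_r_min)
  cores <- clust$cores

  sigma_use <- intersect(sigma_ids, intersect(complete, nonconst))
  sigma_profiles <- profiles$values[sigma_use, , drop = FALSE]
  core_profiles <- do.call(rbind, lapply(cores, `[[`, "core_profile"))
  rownames(core_profiles) <- sprintf("CL%d", vapply(cores, `[[`,
                                                    integer(1), "core_id"))

  edges_clusters <- screen_regulations(sigma_profiles, core_profiles, grid,
                                       priors = NULL, config = fit_cfg,
                                       r_accept, r_accept_prior, r_trivial,
                                       target_kind = "cluster")
  edges_sigma <- if (length(sigma_use) >= 2)
    sigma_sigma_network(sigma_profiles, grid, priors, fit_cfg, r_accept,
                        r_accept_prior, r_trivial)
  else .empty_edges()
  edges_genes <- NULL
  if (screen_genes) {
    gene_targets <- setdiff(clusterable, sigma_use)
    edges_genes <- screen_regulations(
      sigma_profiles, profiles$values[gene_targets, , drop = FALSE], grid,
      priors, fit_cfg, r_accept, r_accept_prior, r_trivial,
      target_kind = "gene")
  }

  enrichment <- significant <- sigma_links <- NULL
  if (!is.null(annotation)) {
    universe <- highly
    enrichment <- do.call(rbind, lapply(cores, function(core) {
      members <- union(core$member_gene_ids, core$assigned$gene_id)
      members <- intersect(members, universe)
      res <- fisher_enrichment(members, annotation, universe)
      if (is.null(res)) return(NULL)
      cbind(cluster_id = sprintf("CL%d", core$core_id), res,
            stringsAsFactors = FALSE)
    }))
    if (!is.null(enrichment)) {
      significant <- significant_classes(enrichment)
      sigma_links <- link_sigma_functions(edges_clusters, significant)
    }
  }

  list(profiles = profiles, expression_summary = summary_df,
       low_cv_ids = low_cv, clustered_ids = clusterable, scan = scan,
       n_clusters = n_clusters, cores = cores, run_J = clust$run_J,
       edges_clusters = edges_clusters, edges_genes = edges_genes,
       edges_sigma = edges_sigma, enrichment = enrichment,
       significant = significant, sigma_links = sigma_links)
}

# Per-gene, per-time-point mean sample-channel intensity (peak detection).
# Replicates pass the same outlier rejection as expression profiles, so a
# single gross outlier cannot manufacture a rescue peak.
.signal_by_time <- function(sample_signal, meta, grid) {
  out <- matrix(NA_real_, nrow(sample_signal), nrow(grid),
                dimnames = list(rownames(sample_signal), grid$label))
  for (k in seq_len(nrow(grid))) {
    cols <- intersect(meta$array_id[meta$time_label == grid$label[k]],
                      colnames(sample_signal))
    if (length(cols))
      out[, k] <- apply(sample_signal[, cols, drop = FALSE], 1, function(v) {
        kept <- remove_outliers(v)
        if (length(kept)) mean(kept) else NA_real_
      })
  }
  out
}

#' Recall and precision of screened edges against a ground truth
#'
#' @param edges Edge data frame (accepted rows are evaluated).
#' @param truth Data frame with `regulator_id`, `target_id` of true edges.
#' @param candidate_targets Optional restriction of the evaluated universe
#'   (e.g. only genes that survived filtering).
#' @return List with `recall`, `precision`, `n_true`, `n_accepted`,
#'   `n_correct`.
#' @export
edge_recovery <- function(edges, truth, candidate_targets = NULL) {
  if ("accepted" %in% names(edges))
    edges <- edges[edges$accepted, , drop = FALSE]
  if (!is.null(candidate_targets))
    truth <- truth[truth$target_id %in% candidate_targets, , drop = FALSE]
  true_key <- paste(truth$regulator_id, truth$target_id)
  got_key <- paste(edges$regulator_id, edges$target_id)
  n_correct <- sum(got_key %in% true_key)
  list(recall = if (length(true_key)) n_correct / length(true_key) else NA,
       precision = if (length(got_key)) n_correct / length(got_key) else NA,
       n_true = length(true_key), n_accepted = length(got_key),
       n_correct = n_correct)
}
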