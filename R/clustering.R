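#' Clustering configuration
#'
#' Defaults follow the study design: 500 repeated k-means runs, 50% core
#' consensus, 1.5% jackknife omission, cluster-count scan over 30-70, and
#' post-hoc assignment of genes to cores at correlation >= 0.8.
#'
#' @param n_clusters Number of clusters (study value 42).
#' @param n_runs Repeated k-means runs entering the consensus.
#' @param core_fraction Fraction of runs a gene must co-occur in a matched
#'   cluster to be a core member.
#' @param jackknife_fraction Fraction of profiles omitted per jackknife
#'   repeat.
#' @param n_range Candidate cluster counts for the jackknife scan.
#' @param assign_r_min Minimal correlation for post-hoc core assignment.
#' @param scan_runs Jackknife repeats per candidate n.
#' @param scan_n_init Random initializations per scan repeat (best J kept),
#'   so the J curve approximates the optimal J(n) rather than local-minimum
#'   noise.
#' @param max_iter Lloyd iteration cap per run.
#' @return A list of class `clustering_config`.
#' @export
clustering_config <- function(n_clusters = 42, n_runs = 500,
                              core_fraction = 0.5, jackknife_fraction = 0.015,
                              n_range = 30:70, assign_r_min = 0.8,
                              scan_runs = 30, scan_n_init = 5,
                              max_iter = 100) {
  stopifnot(n_clusters >= 2, core_fraction > 0, core_fraction <= 1,
            assign_r_min > -1, assign_r_min <= 1)
  structure(list(n_clusters = n_clusters, n_runs = n_runs,
                 core_fraction = core_fraction,
                 jackknife_fraction = jackknife_fraction, n_range = n_range,
                 assign_r_min = assign_r_min, scan_runs = scan_runs,
                 scan_n_init = scan_n_init, max_iter = max_iter),
            class = "clustering_config")
}

#' Spearman correlation distance between two profiles
#'
#' `1 - rho` with average ranks for ties; 0 for identical rank orders, 2 for
#' exactly opposite ones. Rank-invariant under monotone transforms.
#'
#' @param p,q Numeric vectors of equal length >= 3, each with more than one
#'   distinct value.
#' @return Distance in `[0, 2]`.
#' @export
spearman_distance <- function(p, q) {
  stopifnot(length(p) == length(q), length(p) >= 3)
  if (length(unique(p)) < 2 || length(unique(q)) < 2)
    stop("spearman_distance: undefined for constant profiles")
  1 - cor(p, q, method = "spearman")
}

# genes x time -> row-standardized rank matrix so that
# Zp %*% Zq / (m - 1) is the Spearman correlation.
.rank_z <- function(values) {
  r <- t(apply(values, 1, rank))
  s <- apply(r, 1, sd)
  if (any(s == 0)) stop("constant profile(s): Spearman distance undefined")
  (r - rowMeans(r)) / s
}

#' k-means clustering of profiles under Spearman distance
#'
#' Lloyd-style iteration: each profile joins the centroid with the smallest
#' Spearman distance; centroids are updated as the per-time-point mean of
#' their members. A cluster emptied during iteration is re-seeded with the
#' profile farthest from its current centroid. Deterministic given the RNG
#' state (set `seed`).
#'
#' @param values Numeric matrix, genes x time points, no missing values, no
#'   constant rows.
#' @param n Number of clusters, `2 <= n <= nrow(values)`.
#' @param seed Optional integer seed; when NULL the current RNG state is
#'   used.
#' @param max_iter Iteration cap.
#' @param n_init Random initializations; the run with the lowest J is
#'   returned. Consensus ensembles use 1 (initialization diversity is the
#'   point there); J-curve scans use several to approximate the optimal
#'   J(n).
#' @return A `cluster_run`: list with `assignment` (named integer vector),
#'   `centroids` (n x time matrix) and `J` (within-cluster sum of
#'   point-to-centroid Spearman distances).
#' @export
kmeans_spearman <- function(values, n, seed = NULL, max_iter = 100,
                            n_init = 1) {
  stopifnot(is.matrix(values), n >= 1, n <= nrow(values))
  if (!is.null(seed)) set.seed(seed)
  if (n_init > 1) {
    runs <- lapply(seq_len(n_init), function(i)
      kmeans_spearman(values, n, seed = NULL, max_iter = max_iter))
    return(runs[[which.min(vapply(runs, `[[`, numeric(1), "J"))]])
  }
  z <- .rank_z(values)
  m <- ncol(values)
  centroid_idx <- sample.int(nrow(values), n)
  centroids <- values[centroid_idx, , drop = FALSE]
  assignment <- rep(0L, nrow(values))
  for (iter in seq_len(max_iter)) {
    cz <- .rank_z(centroids)
    d <- 1 - tcrossprod(z, cz) / (m - 1)   # genes x clusters
    new_assign <- max.col(-d, ties.method = "first")
    # re-seed empty clusters with the farthest profile whose donor cluster
    # keeps at least one member (otherwise reseeding can cycle forever)
    repeat {
      empty <- setdiff(seq_len(n), unique(new_assign))
      if (!length(empty)) break
      counts <- tabulate(new_assign, n)
      cur_d <- d[cbind(seq_len(nrow(d)), new_assign)]
      cur_d[counts[new_assign] < 2] <- -Inf
      far <- which.max(cur_d)
      new_assign[far] <- empty[1]
    }
    for (k in seq_len(n))
      centroids[k, ] <- colMeans(values[new_assign == k, , drop = FALSE])
    if (all(new_assign == assignment)) break
    assignment <- new_assign
  }
  cz <- .rank_z(centroids)
  d <- 1 - tcrossprod(z, cz) / (m - 1)
  J <- sum(d[cbind(seq_len(nrow(d)), assignment)])
  structure(list(assignment = setNames(assignment, rownames(values)),
                 centroids = centroids, J = J),
            class = "cluster_run")
}

#' Within-cluster sum of point-to-centroid Spearman distances
#'
#' @param run A `cluster_run`.
#' @param values The profile matrix the run was computed on.
#' @return The scalar J.
#' @export
within_cluster_J <- function(run, values) {
  z <- .rank_z(values)
  cz <- .rank_z(run$centroids)
  d <- 1 - tcrossprod(z, cz) / (ncol(values) - 1)
  sum(d[cbind(seq_len(nrow(d)), run$assignment)])
}

# Greedy maximal-overlap matching of one run's clusters onto the reference
# partition; returns map[run cluster] -> reference cluster.
.match_clusters <- function(ref_assign, run_assign, n) {
  tab <- table(factor(ref_assign, levels = seq_len(n)),
               factor(run_assign, levels = seq_len(n)))
  map <- integer(n)
  for (step in seq_len(n)) {
    idx <- arrayInd(which.max(tab), dim(tab))
    map[idx[2]] <- idx[1]
    tab[idx[1], ] <- -1
    tab[, idx[2]] <- -1
  }
  map
}

#' Consensus cores from repeated clustering runs
#'
#' The run with the median J serves as the reference partition; every other
#' run's clusters are matched to it by greedy maximal member overlap. A gene
#' is a core member of a cluster when it lands in that (matched) cluster in
#' at least `core_fraction` of the runs. The core profile is the
#' per-time-point mean of its members.
#'
#' @param runs List of `cluster_run` objects over the same genes and the
#'   same number of clusters.
#' @param values Profile matrix the runs were computed on.
#' @param core_fraction Consensus threshold; default 0.5.
#' @return List of `cluster_core` objects: `core_id`, `member_gene_ids`,
#'   `core_profile`, and empty `assigned` slot.
#' @export
consensus_cores <- function(runs, values, core_fraction = 0.5) {
  stopifnot(length(runs) >= 2)
  n <- nrow(runs[[1]]$centroids)
  Js <- vapply(runs, `[[`, numeric(1), "J")
  ref <- runs[[order(Js)[ceiling(length(Js) / 2)]]]
  ng <- length(ref$assignment)
  counts <- matrix(0L, ng, n)
  for (run in runs) {
    map <- .match_clusters(ref$assignment, run$assignment, n)
    mapped <- map[run$assignment]
    counts[cbind(seq_len(ng), mapped)] <- counts[cbind(seq_len(ng), mapped)] + 1L
  }
  frac <- counts / length(runs)
  best <- max.col(frac, ties.method = "first")   # ties toward lower core id
  best_frac <- frac[cbind(seq_len(ng), best)]
  genes <- names(ref$assignment)
  cores <- list()
  cid <- 0L
  for (k in seq_len(n)) {
    members <- genes[best == k & best_frac >= core_fraction]
    if (!length(members)) next
    cid <- cid + 1L
    cores[[cid]] <- structure(
      list(core_id = cid,
           member_gene_ids = members,
           core_profile = colMeans(values[members, , drop = FALSE]),
           assigned = NULL),
      class = "cluster_core")
  }
  cores
}

#' Jackknife scan of cluster counts
#'
#' For each candidate number of clusters, the clustering is repeated with a
#' small random fraction of profiles omitted; the within-cluster distance
#' sum J of each repeat is recorded and summarized as mean and sd.
#'
#' @param values Profile matrix, genes x time points.
#' @param config A [clustering_config()]; `n_range`, `jackknife_fraction`
#'   and `scan_runs` are used.
#' @return Data frame with columns `n`, `J_mean`, `J_sd`.
#' @export
jackknife_scan <- function(values, config = clustering_config()) {
  ng <- nrow(values)
  n_omit <- floor(config$jackknife_fraction * ng)
  out <- lapply(config$n_range, function(n) {
    Js <- vapply(seq_len(config$scan_runs), function(r) {
      keep <- if (n_omit > 0) sort(sample.int(ng, ng - n_omit)) else seq_len(ng)
      kmeans_spearman(values[keep, , drop = FALSE], n,
                      max_iter = config$max_iter,
                      n_init = config$scan_n_init)$J
    }, numeric(1))
    data.frame(n = n, J_mean = mean(Js), J_sd = sd(Js))
  })
  do.call(rbind, out)
}

#' Select the cluster count at the elbow of a J curve
#'
#' The elbow is the candidate n with the largest discrete second difference
#' of J(n) (the sharpest local flattening). If no second difference exceeds
#' `rel_floor` times the total range of J, the curve carries no elbow and
#' the default is returned with a warning.
#'
#' @param J_curve Data frame from [jackknife_scan()] (columns `n`,
#'   `J_mean`), or any data frame with those columns; needs >= 4 points.
#' @param default_n Fallback cluster count (study value 42).
#' @param rel_floor Minimum second difference relative to the J range.
#' @return The selected n.
#' @export
select_n <- function(J_curve, default_n = 42, rel_floor = 0.05) {
  stopifnot(nrow(J_curve) >= 4)
  J <- J_curve$J_mean
  n <- J_curve$n
  d2 <- J[seq_len(length(J) - 2)] - 2 * J[seq(2, length(J) - 1)] +
    J[seq(3, length(J))]
  floor_abs <- rel_floor * (max(J) - min(J))
  if (max(J) == min(J) || max(d2) < floor_abs) {
    warning("no clear elbow in J curve; returning default n = ", default_n)
    return(default_n)
  }
  n[which.max(d2) + 1]
}

#' Assign all genes to consensus cores by profile correlation
#'
#' Each gene joins the core whose profile it correlates with most strongly,
#' provided that maximum reaches `assign_r_min`; ties break toward the lower
#' core id. The correlation is stored as a membership strength. Constant
#' profiles cannot be assigned.
#'
#' @param values Profile matrix (genes x time points), complete rows.
#' @param cores List of `cluster_core` objects.
#' @param assign_r_min Correlation threshold (inclusive); default 0.8.
#' @param method `"pearson"` (default, matching the model-fit criterion) or
#'   `"spearman"`.
#' @return The cores, each with `assigned`: data.frame of `gene_id` and
#'   `correlation`.
#' @export
assign_to_cores <- function(values, cores, assign_r_min = 0.8,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  core_mat <- do.call(rbind, lapply(cores, `[[`, "core_profile"))
  constant <- apply(values, 1, function(v) length(unique(v)) < 2)
  if (any(constant))
    warning(sum(constant), " constant profile(s) left unassigned")
  cc <- matrix(NA_real_, nrow(values), length(cores))
  ok <- !constant
  cc[ok, ] <- cor(t(values[ok, , drop = FALSE]), t(core_mat), method = method)
  best <- max.col(replace(cc, is.na(cc), -2), ties.method = "first")
  best_r <- cc[cbind(seq_len(nrow(values)), best)]
  take <- !is.na(best_r) & best_r >= assign_r_min
  for (k in seq_along(cores)) {
    sel <- take & best == k
    cores[[k]]$assigned <- data.frame(
      gene_id = rownames(values)[sel],
      correlation = unname(best_r[sel]),
      stringsAsFactors = FALSE)
  }
  cores
}

#' Run the full consensus-clustering stage
#'
#' Repeated seeded k-means runs, consensus core extraction and optional
#' post-hoc assignment in one call.
#'
#' @param values Profile matrix, genes x time points.
#' @param config A [clustering_config()].
#' @param assign Assign all profiles back to the cores when TRUE.
#' @return List with `cores`, `runs` (J values only) and the `config`.
#' @export
cluster_profiles <- function(values, config = clustering_config(),
                             assign = TRUE) {
  runs <- lapply(seq_len(config$n_runs), function(r)
    kmeans_spearman(values, config$n_clusters, max_iter = config$max_iter))
  cores <- consensus_cores(runs, values, config$core_fraction)
  if (assign)
    cores <- assign_to_cores(values, cores, config$assign_r_min)
  list(cores = cores, run_J = vapply(runs, `[[`, numeric(1), "J"),
       config = config)
}
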