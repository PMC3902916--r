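test_that("Spearman distance has the expected geometry", {
  p <- c(1, 3, 2, 5, 4, 6, 7)
  expect_equal(spearman_distance(p, p), 0)
  expect_equal(spearman_distance(p, exp(p)), 0)      # monotone transform
  expect_equal(spearman_distance(p, -p), 2)          # reversed ranks
  expect_error(spearman_distance(rep(1, 7), p), "constant")
})

test_that("k-means with Spearman distance separates planted shape groups", {
  set.seed(61)
  rising <- t(replicate(5, sort(runif(13, 1, 5))))
  falling <- t(replicate(5, sort(runif(13, 1, 5), decreasing = TRUE)))
  values <- rbind(rising, falling)
  rownames(values) <- paste0("g", 1:10)
  run <- kmeans_spearman(values, 2, seed = 3)
  expect_equal(length(unique(run$assignment[1:5])), 1)
  expect_equal(length(unique(run$assignment[6:10])), 1)
  expect_false(run$assignment[1] == run$assignment[6])
  # determinism
  run2 <- kmeans_spearman(values, 2, seed = 3)
  expect_identical(run$assignment, run2$assignment)
  # singleton clusters give J = 0
  run3 <- kmeans_spearman(values, 10, seed = 4)
  expect_equal(run3$J, 0, tolerance = 1e-12)
})

test_that("within-cluster J is the sum of member-to-centroid distances", {
  set.seed(62)
  values <- matrix(runif(6 * 13, 1, 4), 6,
                   dimnames = list(paste0("g", 1:6), NULL))
  run <- kmeans_spearman(values, 2, seed = 5)
  expect_equal(within_cluster_J(run, values), run$J, tolerance = 1e-10)
  manual <- sum(vapply(seq_len(6), function(i)
    spearman_distance(values[i, ], run$centroids[run$assignment[i], ]),
    numeric(1)))
  expect_equal(run$J, manual, tolerance = 1e-10)
})

test_that("consensus cores honor the co-occurrence threshold", {
  # hand-built runs over 4 genes, 2 clusters: g1,g2 always together;
  # g3 joins them 6/10 times; g4 only 4/10 times
  mk_run <- function(a) structure(list(
    assignment = setNames(a, paste0("g", 1:4)),
    centroids = matrix(rep(c(1, 2), each = 13), 2, 13, byrow = TRUE),
    J = 1), class = "cluster_run")
  runs <- c(lapply(1:6, function(i) mk_run(c(1, 1, 1, 2))),
            lapply(1:4, function(i) mk_run(c(1, 1, 2, 1))))
  values <- matrix(seq_len(4 * 13), 4, dimnames = list(paste0("g", 1:4),
                                                       NULL))
  cores <- consensus_cores(runs, values, core_fraction = 0.5)
  members <- lapply(cores, `[[`, "member_gene_ids")
  core_of <- function(g) which(vapply(members, function(m) g %in% m,
                                      logical(1)))
  expect_equal(core_of("g1"), core_of("g2"))
  expect_equal(core_of("g3"), core_of("g1"))   # 6/10 >= 0.5
  expect_false(any(core_of("g4") %in% core_of("g1")))  # 4/10 of the time
  # permutation invariance in run order and in cluster labels within runs
  relabel <- function(run) {
    run$assignment <- setNames(3L - run$assignment, names(run$assignment))
    run$centroids <- run$centroids[2:1, ]
    run
  }
  runs2 <- rev(lapply(runs, relabel))
  cores2 <- consensus_cores(runs2, values, core_fraction = 0.5)
  expect_setequal(unlist(lapply(cores2, `[[`, "member_gene_ids")),
                  unlist(members))
  # raising core_fraction shrinks membership monotonically
  cores_strict <- consensus_cores(runs, values, core_fraction = 0.7)
  expect_true(all(unlist(lapply(cores_strict, `[[`, "member_gene_ids")) %in%
                    unlist(members)))
})

test_that("consensus recovers planted groups and cores are self-consistent", {
  set.seed(63)
  fx <- make_cluster_fixture(n_groups = 4, genes_per_group = 15)
  runs <- lapply(1:50, function(i) kmeans_spearman(fx$values, 4))
  cores <- consensus_cores(runs, fx$values, 0.5)
  pred <- integer(0)
  for (co in cores)
    pred <- c(pred, setNames(rep(co$core_id, length(co$member_gene_ids)),
                             co$member_gene_ids))
  tab <- table(pred, fx$labels[names(pred)])
  # every recovered core is dominated by one planted group
  expect_true(all(apply(tab, 1, max) / rowSums(tab) > 0.95))
  # every core member correlates positively with its own core profile
  cores <- assign_to_cores(fx$values, cores, assign_r_min = 0)
  for (co in cores) {
    r <- cor(t(fx$values[co$member_gene_ids, , drop = FALSE]),
             co$core_profile)
    expect_true(all(r > 0))
  }
})

test_that("the J elbow picks the sharpest local flattening", {
  curve <- data.frame(n = 2:5, J_mean = c(10, 6, 5.8, 5.7))
  expect_equal(select_n(curve), 3)
  lin <- data.frame(n = 2:8, J_mean = seq(10, 4, by = -1))
  expect_warning(n_star <- select_n(lin, default_n = 42), "elbow")
  expect_equal(n_star, 42)
  drop <- data.frame(n = 2:8, J_mean = c(30, 29, 28, 9, 8.5, 8.2, 8))
  expect_equal(select_n(drop), 5)
})

test_that("jackknife scan covers the requested range", {
  set.seed(64)
  fx <- make_cluster_fixture(n_groups = 3, genes_per_group = 12)
  cfg <- clustering_config(n_clusters = 2, n_range = 2:5, scan_runs = 5,
                           scan_n_init = 2)
  scan <- jackknife_scan(fx$values, cfg)
  expect_equal(scan$n, 2:5)
  expect_true(all(is.finite(scan$J_mean)))
  expect_true(all(diff(scan$J_mean) <= 1e-9))  # J decreases with n here
})

test_that("post-hoc assignment respects the correlation gate and ties", {
  grid <- time_grid()
  core_a <- sin(seq(0, pi, length.out = 13)) + 1.5
  core_b <- seq(1, 4, length.out = 13)
  cores <- list(structure(list(core_id = 1L, member_gene_ids = "m1",
                               core_profile = core_a, assigned = NULL),
                          class = "cluster_core"),
                structure(list(core_id = 2L, member_gene_ids = "m2",
                               core_profile = core_b, assigned = NULL),
                          class = "cluster_core"))
  set.seed(65)
  values <- rbind(exact = core_b,
                  close_a = core_a + rnorm(13, 0, 0.05),
                  neither = abs(rnorm(13, 2, 1)) + 8 * cos(seq(0, 20,
                                                   length.out = 13)))
  out <- assign_to_cores(values, cores, assign_r_min = 0.8)
  expect_true("exact" %in% out[[2]]$assigned$gene_id)
  expect_equal(out[[2]]$assigned$correlation[
    out[[2]]$assigned$gene_id == "exact"], 1)
  expect_true("close_a" %in% out[[1]]$assigned$gene_id)
  assigned_all <- c(out[[1]]$assigned$gene_id, out[[2]]$assigned$gene_id)
  expect_false("neither" %in% assigned_all)
})
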