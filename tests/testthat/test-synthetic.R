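test_that("fixture generation is fully deterministic under a seed", {
  spec <- synthetic_spec(n_regulators = 3, targets_per_regulator = 5,
                         n_decoys = 10)
  d1 <- generate_fixture(spec, seed = 9)
  d2 <- generate_fixture(spec, seed = 9)
  expect_identical(d1$profiles, d2$profiles)
  expect_identical(d1$arrays$log2ratio, d2$arrays$log2ratio)
  expect_identical(d1$annotation, d2$annotation)
  expect_identical(d1$priors, d2$priors)
  d3 <- generate_fixture(spec, seed = 10)
  expect_false(identical(d1$arrays$log2ratio, d3$arrays$log2ratio))
})

test_that("regulator profiles are positive, distinct and well shaped", {
  set.seed(91)
  spec <- synthetic_spec(n_regulators = 5)
  reg <- make_regulator_profiles(spec)
  expect_equal(dim(reg), c(5, 13))
  expect_true(all(reg > 0))
  rho <- abs(cor(t(reg), method = "spearman"))
  expect_lt(max(rho[upper.tri(rho)]), 0.7)
  # dynamics floor: a measured regulator must be signal-dominated
  expect_true(all(apply(reg, 1, max) >= 4 * apply(reg, 1, min)))
  set.seed(91)
  reg2 <- make_regulator_profiles(spec)
  expect_identical(reg, reg2)
})

test_that("targets carry consistent ground truth and refit cleanly", {
  set.seed(92)
  spec <- synthetic_spec(n_regulators = 2, targets_per_regulator = 4,
                         n_decoys = 3)
  reg <- make_regulator_profiles(spec)
  tg <- make_targets(spec, reg)
  expect_equal(nrow(tg$truth), 2 * 4)
  expect_equal(nrow(tg$profiles), 2 * 4 + 3)
  expect_true(all(tg$profiles > 0))
  expect_equal(sum(!is.na(tg$cluster_labels)), 8)
  # a noise-free target refits against its own regulator (full budget)
  fit <- anneal_fit(tg$profiles[1, ], reg[tg$truth$regulator_id[1], ],
                    config = fit_config(), seed = 5)
  expect_gte(fit$correlation, 0.99)
})

test_that("replicate noise reproduces the requested coefficient of variation", {
  base_spec <- synthetic_spec(n_regulators = 2, targets_per_regulator = 5,
                              n_decoys = 0, outlier_rate = 0,
                              replicates_per_point = 50)
  set.seed(93)
  reg <- make_regulator_profiles(base_spec, max_rho = 1)
  profiles <- make_targets(base_spec, reg)$profiles
  for (cv in c(0.05, 0.2, 0.5)) {
    spec <- base_spec
    spec$noise_cv <- cv
    arr <- add_replicate_noise(profiles, spec)
    value <- 2^arr$log2ratio * arr$reference
    cvs <- vapply(rownames(profiles), function(g) {
      per_t <- vapply(unique(arr$meta$time_label), function(tl) {
        v <- value[g, arr$meta$array_id[arr$meta$time_label == tl]]
        sd(v) / mean(v)
      }, numeric(1))
      mean(per_t)
    }, numeric(1))
    expect_equal(mean(cvs), cv, tolerance = 0.1 * cv + 0.01)
  }
})

test_that("outlier injection matches its binomial rate", {
  spec <- synthetic_spec(n_regulators = 2, targets_per_regulator = 10,
                         n_decoys = 8, outlier_rate = 0.01,
                         replicates_per_point = 30, noise_cv = 0)
  set.seed(94)
  reg <- make_regulator_profiles(spec, max_rho = 1)
  profiles <- make_targets(spec, reg)$profiles
  arr <- add_replicate_noise(rbind(reg, profiles), spec)
  n_values <- length(arr$log2ratio)
  ci <- qbinom(c(0.005, 0.995), n_values, 0.01)
  expect_gte(arr$n_outliers, ci[1])
  expect_lte(arr$n_outliers, ci[2])
})

test_that("emitted channels satisfy the construction identity", {
  set.seed(95)
  ds <- generate_fixture(synthetic_spec(n_regulators = 2,
                                        targets_per_regulator = 3,
                                        n_decoys = 4), seed = 3)
  value_from_ratio <- 2^ds$arrays$log2ratio * ds$arrays$reference
  value_from_signal <- ds$arrays$sample_signal / ds$spec$signal_scale
  expect_equal(value_from_ratio, value_from_signal, tolerance = 1e-12)
})

test_that("planted annotations give every gene one class and record truth", {
  set.seed(96)
  labels <- setNames(rep(c("A", "B", NA), each = 40), paste0("g", 1:120))
  spec <- synthetic_spec(n_classes = 10, planted_enrichment_factor = 5)
  out <- plant_annotations(labels, spec)
  expect_equal(nrow(out$annotation), 120)
  expect_equal(anyDuplicated(out$annotation$gene_id), 0)
  expect_equal(nrow(out$planted), 2)
  # planted class frequency ~ factor / n_classes inside its cluster
  pl <- out$planted[1, ]
  members <- names(labels)[!is.na(labels) & labels == pl$cluster_id]
  k <- sum(out$annotation$class[out$annotation$gene_id %in% members] ==
             pl$class)
  expect_gt(k, 10)  # expectation 20 of 40; binomial floor
  # factor 1 plants nothing
  spec1 <- synthetic_spec(planted_enrichment_factor = 1)
  expect_equal(nrow(plant_annotations(labels, spec1)$planted), 0)
})

test_that("fixture files round-trip bit-exactly", {
  ds <- generate_fixture(synthetic_spec(n_regulators = 2,
                                        targets_per_regulator = 3,
                                        n_decoys = 4), seed = 17)
  dir <- file.path(tempdir(), "fixture_roundtrip")
  write_fixture(ds, dir)
  back <- read_fixture(dir)
  expect_identical(back$arrays$log2ratio, ds$arrays$log2ratio)
  expect_identical(back$arrays$sample_signal, ds$arrays$sample_signal)
  expect_identical(back$profiles, ds$profiles)
  expect_equal(back$truth$k1, ds$truth$k1)
  expect_identical(back$sigma_ids, ds$sigma_ids)
  expect_equal(back$annotation, ds$annotation)
  # priors are sampled from true edges
  key <- paste(back$priors$regulator_id, back$priors$target_id)
  expect_true(all(key %in% paste(ds$truth$regulator_id,
                                 ds$truth$target_id)))
  unlink(dir, recursive = TRUE)
})

test_that("recovery pairs are informative by construction", {
  set.seed(97)
  pairs <- make_recovery_pairs(10)
  folds <- apply(pairs$targets, 1, function(y) max(y) / min(y))
  expect_true(all(folds >= 2))
  expect_true(all(pairs$targets > 0))
  expect_equal(nrow(pairs$truth), 10)
})

test_that("cluster fixtures meet their separation contracts", {
  set.seed(98)
  fx <- make_cluster_fixture(n_groups = 4, genes_per_group = 10)
  within <- vapply(seq_len(nrow(fx$values)), function(i)
    cor(fx$values[i, ], fx$shapes[fx$labels[i], ], method = "spearman"),
    numeric(1))
  expect_true(all(within >= 0.95))
  between <- abs(cor(t(fx$shapes), method = "spearman"))
  expect_lt(max(between[upper.tri(between)]), 0.3)
})
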