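grid13 <- time_grid()

test_that("acceptance obeys the prior-dependent correlation thresholds", {
  set.seed(71)
  spec <- synthetic_spec(n_regulators = 2, targets_per_regulator = 3,
                         n_decoys = 3)
  reg <- make_regulator_profiles(spec)
  tg <- make_targets(spec, reg)
  priors <- data.frame(regulator_id = "sigma01",
                       target_id = rownames(tg$profiles),
                       source = "chip", citation = "")
  edges <- screen_regulations(reg, tg$profiles, grid13, priors = priors,
                              config = screening_config(), keep_all = TRUE)
  # the rule itself: accepted iff c exceeds the prior-dependent threshold
  thr <- ifelse(edges$prior_source == "none", 0.8, 0.65)
  expect_equal(edges$accepted, edges$correlation > thr)
  expect_equal(edges$accepted_threshold, thr)
  expect_true(all(edges$prior_source[edges$regulator_id == "sigma01"] ==
                    "chip"))
  expect_true(all(edges$prior_source[edges$regulator_id == "sigma02"] ==
                    "none"))
  # no self-pairs, weights non-negative
  expect_false(any(edges$regulator_id == edges$target_id))
  expect_true(all(edges$w >= 0))
  # planted pairs are found
  true_key <- paste(tg$truth$regulator_id, tg$truth$target_id)
  got <- paste(edges$regulator_id[edges$accepted],
               edges$target_id[edges$accepted])
  expect_gte(mean(true_key %in% got), 0.8)
  # threshold monotonicity: the 0.8 set nests inside the 0.65 set
  in8 <- edges$correlation > 0.8
  in65 <- edges$correlation > 0.65
  expect_true(all(which(in8) %in% which(in65)))
})

test_that("mutual sigma-sigma pairs are detected and priors disambiguate", {
  set.seed(72)
  base <- c(1, 1.5, 3, 6, 8, 7, 5, 3.5, 2.5, 2, 1.8, 1.6, 1.5)
  twins <- rbind(sigA = base, sigB = base * 1.05 + 0.1,
                 sigC = rev(base))
  edges <- sigma_sigma_network(twins, grid13, config = screening_config())
  ab <- edges[edges$regulator_id == "sigA" & edges$target_id == "sigB", ]
  ba <- edges[edges$regulator_id == "sigB" & edges$target_id == "sigA", ]
  expect_equal(nrow(ab), 1)
  expect_true(ab$accepted && ba$accepted)
  expect_true(ab$trivial && ba$trivial)
  expect_true(ab$mutual && ba$mutual)
  expect_false(ab$preferred)
  # a literature prior on one direction marks it preferred, keeps both
  priors <- data.frame(regulator_id = "sigA", target_id = "sigB",
                       source = "literature", citation = "x")
  edges2 <- sigma_sigma_network(twins, grid13, priors = priors,
                                config = screening_config())
  ab2 <- edges2[edges2$regulator_id == "sigA" & edges2$target_id == "sigB", ]
  ba2 <- edges2[edges2$regulator_id == "sigB" & edges2$target_id == "sigA", ]
  expect_true(ab2$preferred)
  expect_false(ba2$preferred)
  expect_true(ba2$accepted)
})

test_that("GEXF export round-trips nodes and edges", {
  edges <- data.frame(
    regulator_id = c("sigA", "sigA"), target_id = c("g1", "g2"),
    target_kind = "gene", k1 = 1, k2 = 1, w = c(2.5, 0.7), b = 0,
    correlation = c(0.91, 0.84), F = c(0.09, 0.16),
    trivial = c(TRUE, FALSE), prior_source = c("chip", "none"),
    accepted_threshold = 0.8, accepted = TRUE, stringsAsFactors = FALSE)
  path <- file.path(tempdir(), "net.gexf")
  meta <- data.frame(id = "sigA", kind = "sigma", category = "IV")
  export_network(edges, path, node_metadata = meta)
  back <- read_gexf(path)
  expect_setequal(back$nodes$id, c("sigA", "g1", "g2"))
  expect_equal(back$nodes$kind[back$nodes$id == "sigA"], "sigma")
  expect_equal(nrow(back$edges), 2)
  expect_equal(back$edges$w[back$edges$target_id == "g1"], 2.5)
  expect_equal(back$edges$correlation, edges$correlation)
  expect_equal(back$edges$trivial, edges$trivial)
  expect_equal(back$edges$prior_source, edges$prior_source)
  # empty network still writes a parseable file
  path2 <- file.path(tempdir(), "empty.gexf")
  export_network(edges[0, ], path2)
  back2 <- read_gexf(path2)
  expect_equal(nrow(back2$edges), 0)
})

test_that("edge recovery metrics count hits against ground truth", {
  edges <- data.frame(regulator_id = c("A", "A", "B"),
                      target_id = c("t1", "t2", "t3"),
                      accepted = c(TRUE, TRUE, FALSE))
  truth <- data.frame(regulator_id = c("A", "B"),
                      target_id = c("t1", "t3"))
  m <- edge_recovery(edges, truth)
  expect_equal(m$recall, 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$n_correct, 1)
})
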