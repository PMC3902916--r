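test_that("Fisher p-values equal the hypergeometric tail oracle", {
  # the worked example: 10 of 50 cluster genes in a class of 40 among 1000
  universe <- paste0("g", 1:1000)
  class_genes <- universe[1:40]
  cluster <- c(universe[1:10], universe[41:80])
  ann <- data.frame(gene_id = class_genes, class = "X")
  res <- fisher_enrichment(cluster, ann, universe)
  row <- res[res$class == "X", ]
  expect_equal(row$fold_change, (10 / 50) / (40 / 1000))
  expect_equal(row$p_value, hypergeom_tail(10, 50, 40, 1000),
               tolerance = 1e-12)
  # degenerate cases
  res_all <- fisher_enrichment(universe, ann, universe)
  expect_true(all(abs(res_all$fold_change - 1) < 1e-12))
  cluster2 <- universe[41:90]       # no class-X gene
  res0 <- fisher_enrichment(cluster2, ann, universe)
  expect_equal(res0$fold_change[res0$class == "X"], 0)
  expect_false(res0$significant[res0$class == "X"])
})

test_that("Fisher matches the oracle across random small tables", {
  set.seed(81)
  for (i in 1:200) {
    N <- sample(10:200, 1)
    m <- sample(1:(N - 1), 1)
    K <- sample(1:(N - 1), 1)
    k <- sample(max(0, m + K - N):min(m, K), 1)
    tab <- matrix(c(k, m - k, K - k, N - m - (K - k)), 2, 2)
    p_impl <- fisher.test(tab, alternative = "greater")$p.value
    p_oracle <- hypergeom_tail(k, m, K, N)
    expect_equal(p_impl, p_oracle, tolerance = 1e-9)
  }
})

test_that("class counts are conserved for single-class annotations", {
  set.seed(82)
  universe <- paste0("g", 1:300)
  ann <- data.frame(gene_id = universe,
                    class = sample(paste0("c", 1:6), 300, replace = TRUE))
  cluster <- sample(universe, 70)
  res <- fisher_enrichment(cluster, ann, universe)
  expect_equal(sum(res$k), 70)
  expect_equal(sum(res$K), 300)
})

test_that("the significance rule applies all three strict thresholds", {
  mk <- function(p, fc, k) data.frame(p_value = p, fold_change = fc, k = k)
  expect_equal(nrow(significant_classes(mk(0.01, 5, 10))), 1)
  expect_equal(nrow(significant_classes(mk(0.01, 5, 7))), 0)   # needs k > 7
  expect_equal(nrow(significant_classes(mk(0.01, 5, 8))), 1)
  expect_equal(nrow(significant_classes(mk(0.06, 5, 10))), 0)
  expect_equal(nrow(significant_classes(mk(0.01, 2, 10))), 0)  # needs FC > 2
  expect_equal(nrow(significant_classes(mk(0.05, 5, 10))), 0)  # strict p
})

test_that("planted enrichment is flagged; uniform classes are not inflated", {
  set.seed(83)
  universe <- paste0("g", 1:1000)
  ann <- data.frame(gene_id = universe,
                    class = sample(paste0("c", 1:20), 1000, replace = TRUE))
  # plant: a 60-gene cluster whose class c1 frequency is ~5x background
  c1 <- ann$gene_id[ann$class == "c1"]
  cluster <- c(sample(c1, 15), sample(setdiff(universe, c1), 45))
  res <- fisher_enrichment(cluster, ann, universe)
  expect_true(res$significant[res$class == "c1"])
  # uniform random clusters: p < 0.05 at roughly the nominal rate
  hits <- 0; tests <- 0
  for (r in 1:60) {
    cl <- sample(universe, 60)
    rr <- fisher_enrichment(cl, ann, universe)
    hits <- hits + sum(rr$p_value < 0.05)
    tests <- tests + nrow(rr)
  }
  expect_lt(hits / tests, 0.09)
  expect_gt(hits / tests, 0.01)
})

test_that("sigma factors link to enriched classes through their clusters", {
  edges <- data.frame(regulator_id = c("sigA", "sigB", "sigA"),
                      target_id = c("CL1", "CL1", "CL2"),
                      accepted = c(TRUE, TRUE, TRUE))
  enriched <- data.frame(cluster_id = c("CL1", "CL3"),
                         class = c("macromolecule synthesis", "transport"))
  links <- link_sigma_functions(edges, enriched)
  expect_equal(nrow(links), 2)   # two alternative regulators of CL1's class
  expect_setequal(links$sigma_id, c("sigA", "sigB"))
  expect_true(all(links$class == "macromolecule synthesis"))
  expect_true(all(links$cluster_id == "CL1"))
  # cluster without enrichment yields nothing
  edges2 <- data.frame(regulator_id = "sigA", target_id = "CL9",
                       accepted = TRUE)
  expect_equal(nrow(link_sigma_functions(edges2, enriched)), 0)
})
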