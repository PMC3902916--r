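test_that("center_array standardizes to median 0 and MAD 1", {
  expect_equal(center_array(c(1, 2, 3, 4, 5)), c(-2, -1, 0, 1, 2))
  # idempotence on an already-standardized vector
  v <- center_array(c(0.3, -1.2, 2.5, 0.9, -0.4, 1.7))
  expect_equal(center_array(v), v)
  expect_equal(median(v), 0)
  expect_equal(mad(v, constant = 1), 1)
  expect_error(center_array(rep(3, 10)), "MAD")
  expect_error(center_array(c(1, NA, NA)), "finite")
  # NAs pass through
  x <- c(1, NA, 2, 3, 4, 5)
  expect_true(is.na(center_array(x)[2]))
})

test_that("centering holds exactly over random arrays", {
  set.seed(5)
  for (i in 1:50) {
    x <- rnorm(sample(20:200, 1))
    cx <- center_array(x)
    expect_equal(median(cx), 0)
    expect_equal(mad(cx, constant = 1), 1)
  }
})

test_that("quantile trim masks the expected extremes", {
  x <- sort(rnorm(100))
  m <- trim_intensity_extremes(x, 0.02)
  expect_equal(which(m), c(1, 2, 99, 100))
  expect_equal(sum(trim_intensity_extremes(rep(1, 50), 0.02)), 0)
  expect_equal(sum(trim_intensity_extremes(x, 0)), 0)
  # at most roughly 2q of the entries masked
  set.seed(9)
  y <- rnorm(500)
  expect_lte(sum(trim_intensity_extremes(y, 0.05)), 0.12 * 500)
})

test_that("exponentiation to normalized ratios inverts log2", {
  expect_equal(to_normalized_ratio(0), 1)
  expect_equal(to_normalized_ratio(c(-1, 1)), c(0.5, 2))
  x <- rnorm(40)
  expect_equal(log2(to_normalized_ratio(x)), x)
  expect_true(all(to_normalized_ratio(x) > 0))
})

test_that("Dixon Q test removes a single gross outlier and nothing else", {
  expect_equal(dixon_q_outliers(c(0.10, 0.11, 0.12, 0.50)),
               c(0.10, 0.11, 0.12))
  expect_equal(dixon_q_outliers(c(5, 5, 5)), c(5, 5, 5))
  expect_equal(dixon_q_outliers(c(2, 2, 2, 2)), c(2, 2, 2, 2))
  # retained values are unchanged and in original order
  x <- c(1.02, 0.98, 9, 1.00, 1.01)
  expect_equal(dixon_q_outliers(x), x[-3])
  expect_error(dixon_q_outliers(1:2), "3-9")
  expect_error(dixon_q_outliers(1:10), "3-9")
})

test_that("Peirce's criterion removes gross outliers from larger samples", {
  set.seed(11)
  x <- c(rnorm(11), 10)
  kept <- peirce_outliers(x)
  expect_false(10 %in% kept)
  expect_true(all(kept %in% x))
  # homogeneous sample untouched
  y <- rep(2.5, 12)
  expect_equal(peirce_outliers(y), y)
  # two symmetric gross outliers among 12 both removed
  set.seed(12)
  z <- c(rnorm(10, sd = 0.5), 8, -8)
  keptz <- peirce_outliers(z)
  expect_false(any(c(8, -8) %in% keptz))
  expect_equal(length(keptz), 10)
})

test_that("outlier dispatch never alters homogeneous replicates", {
  for (n in c(2, 3, 5, 9, 10, 15)) {
    v <- rep(1.7, n)
    expect_equal(remove_outliers(v), v)
  }
  # < 3 replicates: no test applied
  expect_equal(remove_outliers(c(1, 100)), c(1, 100))
})

test_that("replicate averaging applies outlier tests and records cv", {
  grid <- time_grid(labels = c("A", "B"), hours = c(0, 1))
  meta <- data.frame(array_id = paste0("a", 1:6),
                     time_label = rep(c("A", "B"), each = 3),
                     replicate = rep(1:3, 2))
  ratios <- rbind(g1 = c(2, 4, 6, 2, 4, 100))
  colnames(ratios) <- meta$array_id
  prof <- average_replicates(ratios, meta, grid)
  expect_equal(unname(prof$values["g1", "A"]), 4)
  # 100 rejected by the Q test, mean of the rest
  expect_equal(unname(prof$values["g1", "B"]), 3)
  expect_equal(unname(prof$n_used["g1", ]), c(2, 2) + c(1, 0))
  expect_equal(unname(prof$cv["g1", "A"]), sd(c(2, 4, 6)) / 4)
  # permutation invariance in replicate order
  perm <- c(3, 1, 2, 6, 4, 5)
  prof2 <- average_replicates(ratios[, perm, drop = FALSE], meta[perm, ],
                              grid)
  expect_equal(prof2$values, prof$values)
})

test_that("single replicates average to themselves with undefined cv", {
  grid <- time_grid(labels = "A", hours = 0)
  meta <- data.frame(array_id = "a1", time_label = "A", replicate = 1)
  ratios <- rbind(g1 = 7)
  colnames(ratios) <- "a1"
  prof <- average_replicates(ratios, meta, grid)
  expect_equal(unname(prof$values["g1", 1]), 7)
  expect_true(is.na(prof$cv["g1", 1]))
  expect_equal(unname(prof$n_used["g1", 1]), 1L)
})

test_that("interior gaps are linearly interpolated, boundary gaps flagged", {
  grid <- time_grid(labels = paste0("T", 1:4), hours = 0:3)
  v <- rbind(a = c(2, NA, 4, 5), b = c(NA, 3, 4, 5), c = c(1, NA, NA, 4))
  ps <- profile_set(v, grid = grid)
  filled <- fill_internal_gaps(ps)
  expect_equal(unname(filled$values["a", ]), c(2, 3, 4, 5))
  expect_equal(unname(filled$values["c", ]), c(1, 2, 3, 4))
  expect_true(is.na(filled$values["b", 1]))
  expect_true(filled$incomplete[["b"]])
  expect_false(filled$incomplete[["a"]])
  # present values are bit-identical
  expect_identical(filled$values["a", c(1, 3, 4)], ps$values["a", c(1, 3, 4)])
})

test_that("array normalization drops degenerate arrays with a warning", {
  m <- cbind(a1 = c(1, 2, 3, 4, 5), a2 = rep(2, 5))
  rownames(m) <- paste0("g", 1:5)
  expect_warning(out <- normalize_arrays(m), "degenerate")
  expect_equal(colnames(out), "a1")
  expect_true(all(out > 0, na.rm = TRUE))
})
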