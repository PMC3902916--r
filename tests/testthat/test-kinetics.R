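grid13 <- time_grid()

test_that("simulated profiles match closed forms", {
  at <- function(y, t) y[which(abs(grid13$hours - t) < 1e-9)]
  y1 <- simulate_target(c(k1 = 2, k2 = 1, w = 0, b = 0), rep(1, 13), 0,
                        grid13)
  expect_equal(at(y1, 1), 1 - exp(-1), tolerance = 1e-7)
  y2 <- simulate_target(c(k1 = 0, k2 = 1, w = 0, b = 0), rep(1, 13), 1,
                        grid13)
  expect_equal(at(y2, 2), exp(-2), tolerance = 1e-7)
  y3 <- simulate_target(c(k1 = 1, k2 = 1, w = 1, b = 0), rep(1, 13), 0,
                        grid13)
  expect_equal(at(y3, 6), plogis(1) * (1 - exp(-6)), tolerance = 1e-6)
})

test_that("solution is non-negative and matches a fine-grid Euler oracle", {
  set.seed(14)
  R <- abs(rnorm(13, 2, 1)) + 0.2
  p <- c(k1 = 3, k2 = 1.2, w = 1.5, b = -1)
  y <- simulate_target(p, R, 0.5, grid13)
  expect_true(all(y >= 0))
  oracle <- euler_oracle(p, R, 0.5, grid13)
  expect_equal(y, oracle, tolerance = 1e-3)
})

test_that("production term is monotone in the regulator weight", {
  set.seed(15)
  R <- abs(rnorm(13, 1, 0.5)) + 0.1
  y_prev <- simulate_target(c(k1 = 2, k2 = 1, w = 0, b = 0), R, 0, grid13)
  for (w in c(0.5, 1, 3, 8)) {
    y_w <- simulate_target(c(k1 = 2, k2 = 1, w = w, b = 0), R, 0, grid13)
    expect_true(all(y_w >= y_prev - 1e-8))
    y_prev <- y_w
  }
})

test_that("regulator interpolant is piecewise linear with clamped ends", {
  R <- seq(2, 14, by = 1)
  f <- regulator_interpolant(R, grid13)
  expect_equal(f(grid13$hours[3]), R[3])
  expect_equal(f(mean(grid13$hours[1:2])), mean(R[1:2]))
  expect_equal(f(100), R[13])
  expect_equal(f(-5), R[1])
})

test_that("objective is 1 - Pearson with worst case for degenerate input", {
  m <- c(1, 3, 2, 5, 4)
  expect_equal(objective(m, m), 0)
  expect_equal(objective(m, 2 * m + 7), 0)
  expect_equal(objective(m, -m), 2)
  expect_equal(objective(m, rep(1, 5)), 2)
  expect_error(objective(rep(1, 5), m), "constant")
})

test_that("annealing fit recovers noise-free synthetic pairs", {
  set.seed(2028)
  pairs <- make_recovery_pairs(5)
  for (i in 1:5) {
    fit <- anneal_fit(pairs$targets[i, ], pairs$regulators[i, ], grid13,
                      screening_config(), seed = 400 + i)
    expect_gte(fit$correlation, 0.98)
    expect_true(all(unclass(fit$params)[c("k1", "k2", "w")] >= 0))
    expect_equal(fit$F, 1 - fit$correlation)
  }
})

test_that("annealing is deterministic under a fixed seed", {
  set.seed(2029)
  pairs <- make_recovery_pairs(1)
  f1 <- anneal_fit(pairs$targets[1, ], pairs$regulators[1, ], grid13,
                   screening_config(), seed = 99)
  f2 <- anneal_fit(pairs$targets[1, ], pairs$regulators[1, ], grid13,
                   screening_config(), seed = 99)
  expect_identical(unclass(f1$params), unclass(f2$params))
  expect_identical(f1$simulated, f2$simulated)
  expect_identical(f1$restart_F, f2$restart_F)
})

test_that("uncorrelated noise targets are not kinetically plausible", {
  set.seed(2030)
  pairs <- make_recovery_pairs(1)
  noise <- abs(rnorm(13, 1, 0.8)) + 0.05
  fit <- anneal_fit(noise, pairs$regulators[1, ], grid13,
                    screening_config(), seed = 12)
  expect_lt(fit$correlation, 0.9)
})

test_that("trivial regulation is flagged by profile correlation", {
  R <- c(1, 2, 4, 7, 9, 8, 6, 4, 3, 2, 2, 1, 1)
  expect_true(classify_trivial(R, R))
  # mildly perturbed copy stays above the 0.9 default
  set.seed(8)
  expect_true(classify_trivial(R, R + rnorm(13, 0, 0.3)))
  expect_false(classify_trivial(R, rev(R)))
  expect_error(classify_trivial(rep(1, 13), R), "constant")
})

test_that("w = 0 solutions follow the two-parameter relaxation closed form", {
  set.seed(77)
  for (i in 1:25) {
    k1 <- runif(1, 0.01, 10); k2 <- runif(1, 0.01, 10)
    b <- runif(1, -10, 10); y0 <- runif(1, 0, 10)
    yss <- k1 / (k2 * (1 + exp(-b)))
    y <- simulate_target(c(k1 = k1, k2 = k2, w = 0, b = b), rep(1, 13), y0,
                         grid13)
    expect_lt(max(abs(y - (yss + (y0 - yss) * exp(-k2 * grid13$hours)))),
              1e-6)
  }
})
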