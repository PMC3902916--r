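# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files are read.

# A small replicated array set with known true profiles: `n_genes` positive
# profiles, `reps` replicates at each of the 13 default time points.
tiny_array_set <- function(n_genes = 8, reps = 3, noise_cv = 0.05,
                           seed = 101) {
  set.seed(seed)
  spec <- synthetic_spec(n_regulators = 2,
                         targets_per_regulator = max(0, n_genes - 4),
                         n_decoys = 2, replicates_per_point = reps,
                         noise_cv = noise_cv, outlier_rate = 0)
  reg <- make_regulator_profiles(spec, max_rho = 1)
  tg <- make_targets(spec, reg)
  profiles <- rbind(reg, tg$profiles)
  arrays <- add_replicate_noise(profiles, spec)
  list(spec = spec, profiles = profiles, arrays = arrays,
       truth = tg$truth, labels = tg$cluster_labels)
}

# Independent oracle for the one-sided Fisher over-representation p-value:
# hypergeometric upper-tail sum built from binomial coefficients only.
hypergeom_tail <- function(k, m, K, N) {
  kk <- k:min(m, K)
  sum(exp(lchoose(K, kk) + lchoose(N - K, m - kk) - lchoose(N, m)))
}

# Fine-grid Euler oracle for the sigmoid transcription ODE, independent of
# the package's Runge-Kutta path.
euler_oracle <- function(params, R_values, y0, grid, dt = 1e-4) {
  R_fun <- approxfun(grid$hours, R_values, rule = 2)
  y <- y0
  out <- numeric(nrow(grid))
  out[1] <- y0
  t <- grid$hours[1]
  for (i in 2:nrow(grid)) {
    while (t < grid$hours[i] - dt / 2) {
      y <- y + dt * (params[["k1"]] * plogis(params[["w"]] * R_fun(t) +
                                             params[["b"]]) -
                     params[["k2"]] * y)
      t <- t + dt
    }
    out[i] <- y
  }
  out
}
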