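#' Specification of a synthetic germination-style data set
#'
#' Describes a fixture that mirrors the structure of the real experiment:
#' 13 time points at 30-min spacing, 2-3 biological replicates per point,
#' multiplicative (lognormal) replicate noise with occasional gross
#' outliers, groups of targets driven by shared sigma-factor regulators
#' through the sigmoid kinetic model, decoy genes with no regulator, and
#' functional classes planted as enriched within kinetic groups.
#'
#' Default kinetic ranges are chosen as biologically plausible for bacterial
#' germination and keep the model identifiable at 30-min sampling:
#' degradation rates 0.8-3 per hour (mRNA half-lives of 14-50 min, so a
#' transcript tracks its production window instead of integrating it into a
#' featureless rising step) and regulator weights that hold the sigmoid in
#' its responsive regime, so a target inherits the temporal fine structure
#' of its own regulator rather than a saturated on/off version of it.
#'
#' @param n_regulators Number of sigma-factor regulators.
#' @param targets_per_regulator Targets driven by each regulator.
#' @param n_decoys Decoy genes attached to no regulator.
#' @param n_time_points Length of the time grid (30-min spacing).
#' @param replicates_per_point Replicate values per time point entering the
#'   averaging step. The default 6 emulates 3 biological replicates with 2
#'   replicate spots per gene and array, the pooled replicate set the
#'   study's averaging works on; with fewer than ~5 values the Dixon Q test
#'   has essentially no power against a single gross outlier.
#' @param noise_cv Multiplicative replicate noise of regulated (bright)
#'   genes, as a coefficient of variation.
#' @param decoy_noise_cv Replicate noise of the dim background population;
#'   dim probes are noisy (the intensity-variance funnel), which is what
#'   the coefficient-of-variation gate screens out in real data.
#' @param outlier_rate Probability a replicate value is a gross outlier.
#' @param outlier_fold Fold applied to outlier replicate values.
#' @param k1_range,k2_range,w_range,b_range Kinetic parameter ranges
#'   (uniform draws). `w_range` and `b_range` are sampled in normalized
#'   drive units: the drawn w is the sigmoid-input swing per quarter of the
#'   regulator's dynamic range and the drawn b offsets the sigmoid midpoint
#'   from the regulator's mid-level, so every regulator operates in the
#'   responsive regime of the sigmoid whatever its absolute scale. The
#'   realized (w, b) pair is recorded in the ground truth.
#' @param param_jitter Relative within-group jitter of kinetic parameters;
#'   targets of one regulator share base parameters so that each regulon
#'   forms a kinetic group.
#' @param n_classes Number of functional classes.
#' @param planted_enrichment_factor Over-sampling factor of the planted
#'   class inside each kinetic group (1 = no planting).
#' @param decoy_level Brightness of decoy genes relative to typical targets;
#'   decoys emulate unregulated background genes, which sit in the dim tail
#'   of the intensity distribution in real data.
#' @param channel_bias_sd Standard deviation (log2 units) of the per-gene
#'   channel bias of regulated genes: gene-specific dye and probe response
#'   differences between the sample and reference channels, constant
#'   across arrays. A constant per-gene bias rescales that gene's
#'   normalized Ratio and leaves profile shapes (and all correlation-based
#'   stages) untouched.
#' @param decoy_channel_bias_sd Channel-bias standard deviation of the dim
#'   background population; ratios of dim probes are unreliable (the
#'   MA-plot funnel), and this population dominates the spread of the
#'   Log2Ratio distribution the per-array normalization standardizes.
#' @param signal_scale Arbitrary intensity unit of the emulated sample
#'   channel.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_regulators = 5, targets_per_regulator = 20,
                           n_decoys = 150, n_time_points = 13,
                           replicates_per_point = 6, noise_cv = 0.1,
                           decoy_noise_cv = 1.2,
                           outlier_rate = 0.01, outlier_fold = 10,
                           k1_range = c(1, 8), k2_range = c(0.8, 3),
                           w_range = c(0.6, 2), b_range = c(-2, 1),
                           param_jitter = 0.1, n_classes = 8,
                           planted_enrichment_factor = 5,
                           decoy_level = 0.15, channel_bias_sd = 0.5,
                           decoy_channel_bias_sd = 2,
                           signal_scale = 1000) {
  stopifnot(n_regulators >= 0, targets_per_regulator >= 0, n_decoys >= 0,
            noise_cv >= 0, outlier_rate >= 0, outlier_rate <= 1,
            replicates_per_point >= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Grid matching a synthetic spec
#' @param spec A [synthetic_spec()].
#' @return A [time_grid()] of `n_time_points` points at 30-min spacing.
#' @export
spec_grid <- function(spec) {
  if (spec$n_time_points == 13) return(time_grid())
  time_grid(labels = paste0("T", seq_len(spec$n_time_points)),
            hours = seq(0, by = 0.5, length.out = spec$n_time_points))
}

# Unit-peak gamma pulse starting at `onset`.
.gamma_pulse <- function(hours, onset, theta, shape) {
  s <- pmax(hours - onset, 0) / theta
  pulse <- s^(shape - 1) * exp(-s)
  if (max(pulse) > 0) pulse / max(pulse) else pulse
}

# Backwards-compatible single-pulse profile (baseline + gamma pulse).
.pulse_profile <- function(hours, onset, shape, theta, amplitude, baseline,
                           slope = 0) {
  mid <- (hours[1] + hours[length(hours)]) / 2
  trend <- baseline * (1 + slope * (hours - mid) / max(hours - hours[1]))
  pmax(trend + amplitude * .gamma_pulse(hours, onset, theta, shape), 0.05)
}

# One positive regulator profile: baseline plus a primary gamma pulse and a
# secondary gamma component (a smaller pulse or a transient dip) at another
# time. The biphasic fine structure is what makes regulators mutually
# distinguishable after the monotone sigmoid warp of the kinetic model.
# Redrawn until the profile spans at least a 4-fold dynamic range, so a
# measured version of it is signal- rather than noise-dominated.
.draw_pulse <- function(hours) {
  span <- max(hours) - min(hours)
  for (try in 1:200) {
    t1 <- runif(1, min(hours) - 0.5, min(hours) + 0.85 * span)
    t2 <- runif(1, min(hours) - 0.5, min(hours) + 0.85 * span)
    A1 <- runif(1, 2, 6)
    sign2 <- sample(c(1, -1), 1)
    A2 <- sign2 * A1 * runif(1, 0.4, 0.9)
    baseline <- if (sign2 > 0) runif(1, 0.2, 0.5)
                else runif(1, 0.8, 1.2) * abs(A2)
    prof <- pmax(baseline + A1 * .gamma_pulse(hours, t1, runif(1, 0.3, 0.7),
                                              runif(1, 1.5, 3)) +
                 A2 * .gamma_pulse(hours, t2, runif(1, 0.3, 0.7),
                                   runif(1, 1.5, 3)),
                 0.05)
    if (max(prof) >= 4 * min(prof)) return(prof)
  }
  prof
}

# Canonical kinetic response of a regulator (mid-range normalized drive,
# steady initial state): the shape a typical target driven by R inherits.
.canonical_response <- function(R, grid) {
  w <- 4 / (max(R) - min(R))
  p <- c(k1 = 1, k2 = 1.5, w = w, b = -w * (max(R) + min(R)) / 2)
  y0 <- p[["k1"]] / (1 + exp(-(p[["w"]] * R[[1]] + p[["b"]]))) / p[["k2"]]
  simulate_target(p, R, y0, grid, rtol = 1e-6, atol = 1e-9)
}

# Confusability of regulator j for a target shape: the best Pearson
# correlation any coarse model warp of R_j achieves against it. The (w, b)
# grid works in normalized drive units -- sigmoid input swing over R_j's
# range, midpoint offset from R_j's mid-level -- so the probes stay in the
# sigmoid's responsive regime whatever R_j's absolute scale. Pairs with low
# mutual confusability keep the correlation screen attributable.
.confusability <- function(canon_i, Rj, grid) {
  span <- max(Rj) - min(Rj)
  mid <- (max(Rj) + min(Rj)) / 2
  best <- 0
  for (u in c(1, 2, 3, 4.5, 6, 9, 12)) for (m in c(-2.5, -1.2, 0, 1.2, 2.5))
    for (k2 in c(0.4, 0.8, 1.5, 3, 6)) {
      w <- u / span
      b <- m - w * mid
      y0 <- 1 / (1 + exp(-(w * Rj[[1]] + b))) / k2
      y <- simulate_target(c(k1 = 1, k2 = k2, w = w, b = b), Rj, y0, grid,
                           rtol = 1e-6, atol = 1e-9)
      if (length(unique(y)) > 1 && length(unique(canon_i)) > 1)
        best <- max(best, abs(cor(canon_i, y)))
    }
  best
}

# Select n pool rows that are mutually distinguishable: Spearman-separated
# preselection, then greedy minimization of pairwise kinetic confusability.
.select_identifiable <- function(pool, n, max_rho, grid, n_finalists = 24) {
  fin <- .select_separated(pool, min(n_finalists, nrow(pool)),
                           max_rho = 1, n_starts = 10)
  finalists <- pool[fin, , drop = FALSE]
  canon <- t(apply(finalists, 1, .canonical_response, grid = grid))
  m <- nrow(finalists)
  conf <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) if (i != j)
    conf[i, j] <- .confusability(canon[i, ], finalists[j, ], grid)
  conf <- pmax(conf, t(conf))
  # also separate the regulons the regulators will drive: canonical
  # responses that rank-correlate strongly would merge under Spearman
  # clustering even when the fits stay attributable
  conf <- pmax(conf, abs(cor(t(canon), method = "spearman")) *
                 (1 - diag(m)))
  rho <- abs(cor(t(finalists), method = "spearman"))
  best_sel <- NULL
  best_v <- Inf
  for (s in seq_len(m)) {
    sel <- s
    for (k in seq_len(n - 1)) {
      cand_max <- apply(conf[, sel, drop = FALSE], 1, max)
      cand_max[sel] <- Inf
      cand_max[apply(rho[, sel, drop = FALSE], 1, max) >= max_rho] <- Inf
      if (!any(is.finite(cand_max))) break
      sel <- c(sel, which.min(cand_max))
    }
    if (length(sel) < n) next
    v <- max(conf[sel, sel])
    if (v < best_v) {
      best_v <- v
      best_sel <- sel
    }
  }
  if (is.null(best_sel))
    stop("could not select mutually distinguishable regulators")
  fin[best_sel]
}

# Pick n rows of pool with small pairwise |Spearman|: farthest-point greedy
# from several random starts, keeping the best set found.
.select_separated <- function(pool, n, max_rho, n_starts = 20) {
  rho <- abs(cor(t(pool), method = "spearman"))
  best <- NULL
  best_v <- Inf
  starts <- sample.int(nrow(pool), min(n_starts, nrow(pool)))
  for (s in starts) {
    sel <- s
    for (k in seq_len(n - 1)) {
      cand_max <- apply(rho[, sel, drop = FALSE], 1, max)
      cand_max[sel] <- Inf
      sel <- c(sel, which.min(cand_max))
    }
    v <- max(rho[sel, sel][upper.tri(diag(n))])
    if (v < best_v) {
      best_v <- v
      best <- sel
    }
  }
  if (best_v >= max_rho)
    stop(sprintf(paste("could not draw %d profiles with pairwise Spearman",
                       "below %.2f (best attainable %.2f)"),
                 n, max_rho, best_v))
  best
}

#' Generate distinct regulator profiles
#'
#' Each regulator is a positive profile from a pulse family: a baseline with
#' a gentle linear trend plus a gamma-shaped pulse (or transient dip), with
#' randomly drawn onset, width and amplitude. A pool of candidates is drawn
#' and a maximally separated subset is selected (farthest-point greedy on
#' absolute Spearman correlation) so that all pairwise correlations stay
#' below `max_rho` and the regulators are kinetically distinguishable.
#'
#' On a 13-point grid the smooth-profile family supports mutual separation
#' down to roughly 0.45; the default 0.7 leaves headroom. Pass `max_rho = 1`
#' to skip the selection when drawing many independent regulators whose
#' mutual similarity is irrelevant (e.g. for one-pair recovery studies).
#'
#' @param spec A [synthetic_spec()].
#' @param max_rho Pairwise absolute-Spearman ceiling; `1` disables the
#'   check.
#' @param pool_size Candidate pool for the separation selection.
#' @return Matrix `n_regulators` x `n_time_points` with rownames
#'   `sigma01`, ...
#' @export
make_regulator_profiles <- function(spec, max_rho = 0.7, pool_size = 2000) {
  grid <- spec_grid(spec)
  hours <- grid$hours
  n <- spec$n_regulators
  rn <- sprintf("sigma%02d", seq_len(n))
  if (max_rho >= 1 || n < 2) {
    profiles <- t(replicate(n, .draw_pulse(hours)))
    dimnames(profiles) <- list(rn, grid$label)
    return(profiles)
  }
  pool <- t(replicate(max(pool_size, 4 * n), .draw_pulse(hours)))
  sel <- .select_identifiable(pool, n, max_rho, grid)
  profiles <- pool[sel, , drop = FALSE]
  dimnames(profiles) <- list(rn, grid$label)
  profiles
}

# Best Pearson correlation of y with an unregulated first-order relaxation
# y0 + (yss - y0) exp(-k t): by affine invariance this is the maximal
# |cor(y, exp(-k t))| over decay rates k. Profiles close to this family are
# reproduced by the kinetic model with w ~ 0 for any regulator, so they can
# carry no regulator attribution.
.relaxation_c <- function(y, hours, k_grid = exp(seq(log(0.05), log(20),
                                                     length.out = 40))) {
  if (length(unique(y)) < 2) return(1)
  max(vapply(k_grid, function(k) abs(cor(y, exp(-k * hours))), numeric(1)))
}

.jitter_pos <- function(x, rel) x * exp(rnorm(length(x), 0, rel))

#' Generate noise-free target profiles with ground-truth kinetics
#'
#' Each regulator drives `targets_per_regulator` targets through the
#' sigmoid kinetic model; targets of one regulator share base parameters
#' with a small relative jitter, so each regulon forms a planted kinetic
#' group. Decoy genes are smooth seeded random profiles (cubic-smoothed
#' noise) attached to no regulator. The initial condition of each target is
#' its steady state at the first time point.
#'
#' @param spec A [synthetic_spec()].
#' @param regulators Matrix from [make_regulator_profiles()].
#' @return List with `profiles` (targets + decoys matrix), `truth`
#'   (data.frame: target_id, regulator_id, k1, k2, w, b) and
#'   `cluster_labels` (named vector; regulator id per target, NA for
#'   decoys).
#' @export
make_targets <- function(spec, regulators) {
  grid <- spec_grid(spec)
  hours <- grid$hours
  nt <- spec$n_regulators * spec$targets_per_regulator
  ids <- sprintf("gene%04d", seq_len(nt + spec$n_decoys))
  profiles <- matrix(NA_real_, nt + spec$n_decoys, length(hours),
                     dimnames = list(ids, grid$label))
  truth <- vector("list", nt)
  labels <- setNames(rep(NA_character_, nt + spec$n_decoys), ids)
  base_shapes <- NULL
  row <- 0
  for (r in seq_len(spec$n_regulators)) {
    # redraw group base parameters until the driven profile (i) shows at
    # least a 4-fold dynamic range -- germination induces transcription
    # from near-dormant levels, and an undriven flat target is not a
    # regulon member in any meaningful sense -- and (ii) is distinguishable
    # from an unregulated first-order relaxation, which the model emits for
    # w ~ 0 under every regulator and which therefore carries no
    # attribution signal
    R <- regulators[r, ]
    R_span <- max(R) - min(R)
    R_mid <- (max(R) + min(R)) / 2
    best_conf <- Inf
    best_base <- NULL
    for (try in 1:400) {
      w_norm <- runif(1, spec$w_range[1], spec$w_range[2])
      b_norm <- runif(1, spec$b_range[1], spec$b_range[2])
      w_act <- 4 * w_norm / R_span
      base <- c(k1 = runif(1, spec$k1_range[1], spec$k1_range[2]),
                k2 = runif(1, spec$k2_range[1], spec$k2_range[2]),
                w = w_act,
                b = b_norm - w_act * R_mid)
      y0b <- base[["k1"]] /
        (1 + exp(-(base[["w"]] * R[[1]] + base[["b"]]))) / base[["k2"]]
      yb <- simulate_target(base, R, y0b, grid)
      # shape requirements: dynamic (>= 4-fold, germination-scale), not a
      # relaxation (w ~ 0 limit reachable by any regulator), and separated
      # from the groups already planted (distinct regulators can still
      # drive convergent kinetics, blurring the planted clusters)
      if (!(min(yb) > 0 && max(yb) >= 4 * min(yb) &&
              .relaxation_c(yb, hours) < 0.9))
        next
      if (!is.null(base_shapes) &&
          max(abs(apply(base_shapes, 1, cor, y = yb,
                        method = "spearman"))) >= 0.4)
        next
      # attribution margin: no other regulator may come close to
      # reproducing this shape through a model warp, else the planted edge
      # carries no attribution signal and precision against ground truth is
      # undefined; keep the least-confusable candidate seen
      conf <- 0
      if (spec$n_regulators > 1)
        for (j in seq_len(spec$n_regulators)) {
          if (j == r) next
          conf <- max(conf, .confusability(yb, regulators[j, ], grid))
          if (conf >= best_conf) break
        }
      if (conf < best_conf) {
        best_conf <- conf
        best_base <- base
        yb_best <- yb
      }
      if (best_conf < 0.7) break
    }
    if (!is.null(best_base)) {
      base <- best_base
      yb <- yb_best
    }
    base_shapes <- rbind(base_shapes, yb)
    for (s in seq_len(spec$targets_per_regulator)) {
      row <- row + 1
      p <- c(.jitter_pos(base[c("k1", "k2", "w")], spec$param_jitter),
             b = unname(base[["b"]] + rnorm(1, 0, spec$param_jitter)))
      y0 <- p[["k1"]] / (1 + exp(-(p[["w"]] * R[[1]] + p[["b"]]))) / p[["k2"]]
      profiles[row, ] <- simulate_target(p, R, y0, grid)
      truth[[row]] <- data.frame(target_id = ids[row],
                                 regulator_id = rownames(regulators)[r],
                                 k1 = p[["k1"]], k2 = p[["k2"]],
                                 w = p[["w"]], b = p[["b"]],
                                 stringsAsFactors = FALSE)
      labels[row] <- rownames(regulators)[r]
    }
  }
  for (d in seq_len(spec$n_decoys)) {
    # decoys are true negatives; a decoy inside the w = 0 relaxation family
    # is model-indistinguishable from an unregulated gene and is redrawn
    for (try in 1:500) {
      raw <- abs(rnorm(length(hours), 1, 0.6)) + 0.05
      sm <- pmax(predict(smooth.spline(hours, raw, df = 10), hours)$y, 0.02)
      if (.relaxation_c(sm, hours) < 0.9) break
    }
    profiles[nt + d, ] <- spec$decoy_level * sm
  }
  list(profiles = profiles,
       truth = if (nt) do.call(rbind, truth) else NULL,
       cluster_labels = labels)
}

#' Emulate replicated two-channel arrays from true profiles
#'
#' Per time point, `replicates_per_point` arrays are emitted. Each replicate
#' value is the true value times a lognormal factor with unit mean and
#' coefficient of variation `noise_cv`; with probability `outlier_rate` it
#' is further multiplied by `outlier_fold`. The sample channel is the
#' replicate value in arbitrary intensity units; the Log2Ratio channel uses
#' a per-gene reference equal to the gene's mean across all emitted samples
#' scaled by a gene-specific channel bias (dye/probe response), mirroring a
#' pooled-reference two-channel design.
#'
#' @param profiles True expression matrix (genes x time points), positive.
#' @param spec A [synthetic_spec()].
#' @param grid A [time_grid()] matching the columns.
#' @param noise_cv Scalar or per-gene vector of replicate noise CVs;
#'   defaults to `spec$noise_cv` for every gene.
#' @param bias_sd Scalar or per-gene vector of channel-bias standard
#'   deviations; defaults to `spec$channel_bias_sd` for every gene.
#' @return List with matrices `log2ratio` and `sample_signal`
#'   (genes x arrays), `meta` (array_id, time_label, replicate),
#'   `reference` (per-gene reference), and `n_outliers` injected.
#' @export
add_replicate_noise <- function(profiles, spec, grid = spec_grid(spec),
                                noise_cv = NULL, bias_sd = NULL) {
  stopifnot(all(profiles > 0))
  nt <- ncol(profiles)
  reps <- spec$replicates_per_point
  noise_cv <- rep_len(noise_cv %||% spec$noise_cv, nrow(profiles))
  bias_sd <- rep_len(bias_sd %||% spec$channel_bias_sd, nrow(profiles))
  sigma <- sqrt(log(1 + noise_cv^2))
  arrays <- as.vector(outer(seq_len(reps), seq_len(nt), function(r, k)
    sprintf("%s_r%d", grid$label[k], r)))
  meta <- data.frame(array_id = arrays,
                     time_label = rep(grid$label, each = reps),
                     replicate = rep(seq_len(reps), times = nt),
                     stringsAsFactors = FALSE)
  value <- matrix(NA_real_, nrow(profiles), length(arrays),
                  dimnames = list(rownames(profiles), arrays))
  for (j in seq_along(arrays)) {
    true_col <- profiles[, meta$time_label[j]]
    noise <- ifelse(sigma > 0,
                    rlnorm(length(true_col), meanlog = -sigma^2 / 2,
                           sdlog = sigma),
                    1)
    value[, j] <- true_col * noise
  }
  n_out <- 0L
  if (spec$outlier_rate > 0 && spec$outlier_fold != 1) {
    hit <- matrix(runif(length(value)) < spec$outlier_rate, nrow(value))
    value[hit] <- value[hit] * spec$outlier_fold
    n_out <- sum(hit)
  }
  bias <- rnorm(nrow(profiles), 0, bias_sd)
  reference <- rowMeans(value) / 2^bias
  list(log2ratio = log2(value / reference),
       sample_signal = value * spec$signal_scale,
       meta = meta, reference = reference, n_outliers = n_out)
}

#' Plant functional-class annotations with known enrichment
#'
#' Every gene receives exactly one class. Genes outside planted clusters
#' draw uniformly among the classes; inside each planted cluster one
#' designated class is over-sampled so its within-cluster frequency is
#' `planted_enrichment_factor` times the background frequency (capped at 1).
#'
#' @param cluster_labels Named vector (gene id -> cluster label, NA for
#'   unclustered genes).
#' @param spec A [synthetic_spec()].
#' @return List with `annotation` (data.frame gene_id, class) and
#'   `planted` (data.frame cluster_id, class), empty when the factor is 1.
#' @export
plant_annotations <- function(cluster_labels, spec) {
  classes <- sprintf("class%02d", seq_len(spec$n_classes))
  genes <- names(cluster_labels)
  class_of <- setNames(rep(NA_character_, length(genes)), genes)
  clusters <- unique(cluster_labels[!is.na(cluster_labels)])
  factor_ <- spec$planted_enrichment_factor
  planted <- list()
  for (i in seq_along(clusters)) {
    cl <- clusters[i]
    members <- genes[!is.na(cluster_labels) & cluster_labels == cl]
    target_class <- classes[(i - 1) %% spec$n_classes + 1]
    p_target <- min(factor_ / spec$n_classes, 1)
    probs <- rep((1 - p_target) / (spec$n_classes - 1), spec$n_classes)
    probs[match(target_class, classes)] <- p_target
    class_of[members] <- sample(classes, length(members), replace = TRUE,
                                prob = probs)
    if (factor_ > 1)
      planted[[length(planted) + 1L]] <-
        data.frame(cluster_id = cl, class = target_class,
                   stringsAsFactors = FALSE)
  }
  rest <- is.na(class_of)
  class_of[rest] <- sample(classes, sum(rest), replace = TRUE)
  list(annotation = data.frame(gene_id = genes, class = unname(class_of),
                               stringsAsFactors = FALSE),
       planted = if (length(planted)) do.call(rbind, planted) else
         data.frame(cluster_id = character(), class = character(),
                    stringsAsFactors = FALSE))
}

#' Generate a complete synthetic data set with ground truth
#'
#' Regulators, kinetic targets, decoys, replicated noisy arrays, planted
#' annotations and a prior table sampled from the true edges, in one call.
#' Fully deterministic for a given seed.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @param prior_fraction Fraction of true edges emitted as a ChIP-style
#'   prior table.
#' @return List of class `synthetic_dataset`: `spec`, `grid`, `regulators`,
#'   `profiles` (true noise-free gene profiles incl. regulators), `truth`,
#'   `cluster_labels`, `arrays` (from [add_replicate_noise()]),
#'   `annotation`, `planted_enrichment`, `priors`, `sigma_ids`.
#' @export
generate_fixture <- function(spec = synthetic_spec(), seed = 1,
                             prior_fraction = 0.2) {
  set.seed(seed)
  grid <- spec_grid(spec)
  regulators <- make_regulator_profiles(spec)
  tg <- make_targets(spec, regulators)
  all_profiles <- rbind(regulators, tg$profiles)
  labels <- c(setNames(rep(NA_character_, nrow(regulators)),
                       rownames(regulators)), tg$cluster_labels)
  is_decoy <- rownames(all_profiles) %in%
    names(tg$cluster_labels)[is.na(tg$cluster_labels)]
  arrays <- add_replicate_noise(
    all_profiles, spec, grid,
    noise_cv = ifelse(is_decoy, spec$decoy_noise_cv, spec$noise_cv),
    bias_sd = ifelse(is_decoy, spec$decoy_channel_bias_sd,
                     spec$channel_bias_sd))
  ann <- plant_annotations(tg$cluster_labels, spec)
  priors <- NULL
  if (!is.null(tg$truth) && prior_fraction > 0) {
    n_pick <- max(1L, round(prior_fraction * nrow(tg$truth)))
    pick <- sort(sample.int(nrow(tg$truth), n_pick))
    priors <- data.frame(regulator_id = tg$truth$regulator_id[pick],
                         target_id = tg$truth$target_id[pick],
                         source = "chip", citation = "synthetic",
                         stringsAsFactors = FALSE)
  }
  structure(list(spec = spec, grid = grid, regulators = regulators,
                 profiles = all_profiles, truth = tg$truth,
                 cluster_labels = labels, arrays = arrays,
                 annotation = ann$annotation,
                 planted_enrichment = ann$planted, priors = priors,
                 sigma_ids = rownames(regulators), seed = seed),
            class = "synthetic_dataset")
}

#' Planted kinetic groups for clustering validation
#'
#' Generates well-separated kinetic groups: distinct smooth group shapes
#' (cubic-smoothed seeded noise, selected so all pairwise Spearman
#' correlations stay below `max_between_rho`) and members equal to the
#' group shape under small multiplicative noise, redrawn until each
#' member's Spearman correlation with its group shape reaches
#' `min_within_rho`.
#'
#' @param n_groups Number of planted groups.
#' @param genes_per_group Members per group.
#' @param min_within_rho Within-group Spearman floor (member vs group
#'   shape).
#' @param max_between_rho Between-group Spearman ceiling (group shapes).
#' @param member_cv Multiplicative noise CV of members.
#' @param grid A [time_grid()].
#' @return List with `values` (matrix) and `labels` (named integer vector
#'   of planted group per gene).
#' @export
make_cluster_fixture <- function(n_groups = 6, genes_per_group = 60,
                                 min_within_rho = 0.95,
                                 max_between_rho = 0.3, member_cv = 0.05,
                                 grid = time_grid()) {
  hours <- grid$hours
  pool <- t(replicate(3000, {
    raw <- abs(rnorm(length(hours), 1, 0.6)) + 0.05
    pmax(predict(smooth.spline(hours, raw, df = 8), hours)$y, 0.02)
  }))
  shapes <- pool[.select_separated(pool, n_groups, max_between_rho), ,
                 drop = FALSE]
  dimnames(shapes) <- list(sprintf("shape%02d", seq_len(n_groups)),
                           grid$label)
  ng <- n_groups * genes_per_group
  values <- matrix(NA_real_, ng, nrow(grid),
                   dimnames = list(sprintf("g%04d", seq_len(ng)),
                                   grid$label))
  labels <- setNames(integer(ng), rownames(values))
  row <- 0
  for (g in seq_len(n_groups)) {
    for (i in seq_len(genes_per_group)) {
      row <- row + 1
      for (try in 1:500) {
        cand <- shapes[g, ] * exp(rnorm(nrow(grid), 0, member_cv))
        if (cor(cand, shapes[g, ], method = "spearman") >= min_within_rho)
          break
      }
      values[row, ] <- cand
      labels[row] <- g
    }
  }
  list(values = values, labels = labels, shapes = shapes)
}

#' @importFrom stats smooth.spline predict
NULL

#' Random regulator-target pairs for fit-recovery studies
#'
#' Draws independent pairs: a pulse-shaped regulator and a target simulated
#' from it with kinetic parameters sampled uniformly from the given ranges
#' (defaulting to the annealing initialization ranges). Parameter draws
#' whose target is kinetically uninformative -- a dynamic range below the
#' field's customary two-fold differential-expression threshold, as happens
#' when the sigmoid is saturated or switched off -- are rejected and
#' redrawn: a target that a regulator does not visibly drive is not a
#' regulator-target pair.
#'
#' @param n_pairs Number of pairs.
#' @param k1_range,k2_range,w_range,b_range Uniform sampling ranges.
#' @param min_fold Minimal max/min dynamic range of an acceptable target.
#' @param grid A [time_grid()].
#' @return List with `regulators` and `targets` (n_pairs x time matrices,
#'   row i of one paired with row i of the other) and `truth` (data.frame
#'   of the sampled parameters).
#' @export
make_recovery_pairs <- function(n_pairs = 50,
                                k1_range = c(1e-3, 10),
                                k2_range = c(1e-3, 10),
                                w_range = c(1e-3, 50),
                                b_range = c(-10, 10),
                                min_fold = 2, grid = time_grid()) {
  hours <- grid$hours
  span <- max(hours)
  regulators <- targets <- matrix(NA_real_, n_pairs, length(hours),
                                  dimnames = list(sprintf("pair%03d",
                                                          seq_len(n_pairs)),
                                                  grid$label))
  truth <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    for (try in 1:1000) {
      R <- .pulse_profile(hours,
                          onset = runif(1, -2, 0.8 * span),
                          shape = runif(1, 1.2, 5),
                          theta = runif(1, 0.2, 2.5),
                          amplitude = runif(1, 1, 8),
                          baseline = runif(1, 0.2, 1))
      p <- c(k1 = runif(1, k1_range[1], k1_range[2]),
             k2 = runif(1, k2_range[1], k2_range[2]),
             w = runif(1, w_range[1], w_range[2]),
             b = runif(1, b_range[1], b_range[2]))
      y0 <- p[["k1"]] / (1 + exp(-(p[["w"]] * R[[1]] + p[["b"]]))) / p[["k2"]]
      y <- simulate_target(p, R, y0, grid)
      if (all(is.finite(y)) && min(y) > 0 && max(y) >= min_fold * min(y))
        break
    }
    regulators[i, ] <- R
    targets[i, ] <- y
    truth[[i]] <- data.frame(pair = rownames(targets)[i], k1 = p[["k1"]],
                             k2 = p[["k2"]], w = p[["w"]], b = p[["b"]],
                             stringsAsFactors = FALSE)
  }
  list(regulators = regulators, targets = targets,
       truth = do.call(rbind, truth))
}

#' Apply multiplicative lognormal noise to profiles
#'
#' Unit-mean lognormal noise with coefficient of variation `cv`, the same
#' replicate-noise model the array emulation uses.
#'
#' @param profiles Numeric matrix or vector of positive values.
#' @param cv Coefficient of variation of the noise factor.
#' @return Noisy object of the same shape.
#' @export
multiplicative_noise <- function(profiles, cv) {
  if (cv <= 0) return(profiles)
  sigma <- sqrt(log(1 + cv^2))
  noise <- rlnorm(length(profiles), meanlog = -sigma^2 / 2, sdlog = sigma)
  profiles * noise
}
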