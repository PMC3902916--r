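#' Default germination time grid
#'
#' Thirteen sampling points: the dormant-spore sample followed by 30-min
#' intervals across germination. The dormant point is placed half an interval
#' before the first germination sample; any constant offset is absorbed by
#' the kinetic model parameters. Both labels and hours are configurable.
#'
#' @param labels Character vector of time-point labels, in temporal order.
#' @param hours Numeric hours assigned to each label; strictly increasing.
#' @return A `time_grid` object: data.frame with columns `label` and `hours`.
#' @export
time_grid <- function(labels = c("TDorm", paste0("T", seq(0, 5.5, by = 0.5))),
                      hours = seq(0, by = 0.5, length.out = length(labels))) {
  stopifnot(length(labels) == length(hours), !anyDuplicated(labels))
  if (any(diff(hours) <= 0)) stop("grid hours must be strictly increasing")
  structure(data.frame(label = as.character(labels), hours = as.numeric(hours),
                       stringsAsFactors = FALSE),
            class = c("time_grid", "data.frame"))
}

#' Center one array's Log2Ratio distribution
#'
#' Subtracts the array median and divides by the (unscaled) median absolute
#' deviation, so all arrays share median 0 and MAD 1. Missing entries are
#' preserved.
#'
#' @param x Numeric vector of Log2Ratio values for one array (NAs allowed).
#' @return Centered vector with median 0 and MAD 1 over non-missing entries.
#' @export
center_array <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 2) stop("center_array: need at least 2 finite values")
  m <- median(x[ok])
  s <- median(abs(x[ok] - m))
  if (s == 0) stop("center_array: degenerate array (MAD = 0)")
  (x - m) / s
}

#' Mask the most extreme values of a centered array
#'
#' Flags entries strictly below the `q` quantile or strictly above the
#' `1 - q` quantile (linear-interpolation quantile convention) as missing.
#'
#' @param x Centered numeric vector.
#' @param q Trim fraction per tail, in `[0, 0.5)`; default 0.02.
#' @return Logical mask, `TRUE` where the value should be treated as missing.
#' @export
trim_intensity_extremes <- function(x, q = 0.02) {
  stopifnot(q >= 0, q < 0.5)
  mask <- rep(FALSE, length(x))
  if (q == 0) return(mask)
  ok <- is.finite(x)
  if (!any(ok)) return(mask)
  lo <- quantile(x[ok], q, names = FALSE, type = 7)
  hi <- quantile(x[ok], 1 - q, names = FALSE, type = 7)
  mask[ok] <- x[ok] < lo | x[ok] > hi
  mask
}

#' Exponentiate centered Log2Ratios back to the ratio scale
#'
#' @param x Centered Log2Ratio vector or matrix.
#' @return `2^x`; strictly positive, NAs preserved.
#' @export
to_normalized_ratio <- function(x) 2^x

# 95% two-sided Dixon r10 critical values, n = 3..9.
.dixon_q95 <- c(`3` = 0.970, `4` = 0.829, `5` = 0.710, `6` = 0.625,
                `7` = 0.568, `8` = 0.526, `9` = 0.493)

#' Dixon Q test for a single replicate outlier
#'
#' Single-pass Q test (r10 statistic, 95% two-sided critical values) for 3-9
#' replicates: the more extreme of the two candidate values is removed when
#' its gap/range ratio exceeds the critical value. At most one value is
#' removed. A zero range leaves the sample untouched.
#'
#' @param x Numeric vector of 3 to 9 replicate values.
#' @return The retained values, in original order.
#' @export
dixon_q_outliers <- function(x) {
  n <- length(x)
  if (n < 3 || n > 9) stop("dixon_q_outliers: requires 3-9 values")
  rng <- max(x) - min(x)
  if (rng == 0) return(x)
  s <- sort(x)
  q_low <- (s[2] - s[1]) / rng
  q_high <- (s[n] - s[n - 1]) / rng
  q_crit <- .dixon_q95[[as.character(n)]]
  if (max(q_low, q_high) <= q_crit) return(x)
  drop_val <- if (q_low >= q_high) s[1] else s[n]
  x[-which(x == drop_val)[1]]
}

#' Peirce's criterion for replicate outliers
#'
#' Iterative maximum-allowable-deviation rule (Gould's formulation): for an
#' increasing count of doubtful observations, solve for the deviation ratio
#' R such that observations with |x - mean| > R * sd are rejected, until the
#' rejected count stops growing. Mean and sd are taken from the full sample.
#'
#' @param x Numeric vector, length >= 3 (intended for n >= 10).
#' @return The retained values, in original order.
#' @export
peirce_outliers <- function(x) {
  n <- length(x)
  if (n < 3) stop("peirce_outliers: requires at least 3 values")
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(x)
  dev <- abs(x - mean(x))
  removed <- 0L
  for (m in seq_len(n - 2)) {
    r <- .peirce_ratio(n, m)
    if (is.na(r)) break
    out <- dev > r * s
    if (sum(out) <= removed) break
    removed <- sum(out)
    if (removed <= m) break  # count consistent with assumed doubtful m
  }
  if (removed == 0) return(x)
  r <- .peirce_ratio(n, max(1L, min(removed, n - 2L)))
  x[dev <= r * s]
}

# Gould's iterative solution for Peirce's ratio R(n, m): the threshold in
# sample-sd units for m doubtful observations among n.
.peirce_ratio <- function(n, m) {
  if (n - m - 1 <= 0) return(NA_real_)
  log_q <- (m * log(m) + (n - m) * log(n - m) - n * log(n)) / n
  x2 <- 1
  r_old <- Inf
  for (iter in 1:200) {
    lambda <- exp((n * log_q - m * ((x2 - 1) / 2 +
                   log(2 * pnorm(sqrt(x2), lower.tail = FALSE)))) / (n - m))
    # lambda above folds in R = exp((x^2-1)/2) * erfc(x/sqrt 2); iterate x^2
    x2_new <- 1 + (n - m - 1) / m * (1 - lambda^2)
    if (!is.finite(x2_new) || x2_new <= 0) return(NA_real_)
    if (abs(x2_new - x2) < 1e-10) { x2 <- x2_new; break }
    x2 <- x2_new
    r_old <- lambda
  }
  sqrt(x2)
}

#' Remove replicate outliers with the test matched to sample size
#'
#' Dispatch rule: fewer than 3 replicates are returned unchanged (the tests
#' are undefined), 3-9 go to the Dixon Q test, 10 or more to Peirce's
#' criterion.
#'
#' @param x Numeric vector of replicate values (NAs dropped first).
#' @return The retained values.
#' @export
remove_outliers <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(x)
  if (n <= 9) dixon_q_outliers(x) else peirce_outliers(x)
}

#' Normalize a Log2Ratio matrix array by array
#'
#' For each array (column): median/MAD centering, masking of the `trim_q`
#' most extreme values in each tail, and exponentiation to the normalized
#' Ratio scale. Arrays with MAD 0 or fewer than 2 finite values are dropped
#' with a warning.
#'
#' @param log2ratio Numeric matrix, genes x arrays, NAs for missing.
#' @param trim_q Per-tail trim fraction; default 0.02.
#' @return Matrix of normalized Ratios (same rownames; possibly fewer
#'   columns), masked entries set to NA.
#' @export
normalize_arrays <- function(log2ratio, trim_q = 0.02) {
  stopifnot(is.matrix(log2ratio))
  out <- matrix(NA_real_, nrow(log2ratio), ncol(log2ratio),
                dimnames = dimnames(log2ratio))
  keep <- logical(ncol(log2ratio))
  for (j in seq_len(ncol(log2ratio))) {
    centered <- tryCatch(center_array(log2ratio[, j]), error = function(e) NULL)
    if (is.null(centered)) next
    keep[j] <- TRUE
    centered[trim_intensity_extremes(centered, trim_q)] <- NA_real_
    out[, j] <- to_normalized_ratio(centered)
  }
  if (!all(keep))
    warning(sprintf("dropped %d degenerate array(s): %s", sum(!keep),
                    paste(colnames(log2ratio)[!keep], collapse = ", ")))
  out[, keep, drop = FALSE]
}

#' Collapse replicate arrays into per-gene expression profiles
#'
#' Per gene and time point, replicate values are screened for outliers
#' ([remove_outliers()]) and averaged; the per-time-point coefficient of
#' variation (sd/mean of retained replicates) and retained replicate count
#' are recorded. Time points with no surviving value are missing (NA).
#'
#' @param ratios Normalized Ratio matrix (genes x arrays) from
#'   [normalize_arrays()].
#' @param meta Data frame with columns `array_id`, `time_label`,
#'   `replicate`; one row per array column of `ratios`.
#' @param grid A [time_grid()].
#' @return A `profile_set`: list with matrices `values`, `cv`, `n_used`
#'   (genes x time points) and the `grid`.
#' @export
average_replicates <- function(ratios, meta, grid = time_grid()) {
  stopifnot(is.matrix(ratios), all(c("array_id", "time_label", "replicate")
                                   %in% names(meta)))
  missing_arrays <- setdiff(colnames(ratios), meta$array_id)
  if (length(missing_arrays))
    stop("arrays without metadata: ", paste(missing_arrays, collapse = ", "))
  if (anyDuplicated(meta[, c("time_label", "replicate")]))
    stop("duplicate (time_label, replicate) pairs in metadata")
  nt <- nrow(grid)
  ng <- nrow(ratios)
  values <- cv <- matrix(NA_real_, ng, nt,
                         dimnames = list(rownames(ratios), grid$label))
  n_used <- matrix(0L, ng, nt, dimnames = dimnames(values))
  for (k in seq_len(nt)) {
    cols <- meta$array_id[meta$time_label == grid$label[k]]
    cols <- intersect(cols, colnames(ratios))
    if (!length(cols)) next
    sub <- ratios[, cols, drop = FALSE]
    for (g in seq_len(ng)) {
      kept <- remove_outliers(sub[g, ])
      if (!length(kept)) next
      values[g, k] <- mean(kept)
      n_used[g, k] <- length(kept)
      if (length(kept) >= 2 && mean(kept) != 0)
        cv[g, k] <- sd(kept) / mean(kept)
    }
  }
  all_missing <- rowSums(!is.na(values)) == 0
  if (any(all_missing)) {
    warning(sprintf("%d gene(s) with no values at any time point omitted",
                    sum(all_missing)))
    values <- values[!all_missing, , drop = FALSE]
    cv <- cv[!all_missing, , drop = FALSE]
    n_used <- n_used[!all_missing, , drop = FALSE]
  }
  profile_set(values, cv = cv, n_used = n_used, grid = grid)
}

#' Construct a profile set
#'
#' Container for per-gene expression profiles over a common time grid, with
#' optional replicate coefficient-of-variation and replicate-count matrices.
#'
#' @param values Numeric matrix, genes x time points, NA for missing.
#' @param cv Optional matrix of per-time-point coefficients of variation.
#' @param n_used Optional integer matrix of retained replicate counts.
#' @param grid A [time_grid()] whose length matches `ncol(values)`.
#' @param incomplete Optional logical vector flagging profiles with
#'   boundary gaps left after interpolation.
#' @return A `profile_set` object.
#' @export
profile_set <- function(values, cv = NULL, n_used = NULL, grid = time_grid(),
                        incomplete = NULL) {
  stopifnot(is.matrix(values), ncol(values) == nrow(grid))
  if (any(values < 0, na.rm = TRUE))
    stop("profile values must be non-negative where present")
  structure(list(values = values, cv = cv, n_used = n_used, grid = grid,
                 incomplete = incomplete %||%
                   setNames(rep(FALSE, nrow(values)), rownames(values))),
            class = "profile_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("profile_set: %d gene(s) x %d time point(s), %d incomplete\n",
              nrow(x$values), ncol(x$values), sum(x$incomplete)))
  invisible(x)
}

#' Linearly interpolate interior missing values of profiles
#'
#' A missing time point flanked by present values on both sides is filled by
#' linear interpolation in time (runs of consecutive interior gaps are
#' interpolated along the same segment). Leading or trailing gaps are left
#' missing and the profile is flagged incomplete.
#'
#' @param profiles A `profile_set`.
#' @return The `profile_set` with interior gaps filled and the `incomplete`
#'   flag updated; present values are unchanged.
#' @export
fill_internal_gaps <- function(profiles) {
  v <- profiles$values
  hours <- profiles$grid$hours
  incomplete <- logical(nrow(v))
  for (g in seq_len(nrow(v))) {
    y <- v[g, ]
    ok <- !is.na(y)
    if (all(ok) || sum(ok) < 2) {
      incomplete[g] <- !all(ok)
      next
    }
    interior <- !ok & seq_along(y) > min(which(ok)) & seq_along(y) < max(which(ok))
    if (any(interior))
      y[interior] <- approx(hours[ok], y[ok], xout = hours[interior])$y
    v[g, ] <- y
    incomplete[g] <- any(is.na(y))
  }
  profiles$values <- v
  profiles$incomplete <- setNames(incomplete, rownames(v))
  profiles
}

#' @importFrom stats pnorm
NULL
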