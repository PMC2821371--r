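#' SAM test configuration
#'
#' Settings for the two-class unpaired SAM (Significance Analysis of
#' Microarrays) permutation test: the permutation design, the fudge-factor
#' (s0) selection strategy, the delta grid scanned for the FDR curve, and
#' the target false discovery rate used to set called flags.
#'
#' @param n_permutations Number of distinct label arrangements sampled
#'   without replacement when enumeration is not feasible (default 1000;
#'   must be >= 100).
#' @param seed Integer seed for permutation sampling.
#' @param s0_strategy Either \code{"cv_minimization"} (the classic SAM
#'   selection: pick the s percentile minimizing the coefficient of
#'   variation of the d spreads across s-quantile windows) or
#'   \code{list(fixed_percentile = q)} with \code{q} in [0, 1].
#' @param target_fdr FDR at which called flags are set (default 0.05).
#' @param delta_grid Strictly increasing positive thresholds; \code{NULL}
#'   (default) builds an even grid over the observed range of
#'   \code{|d - dbar|}.
#' @param fdr_statistic \code{"median"} (default) or \code{"mean"}: summary
#'   over permutations of the false-call count.
#' @param exhaustive_cap Enumerate all label arrangements when their number
#'   is at most this cap (default 50000, which covers a 9-vs-9 design:
#'   choose(18, 9) = 48620).
#' @param include_original Include the observed labelling among the
#'   permutations (default TRUE).
#' @return A list of class \code{"sam_config"}.
#' @export
sam_config <- function(n_permutations = 1000L, seed = 1L,
                       s0_strategy = "cv_minimization",
                       target_fdr = 0.05, delta_grid = NULL,
                       fdr_statistic = c("median", "mean"),
                       exhaustive_cap = 50000L,
                       include_original = TRUE) {
  fdr_statistic <- match.arg(fdr_statistic)
  if (n_permutations < 100L)
    stop("n_permutations must be >= 100 (exhaustive enumeration is used automatically when feasible)")
  if (!is.null(delta_grid)) {
    if (any(delta_grid <= 0) || is.unsorted(delta_grid, strictly = TRUE))
      stop("delta_grid must be strictly increasing and positive")
  }
  if (!(target_fdr > 0 && target_fdr < 1))
    stop("target_fdr must be in (0, 1)")
  ok_strategy <- identical(s0_strategy, "cv_minimization") ||
    (is.list(s0_strategy) && identical(names(s0_strategy), "fixed_percentile"))
  if (!ok_strategy)
    stop("s0_strategy must be \"cv_minimization\" or list(fixed_percentile = q)")
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 s0_strategy = s0_strategy,
                 target_fdr = target_fdr,
                 delta_grid = delta_grid,
                 fdr_statistic = fdr_statistic,
                 exhaustive_cap = as.integer(exhaustive_cap),
                 include_original = include_original),
            class = "sam_config")
}

#' SAM relative difference
#'
#' The moderated t-like statistic d = (mean_male - mean_female) / (s + s0),
#' where s is the pooled standard-error scatter
#' \code{sqrt((1/n_M + 1/n_F) * (SS_M + SS_F) / (n_M + n_F - 2))}.
#'
#' @param mean_a,mean_b Group means (vectors allowed).
#' @param s Pooled scatter per probeset (see \code{\link{pooled_scatter}}).
#' @param s0 Scalar fudge factor, >= 0.
#' @return d values; sign follows \code{mean_a - mean_b}.
#' @export
relative_difference <- function(mean_a, mean_b, s, s0) {
  if (any(s + s0 <= 0))
    stop("zero denominator: all values identical and s0 = 0")
  (mean_a - mean_b) / (s + s0)
}

#' Pooled standard-error scatter of a two-group comparison
#'
#' @param x Numeric matrix (probesets x samples), typically log2 scale.
#' @param group_a,group_b Logical or integer column indices of the two
#'   groups (each of size >= 2).
#' @return List with \code{mean_a}, \code{mean_b}, \code{s} per row.
#' @export
pooled_scatter <- function(x, group_a, group_b) {
  xa <- x[, group_a, drop = FALSE]
  xb <- x[, group_b, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  if (na < 2L || nb < 2L) stop("each group needs >= 2 samples")
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  ssa <- rowSums((xa - ma)^2)
  ssb <- rowSums((xb - mb)^2)
  s <- sqrt((1 / na + 1 / nb) * (ssa + ssb) / (na + nb - 2))
  list(mean_a = ma, mean_b = mb, s = s)
}

#' Select the SAM fudge factor s0
#'
#' \code{cv_minimization}: candidate s0 values are the \{0, 5, ..., 95\}
#' percentiles of s; for each candidate the probesets are partitioned into
#' 100 s-quantile windows, the median absolute deviation of d within each
#' window is computed, and the candidate minimizing the coefficient of
#' variation of those 100 spreads is chosen (ties broken towards the
#' smallest candidate). \code{fixed_percentile}: s0 is the q-th percentile
#' of s.
#'
#' @param numerator Per-probeset mean difference (d numerator).
#' @param s Per-probeset pooled scatter.
#' @param strategy \code{"cv_minimization"} or
#'   \code{list(fixed_percentile = q)}.
#' @return Scalar s0.
#' @export
choose_s0 <- function(numerator, s, strategy = "cv_minimization") {
  if (is.list(strategy) && !is.null(strategy$fixed_percentile)) {
    q <- strategy$fixed_percentile
    stopifnot(q >= 0, q <= 1)
    return(unname(stats::quantile(s, q)))
  }
  if (!identical(strategy, "cv_minimization"))
    stop("unknown s0 strategy")
  if (length(s) < 100L)
    stop("cv_minimization needs >= 100 probesets; use list(fixed_percentile = q)")
  if (stats::sd(s) == 0)
    warning("degenerate scatter (all s equal); ties resolve to the 0th percentile")
  candidates <- unname(stats::quantile(s, seq(0, 0.95, by = 0.05)))
  n_windows <- 100L
  win <- cut(rank(s, ties.method = "first"),
             breaks = n_windows, labels = FALSE)
  cv <- vapply(candidates, function(alpha) {
    d_alpha <- numerator / (s + alpha)
    spreads <- tapply(d_alpha, win, stats::mad)
    stats::sd(spreads) / mean(spreads)
  }, numeric(1))
  candidates[which.min(cv)]  # which.min takes the first (smallest) on ties
}

#' Permutation null of the SAM statistic
#'
#' Builds the permutation distribution of d over distinct relabellings of
#' the samples: all \code{choose(n, n_male)} arrangements when that number
#' is at most \code{exhaustive_cap}, otherwise \code{n_permutations}
#' distinct arrangements sampled uniformly without replacement (seeded).
#' The expected order statistics \code{dbar[i]} are the means over
#' permutations of the i-th smallest d.
#'
#' @param x Numeric matrix (probesets x samples), log2 scale.
#' @param male Logical vector marking the male columns.
#' @param s0 Fudge factor (held fixed across permutations).
#' @param config A \code{\link{sam_config}}.
#' @return List with \code{d_sorted} (probesets x permutations matrix of
#'   column-sorted permuted d), \code{dbar}, \code{n_perm},
#'   \code{exhaustive}.
#' @export
permutation_null <- function(x, male, s0, config = sam_config()) {
  n <- ncol(x)
  n_m <- sum(male)
  n_arrangements <- choose(n, n_m)
  if (n_arrangements < 4)
    stop("fewer than 4 distinct label arrangements; permutation test not meaningful")
  if (n_arrangements < 10)
    warning("fewer than 10 distinct label arrangements; FDR estimates will be coarse")
  exhaustive <- n_arrangements <= config$exhaustive_cap
  if (exhaustive) {
    arr <- utils::combn(n, n_m)
  } else {
    n_wanted <- min(config$n_permutations, n_arrangements)
    arr <- sample_arrangements(n, n_m, n_wanted, config$seed,
                               original = if (config$include_original)
                                 which(male) else NULL)
  }
  n_perm <- ncol(arr)
  n_probes <- nrow(x)

  x2 <- x^2
  n_f <- n - n_m
  d_sorted <- matrix(NA_real_, n_probes, n_perm)
  block <- max(1L, min(n_perm, floor(2e7 / n_probes)))
  for (start in seq(1L, n_perm, by = block)) {
    cols <- start:min(start + block - 1L, n_perm)
    w <- matrix(0, n, length(cols))
    w[arr[, cols, drop = FALSE] +
        rep((seq_along(cols) - 1L) * n, each = n_m)] <- 1
    sum_m <- x %*% w
    sum2_m <- x2 %*% w
    mean_m <- sum_m / n_m
    mean_f <- (rowSums(x) - sum_m) / n_f
    ss_m <- sum2_m - n_m * mean_m^2
    ss_f <- (rowSums(x2) - sum2_m) - n_f * mean_f^2
    ss_m[ss_m < 0] <- 0  # numerical guard
    ss_f[ss_f < 0] <- 0
    s <- sqrt((1 / n_m + 1 / n_f) * (ss_m + ss_f) / (n - 2))
    d <- (mean_m - mean_f) / (s + s0)
    for (j in seq_along(cols))
      d_sorted[, cols[j]] <- sort.int(d[, j], method = "quick")
  }
  list(d_sorted = d_sorted,
       dbar = rowMeans(d_sorted),
       n_perm = n_perm,
       exhaustive = exhaustive)
}

# Distinct label arrangements sampled uniformly without replacement.
sample_arrangements <- function(n, n_m, n_wanted, seed, original = NULL) {
  set.seed(seed)
  seen <- new.env(hash = TRUE)
  out <- vector("list", n_wanted)
  k <- 0L
  if (!is.null(original)) {
    key <- paste(sort(original), collapse = ",")
    assign(key, TRUE, envir = seen)
    k <- 1L
    out[[1L]] <- sort(original)
  }
  guard <- 0L
  while (k < n_wanted) {
    guard <- guard + 1L
    if (guard > 200L * n_wanted)
      stop("could not sample enough distinct arrangements")
    cand <- sort(sample.int(n, n_m))
    key <- paste(cand, collapse = ",")
    if (!exists(key, envir = seen, inherits = FALSE)) {
      assign(key, TRUE, envir = seen)
      k <- k + 1L
      out[[k]] <- cand
    }
  }
  matrix(unlist(out), nrow = n_m)
}

#' Apply the SAM delta-threshold calling rule
#'
#' Given observed d sorted ascending and the expected order statistics
#' dbar, the upper cutoff is the smallest \code{d[i]} with
#' \code{d[i] - dbar[i] >= delta}; all probesets with d at or above it are
#' called positive. The lower cutoff is the largest \code{d[i]} with
#' \code{d[i] - dbar[i] <= -delta}; probesets at or below it are called
#' negative. A side with no crossing yields no calls.
#'
#' @param d_sorted Observed d, ascending.
#' @param dbar Expected order statistics (same length).
#' @param delta Positive threshold.
#' @return List with \code{cut_up}, \code{cut_low} (Inf/-Inf when no
#'   crossing) and logical index vectors \code{called_pos},
#'   \code{called_neg} relative to \code{d_sorted}.
#' @export
call_at_delta <- function(d_sorted, dbar, delta) {
  stopifnot(length(d_sorted) == length(dbar))
  gap <- d_sorted - dbar
  up_idx <- which(gap >= delta)
  cut_up <- if (length(up_idx)) min(d_sorted[up_idx]) else Inf
  low_idx <- which(gap <= -delta)
  cut_low <- if (length(low_idx)) max(d_sorted[low_idx]) else -Inf
  list(cut_up = cut_up, cut_low = cut_low,
       called_pos = d_sorted >= cut_up,
       called_neg = d_sorted <= cut_low)
}

#' Two-class unpaired SAM test with permutation FDR and q-values
#'
#' Runs the full SAM pipeline on an expression dataset: log2 transform
#' (with clip floor), relative differences with a data-driven fudge
#' factor, the permutation null over sex-label arrangements, the
#' delta-threshold FDR curve, per-probeset q-values (the smallest FDR at
#' which a probeset is called), and directional called flags at
#' \code{target_fdr}. The FDR at a delta is the median (or mean) over
#' permutations of the number of permuted d values outside the cutoffs,
#' divided by the number of called probesets, capped at 1.
#'
#' @param ds An \code{\link{expression_dataset}} with >= 2 samples per sex.
#' @param config A \code{\link{sam_config}}.
#' @param floor_intensity Clip floor applied before the log2 transform and
#'   in the linear fold change (default 1.0).
#' @return Object of class \code{"sam_result"}: list with \code{table}
#'   (data.frame: probeset_id, d, s, fold_change, q_value, called_positive,
#'   called_negative), \code{delta_table} (delta, n_called, n_false, fdr),
#'   \code{s0}, \code{chosen_delta} (NA if no delta meets target_fdr),
#'   \code{dbar}, \code{d_order} (row order by ascending d),
#'   \code{n_permutations}, \code{exhaustive}.
#' @export
sam_test <- function(ds, config = sam_config(), floor_intensity = 1.0) {
  stopifnot(inherits(ds, "expression_dataset"))
  male <- ds$sex == "male"
  if (sum(male) < 2L || sum(!male) < 2L)
    stop("SAM needs >= 2 samples per sex")
  xlin <- pmax(ds$intensities, floor_intensity)
  x <- log2(xlin)

  ps <- pooled_scatter(x, male, !male)
  s0 <- choose_s0(ps$mean_a - ps$mean_b, ps$s, config$s0_strategy)
  d <- relative_difference(ps$mean_a, ps$mean_b, ps$s, s0)

  null <- permutation_null(x, male, s0, config)
  dbar <- null$dbar

  # ties in d broken by probeset id for a deterministic order
  ord <- order(d, ds$probeset_ids)
  d_sorted <- d[ord]

  delta_grid <- config$delta_grid
  if (is.null(delta_grid)) {
    max_gap <- max(abs(d_sorted - dbar))
    if (max_gap <= 0) max_gap <- 1e-8
    delta_grid <- seq(0, max_gap, length.out = 41L)[-1L]
  }

  summarize <- if (config$fdr_statistic == "median") stats::median else mean
  n_delta <- length(delta_grid)
  n_called <- integer(n_delta)
  n_false <- numeric(n_delta)
  fdr <- numeric(n_delta)
  cuts <- vector("list", n_delta)
  for (j in seq_len(n_delta)) {
    cl <- call_at_delta(d_sorted, dbar, delta_grid[j])
    cuts[[j]] <- cl
    n_called[j] <- sum(cl$called_pos) + sum(cl$called_neg)
    if (n_called[j] == 0L) {
      n_false[j] <- 0
      fdr[j] <- 0
      next
    }
    counts <- count_outside(null$d_sorted, cl$cut_low, cl$cut_up)
    n_false[j] <- summarize(counts)
    fdr[j] <- min(1, n_false[j] / n_called[j])
  }

  # q-value: smallest FDR among the deltas at which the probeset is called
  q_sorted <- rep(1, length(d_sorted))
  for (j in seq_len(n_delta)) {
    called <- cuts[[j]]$called_pos | cuts[[j]]$called_neg
    q_sorted[called] <- pmin(q_sorted[called], fdr[j])
  }

  ok <- which(fdr <= config$target_fdr & n_called > 0L)
  chosen <- if (length(ok)) ok[1L] else NA_integer_
  called_pos_sorted <- logical(length(d_sorted))
  called_neg_sorted <- logical(length(d_sorted))
  if (!is.na(chosen)) {
    called_pos_sorted <- cuts[[chosen]]$called_pos
    called_neg_sorted <- cuts[[chosen]]$called_neg
  }

  # map back from d-sorted order to input row order
  unsort <- order(ord)
  mf <- rowMeans(xlin[, male, drop = FALSE]) /
    rowMeans(xlin[, !male, drop = FALSE])

  structure(list(
    table = data.frame(probeset_id = ds$probeset_ids,
                       d = d,
                       s = ps$s,
                       fold_change = mf,
                       q_value = q_sorted[unsort],
                       called_positive = called_pos_sorted[unsort],
                       called_negative = called_neg_sorted[unsort],
                       row.names = NULL,
                       stringsAsFactors = FALSE),
    delta_table = data.frame(delta = delta_grid, n_called = n_called,
                             n_false = n_false, fdr = fdr),
    s0 = s0,
    chosen_delta = if (is.na(chosen)) NA_real_ else delta_grid[chosen],
    dbar = dbar,
    d_order = ord,
    n_permutations = null$n_perm,
    exhaustive = null$exhaustive), class = "sam_result")
}

# Per-permutation count of d values outside (cut_low, cut_up); columns of
# d_sorted are ascending, so binary search suffices.
count_outside <- function(d_sorted_mat, cut_low, cut_up) {
  n <- nrow(d_sorted_mat)
  vapply(seq_len(ncol(d_sorted_mat)), function(j) {
    v <- d_sorted_mat[, j]
    n_low <- if (cut_low == -Inf) 0L else findInterval(cut_low, v)
    n_up <- if (cut_up == Inf) 0L else n - findInterval(cut_up - 1e-12, v)
    n_low + n_up
  }, integer(1))
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf("sam_result: %d probesets, %d permutations%s, s0 = %.4g\n",
              nrow(x$table), x$n_permutations,
              if (x$exhaustive) " (exhaustive)" else "", x$s0))
  cat(sprintf("  called at target FDR: %d positive, %d negative (delta = %s)\n",
              sum(x$table$called_positive), sum(x$table$called_negative),
              format(x$chosen_delta)))
  invisible(x)
}
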