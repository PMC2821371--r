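#' Positional running average
#'
#' Sliding boxcar over probesets ordered by chromosomal position: each
#' window holds exactly \code{window} consecutive probesets (step 1), its
#' value is the arithmetic mean of their values and its position the
#' median of their positions (mean of the two central positions for an
#' even window). Position ties are broken by probeset id so profiles are
#' deterministic; input row order does not matter.
#'
#' @param positions Base-pair positions (length n).
#' @param values Values to average (e.g. log2 M:F ratios).
#' @param window Window size (default 30, the study's choice).
#' @param ids Optional probeset ids used only to break position ties.
#' @return Data.frame of class \code{"profile_points"}: \code{window_index},
#'   \code{position_bp} (median of the window), \code{value}; \code{n -
#'   window + 1} rows.
#' @export
running_average <- function(positions, values, window = 30, ids = NULL) {
  stopifnot(length(positions) == length(values), window >= 1)
  keep <- !is.na(positions) & !is.na(values)
  if (any(!keep))
    message(sum(!keep), " probeset(s) without position dropped from profile")
  positions <- positions[keep]
  values <- values[keep]
  ids <- if (is.null(ids)) seq_along(positions) else ids[keep]
  n <- length(positions)
  if (n < window)
    stop(sprintf("need >= %d positioned probesets for window %d; use a smaller window",
                 window, window))
  ord <- order(positions, ids)
  positions <- positions[ord]
  values <- values[ord]

  n_out <- n - window + 1L
  # windowed mean via cumulative sums
  cs <- c(0, cumsum(values))
  mean_v <- (cs[(window + 1):(n + 1)] - cs[1:n_out]) / window
  mid <- (window + 1) / 2
  med_pos <- if (window %% 2 == 1) {
    positions[seq_len(n_out) + mid - 1]
  } else {
    (positions[seq_len(n_out) + window / 2 - 1] +
       positions[seq_len(n_out) + window / 2]) / 2
  }
  out <- data.frame(window_index = seq_len(n_out),
                    position_bp = med_pos,
                    value = mean_v)
  class(out) <- c("profile_points", "data.frame")
  out
}

#' Amplitude profile along a chromosome
#'
#' Running average of \code{|log2 ratio|}; a direction-free measure of
#' departure from parity, so a compensated region shows a valley whether
#' its residual biases are male- or female-ward.
#'
#' @inheritParams running_average
#' @param log2_ratios Per-probeset log2(M:F) values.
#' @return As \code{\link{running_average}}.
#' @export
amplitude_profile <- function(positions, log2_ratios, window = 30, ids = NULL) {
  running_average(positions, abs(log2_ratios), window = window, ids = ids)
}

#' Distribution of log2 ratios
#'
#' Histogram of log2(M:F) values normalized to percent, with simple mode
#' detection (bins strictly higher than both neighbours).
#'
#' @param log2_ratios Numeric vector (n >= 1).
#' @param bin_width Bin width in log2 units (default 0.1).
#' @return List of class \code{"ratio_distribution"}: \code{bin_centers},
#'   \code{percent_per_bin}, \code{modes} (bin centers of local maxima).
#' @export
ratio_distribution <- function(log2_ratios, bin_width = 0.1) {
  stopifnot(length(log2_ratios) >= 1, bin_width > 0)
  lo <- floor(min(log2_ratios) / bin_width) * bin_width
  hi <- ceiling(max(log2_ratios) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  h <- hist(log2_ratios, breaks = breaks, plot = FALSE)
  pct <- 100 * h$counts / length(log2_ratios)
  k <- length(pct)
  is_mode <- if (k >= 3) {
    c(FALSE, pct[2:(k - 1)] > pct[1:(k - 2)] & pct[2:(k - 1)] > pct[3:k], FALSE)
  } else rep(pct == max(pct), length.out = k) & k == 1
  structure(list(bin_centers = h$mids,
                 percent_per_bin = pct,
                 modes = h$mids[is_mode]),
            class = "ratio_distribution")
}

#' Contrast a chromosomal region against the rest of the chromosome
#'
#' Compares per-probeset values (log2 ratios, amplitudes, or a 0/1
#' compensated indicator) inside a declared region against those outside
#' it. Numeric values are compared with \code{\link{rank_sum_compare}};
#' binary class indicators with \code{\link{overlap_significance}} (is the
#' in-region overlap of the class larger than chance?).
#'
#' @param values Per-probeset values, or a logical class indicator.
#' @param positions Matching base-pair positions.
#' @param region \code{c(start_bp, end_bp)}, inclusive.
#' @param ids Optional probeset ids (needed for the indicator mode).
#' @param alternative Passed to \code{\link{rank_sum_compare}} for the
#'   numeric mode (default \code{"two.sided"}).
#' @param n_sims,seed Overlap-test settings for the indicator mode.
#' @param min_inside Minimum probesets required inside the region
#'   (default 5).
#' @return List with \code{inside_mean}, \code{outside_mean},
#'   \code{n_inside}, \code{n_outside}, \code{p_value}.
#' @export
region_contrast <- function(values, positions, region, ids = NULL,
                            alternative = "two.sided",
                            n_sims = 10000, seed = 1L, min_inside = 5L) {
  stopifnot(length(values) == length(positions), length(region) == 2,
            region[1] < region[2])
  keep <- !is.na(positions)
  values <- values[keep]
  positions <- positions[keep]
  if (is.null(ids)) ids <- paste0("p", seq_along(values)) else ids <- ids[keep]
  inside <- positions >= region[1] & positions <= region[2]
  if (sum(inside) < min_inside)
    stop(sprintf("region holds %d probesets; need >= %d", sum(inside), min_inside))
  if (!any(!inside))
    stop("region covers the whole chromosome; nothing outside to contrast")

  if (is.logical(values)) {
    res <- overlap_significance(set_a = ids[inside], set_b = ids[values],
                                universe = ids, n_sims = n_sims, seed = seed)
    p <- res$empirical_p
  } else {
    p <- rank_sum_compare(values[inside], values[!inside],
                          alternative = alternative)$p_value
  }
  list(inside_mean = mean(values[inside]),
       outside_mean = mean(values[!inside]),
       n_inside = sum(inside),
       n_outside = sum(!inside),
       p_value = p)
}
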