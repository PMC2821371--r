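#' Present-call detection filter
#'
#' Retains probesets called \code{Present} in at least
#' \code{ceiling(min_present_fraction * n_samples)} samples, the classic
#' "Present in at least half of the arrays" rule (9 of 18 at the default
#' fraction of 0.5). Marginal calls do not count as Present. Row order is
#' preserved.
#'
#' @param ds An \code{\link{expression_dataset}}.
#' @param min_present_fraction Fraction of samples in (0, 1]; default 0.5.
#' @return The filtered \code{expression_dataset}; the number of retained
#'   probesets and the applied threshold are attached as attributes
#'   \code{"n_retained"} and \code{"present_threshold"}.
#' @export
detection_filter <- function(ds, min_present_fraction = 0.5) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!(min_present_fraction > 0 && min_present_fraction <= 1))
    stop("min_present_fraction must be in (0, 1]")
  threshold <- ceiling(min_present_fraction * n_samples(ds))
  n_present <- rowSums(ds$detection == "Present")
  keep <- n_present >= threshold
  if (!any(keep))
    warning("detection filter retained no probesets")
  out <- expression_dataset(ds$intensities[keep, , drop = FALSE],
                            ds$detection[keep, , drop = FALSE],
                            ds$sex)
  attr(out, "n_retained") <- sum(keep)
  attr(out, "present_threshold") <- threshold
  out
}

#' Per-probeset male:female expression ratios
#'
#' Computes, for every probeset, the linear-scale mean over male samples
#' and over female samples (after clipping intensities below
#' \code{floor_intensity} up to it) and the ratio of those means -- ratio
#' of means, not mean of ratios. \code{log2_mf} is \code{log2} of the M:F
#' ratio and \code{fm_ratio} its reciprocal.
#'
#' @param ds An \code{\link{expression_dataset}} with both sexes present.
#' @param floor_intensity Positive clip floor (default 1.0) guarding
#'   against division blow-ups on near-zero values.
#' @return Data frame with columns \code{probeset_id}, \code{mean_male},
#'   \code{mean_female}, \code{mf_ratio}, \code{log2_mf}, \code{fm_ratio}.
#' @export
sex_ratios <- function(ds, floor_intensity = 1.0) {
  stopifnot(inherits(ds, "expression_dataset"), floor_intensity > 0)
  males <- ds$sex == "male"
  females <- ds$sex == "female"
  if (!any(males) || !any(females))
    stop("both sexes must be represented to compute M:F ratios")
  x <- pmax(ds$intensities, floor_intensity)
  mean_male <- rowMeans(x[, males, drop = FALSE])
  mean_female <- rowMeans(x[, females, drop = FALSE])
  mf <- mean_male / mean_female
  data.frame(probeset_id = ds$probeset_ids,
             mean_male = mean_male,
             mean_female = mean_female,
             mf_ratio = mf,
             log2_mf = log2(mf),
             fm_ratio = 1 / mf,
             row.names = NULL,
             stringsAsFactors = FALSE)
}
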