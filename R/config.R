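#' Pipeline run configuration
#'
#' Collects every tunable threshold of the pipeline with the study's
#' defaults: the Present-call filter fraction (one half of the samples),
#' SAM settings (5\% target FDR), the ratio bands (male-biased 1.5--3.2,
#' compensated 0.8--1.3, non-compensated >= 1.5), the running-average
#' window of 30 consecutive ratios, the 10000-draw overlap simulation, and
#' the enrichment background mode.
#'
#' @param filter List: \code{min_present_fraction} (default 0.5).
#' @param sam List passed to \code{\link{sam_config}}.
#' @param bands List: \code{biased_min} (1.5), \code{biased_max} (3.2),
#'   \code{comp_lo} (0.8), \code{comp_hi} (1.3), \code{noncomp_min} (1.5).
#'   Band endpoints are inclusive.
#' @param profile List: \code{window} (30), optional
#'   \code{region_of_interest} as \code{c(start_bp, end_bp)}.
#' @param overlap List: \code{n_sims} (10000), \code{seed}.
#' @param enrichment List: \code{background_mode} in \code{"genome"} /
#'   \code{"transcriptome"}, \code{seed} (for probeset-to-gene tie breaks).
#' @return A validated list of class \code{"run_config"}.
#' @export
run_config <- function(filter = list(), sam = list(), bands = list(),
                       profile = list(), overlap = list(),
                       enrichment = list()) {
  merge_defaults <- function(user, defaults) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    utils::modifyList(defaults, user)
  }
  cfg <- list(
    filter = merge_defaults(filter, list(min_present_fraction = 0.5)),
    sam = do.call(sam_config, sam),
    bands = merge_defaults(bands, list(biased_min = 1.5, biased_max = 3.2,
                                       comp_lo = 0.8, comp_hi = 1.3,
                                       noncomp_min = 1.5)),
    profile = merge_defaults(profile, list(window = 30,
                                           region_of_interest = NULL)),
    overlap = merge_defaults(overlap, list(n_sims = 10000, seed = 1L)),
    enrichment = merge_defaults(enrichment,
                                list(background_mode = "transcriptome",
                                     seed = 1L)))
  with(cfg$bands, {
    if (any(c(biased_min, biased_max, comp_lo, comp_hi, noncomp_min) <= 0))
      stop("all ratio thresholds must be positive")
    if (!(comp_lo < comp_hi && comp_hi < noncomp_min))
      stop("bands must satisfy comp_lo < comp_hi < noncomp_min")
  })
  f <- cfg$filter$min_present_fraction
  if (!(f > 0 && f <= 1))
    stop("min_present_fraction must be in (0, 1]")
  if (!cfg$enrichment$background_mode %in% c("genome", "transcriptome"))
    stop("background_mode must be 'genome' or 'transcriptome'")
  if (cfg$overlap$n_sims < 1000)
    stop("overlap n_sims must be >= 1000")
  structure(cfg, class = "run_config")
}
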