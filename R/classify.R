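#' Two-stage sex-bias classification
#'
#' Applies the study's funnel: a probeset is a candidate if it is
#' FDR-significant in the given direction (SAM called flag), and it is
#' dimorphically biased if, in addition, its ratio clears the band. For the
#' male direction the band is \code{mf_ratio > biased_min} (and
#' \code{< biased_max} when the upper bound is enabled); for the female
#' direction the analogous rule on \code{fm_ratio} (no upper bound). Both
#' stage counts are reported so the FDR-stage and ratio-stage lists can be
#' compared (e.g. 406 significant, 275 biased).
#'
#' @param sam A \code{\link{sam_test}} result.
#' @param ratios Output of \code{\link{sex_ratios}} on the same probesets.
#' @param bands List with \code{biased_min} (default 1.5) and
#'   \code{biased_max} (default 3.2).
#' @param use_upper_bound Apply \code{biased_max} to the male band (default
#'   TRUE, as in the dimorphic male-biased list); never applied to the
#'   female band.
#' @return Object of class \code{"bias_calls"}: data.frame with
#'   \code{probeset_id}, \code{direction} in \{male, female, none\},
#'   \code{passed_fdr}, \code{passed_ratio}, \code{mf_ratio}; stage counts
#'   in \code{attr(, "funnel")}.
#' @export
classify_bias <- function(sam, ratios, bands = list(biased_min = 1.5,
                                                    biased_max = 3.2),
                          use_upper_bound = TRUE) {
  tab <- if (inherits(sam, "sam_result")) sam$table else sam
  if (!setequal(tab$probeset_id, ratios$probeset_id))
    stop("sam result and ratios must share the same probeset universe")
  ratios <- ratios[match(tab$probeset_id, ratios$probeset_id), ]

  sig_male <- tab$called_positive
  sig_female <- tab$called_negative
  in_male_band <- ratios$mf_ratio > bands$biased_min &
    (!use_upper_bound | ratios$mf_ratio < bands$biased_max)
  in_female_band <- ratios$fm_ratio > bands$biased_min

  direction <- rep("none", nrow(tab))
  direction[sig_male & in_male_band] <- "male"
  direction[sig_female & in_female_band] <- "female"

  out <- data.frame(probeset_id = tab$probeset_id,
                    direction = direction,
                    passed_fdr = sig_male | sig_female,
                    passed_ratio = (sig_male & in_male_band) |
                      (sig_female & in_female_band),
                    mf_ratio = ratios$mf_ratio,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "funnel") <- list(
    male = c(fdr_stage = sum(sig_male), ratio_stage = sum(sig_male & in_male_band)),
    female = c(fdr_stage = sum(sig_female),
               ratio_stage = sum(sig_female & in_female_band)))
  class(out) <- c("bias_calls", "data.frame")
  out
}

#' Compensation banding of M:F ratios
#'
#' Three-way partition of probesets by their M:F ratio of means:
#' compensated when \code{comp_lo <= mf_ratio <= comp_hi} (default
#' [0.8, 1.3]), non-compensated when \code{mf_ratio >= noncomp_min}
#' (default 1.5), intermediate otherwise. Endpoints are inclusive. When an
#' annotation and chromosome are given, banding is restricted to that
#' chromosome's probesets (the expressed-Z subset in the study design).
#'
#' @param ratios Output of \code{\link{sex_ratios}}.
#' @param bands List with \code{comp_lo}, \code{comp_hi},
#'   \code{noncomp_min}.
#' @param annotation Optional \code{\link{probeset_annotation}}.
#' @param chromosome Optional chromosome name to restrict to (e.g.
#'   \code{"Z"}); requires \code{annotation}.
#' @return Data.frame of class \code{"compensation_calls"} with
#'   \code{probeset_id}, \code{class} in \{compensated, non_compensated,
#'   intermediate\}, \code{mf_ratio}.
#' @export
classify_compensation <- function(ratios,
                                  bands = list(comp_lo = 0.8, comp_hi = 1.3,
                                               noncomp_min = 1.5),
                                  annotation = NULL, chromosome = NULL) {
  stopifnot(all(ratios$mf_ratio > 0))
  if (!is.null(chromosome)) {
    if (is.null(annotation))
      stop("chromosome restriction requires an annotation")
    keep_ids <- annotation$probeset_id[annotation$chromosome %in% chromosome]
    ratios <- ratios[ratios$probeset_id %in% keep_ids, ]
  }
  cls <- ifelse(ratios$mf_ratio >= bands$comp_lo &
                  ratios$mf_ratio <= bands$comp_hi, "compensated",
                ifelse(ratios$mf_ratio >= bands$noncomp_min,
                       "non_compensated", "intermediate"))
  out <- data.frame(probeset_id = ratios$probeset_id,
                    class = cls,
                    mf_ratio = ratios$mf_ratio,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("compensation_calls", "data.frame")
  out
}

#' Chromosomal distribution of a probeset list
#'
#' Tallies calls per chromosome; probesets missing from the annotation go
#' to an \code{"unknown"} stratum, so totals are preserved.
#'
#' @param probesets Character vector of probeset ids.
#' @param annotation A \code{\link{probeset_annotation}}.
#' @return Named integer vector of per-chromosome counts.
#' @export
chromosome_distribution <- function(probesets, annotation) {
  chrom <- annotation$chromosome[match(probesets, annotation$probeset_id)]
  chrom[is.na(chrom)] <- "unknown"
  counts <- table(chrom)
  out <- c(unclass(counts))
  stopifnot(sum(out) == length(probesets))
  out
}

#' Wilcoxon rank-sum comparison of two samples
#'
#' Two-sample location comparison as used for the Z-versus-autosome
#' log2(M:F) contrast: the exact distribution when the combined sample is
#' small (\code{n_a + n_b <= 12}) and tie-free, otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param values_a,values_b Numeric vectors (both non-empty).
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"} (refers to \code{values_a} relative to
#'   \code{values_b}).
#' @return List with \code{statistic} (the Mann-Whitney U of
#'   \code{values_a}) and \code{p_value}.
#' @export
rank_sum_compare <- function(values_a, values_b,
                             alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(values_a) || !length(values_b))
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- (length(values_a) + length(values_b)) <= 12 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = alternative,
                       exact = exact, correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Per-chromosome ratio and expression summaries
#'
#' Mean log2(M:F) per chromosome, plus per-sex mean log2 expression for the
#' strata used in the compensation analysis: all probesets of the focal
#' chromosome, its compensated subset, its non-compensated subset, and the
#' autosomes. Chromosome 32 and W are excluded from the per-chromosome
#' table (unannotated / female-specific). Means are taken on the log2 scale.
#'
#' @param ratios Output of \code{\link{sex_ratios}}.
#' @param ds The matching \code{\link{expression_dataset}}.
#' @param annotation A \code{\link{probeset_annotation}}.
#' @param calls Optional \code{\link{classify_compensation}} result
#'   defining the compensated / non-compensated strata.
#' @param focal_chromosome Chromosome contrasted against the autosomes
#'   (default \code{"Z"}).
#' @param floor_intensity Clip floor before the log2 transform.
#' @return List with \code{per_chromosome} (data.frame: chromosome, n,
#'   mean_log2_mf, mean_log2_male, mean_log2_female) and \code{strata}
#'   (data.frame: stratum, n, mean_log2_male, mean_log2_female, gap =
#'   male - female).
#' @export
chromosome_summary <- function(ratios, ds, annotation, calls = NULL,
                               focal_chromosome = "Z",
                               floor_intensity = 1.0) {
  ids <- ratios$probeset_id
  chrom <- annotation$chromosome[match(ids, annotation$probeset_id)]
  chrom[is.na(chrom)] <- "unknown"
  x <- log2(pmax(ds$intensities[match(ids, ds$probeset_ids), , drop = FALSE],
                 floor_intensity))
  male_mean <- rowMeans(x[, ds$sex == "male", drop = FALSE])
  female_mean <- rowMeans(x[, ds$sex == "female", drop = FALSE])

  keep <- !(chrom %in% c("32", "W", "Un_random", "unknown"))
  per_chrom <- do.call(rbind, lapply(split(which(keep), chrom[keep]), function(i)
    data.frame(n = length(i),
               mean_log2_mf = mean(ratios$log2_mf[i]),
               mean_log2_male = mean(male_mean[i]),
               mean_log2_female = mean(female_mean[i]))))
  per_chrom <- data.frame(chromosome = rownames(per_chrom), per_chrom,
                          row.names = NULL, stringsAsFactors = FALSE)
  # order: numeric chromosomes, then the focal (sex) chromosome
  num <- suppressWarnings(as.numeric(per_chrom$chromosome))
  per_chrom <- per_chrom[order(is.na(num), num), ]

  strata <- list(autosomes = which(!is.na(suppressWarnings(as.numeric(chrom)))),
                 focal = which(chrom == focal_chromosome))
  names(strata)[2] <- focal_chromosome
  if (!is.null(calls)) {
    comp_ids <- calls$probeset_id[calls$class == "compensated"]
    noncomp_ids <- calls$probeset_id[calls$class == "non_compensated"]
    strata$compensated <- which(ids %in% comp_ids & chrom == focal_chromosome)
    strata$non_compensated <- which(ids %in% noncomp_ids &
                                      chrom == focal_chromosome)
  }
  empty <- lengths(strata) == 0L
  if (any(empty)) {
    warning("empty stratum(s) omitted: ", paste(names(strata)[empty], collapse = ", "))
    strata <- strata[!empty]
  }
  strata_df <- do.call(rbind, lapply(names(strata), function(nm) {
    i <- strata[[nm]]
    data.frame(stratum = nm, n = length(i),
               mean_log2_male = mean(male_mean[i]),
               mean_log2_female = mean(female_mean[i]),
               gap = mean(male_mean[i]) - mean(female_mean[i]),
               stringsAsFactors = FALSE)
  }))
  list(per_chromosome = per_chrom, strata = strata_df)
}
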