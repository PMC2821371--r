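#' Simulation configuration for synthetic dosage-structured datasets
#'
#' Defines the generative model used to test the pipeline: per-probeset
#' true log2 abundances drawn from a Gaussian, additive Gaussian noise on
#' the log2 scale (log-normal linear intensities), autosomal probesets with
#' M:F = 1, Z-linked probesets that are a mixture of compensated (M:F =
#' \code{compensated_mf}) and non-compensated (M:F = \code{noncompensated_mf},
#' realised by attenuating the female channel -- the male channel is never
#' boosted), W-linked female-specific probesets, spatial enrichment of
#' compensated probesets inside a designated MHM-like window on Z, and a
#' logistic Present-call detection model driven by the noiseless signal.
#'
#' Defaults emulate the statistical structure of an 18-array (9 male, 9
#' female) gastrula study on a chicken-like ZW genome: ~700 expressed
#' Z-linked probesets, a 75 Mb Z chromosome with a 5 Mb MHM-like window on
#' the p arm, and roughly 30\% of Z probesets compensated.
#'
#' @param seed Integer RNG seed; the whole dataset is reproducible from it.
#' @param n_per_sex Samples per sex (default 9).
#' @param n_autosomal,n_z,n_w Probeset counts per compartment.
#' @param baseline_log2_mean,baseline_log2_sd Distribution of per-probeset
#'   true log2 abundance (arbitrary MAS5-like units).
#' @param noise_log2_sd Per-observation log2 noise SD.
#' @param frac_z_compensated Fraction of Z probesets that are compensated;
#'   the realised count is exactly \code{round(frac_z_compensated * n_z)}.
#' @param noncompensated_mf,compensated_mf True M:F ratios of the two Z
#'   classes (defaults 2.0 and 1.0).
#' @param mhm_window \code{c(start_bp, end_bp)} of the compensation-enriched
#'   window on the simulated Z.
#' @param mhm_compensated_boost Extra selection weight for being compensated
#'   inside the window (see Details).
#' @param w_fm_log2 log2 female excess of W probesets (\code{Inf} pins the
#'   male channel at the detection floor).
#' @param z_length_bp,autosome_length_bp Chromosome lengths for uniform
#'   position placement.
#' @param detection_midpoint,detection_slope Logistic Present-call model on
#'   the noiseless log2 signal: P(Present) =
#'   plogis(slope * (signal - midpoint)).
#' @param floor_intensity Detection floor; linear intensities are clamped
#'   from below at this value (default 1.0) so they stay positive and a
#'   silenced channel sits exactly at the floor.
#'
#' @details The compensated Z subset has exact size
#'   \code{round(frac_z_compensated * n_z)} and is drawn without replacement
#'   with per-probeset selection weights \code{frac_z_compensated} outside
#'   the MHM window and \code{min(frac_z_compensated +
#'   mhm_compensated_boost, 1)} inside it, so truth-class counts are
#'   identical across seeds while the window is enriched for compensated
#'   probesets.
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L,
                       n_per_sex = 9L,
                       n_autosomal = 4000L,
                       n_z = 700L,
                       n_w = 30L,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 1.5,
                       noise_log2_sd = 0.25,
                       frac_z_compensated = 0.3,
                       noncompensated_mf = 2.0,
                       compensated_mf = 1.0,
                       mhm_window = c(25e6, 30e6),
                       mhm_compensated_boost = 0.5,
                       w_fm_log2 = 10,
                       z_length_bp = 75e6,
                       autosome_length_bp = 2e8,
                       detection_midpoint = 4,
                       detection_slope = 1.5,
                       floor_intensity = 1.0) {
  cfg <- as.list(environment())
  stopifnot(n_per_sex >= 0, n_autosomal >= 0, n_z >= 0, n_w >= 0,
            noise_log2_sd >= 0, baseline_log2_sd >= 0,
            floor_intensity > 0, z_length_bp > 0, autosome_length_bp > 0)
  if (!(frac_z_compensated >= 0 && frac_z_compensated <= 1))
    stop("frac_z_compensated must be in [0, 1]")
  if (!(noncompensated_mf > compensated_mf))
    stop("noncompensated_mf must exceed compensated_mf")
  if (length(mhm_window) != 2L || mhm_window[1] >= mhm_window[2])
    stop("mhm_window must be c(start_bp, end_bp) with start < end")
  if (mhm_window[1] < 0 || mhm_window[2] > z_length_bp)
    stop("mhm_window lies outside the simulated Z chromosome")
  structure(cfg, class = "sim_config")
}

#' Simulate an expression dataset with known dosage structure
#'
#' Draws a full probeset-by-sample dataset (intensities, detection calls,
#' sex labels), its positional annotation, and the per-probeset ground
#' truth, from a \code{\link{sim_config}}. Roughly one probeset in seven
#' shares its gene (and hence class and position) with its predecessor, so
#' probeset-to-gene de-duplication is exercised downstream.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with elements \code{dataset}
#'   (\code{\link{expression_dataset}}), \code{annotation}
#'   (\code{\link{probeset_annotation}}) and \code{truth} (data.frame with
#'   \code{probeset_id}, \code{true_class} in \{autosomal, z_compensated,
#'   z_noncompensated, w_female\}, \code{true_mf_ratio}, \code{chromosome},
#'   \code{position_bp}).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_per_sex < 1L) stop("n_per_sex must be >= 1 (zero samples)")
  set.seed(config$seed)
  cf <- config

  blocks <- list(
    autosomal = make_autosomal_block(cf),
    z = make_z_block(cf),
    w = make_w_block(cf))
  truth <- do.call(rbind, lapply(blocks, `[[`, "truth"))
  rownames(truth) <- NULL

  n <- nrow(truth)
  if (n == 0L) stop("no probesets to simulate")

  # shared-gene probesets copy locus info from a same-class predecessor,
  # leaving truth-class counts untouched
  idx <- seq_len(n)
  share <- idx %% 7L == 0L & idx > 1L &
    truth$true_class == c("", truth$true_class[-n])
  prev <- which(share) - 1L
  truth$chromosome[share] <- truth$chromosome[prev]
  truth$position_bp[share] <- truth$position_bp[prev]
  gene_idx <- seq_len(n)
  gene_idx[share] <- prev
  gene_id <- sprintf("G%05d", match(gene_idx, unique(gene_idx)))

  n_m <- cf$n_per_sex
  n_f <- cf$n_per_sex
  sample_ids <- c(sprintf("M%02d", seq_len(n_m)), sprintf("F%02d", seq_len(n_f)))
  sex <- stats::setNames(rep(c("male", "female"), c(n_m, n_f)), sample_ids)

  baseline <- stats::rnorm(n, cf$baseline_log2_mean, cf$baseline_log2_sd)
  male_sig <- baseline
  female_sig <- baseline - log2(truth$true_mf_ratio)
  # W probesets: baseline is the *female* channel, male channel attenuated
  is_w <- truth$true_class == "w_female"
  female_sig[is_w] <- baseline[is_w]
  male_sig[is_w] <- baseline[is_w] - cf$w_fm_log2

  signal <- cbind(matrix(male_sig, n, n_m), matrix(female_sig, n, n_f))
  noise <- matrix(stats::rnorm(n * (n_m + n_f), 0, cf$noise_log2_sd), n)
  intensities <- pmax(2^(signal + noise), cf$floor_intensity)
  dimnames(intensities) <- list(truth$probeset_id, sample_ids)

  p_present <- stats::plogis(cf$detection_slope * (signal - cf$detection_midpoint))
  p_present[signal == -Inf] <- 0
  detection <- matrix(ifelse(stats::runif(n * (n_m + n_f)) < p_present,
                             "Present", "Absent"), n)
  dimnames(detection) <- dimnames(intensities)

  ann <- probeset_annotation(data.frame(
    probeset_id = truth$probeset_id,
    chromosome = truth$chromosome,
    position_bp = truth$position_bp,
    gene_id = gene_id,
    quality = round(stats::runif(n, 0.3, 1), 3),
    stringsAsFactors = FALSE))

  list(dataset = expression_dataset(intensities, detection, sex),
       annotation = ann,
       truth = truth)
}

make_autosomal_block <- function(cf) {
  n <- cf$n_autosomal
  if (n == 0L) return(list(truth = empty_truth()))
  # stylized karyotype: macrochromosomes carry more probesets
  chrom <- sample(1:28, n, replace = TRUE, prob = (29 - (1:28))^1.5)
  list(truth = data.frame(
    probeset_id = sprintf("A%05d_at", seq_len(n)),
    true_class = "autosomal",
    true_mf_ratio = 1,
    chromosome = as.character(chrom),
    position_bp = floor(stats::runif(n, 1, cf$autosome_length_bp / sqrt(chrom))),
    stringsAsFactors = FALSE))
}

make_z_block <- function(cf) {
  n <- cf$n_z
  if (n == 0L) return(list(truth = empty_truth()))
  pos <- floor(stats::runif(n, 1, cf$z_length_bp))
  inside <- pos >= cf$mhm_window[1] & pos <= cf$mhm_window[2]
  n_comp <- round(cf$frac_z_compensated * n)
  w <- ifelse(inside, min(cf$frac_z_compensated + cf$mhm_compensated_boost, 1),
              cf$frac_z_compensated)
  comp_idx <- if (n_comp > 0 && any(w > 0))
    sample(n, n_comp, prob = w) else integer(0)
  cls <- rep("z_noncompensated", n)
  cls[comp_idx] <- "z_compensated"
  mf <- ifelse(cls == "z_compensated", cf$compensated_mf, cf$noncompensated_mf)
  list(truth = data.frame(
    probeset_id = sprintf("Z%05d_at", seq_len(n)),
    true_class = cls,
    true_mf_ratio = mf,
    chromosome = "Z",
    position_bp = pos,
    stringsAsFactors = FALSE))
}

make_w_block <- function(cf) {
  n <- cf$n_w
  if (n == 0L) return(list(truth = empty_truth()))
  list(truth = data.frame(
    probeset_id = sprintf("W%05d_at", seq_len(n)),
    true_class = "w_female",
    true_mf_ratio = 2^(-cf$w_fm_log2),
    chromosome = "W",
    position_bp = NA_real_,
    stringsAsFactors = FALSE))
}

empty_truth <- function() {
  data.frame(probeset_id = character(), true_class = character(),
             true_mf_ratio = numeric(), chromosome = character(),
             position_bp = numeric(), stringsAsFactors = FALSE)
}

#' Summarize simulation ground truth
#'
#' Tallies the truth classes and reports the expected mean log2 M:F of the
#' Z compartment implied by the realised compensated/non-compensated
#' mixture: \code{frac_comp * log2(comp_mf) + (1 - frac_comp) *
#' log2(noncomp_mf)}.
#'
#' @param truth Truth data.frame from \code{\link{simulate_dataset}}.
#' @return List with \code{class_counts} (named integer vector),
#'   \code{expected_z_mean_log2_mf}, and \code{expected_log2_mf_by_class}.
#' @export
truth_summary <- function(truth) {
  counts <- table(factor(truth$true_class,
                         levels = c("autosomal", "z_compensated",
                                    "z_noncompensated", "w_female")))
  z <- truth$true_class %in% c("z_compensated", "z_noncompensated")
  expected_z <- if (any(z)) mean(log2(truth$true_mf_ratio[z])) else NA_real_
  by_class <- tapply(log2(truth$true_mf_ratio), truth$true_class, mean)
  list(class_counts = c(unclass(counts)),
       expected_z_mean_log2_mf = expected_z,
       expected_log2_mf_by_class = by_class)
}
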