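#' Expression dataset container
#'
#' Bundles a normalized (linear-scale) probeset-by-sample intensity matrix,
#' the matching matrix of detection calls, and per-sample sex labels. This is
#' the single input object consumed by every downstream stage of the
#' pipeline. Intensities are expected on the scale produced by standard
#' MAS5-style summarization: linear, arbitrary units, non-negative.
#'
#' @param intensities Numeric matrix (probesets x samples) with rownames
#'   (probeset ids) and colnames (sample ids). Values must be finite and
#'   non-negative; missing values are rejected.
#' @param detection Character matrix of the same dimension with calls in
#'   \code{"Present"}, \code{"Marginal"}, \code{"Absent"} (or their
#'   one-letter abbreviations, any case).
#' @param sex Character vector of \code{"male"}/\code{"female"} labels,
#'   either named by sample id or in column order.
#' @return An object of class \code{"expression_dataset"}: a list with
#'   elements \code{probeset_ids}, \code{sample_ids}, \code{intensities},
#'   \code{detection} (normalized to full call names) and \code{sex}.
#' @examples
#' x <- matrix(2^rnorm(12, 7), 3, 4,
#'             dimnames = list(paste0("ps", 1:3), paste0("s", 1:4)))
#' calls <- matrix("P", 3, 4, dimnames = dimnames(x))
#' ds <- expression_dataset(x, calls, c(s1 = "male", s2 = "male",
#'                                      s3 = "female", s4 = "female"))
#' ds
#' @export
expression_dataset <- function(intensities, detection, sex) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("'intensities' must be a numeric matrix")
  if (nrow(intensities) > 0 && is.null(rownames(intensities)))
    stop("'intensities' must carry probeset ids as rownames")
  if (is.null(colnames(intensities)))
    stop("'intensities' must carry sample ids as colnames")
  if (is.null(rownames(intensities)))
    rownames(intensities) <- character(0)
  if (anyDuplicated(rownames(intensities)))
    stop("duplicate probeset ids in intensity matrix")
  if (anyDuplicated(colnames(intensities)))
    stop("duplicate sample ids in intensity matrix")
  if (any(!is.finite(intensities)))
    stop("intensities must be finite (missing values are rejected)")
  if (any(intensities < 0))
    stop("intensities must be non-negative")

  if (!is.matrix(detection))
    stop("'detection' must be a matrix of calls")
  if (!all(dim(detection) == dim(intensities)))
    stop(sprintf("dimension mismatch: intensities %dx%d vs detection %dx%d",
                 nrow(intensities), ncol(intensities),
                 nrow(detection), ncol(detection)))
  detection <- normalize_calls(detection)
  dimnames(detection) <- dimnames(intensities)

  sex <- normalize_sex(sex, colnames(intensities))

  structure(
    list(probeset_ids = rownames(intensities),
         sample_ids   = colnames(intensities),
         intensities  = intensities,
         detection    = detection,
         sex          = sex),
    class = "expression_dataset")
}

# Accepts {P, M, A} and full names, case-insensitively.
normalize_calls <- function(calls) {
  key <- c(p = "Present", present = "Present",
           m = "Marginal", marginal = "Marginal",
           a = "Absent",  absent   = "Absent")
  out <- key[tolower(trimws(as.character(calls)))]
  if (any(is.na(out))) {
    bad <- unique(as.character(calls)[is.na(out)])
    stop("invalid detection call(s): ", paste(bad, collapse = ", "))
  }
  matrix(out, nrow(calls), ncol(calls))
}

normalize_sex <- function(sex, sample_ids) {
  sex_chr <- tolower(trimws(as.character(sex)))
  if (!is.null(names(sex))) {
    missing <- setdiff(sample_ids, names(sex))
    if (length(missing))
      stop("sample(s) in matrix missing from sex labels: ",
           paste(missing, collapse = ", "))
    sex_chr <- sex_chr[match(sample_ids, names(sex))]
  } else if (length(sex) != length(sample_ids)) {
    stop("unnamed 'sex' must have one label per sample")
  }
  bad <- setdiff(unique(sex_chr), c("male", "female"))
  if (length(bad))
    stop("invalid sex label(s): ", paste(bad, collapse = ", "),
         " (expected 'male' or 'female')")
  names(sex_chr) <- sample_ids
  sex_chr
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d probesets x %d samples (%d male, %d female)\n",
              length(x$probeset_ids), length(x$sample_ids),
              sum(x$sex == "male"), sum(x$sex == "female")))
  pct_present <- 100 * mean(x$detection == "Present")
  cat(sprintf("  Present calls: %.1f%%\n", pct_present))
  invisible(x)
}

#' Number of probesets / samples in a dataset
#' @param ds An \code{expression_dataset}.
#' @return Integer count.
#' @export
n_probesets <- function(ds) length(ds$probeset_ids)

#' @rdname n_probesets
#' @export
n_samples <- function(ds) length(ds$sample_ids)

#' Subset a dataset to a set of probesets (order preserved)
#' @param ds An \code{expression_dataset}.
#' @param probesets Character vector of probeset ids to keep.
#' @return An \code{expression_dataset} restricted to \code{probesets},
#'   keeping the original row order.
#' @export
subset_probesets <- function(ds, probesets) {
  keep <- ds$probeset_ids %in% probesets
  expression_dataset(ds$intensities[keep, , drop = FALSE],
                     ds$detection[keep, , drop = FALSE],
                     ds$sex)
}

#' Swap the sex labels of every sample
#'
#' Utility for label-symmetry checks: males become females and vice versa,
#' leaving intensities untouched.
#' @param ds An \code{expression_dataset}.
#' @return The dataset with inverted sex labels.
#' @export
swap_sex_labels <- function(ds) {
  flipped <- ifelse(ds$sex == "male", "female", "male")
  names(flipped) <- names(ds$sex)
  ds$sex <- flipped
  ds
}
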