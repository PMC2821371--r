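# Small in-code fixtures shared across test files.

toy_dataset <- function(intensities, sex = NULL, calls = NULL) {
  n <- nrow(intensities)
  p <- ncol(intensities)
  if (is.null(rownames(intensities)))
    rownames(intensities) <- sprintf("ps%02d", seq_len(n))
  if (is.null(colnames(intensities)))
    colnames(intensities) <- sprintf("s%02d", seq_len(p))
  if (is.null(sex))
    sex <- rep(c("male", "female"), length.out = p)
  if (is.null(calls))
    calls <- matrix("Present", n, p)
  expression_dataset(intensities, calls,
                     stats::setNames(sex, colnames(intensities)))
}

# deterministic two-group dataset on the log2 scale
toy_log2_dataset <- function(log2_mat, sex = NULL) {
  toy_dataset(2^log2_mat, sex = sex)
}

toy_annotation <- function(probeset_ids, chromosome, position_bp = NULL,
                           gene_id = NULL, quality = NULL) {
  n <- length(probeset_ids)
  probeset_annotation(data.frame(
    probeset_id = probeset_ids,
    chromosome = chromosome,
    position_bp = if (is.null(position_bp)) seq_len(n) * 1e5 else position_bp,
    gene_id = if (is.null(gene_id)) paste0("G", seq_len(n)) else gene_id,
    quality = if (is.null(quality)) rep(0.9, n) else quality,
    stringsAsFactors = FALSE))
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
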