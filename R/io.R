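#' Read an expression dataset from tab-separated files
#'
#' Expects the dialect used throughout the pipeline: UTF-8, tab-separated,
#' '.' decimal, a header row of sample ids (the first header cell is
#' ignored) and probeset ids in the first column. The calls file must have
#' exactly the same layout as the matrix; the sex file maps sample id to
#' \code{male}/\code{female} (two columns, no header required).
#'
#' @param matrix_path Path to the intensity matrix TSV.
#' @param calls_path Path to the detection-call TSV (same shape).
#' @param sex_path Path to the two-column sample-id / sex TSV.
#' @return A validated \code{\link{expression_dataset}}. Call columns are
#'   reordered to match the matrix if needed.
#' @export
read_expression <- function(matrix_path, calls_path, sex_path) {
  intens <- read_tsv_matrix(matrix_path, numeric = TRUE)
  calls <- read_tsv_matrix(calls_path, numeric = FALSE)
  if (!identical(dim(calls), dim(intens)))
    stop(sprintf("dimension mismatch: matrix is %dx%d but calls file is %dx%d",
                 nrow(intens), ncol(intens), nrow(calls), ncol(calls)))
  if (!setequal(colnames(calls), colnames(intens)) ||
      !setequal(rownames(calls), rownames(intens)))
    stop("calls file ids do not match matrix ids")
  calls <- calls[rownames(intens), colnames(intens), drop = FALSE]

  sx <- utils::read.delim(sex_path, header = FALSE, sep = "\t",
                          colClasses = "character",
                          strip.white = TRUE, comment.char = "#")
  # tolerate an optional header line
  if (nrow(sx) && tolower(sx[1, 2]) %in% c("sex", "label"))
    sx <- sx[-1, , drop = FALSE]
  sex <- stats::setNames(sx[[2]], sx[[1]])
  expression_dataset(intens, calls, sex)
}

#' Write an expression dataset to tab-separated files
#'
#' Inverse of \code{\link{read_expression}}; full numeric precision is kept
#' (15 significant digits) so that a read/write cycle round-trips.
#'
#' @param ds An \code{expression_dataset}.
#' @param matrix_path,calls_path,sex_path Output paths.
#' @return Invisibly, the dataset.
#' @export
write_expression <- function(ds, matrix_path, calls_path, sex_path) {
  write_tsv_matrix(ds$intensities, matrix_path, digits = 15)
  write_tsv_matrix(ds$detection, calls_path)
  utils::write.table(data.frame(sample_id = ds$sample_ids,
                                sex = unname(ds$sex)),
                     sex_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(ds)
}

#' Read a probeset annotation table
#'
#' Tab-separated columns: probeset_id, chromosome, position_bp, gene_id,
#' quality. Chromosome names are normalized to the canonical set (a leading
#' \code{chr} prefix is stripped, so \code{chrZ} becomes \code{Z} and
#' \code{chrUn_random} becomes \code{Un_random}); empty or \code{NA} fields
#' become missing positions/genes. Positions are 1-based base pairs.
#'
#' @param path Path to the annotation TSV (header optional; detected from
#'   the first line).
#' @return A data.frame of class \code{"probeset_annotation"} with columns
#'   \code{probeset_id}, \code{chromosome}, \code{position_bp},
#'   \code{gene_id}, \code{quality}.
#' @export
read_annotation <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("probeset", tolower(first))
  df <- utils::read.delim(path, header = has_header, sep = "\t",
                          colClasses = "character",
                          strip.white = TRUE, comment.char = "#")
  if (ncol(df) < 5L)
    stop("annotation file needs 5 columns: probeset_id, chromosome, position_bp, gene_id, quality")
  df <- df[, 1:5]
  names(df) <- c("probeset_id", "chromosome", "position_bp", "gene_id", "quality")
  probeset_annotation(df)
}

#' Construct/validate a probeset annotation table
#'
#' @param df Data frame with columns \code{probeset_id}, \code{chromosome},
#'   \code{position_bp}, \code{gene_id}, \code{quality}.
#' @return The validated, normalized annotation data.frame.
#' @export
probeset_annotation <- function(df) {
  required <- c("probeset_id", "chromosome", "position_bp", "gene_id", "quality")
  if (!all(required %in% names(df)))
    stop("annotation must have columns: ", paste(required, collapse = ", "))
  df <- as.data.frame(df)[, required]
  if (anyDuplicated(df$probeset_id))
    stop("duplicate probeset id(s) in annotation: ",
         paste(unique(df$probeset_id[duplicated(df$probeset_id)]), collapse = ", "))
  df$chromosome <- normalize_chromosome(df$chromosome)

  if (is.numeric(df$position_bp)) {
    pos <- df$position_bp
    bad <- !is.na(pos) & pos != floor(pos)
    if (any(bad))
      stop("non-integer position_bp: ", paste(unique(pos[bad]), collapse = ", "))
  } else {
    pos_chr <- as.character(df$position_bp)
    pos_chr[pos_chr %in% c("", "NA", ".")] <- NA_character_
    bad <- !is.na(pos_chr) & grepl("\\D", pos_chr)
    if (any(bad))
      stop("non-integer position_bp: ", paste(unique(pos_chr[bad]), collapse = ", "))
    pos <- as.numeric(pos_chr)
  }
  df$position_bp <- pos

  gene <- as.character(df$gene_id)
  gene[gene %in% c("", "NA", ".")] <- NA_character_
  df$gene_id <- gene
  df$quality <- as.numeric(df$quality)

  # assembled chromosomes must come with a coordinate
  assembled <- !(df$chromosome %in% c("Un_random", "unknown", "W"))
  if (any(assembled & is.na(df$position_bp)))
    stop("probeset(s) on assembled chromosomes lack position_bp: ",
         paste(df$probeset_id[assembled & is.na(df$position_bp)], collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("probeset_annotation", "data.frame")
  df
}

normalize_chromosome <- function(chrom) {
  x <- trimws(as.character(chrom))
  x <- sub("^chr", "", x, ignore.case = TRUE)
  x[x %in% c("", "NA", ".", "na")] <- "unknown"
  x[tolower(x) == "un_random"] <- "Un_random"
  x[tolower(x) == "unknown"] <- "unknown"
  x[toupper(x) == "Z"] <- "Z"
  x[toupper(x) == "W"] <- "W"
  x
}

#' Write an annotation table
#' @param ann A \code{probeset_annotation}.
#' @param path Output TSV path.
#' @return Invisibly, \code{ann}.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ann)
}

#' Read gene sets (GMT or two-column format, auto-detected)
#'
#' GMT lines are \code{term<TAB>description<TAB>gene1<TAB>gene2...};
#' two-column files are \code{term<TAB>gene} pairs, one per line (a header
#' is not expected). A file whose lines all have exactly two fields is read
#' as two-column; anything else is read as GMT. Duplicate genes within a
#' term are collapsed.
#'
#' @param path Path to the gene-set file.
#' @return Named list of unique gene-id character vectors; term
#'   descriptions (GMT field 2, or the term id itself) are kept in
#'   \code{attr(, "descriptions")}.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("gene-set file is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) trimws(f))
  two_col <- all(lengths(fields) == 2L)

  if (two_col) {
    term <- vapply(fields, `[`, "", 1L)
    gene <- vapply(fields, `[`, "", 2L)
    if (any(!nzchar(term)) || any(!nzchar(gene)))
      stop("unparseable line in two-column gene-set file (empty term or gene)")
    sets <- lapply(split(gene, term), unique)
    desc <- stats::setNames(names(sets), names(sets))
  } else {
    parse_gmt_line <- function(f, i) {
      if (length(f) < 3L)
        stop(sprintf("unparseable GMT line %d: need term, description and >=1 gene", i))
      genes <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
      if (!nzchar(f[1L])) stop(sprintf("empty term id on GMT line %d", i))
      if (!length(genes)) stop(sprintf("GMT term '%s' has no genes", f[1L]))
      list(term = f[1L], desc = f[2L], genes = genes)
    }
    parsed <- Map(parse_gmt_line, fields, seq_along(fields))
    terms <- vapply(parsed, `[[`, "", "term")
    if (anyDuplicated(terms)) stop("duplicate term id(s) in GMT file")
    sets <- stats::setNames(lapply(parsed, `[[`, "genes"), terms)
    desc <- stats::setNames(vapply(parsed, `[[`, "", "desc"), terms)
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a result table with a commented provenance header
#'
#' Writes a data.frame as a TSV preceded by \code{# key: value} comment
#' lines (typically the seed and a hash of the configuration used), so
#' every output table records how it was produced. Readers in this package
#' skip \code{#} lines.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param meta Named list of scalar metadata to record.
#' @return Invisibly, \code{path}.
#' @export
write_result_table <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(meta))
    writeLines(sprintf("# %s: %s", key, format(meta[[key]])), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stable hash of a configuration object
#'
#' Short checksum of a deparsed R object, recorded in output headers so
#' tables can be traced to the exact configuration that produced them.
#'
#' @param x Any R object (e.g. a \code{\link{run_config}}).
#' @return An 8-character hexadecimal string.
#' @export
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(txt)
  # 31-base polynomial rolling hash in double arithmetic (exact below 2^53)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

## ---- internal TSV helpers ----

read_tsv_matrix <- function(path, numeric) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", comment.char = "#")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate probeset id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  if (numeric) {
    mn <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                  dimnames = dimnames(m)))
    if (anyNA(mn) != anyNA(m) || anyNA(mn))
      stop("non-numeric or missing value(s) in ", path)
    m <- mn
  }
  m
}

write_tsv_matrix <- function(m, path, digits = NULL) {
  vals <- if (is.null(digits)) m else signif(m, digits)
  df <- data.frame(probeset_id = rownames(m), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
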