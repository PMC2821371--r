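#' Collapse probesets to a unique gene set
#'
#' Many-to-one probeset-to-gene annotation inflates enrichment counts, so
#' each gene is represented once: when several probesets map to the same
#' gene the highest-quality mapping wins, full ties are broken uniformly
#' at random (seeded), and probesets without a gene are dropped with a
#' message.
#'
#' @param probesets Character vector of probeset ids.
#' @param annotation A \code{\link{probeset_annotation}} with
#'   \code{gene_id} and \code{quality}.
#' @param seed Integer seed for tie-breaking.
#' @return Character vector of unique gene ids; the number of dropped
#'   (gene-less) probesets is attached as \code{attr(, "n_dropped")}.
#' @export
collapse_probesets_to_genes <- function(probesets, annotation, seed = 1L) {
  idx <- match(probesets, annotation$probeset_id)
  if (anyNA(idx))
    stop("probeset(s) missing from annotation: ",
         paste(probesets[is.na(idx)], collapse = ", "))
  gene <- annotation$gene_id[idx]
  quality <- annotation$quality[idx]
  dropped <- is.na(gene)
  if (any(dropped))
    message(sum(dropped), " probeset(s) without a gene id dropped")
  gene <- gene[!dropped]
  quality <- quality[!dropped]

  set.seed(seed)
  # random jitter breaks full-quality ties uniformly; order is otherwise
  # by descending quality within gene
  pick <- tapply(seq_along(gene),
                 gene,
                 function(i) i[order(-quality[i], stats::runif(length(i)))][1L])
  genes <- names(pick)
  attr(genes, "n_dropped") <- sum(dropped)
  genes
}

#' Hypergeometric term over-representation
#'
#' For each term, tests whether the query gene set contains more of the
#' term's genes than expected from a uniform draw out of the background:
#' \code{raw_p = P(X >= k)} for X ~ Hypergeometric(N, K, n) with N the
#' background size, K the term's background genes, n the query size and k
#' the term genes in the query (exact tail). P-values are
#' Benjamini-Hochberg adjusted over all terms with K >= 1 in the
#' background, and records are sorted by raw p.
#'
#' @param query_genes Character vector, a subset of
#'   \code{background_genes}.
#' @param term_map Named list term -> gene-id vector (see
#'   \code{\link{read_gene_sets}}); genome-mode maps may contain genes
#'   outside the background, which are ignored.
#' @param background_genes Character vector: the genome or the
#'   transcriptome represented on the array.
#' @return Data.frame of class \code{"enrichment_records"}: term_id,
#'   term_description, k, K, n, N, raw_p, adjusted_p; sorted by raw_p.
#' @export
hypergeometric_enrichment <- function(query_genes, term_map,
                                      background_genes) {
  query_genes <- unique(query_genes)
  background_genes <- unique(background_genes)
  missing <- setdiff(query_genes, background_genes)
  if (length(missing))
    stop("query gene(s) absent from background: ",
         paste(missing, collapse = ", "))
  N <- length(background_genes)
  n <- length(query_genes)
  desc <- attr(term_map, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(names(term_map), names(term_map))

  rows <- lapply(names(term_map), function(term) {
    in_bg <- intersect(term_map[[term]], background_genes)
    K <- length(in_bg)
    if (K == 0L) return(NULL)  # terms absent from the background are dropped
    k <- length(intersect(in_bg, query_genes))
    raw_p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term,
               term_description = unname(desc[term]),
               k = k, K = K, n = n, N = N,
               raw_p = raw_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no term has any gene in the chosen background")
  out$adjusted_p <- benjamini_hochberg(out$raw_p)
  out <- out[order(out$raw_p, out$term_id), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_records", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' \code{adj_(i) = min_\{j >= i\} (m * p_(j) / j)} on the sorted p-values,
#' capped at 1 and mapped back to the input order.
#'
#' @param raw_p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(raw_p) {
  stopifnot(all(raw_p > 0), all(raw_p <= 1))
  stats::p.adjust(raw_p, method = "BH")
}
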