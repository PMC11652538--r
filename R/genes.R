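#' Select the top fraction of genes by local score
#'
#' At the time point where the early-warning signal appears, the genes with
#' the largest local scores are the candidate signaling genes. The selection
#' size is `ceiling(fraction * N)`, so any positive fraction yields at least
#' one gene; ties at the cut are broken by gene identifier for determinism.
#'
#' @param table an [`spcr_local_scores`][local_scores] data frame.
#' @param fraction fraction of genes to keep, in (0, 1]; default 0.05
#'   (the top 5 percent).
#' @param use_absolute rank genes by `|S|` instead of signed `S`
#'   (same option as [sample_score()]).
#' @return Character vector of selected gene identifiers, in decreasing
#'   score order.
#' @export
select_top_fraction <- function(table, fraction = 0.05, use_absolute = FALSE) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("`table` must be a non-empty local-score table", call. = FALSE)
  }
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(table)
  k <- as.integer(ceiling(fraction * n))
  s <- table$local_score
  key <- if (use_absolute) abs(s) else s
  ord <- order(-key, table$gene_id)
  table$gene_id[ord[seq_len(k)]]
}

#' Genes shared by enough subjects' candidate sets
#'
#' Intersects per-subject candidate signaling-gene sets: a gene is kept when
#' it appears in at least `min_subjects` of the sets. The default of 5
#' encodes "more than four subjects". With `min_subjects = 1` this is the
#' union of the sets.
#'
#' @param sets list of character vectors of gene identifiers (duplicates
#'   within a set are ignored).
#' @param min_subjects minimum number of sets a gene must appear in
#'   (default 5).
#' @return Sorted character vector of common gene identifiers.
#' @export
common_genes <- function(sets, min_subjects = 5L) {
  if (!is.list(sets) || length(sets) == 0L) {
    stop("`sets` must be a non-empty list of gene-id vectors", call. = FALSE)
  }
  if (!is.numeric(min_subjects) || min_subjects < 1L) {
    stop("`min_subjects` must be a positive integer", call. = FALSE)
  }
  counts <- table(unlist(lapply(sets, unique), use.names = FALSE))
  sort(names(counts)[counts >= min_subjects])
}

#' Per-gene membership counts across candidate sets
#'
#' @param sets list of character vectors of gene identifiers.
#' @return Data frame with columns `gene_id` and `n_sets`, sorted by
#'   decreasing count then gene id.
#' @export
gene_set_counts <- function(sets) {
  counts <- table(unlist(lapply(sets, unique), use.names = FALSE))
  out <- data.frame(gene_id = names(counts), n_sets = as.integer(counts),
                    stringsAsFactors = FALSE)
  out[order(-out$n_sets, out$gene_id), , drop = FALSE]
}

#' Hypergeometric enrichment of a gene selection in a reference set
#'
#' Upper-tail hypergeometric test that a selection of genes overlaps a
#' reference set (e.g. a planted DNB module) more than chance, given the
#' gene universe size.
#'
#' @param selected character vector of selected gene ids.
#' @param reference character vector of reference gene ids.
#' @param n_universe total number of genes in the universe.
#' @return List with `overlap` and `p_value`
#'   (`P(X >= overlap)`, hypergeometric).
#' @export
enrichment_test <- function(selected, reference, n_universe) {
  selected <- unique(selected)
  reference <- unique(reference)
  stopifnot(n_universe >= length(reference), n_universe >= length(selected))
  ov <- length(intersect(selected, reference))
  p <- phyper(ov - 1L, length(reference), n_universe - length(reference),
              length(selected), lower.tail = FALSE)
  list(overlap = ov, p_value = p)
}
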