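#' Build the per-gene baseline profile from normal samples
#'
#' The baseline expression of each gene is its arithmetic mean over the
#' designated normal samples; the baseline ranking is the fractional
#' (average-tie) ascending rank of those baseline values, rank 1 for the
#' lowest expression. Every later change is measured against this profile.
#'
#' @param normal_samples numeric matrix, genes in rows (unique row names),
#'   normal samples in columns; no missing values.
#' @return An object of class `spcr_baseline`: a list with `gene_ids`,
#'   `baseline_expression` (named numeric), `baseline_rank` (named fractional
#'   ranks) and `n_normal` (number of samples averaged).
#' @examples
#' m <- matrix(c(1, 3, 2, 2, 5, 1), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' compute_baseline(m)
#' @seealso [local_scores()], [score_series()]
#' @export
compute_baseline <- function(normal_samples) {
  validate_expression_matrix(normal_samples, what = "normal-sample matrix")
  eb <- rowMeans(normal_samples)
  structure(
    list(
      gene_ids = rownames(normal_samples),
      baseline_expression = eb,
      baseline_rank = rank_expressions(eb),
      n_normal = ncol(normal_samples)
    ),
    class = "spcr_baseline"
  )
}

#' @export
print.spcr_baseline <- function(x, ...) {
  cat("Baseline profile: ", length(x$gene_ids), " genes averaged over ",
      x$n_normal, " normal sample(s)\n", sep = "")
  invisible(x)
}

#' Fractional expression ranks
#'
#' Ascending fractional ranks (rank 1 = lowest expression); ties receive the
#' average of the ranks they span, so ranks always sum to N(N+1)/2 and the
#' result is independent of gene order.
#'
#' @param values named numeric vector of expression values (length >= 2,
#'   no missing values).
#' @return Named numeric vector of fractional ranks.
#' @examples
#' rank_expressions(c(a = 1, b = 1, c = 2))  # 1.5 1.5 3
#' @export
rank_expressions <- function(values) {
  if (length(values) < 2L) {
    stop("need at least 2 values to rank", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- names(values)[!is.finite(values)]
    stop("cannot rank missing/non-finite values",
         if (length(bad)) paste0(" (gene(s): ",
                                 paste(head(bad, 5L), collapse = ", "), ")"),
         call. = FALSE)
  }
  rank(values, ties.method = "average")
}

#' Per-gene local scores of one sample against the baseline
#'
#' For each gene the expression change is `dE = E_t - E_b`, the ranking
#' change is `dR = R_t - R_b` (fractional ranks of the sample vs. of the
#' baseline profile), and the local score is their product `S = dE * dR`.
#' A gene that moves strongly moves its rank in the same direction, so
#' coordinated large shifts yield large positive products regardless of
#' direction, while noise-level shifts yield small products.
#'
#' If the sample and baseline cover different gene universes the
#' intersection is used (with a warning) and ranks are recomputed on it;
#' fewer than 2 shared genes is an error.
#'
#' @param sample named numeric vector: one sample's expression per gene.
#' @param baseline an [`spcr_baseline`][compute_baseline] object.
#' @return An object of class `spcr_local_scores`: a data frame with columns
#'   `gene_id`, `delta_expression`, `delta_rank`, `local_score`.
#' @examples
#' b <- compute_baseline(matrix(c(1, 2, 3), 3, 1,
#'        dimnames = list(c("g1", "g2", "g3"), "n1")))
#' local_scores(c(g1 = 3, g2 = 2, g3 = 1), b)
#' @export
local_scores <- function(sample, baseline) {
  stopifnot(inherits(baseline, "spcr_baseline"))
  if (is.null(names(sample))) {
    stop("`sample` must be a named vector of per-gene expression values",
         call. = FALSE)
  }
  common <- intersect(names(sample), baseline$gene_ids)
  if (length(common) == 0L) {
    stop("sample and baseline share no genes", call. = FALSE)
  }
  if (length(common) < 2L) {
    stop("fewer than 2 genes shared between sample and baseline", call. = FALSE)
  }
  full <- length(common) == length(sample) &&
    length(common) == length(baseline$gene_ids)
  if (!full) {
    warning("sample and baseline gene universes differ; using their ",
            "intersection of ", length(common), " genes", call. = FALSE)
  }
  et <- sample[common]
  eb <- baseline$baseline_expression[common]
  rb <- if (full) baseline$baseline_rank[common] else rank_expressions(eb)
  rt <- rank_expressions(et)
  de <- unname(et - eb)
  dr <- unname(rt - rb)
  structure(
    data.frame(
      gene_id = common,
      delta_expression = de,
      delta_rank = dr,
      local_score = de * dr,
      stringsAsFactors = FALSE
    ),
    class = c("spcr_local_scores", "data.frame")
  )
}

#' Aggregate local scores into a per-sample ranking score
#'
#' The sample-level score is the sum of the `m` largest per-gene local scores
#' divided by `m * N`, where `N` is the number of genes scored. "Largest" is
#' by signed value by default (`use_absolute = TRUE` selects by absolute
#' value instead); ties at the m-th score are broken by gene identifier so
#' the selected set is deterministic (tied scores contribute equally to the
#' sum either way).
#'
#' @param table an [`spcr_local_scores`][local_scores] data frame.
#' @param m number of top genes to aggregate (default 50); must satisfy
#'   `1 <= m <= N` — an error, not a clamp, otherwise.
#' @param use_absolute select the top m by `|S|` rather than signed `S`.
#' @return A single numeric score.
#' @examples
#' tab <- structure(data.frame(gene_id = c("a", "b", "c"),
#'                             delta_expression = c(2, 0, -2),
#'                             delta_rank = c(2, 0, -2),
#'                             local_score = c(4, 0, 4)),
#'                  class = c("spcr_local_scores", "data.frame"))
#' sample_score(tab, m = 2)  # (4 + 4) / (2 * 3)
#' @export
sample_score <- function(table, m = 50L, use_absolute = FALSE) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("`table` must be a non-empty local-score table", call. = FALSE)
  }
  n <- nrow(table)
  if (!is.numeric(m) || length(m) != 1L || m < 1L || m != floor(m)) {
    stop("`m` must be a positive integer", call. = FALSE)
  }
  if (m > n) {
    stop("m (", m, ") exceeds the number of genes (", n, ")", call. = FALSE)
  }
  s <- table$local_score
  key <- if (use_absolute) abs(s) else s
  ord <- order(-key, table$gene_id)
  sum(s[ord[seq_len(m)]]) / (m * n)
}

#' Score a subject's time course against a baseline
#'
#' Computes the per-time-point score `S_t` ([local_scores()] +
#' [sample_score()]) for every column of the course, then the ranking score
#' `dS_t = S_t - S_0`, where `S_0` belongs to the first post-baseline time
#' point. The ranking score at the initial point is therefore identically 0;
#' its subsequent significant increase is the early-warning signal.
#'
#' @param course numeric matrix of one subject's samples, genes in rows,
#'   time points in columns; column names are the time labels (strictly
#'   increasing when numeric).
#' @param baseline an [`spcr_baseline`][compute_baseline] object.
#' @param m,use_absolute passed to [sample_score()].
#' @param subject_id optional subject identifier carried into the result.
#' @param time_order optional explicit ordering for non-numeric time labels.
#' @return An object of class `spcr_score_series`: a data frame with columns
#'   `time`, `score` (`S_t`) and `ranking_score` (`dS_t`), with attributes
#'   `subject_id` and `m_used`.
#' @export
score_series <- function(course, baseline, m = 50L, use_absolute = FALSE,
                         subject_id = NULL, time_order = NULL) {
  validate_expression_matrix(course, what = "time-course matrix")
  check_time_labels(colnames(course), time_order)
  s <- vapply(seq_len(ncol(course)), function(j) {
    sample_score(local_scores(course[, j], baseline), m = m,
                 use_absolute = use_absolute)
  }, numeric(1))
  structure(
    data.frame(
      time = colnames(course),
      score = s,
      ranking_score = s - s[1L],
      stringsAsFactors = FALSE
    ),
    subject_id = subject_id,
    m_used = as.integer(m),
    class = c("spcr_score_series", "data.frame")
  )
}

#' @export
print.spcr_score_series <- function(x, ...) {
  sid <- attr(x, "subject_id")
  cat("Ranking-score series",
      if (!is.null(sid)) paste0(" for subject ", sid),
      " (m = ", attr(x, "m_used"), "):\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Normalize positive values by their minimum
#'
#' Divides each value by the minimum of the vector, mapping the minimum to 1.
#' Used to put gene expression values and ranking scores on a comparable,
#' unitless scale. All values must be strictly positive.
#'
#' @param values numeric vector with `min(values) > 0`.
#' @return `values / min(values)`.
#' @examples
#' normalize_by_min(c(2, 4, 8))  # 1 2 4
#' @export
normalize_by_min <- function(values) {
  if (length(values) < 1L || anyNA(values)) {
    stop("`values` must be a non-empty vector without missing values",
         call. = FALSE)
  }
  mn <- min(values)
  if (mn <= 0) {
    stop("min-normalization requires strictly positive values; minimum is ",
         format(mn), call. = FALSE)
  }
  values / mn
}
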