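# Fixture builders and independent oracles used across the test files.

# Small labelled matrix from a vector (byrow).
mat3 <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

# Independent oracle for sample_score(): fully sorts all N local scores and
# averages the top m. Kept deliberately naive.
oracle_sample_score <- function(local_score, m, use_absolute = FALSE) {
  n <- length(local_score)
  key <- if (use_absolute) abs(local_score) else local_score
  top <- local_score[order(key, decreasing = TRUE)][seq_len(m)]
  sum(top) / (m * n)
}

# Random local-score table with distinct gene ids.
random_score_table <- function(n) {
  structure(
    data.frame(gene_id = sprintf("g%04d", seq_len(n)),
               delta_expression = rnorm(n),
               delta_rank = rnorm(n),
               local_score = rnorm(n, sd = 5),
               stringsAsFactors = FALSE),
    class = c("spcr_local_scores", "data.frame"))
}

# Score a study's course (and optional same-cohort null courses) against its
# own normal pool.
score_study <- function(study, m = 50L) {
  bl <- compute_baseline(study$normal_matrix)
  list(
    baseline = bl,
    case = score_series(study$course, bl, m = m),
    nulls = lapply(study$null_courses, score_series, baseline = bl, m = m)
  )
}

# Cohort-level early-warning experiment on one factor-model study: theta is
# calibrated from the same cohort's null subjects with a family-wise
# (Bonferroni over the T - 1 tested time points) alpha, then the case course
# is scored. Returns the signal index (NA if none) plus the enrichment
# p-value of the top-fraction genes at the signal time point.
run_recovery_experiment <- function(seed, n_null_subjects = 8L,
                                    alpha_family = 0.05, m = 50L,
                                    fraction = 0.05) {
  cfg <- simulation_config(seed = seed)
  study <- simulate_factor_study(cfg, n_null_subjects = n_null_subjects)
  sc <- score_study(study, m = m)
  pool <- unlist(lapply(sc$nulls, function(s) s$ranking_score[-1L]))
  theta <- compute_threshold(pool, alpha = alpha_family / (cfg$n_timepoints - 1L))
  w <- detect_warning(sc$case, theta)
  p <- NA_real_
  if (!is.na(w$signal_index)) {
    tab <- local_scores(study$course[, w$signal_index], sc$baseline)
    p <- enrichment_test(select_top_fraction(tab, fraction),
                         study$dnb_gene_ids, cfg$n_genes)$p_value
  }
  list(signal_index = w$signal_index, truth = study$truth_transition_index,
       enrichment_p = p)
}

# Cache for the 100-run recovery batch shared by the acceptance tests.
.recovery_cache <- new.env(parent = emptyenv())
recovery_batch <- function(n_runs = 100L) {
  key <- as.character(n_runs)
  if (is.null(.recovery_cache[[key]])) {
    .recovery_cache[[key]] <- lapply(seq_len(n_runs), run_recovery_experiment)
  }
  .recovery_cache[[key]]
}
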