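#' Run the full early-warning pipeline on delimited inputs
#'
#' Reads an expression matrix and metadata, fits the time-course or
#' stage-averaged model, and writes the standard report files to `out_dir`:
#' `scores.tsv` (per-subject score series), `threshold.json`, `calls.json`
#' (warning or stage calls), and in course mode `signaling_genes.txt` /
#' `gene_counts.tsv` when signals were found. Outputs are deterministic
#' functions of the inputs.
#'
#' @param matrix_path path to the delimited expression matrix (or a numeric
#'   matrix).
#' @param metadata_path path to the metadata table (or a data frame).
#' @param out_dir output directory (created if absent).
#' @param mode `"course"` (per-subject time courses) or `"stage"`
#'   (stage-averaged single course).
#' @param m,alpha,baseline_mode,use_absolute,time_order,theta,log2_transform
#'   passed to [spcr()] / [spcr_stages()].
#' @param fraction,min_subjects signaling-gene selection parameters
#'   (course mode), see [signaling_genes()].
#' @param min_consecutive_increases,min_relative_jump stage-rule parameters
#'   (stage mode).
#' @return The fitted object, invisibly.
#' @export
run_spcr <- function(matrix_path, metadata_path, out_dir,
                     mode = c("course", "stage"), m = 50L, alpha = 0.05,
                     baseline_mode = c("per-subject", "pooled"),
                     use_absolute = FALSE, time_order = NULL, theta = NULL,
                     log2_transform = FALSE, fraction = 0.05,
                     min_subjects = 5L,
                     min_consecutive_increases = 2L, min_relative_jump = 1.0) {
  mode <- match.arg(mode)
  baseline_mode <- match.arg(baseline_mode)
  x <- if (is.matrix(matrix_path)) matrix_path else
    read_expression_matrix(matrix_path)
  md <- if (is.data.frame(metadata_path)) validate_metadata(metadata_path) else
    read_metadata(metadata_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (mode == "stage") {
    fit <- spcr_stages(x, md, m = m, stage_order = time_order,
                       use_absolute = use_absolute,
                       min_consecutive_increases = min_consecutive_increases,
                       min_relative_jump = min_relative_jump,
                       log2_transform = log2_transform)
    write_score_series(fit$series, file.path(out_dir, "scores.tsv"))
    jsonlite::write_json(
      list(mode = "stage",
           called_stage = fit$stage_call$called_stage,
           called_index = fit$stage_call$called_index,
           rule_params = fit$stage_call$rule_params,
           m = fit$m),
      file.path(out_dir, "calls.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    return(invisible(fit))
  }

  fit <- spcr(x, md, m = m, alpha = alpha, baseline_mode = baseline_mode,
              use_absolute = use_absolute, time_order = time_order,
              theta = theta, log2_transform = log2_transform)
  write_score_series(fit$series, file.path(out_dir, "scores.tsv"))
  if (!is.null(fit$theta)) {
    th <- if (!is.null(fit$threshold)) unclass(fit$threshold) else
      list(theta = fit$theta, alpha = NA, source = "user-supplied")
    jsonlite::write_json(th, file.path(out_dir, "threshold.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(
    list(mode = "course",
         m = fit$m, alpha = fit$alpha, baseline_mode = fit$baseline_mode,
         subjects = lapply(seq_len(nrow(fit$subjects)), function(i) {
           as.list(fit$subjects[i, , drop = FALSE])
         })),
    file.path(out_dir, "calls.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  if (!is.null(fit$calls)) {
    gs <- signaling_genes(fit, x, md, fraction = fraction,
                          min_subjects = min_subjects)
    if (length(gs$per_subject)) {
      writeLines(if (is.null(gs$common)) character(0) else gs$common,
                 file.path(out_dir, "signaling_genes.txt"))
      write.table(gene_set_counts(gs$per_subject),
                  file.path(out_dir, "gene_counts.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  invisible(fit)
}
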