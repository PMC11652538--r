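#' Fit the single-sample early-warning model to a time-course study
#'
#' The main entry point for time-course studies. For every subject with
#' `case` or `normal` samples, the subject's samples are ordered by time
#' and scored against a baseline ([score_series()]); the threshold is
#' calibrated from the pooled ranking scores of the `normal` subjects
#' ([compute_threshold()]); and the early-warning signal is called per
#' subject ([detect_warning()]).
#'
#' The baseline is built from the `baseline`-group samples: with
#' `baseline_mode = "per-subject"` (appropriate when every subject has its
#' own pre-challenge baseline samples) each subject is scored against its
#' own; with `"pooled"` all baseline samples are averaged into one shared
#' profile. The structural zero at each series' first time point (the
#' ranking score is defined relative to that point) is excluded from the
#' calibration pool, which otherwise contains all time points of all
#' normal subjects.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @param metadata data frame with columns `sample_id`, `subject_id`,
#'   `time`, `group` (`baseline` / `case` / `normal`); every matrix column
#'   must appear exactly once.
#' @param m number of top local scores aggregated per time point
#'   (default 50).
#' @param alpha upper-tail probability for the threshold (default 0.05).
#' @param baseline_mode `"per-subject"` or `"pooled"`.
#' @param use_absolute select top local scores by absolute value
#'   (see [sample_score()]).
#' @param time_order optional explicit ordering of non-numeric time labels.
#' @param theta optional fixed threshold; overrides calibration.
#' @param log2_transform apply `log2(x + 1)` before scoring.
#' @return An object of class `spcr`: list with `series` (named list of
#'   score series), `threshold`, `calls` (named list of warning calls),
#'   `subjects` (summary data frame), `baselines`, and the effective
#'   parameters. Methods: `print`, `summary`, `coef` (ranking-score
#'   matrix), `plot`, `predict`.
#' @examples
#' study <- simulate_factor_study(simulation_config(n_genes = 60,
#'   dnb_size = 8, n_timepoints = 8, transition_index = 5, seed = 42))
#' dat <- with(study, cbind(normal_matrix, course))
#' md <- data.frame(
#'   sample_id = colnames(dat),
#'   subject_id = "s1",
#'   time = c(rep("baseline", ncol(study$normal_matrix)), colnames(study$course)),
#'   group = c(rep("baseline", ncol(study$normal_matrix)), rep("case", ncol(study$course))))
#' fit <- spcr(dat, md, m = 10, theta = 0.5)
#' summary(fit)
#' @export
spcr <- function(x, metadata, m = 50L, alpha = 0.05,
                 baseline_mode = c("per-subject", "pooled"),
                 use_absolute = FALSE, time_order = NULL, theta = NULL,
                 log2_transform = FALSE) {
  baseline_mode <- match.arg(baseline_mode)
  validate_expression_matrix(x)
  md <- validate_metadata(metadata)
  if (log2_transform) {
    if (any(x < 0)) stop("log2(x + 1) requires non-negative values",
                         call. = FALSE)
    x <- log2(x + 1)
  }
  unknown <- setdiff(md$sample_id, colnames(x))
  if (length(unknown)) {
    stop("metadata sample(s) absent from the matrix: ",
         paste(head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  uncovered <- setdiff(colnames(x), md$sample_id)
  if (length(uncovered)) {
    stop("matrix sample(s) absent from the metadata: ",
         paste(head(uncovered, 5L), collapse = ", "), call. = FALSE)
  }

  base_md <- md[md$group == "baseline", , drop = FALSE]
  if (nrow(base_md) == 0L) {
    stop("no baseline-group samples to build a baseline from", call. = FALSE)
  }
  pooled_baseline <- compute_baseline(x[, base_md$sample_id, drop = FALSE])

  course_md <- md[md$group %in% c("case", "normal"), , drop = FALSE]
  if (nrow(course_md) == 0L) {
    stop("no case or normal samples to score", call. = FALSE)
  }
  subjects <- unique(course_md$subject_id)

  baselines <- list()
  series <- list()
  subj_group <- character(0)
  for (sid in subjects) {
    rows <- course_md[course_md$subject_id == sid, , drop = FALSE]
    grp <- if (any(rows$group == "case")) "case" else "normal"
    bl <- if (baseline_mode == "per-subject") {
      own <- base_md[base_md$subject_id == sid, , drop = FALSE]
      if (nrow(own) == 0L) {
        stop("subject ", sid, " has no baseline samples ",
             "(baseline_mode = \"per-subject\")", call. = FALSE)
      }
      compute_baseline(x[, own$sample_id, drop = FALSE])
    } else {
      pooled_baseline
    }
    ord <- match(sort_time_labels(rows$time, time_order), rows$time)
    course <- x[, rows$sample_id[ord], drop = FALSE]
    colnames(course) <- rows$time[ord]
    series[[sid]] <- score_series(course, bl, m = m,
                                  use_absolute = use_absolute,
                                  subject_id = sid, time_order = time_order)
    baselines[[sid]] <- bl
    subj_group[sid] <- grp
  }

  normal_ids <- names(subj_group)[subj_group == "normal"]
  pool <- unlist(lapply(series[normal_ids], function(s) {
    s$ranking_score[-1L]                    # drop the structural zero
  }), use.names = FALSE)

  threshold <- NULL
  if (!is.null(theta)) {
    stopifnot(is.numeric(theta), length(theta) == 1L)
  } else if (length(pool) >= 2L && sd(pool) > 0) {
    threshold <- compute_threshold(pool, alpha = alpha)
    theta <- threshold$theta
  }

  calls <- if (!is.null(theta)) {
    lapply(series, detect_warning, threshold = theta)
  }

  tab <- data.frame(
    subject = names(series),
    group = unname(subj_group[names(series)]),
    n_timepoints = vapply(series, nrow, integer(1)),
    max_ranking_score = vapply(series, function(s) max(s$ranking_score),
                               numeric(1)),
    signal_time = if (is.null(calls)) NA_character_ else
      vapply(calls, function(w) w$signal_time, character(1)),
    signal_index = if (is.null(calls)) NA_integer_ else
      vapply(calls, function(w) w$signal_index, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )

  structure(
    list(series = series, threshold = threshold, theta = theta,
         calls = calls, subjects = tab, baselines = baselines,
         pooled_baseline = pooled_baseline, normal_score_pool = pool,
         m = as.integer(m), alpha = alpha, baseline_mode = baseline_mode,
         use_absolute = use_absolute, time_order = time_order,
         n_genes = nrow(x), call = match.call()),
    class = "spcr"
  )
}

#' @export
print.spcr <- function(x, ...) {
  cat("Single-sample early-warning fit (", x$n_genes, " genes, m = ", x$m,
      ", baseline: ", x$baseline_mode, ")\n", sep = "")
  if (!is.null(x$theta)) {
    cat("Threshold theta = ", format(x$theta),
        if (!is.null(x$threshold)) paste0(" (alpha = ", x$alpha,
          ", calibrated on ", x$threshold$n_normal_scores, " normal scores)")
        else " (user-supplied)", "\n", sep = "")
  } else {
    cat("No threshold (no normal subjects and no theta supplied)\n")
  }
  n_sig <- sum(!is.na(x$subjects$signal_index))
  cat(nrow(x$subjects), " subject(s) scored; ", n_sig,
      " with an early-warning signal\n", sep = "")
  invisible(x)
}

#' @export
summary.spcr <- function(object, ...) {
  structure(list(subjects = object$subjects, theta = object$theta,
                 alpha = object$alpha, m = object$m,
                 n_genes = object$n_genes,
                 baseline_mode = object$baseline_mode),
            class = "summary.spcr")
}

#' @export
print.summary.spcr <- function(x, ...) {
  cat("Early-warning summary: ", x$n_genes, " genes, m = ", x$m,
      ", baseline ", x$baseline_mode, sep = "")
  if (!is.null(x$theta)) cat(", theta = ", format(x$theta), sep = "")
  cat("\n\n")
  print.data.frame(x$subjects, row.names = FALSE)
  invisible(x)
}

#' Ranking-score matrix of a fitted early-warning model
#'
#' @param object an [`spcr`] fit.
#' @param ... unused.
#' @return Numeric matrix, subjects in rows, time labels in columns,
#'   holding the per-time-point ranking scores (NA where a subject lacks a
#'   time point).
#' @export
coef.spcr <- function(object, ...) {
  times <- sort_time_labels(
    unique(unlist(lapply(object$series, function(s) s$time))),
    object$time_order)
  out <- matrix(NA_real_, length(object$series), length(times),
                dimnames = list(names(object$series), times))
  for (sid in names(object$series)) {
    s <- object$series[[sid]]
    out[sid, match(s$time, times)] <- s$ranking_score
  }
  out
}

#' Score new samples against a fitted baseline
#'
#' @param object an [`spcr`] fit.
#' @param newdata numeric matrix of new samples (genes x time points),
#'   column names the time labels.
#' @param subject score against this subject's baseline (default: the
#'   pooled baseline).
#' @param ... unused.
#' @return An [`spcr_score_series`][score_series].
#' @export
predict.spcr <- function(object, newdata, subject = NULL, ...) {
  bl <- if (is.null(subject)) object$pooled_baseline else {
    if (!subject %in% names(object$baselines)) {
      stop("no baseline for subject ", subject, call. = FALSE)
    }
    object$baselines[[subject]]
  }
  score_series(newdata, bl, m = object$m, use_absolute = object$use_absolute,
               subject_id = subject, time_order = object$time_order)
}

#' Plot ranking-score trajectories of a fitted early-warning model
#'
#' One line per subject (case subjects solid, normal subjects dashed grey)
#' with the calibrated threshold as a horizontal line.
#'
#' @param x an [`spcr`] fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.spcr <- function(x, ...) {
  sc <- t(coef(x))
  grp <- x$subjects$group[match(colnames(sc), x$subjects$subject)]
  matplot(seq_len(nrow(sc)), sc, type = "l", lty = ifelse(grp == "case", 1, 2),
          col = ifelse(grp == "case", "firebrick", "grey50"),
          xlab = "time point", ylab = expression(Delta * S^t),
          xaxt = "n", ...)
  axis(1, at = seq_len(nrow(sc)), labels = rownames(sc))
  if (!is.null(x$theta)) {
    abline(h = x$theta, lty = 3)
  }
  legend("topleft", bty = "n", lty = c(1, 2, 3),
         col = c("firebrick", "grey50", "black"),
         legend = c("case", "normal", expression(theta)))
  invisible(x)
}

#' Fit the stage-averaged early-warning model to a cross-sectional cohort
#'
#' Turns a stage-grouped cohort (one `group = "case"` sample set per stage,
#' plus `baseline`-group reference samples such as tumor-adjacent tissue)
#' into a single-sample-per-stage course ([average_by_stage()]), scores it
#' against the pooled baseline, and calls the pre-disease stage with the
#' sustained-drastic-increase rule ([detect_stage_transition()]).
#'
#' @inheritParams spcr
#' @param stage_order optional explicit stage ordering (e.g.
#'   `c("I", "IA", "IB", "II", ...)`).
#' @param min_consecutive_increases,min_relative_jump rule parameters, see
#'   [detect_stage_transition()].
#' @return An object of class `spcr_stages`: list with `series`, `stage_call`,
#'   `baseline`, and the effective parameters.
#' @export
spcr_stages <- function(x, metadata, m = 50L, stage_order = NULL,
                        use_absolute = FALSE,
                        min_consecutive_increases = 2L,
                        min_relative_jump = 1.0, log2_transform = FALSE) {
  validate_expression_matrix(x)
  md <- validate_metadata(metadata)
  if (log2_transform) x <- log2(x + 1)
  base_ids <- md$sample_id[md$group == "baseline"]
  if (length(base_ids) == 0L) {
    stop("no baseline-group (reference) samples", call. = FALSE)
  }
  baseline <- compute_baseline(x[, base_ids, drop = FALSE])
  staged <- average_by_stage(x, md, stage_order = stage_order)
  series <- score_series(staged, baseline, m = m, use_absolute = use_absolute,
                         subject_id = "stage-averaged",
                         time_order = stage_order)
  call_ <- detect_stage_transition(
    setNames(series$ranking_score, series$time),
    min_consecutive_increases = min_consecutive_increases,
    min_relative_jump = min_relative_jump)
  structure(
    list(series = series, stage_call = call_, baseline = baseline,
         m = as.integer(m), use_absolute = use_absolute,
         stage_order = stage_order, n_genes = nrow(x), call = match.call()),
    class = "spcr_stages"
  )
}

#' @export
print.spcr_stages <- function(x, ...) {
  cat("Stage-averaged early-warning fit (", x$n_genes, " genes, m = ", x$m,
      ")\n", sep = "")
  print(x$stage_call)
  invisible(x)
}

#' Candidate signaling genes at each subject's signal time point
#'
#' For every subject with an early-warning signal, re-derives the local
#' scores at the signal time point and selects the top fraction of genes;
#' optionally intersects the per-subject sets.
#'
#' @param fit an [`spcr`] fit (must have a threshold).
#' @param x the expression matrix the model was fitted to.
#' @param metadata the metadata table the model was fitted to.
#' @param fraction fraction of genes selected per subject (default 0.05).
#' @param min_subjects when not `NULL`, also return the genes common to at
#'   least this many subjects' sets (default 5).
#' @return List with `per_subject` (named list of gene-id vectors, one per
#'   signalling subject) and `common` (gene ids in >= `min_subjects` sets,
#'   `NULL` when `min_subjects` is).
#' @export
signaling_genes <- function(fit, x, metadata, fraction = 0.05,
                            min_subjects = 5L) {
  stopifnot(inherits(fit, "spcr"))
  if (is.null(fit$calls)) {
    stop("fit has no threshold, so no signal time points", call. = FALSE)
  }
  md <- validate_metadata(metadata)
  sets <- list()
  for (sid in names(fit$calls)) {
    w <- fit$calls[[sid]]
    if (is.na(w$signal_index)) next
    rows <- md[md$subject_id == sid & md$group %in% c("case", "normal") &
                 md$time == w$signal_time, , drop = FALSE]
    if (nrow(rows) != 1L) next
    tab <- local_scores(x[, rows$sample_id], fit$baselines[[sid]])
    sets[[sid]] <- select_top_fraction(tab, fraction = fraction,
                                       use_absolute = fit$use_absolute)
  }
  list(per_subject = sets,
       common = if (!is.null(min_subjects) && length(sets))
         common_genes(sets, min_subjects = min_subjects))
}
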