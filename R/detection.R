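#' Calibrate the early-warning threshold from normal-sample scores
#'
#' The pooled ranking scores of normal samples are summarized by their mean
#' and (sample, n-1) standard deviation; assuming the standardized scores
#' follow a standard normal distribution, the threshold is the value whose
#' z-score sits at the upper `alpha` tail:
#' `theta = mean + qnorm(1 - alpha) * sd`. The threshold is expressed back
#' on the original ranking-score scale so it is directly comparable to a
#' subject's series.
#'
#' @param normal_scores numeric vector of ranking scores from normal
#'   samples (length >= 2, non-degenerate).
#' @param alpha upper tail probability, default 0.05.
#' @return An object of class `spcr_threshold`: list with `theta`, `alpha`,
#'   `n_normal_scores`, `mean_normal`, `sd_normal`.
#' @examples
#' compute_threshold(c(-1, 0, 1))  # theta = qnorm(0.95) ~ 1.6449
#' @export
compute_threshold <- function(normal_scores, alpha = 0.05) {
  if (length(normal_scores) < 2L) {
    stop("need at least 2 normal scores to calibrate a threshold",
         call. = FALSE)
  }
  if (anyNA(normal_scores)) {
    stop("normal scores contain missing values", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  mu <- mean(normal_scores)
  s <- sd(normal_scores)
  if (s == 0) {
    stop("normal scores are degenerate (zero standard deviation); ",
         "cannot calibrate a threshold", call. = FALSE)
  }
  structure(
    list(
      theta = mu + qnorm(1 - alpha) * s,
      alpha = alpha,
      n_normal_scores = length(normal_scores),
      mean_normal = mu,
      sd_normal = s
    ),
    class = "spcr_threshold"
  )
}

#' @export
print.spcr_threshold <- function(x, ...) {
  cat("Early-warning threshold theta = ", format(x$theta),
      " (alpha = ", x$alpha, ", calibrated on ", x$n_normal_scores,
      " normal scores; mean = ", format(x$mean_normal),
      ", sd = ", format(x$sd_normal), ")\n", sep = "")
  invisible(x)
}

# Accept either a calibrated threshold object or a bare theta.
theta_value <- function(threshold) {
  if (inherits(threshold, "spcr_threshold")) return(threshold$theta)
  if (is.numeric(threshold) && length(threshold) == 1L) return(threshold)
  stop("`threshold` must be an spcr_threshold object or a single number",
       call. = FALSE)
}

#' Call the early-warning signal in a ranking-score series
#'
#' The signal time is the earliest time point whose ranking score strictly
#' exceeds the threshold; a score exactly at the threshold does not fire.
#' If no time point exceeds it, no signal is called.
#'
#' @param series an [`spcr_score_series`][score_series] object (or a data
#'   frame with `time` and `ranking_score` columns).
#' @param threshold an [`spcr_threshold`][compute_threshold] object or a
#'   bare numeric theta.
#' @return An object of class `spcr_warning`: list with `subject_id`,
#'   `signal_time` (label or `NA`), `signal_index` (position in the series
#'   or `NA`), `theta`, and `exceeded` (data frame of all exceeding points).
#' @examples
#' ser <- structure(data.frame(time = c("0", "5", "12", "21"),
#'                             score = c(1, 1.1, 1.9, 1.3),
#'                             ranking_score = c(0, 0.1, 0.9, 0.3)),
#'                  class = c("spcr_score_series", "data.frame"))
#' detect_warning(ser, 0.619)  # fires at the third time point
#' @export
detect_warning <- function(series, threshold) {
  if (!is.data.frame(series) || nrow(series) == 0L ||
      !all(c("time", "ranking_score") %in% names(series))) {
    stop("`series` must be a non-empty score series with `time` and ",
         "`ranking_score` columns", call. = FALSE)
  }
  theta <- theta_value(threshold)
  above <- which(series$ranking_score > theta)
  idx <- if (length(above)) above[1L] else NA_integer_
  structure(
    list(
      subject_id = attr(series, "subject_id"),
      signal_time = if (is.na(idx)) NA_character_ else
        as.character(series$time[idx]),
      signal_index = idx,
      theta = theta,
      exceeded = data.frame(
        time = as.character(series$time[above]),
        ranking_score = series$ranking_score[above],
        stringsAsFactors = FALSE
      )
    ),
    class = "spcr_warning"
  )
}

#' @export
print.spcr_warning <- function(x, ...) {
  sid <- x$subject_id
  if (is.na(x$signal_index)) {
    cat("No early-warning signal",
        if (!is.null(sid)) paste0(" for subject ", sid),
        " (theta = ", format(x$theta), ")\n", sep = "")
  } else {
    cat("Early-warning signal",
        if (!is.null(sid)) paste0(" for subject ", sid),
        " at time ", x$signal_time, " (series position ", x$signal_index,
        "; theta = ", format(x$theta), "; ",
        nrow(x$exceeded), " point(s) above threshold)\n", sep = "")
  }
  invisible(x)
}

#' Call the pre-disease stage in a stage-averaged ranking-score series
#'
#' Cross-sectional cohorts (e.g. tumor stages) yield one averaged sample per
#' stage and too few normal samples to calibrate a threshold; the call is
#' instead based on a drastic, sustained rise of the ranking score after the
#' first stage. The rule: the called stage is the earliest stage `s` at
#' which the score has strictly increased for at least
#' `min_consecutive_increases` consecutive stages, and the cumulative rise
#' over those final `min_consecutive_increases` steps is at least
#' `min_relative_jump` times the range (max - min) of the scores before the
#' run. At least two pre-run stages are required, so the normal-phase
#' fluctuation the rise is compared against is measurable. This is a
#' heuristic formalization of "drastic increase on a continuous basis";
#' both parameters are exposed.
#'
#' @param ranking_scores numeric vector of per-stage ranking scores
#'   (length >= 3), ordered by stage.
#' @param stage_labels optional character labels for the stages (defaults to
#'   names of `ranking_scores` or positional labels).
#' @param min_consecutive_increases minimum run of strict increases ending
#'   at the called stage (default 2).
#' @param min_relative_jump minimum cumulative rise over the run, as a
#'   multiple of the pre-run score range (default 1.0).
#' @return An object of class `spcr_stage_call`: list with `stage_labels`,
#'   `ranking_scores`, `called_stage` (label or `NA`), `called_index`, and
#'   `rule_params`.
#' @examples
#' detect_stage_transition(c(0, 0.1, 0.1, 0.5, 1.2))  # calls the 5th stage
#' @export
detect_stage_transition <- function(ranking_scores, stage_labels = NULL,
                                    min_consecutive_increases = 2L,
                                    min_relative_jump = 1.0) {
  if (length(ranking_scores) < 3L) {
    stop("stage detection needs at least 3 stages", call. = FALSE)
  }
  if (anyNA(ranking_scores)) {
    stop("ranking scores contain missing values", call. = FALSE)
  }
  if (is.null(stage_labels)) {
    stage_labels <- names(ranking_scores)
    if (is.null(stage_labels)) {
      stage_labels <- paste0("stage", seq_along(ranking_scores))
    }
  }
  stopifnot(length(stage_labels) == length(ranking_scores))
  k <- as.integer(min_consecutive_increases)
  stopifnot(k >= 1L, min_relative_jump >= 0)

  inc <- diff(ranking_scores) > 0
  called <- NA_integer_
  run <- 0L
  for (s in seq_along(inc)) {           # inc[s] is the step into stage s + 1
    run <- if (inc[s]) run + 1L else 0L
    at <- s + 1L
    start <- at - k                     # rise measured over the final k steps
    if (run >= k && start >= 2L) {
      rise <- ranking_scores[at] - ranking_scores[start]
      prior <- ranking_scores[seq_len(start)]
      if (rise >= min_relative_jump * (max(prior) - min(prior))) {
        called <- at
        break
      }
    }
  }
  structure(
    list(
      stage_labels = as.character(stage_labels),
      ranking_scores = unname(ranking_scores),
      called_stage = if (is.na(called)) NA_character_ else
        as.character(stage_labels[called]),
      called_index = called,
      rule_params = list(min_consecutive_increases = k,
                         min_relative_jump = min_relative_jump)
    ),
    class = "spcr_stage_call"
  )
}

#' @export
print.spcr_stage_call <- function(x, ...) {
  if (is.na(x$called_index)) {
    cat("No sustained drastic increase across",
        length(x$stage_labels), "stages\n")
  } else {
    cat("Pre-disease stage called at ", x$called_stage,
        " (stage ", x$called_index, " of ", length(x$stage_labels), ")\n",
        sep = "")
  }
  invisible(x)
}
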