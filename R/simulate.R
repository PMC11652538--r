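#' Configuration for a synthetic expression study
#'
#' Bundles the generator parameters shared by the three study generators.
#' Defaults describe the standard in-silico benchmark used throughout the
#' package's tests: 200 genes, a planted 20-gene dynamic-network-biomarker
#' (DNB) module, a 16-point time course with the critical transition at
#' time point 10, a 10-sample normal pool for the baseline, unit
#' observation noise on a log-intensity-like scale, and a factor loading
#' that grows by 1 noise-SD per post-transition step.
#'
#' @param n_genes number of genes (network mode: number of nodes, >= 6).
#' @param dnb_size number of planted DNB genes (`< n_genes`).
#' @param n_timepoints number of time points in the case course.
#' @param transition_index 1-based index of the first post-transition time
#'   point; must satisfy `0 < transition_index < n_timepoints`.
#' @param n_normal_samples number of normal samples in the baseline pool.
#' @param noise_sd observation noise SD (factor mode) or SDE diffusion
#'   coefficient (network mode, where ~0.05 is a sensible value).
#' @param dnb_variance_ramp growth of the shared-factor loading per
#'   post-transition step, in units of `noise_sd`; the default `sqrt(3)`
#'   doubles the DNB-gene SD at the first post-transition time point
#'   (`sqrt(noise_sd^2 + loading^2) = 2 * noise_sd`); 0 disables the
#'   planted signal entirely.
#' @param seed RNG seed; identical configs give identical studies.
#' @param mode `"factor_model"` or `"network_sde"`.
#' @return An object of class `spcr_sim_config` (a validated list).
#' @export
simulation_config <- function(n_genes = 200L, dnb_size = 20L,
                              n_timepoints = 16L, transition_index = 10L,
                              n_normal_samples = 10L, noise_sd = 1,
                              dnb_variance_ramp = sqrt(3), seed = 1L,
                              mode = c("factor_model", "network_sde")) {
  mode <- match.arg(mode)
  cfg <- list(
    n_genes = as.integer(n_genes), dnb_size = as.integer(dnb_size),
    n_timepoints = as.integer(n_timepoints),
    transition_index = as.integer(transition_index),
    n_normal_samples = as.integer(n_normal_samples),
    noise_sd = as.numeric(noise_sd),
    dnb_variance_ramp = as.numeric(dnb_variance_ramp),
    seed = as.integer(seed), mode = mode
  )
  if (cfg$n_genes < 2L) stop("`n_genes` must be >= 2", call. = FALSE)
  if (cfg$dnb_size < 1L || cfg$dnb_size >= cfg$n_genes) {
    stop("`dnb_size` must satisfy 1 <= dnb_size < n_genes", call. = FALSE)
  }
  if (cfg$n_timepoints < 2L) stop("`n_timepoints` must be >= 2", call. = FALSE)
  if (cfg$transition_index < 1L ||
      cfg$transition_index >= cfg$n_timepoints) {
    stop("`transition_index` must satisfy 0 < transition_index < n_timepoints",
         call. = FALSE)
  }
  if (cfg$n_normal_samples < 1L) {
    stop("`n_normal_samples` must be >= 1", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (cfg$dnb_variance_ramp < 0) {
    stop("`dnb_variance_ramp` must be >= 0", call. = FALSE)
  }
  structure(cfg, class = "spcr_sim_config")
}

as_sim_config <- function(config) {
  if (inherits(config, "spcr_sim_config")) return(config)
  if (is.list(config)) return(do.call(simulation_config, config))
  stop("`config` must be an spcr_sim_config (see simulation_config())",
       call. = FALSE)
}

new_sim_study <- function(normal, course, truth, dnb, config) {
  structure(
    list(normal_matrix = normal, course = course,
         truth_transition_index = truth, dnb_gene_ids = dnb,
         config = config),
    class = "spcr_sim_study"
  )
}

#' @export
print.spcr_sim_study <- function(x, ...) {
  cat("Synthetic study (", x$config$mode, "): ",
      nrow(x$course), " genes, ", ncol(x$course), " time points, ",
      ncol(x$normal_matrix), " normal samples; ",
      if (is.na(x$truth_transition_index)) "no planted transition"
      else paste0("transition at time point ", x$truth_transition_index,
                  ", ", length(x$dnb_gene_ids), " DNB genes"),
      "\n", sep = "")
  invisible(x)
}

#' Factor-model study with a planted DNB module
#'
#' Generates the statistical signature that DNB theory predicts near a
#' critical transition, in its simplest sufficient form. Every gene has a
#' fixed mean level (drawn once per study from N(7, 2), a log2-microarray-
#' like scale) plus i.i.d. Gaussian observation noise. From the transition
#' time point onward, the planted DNB genes additionally receive a shared
#' latent displacement `loading * (1 + eta_t)` with `eta_t` standard
#' normal, whose loading grows linearly by `dnb_variance_ramp * noise_sd`
#' per step: their SD, their pairwise correlation, and their mean
#' displacement from baseline all rise with time while non-DNB genes stay
#' stationary. With `dnb_variance_ramp = 0` the study is statistically
#' identical to a null study.
#'
#' With `n_null_subjects > 0` the study additionally carries that many
#' null time courses drawn from the *same cohort* (same gene means, no
#' planted signal) under `$null_courses`, mirroring the asymptomatic
#' subjects of a challenge study; their pooled ranking scores are the
#' natural threshold-calibration set for the cohort.
#'
#' @param config an [`spcr_sim_config`][simulation_config] (or a list of
#'   its arguments).
#' @param n_null_subjects number of same-cohort null subjects to generate
#'   alongside the case course (default 0).
#' @return An object of class `spcr_sim_study`: list with `normal_matrix`
#'   (baseline pool), `course` (time-labelled columns), ground truth
#'   `truth_transition_index` and `dnb_gene_ids`, and (when requested)
#'   `null_courses`.
#' @export
simulate_factor_study <- function(config = simulation_config(),
                                  n_null_subjects = 0L) {
  cfg <- as_sim_config(config)
  stopifnot(n_null_subjects >= 0L)
  with_seed(cfg$seed, {
    genes <- sprintf("g%03d", seq_len(cfg$n_genes))
    mu <- rnorm(cfg$n_genes, mean = 7, sd = 2)
    names(mu) <- genes

    draw_course <- function(labels) {
      m <- matrix(rnorm(cfg$n_genes * length(labels), sd = cfg$noise_sd),
                  cfg$n_genes, length(labels))
      dimnames(m) <- list(genes, labels)
      m + mu
    }

    # normal pool and raw course are drawn before the module is planted, so
    # a zero ramp reproduces the null study of the same seed exactly
    normal <- draw_course(sprintf("n%02d", seq_len(cfg$n_normal_samples)))
    course <- draw_course(as.character(seq_len(cfg$n_timepoints)))
    dnb <- sort(sample(genes, cfg$dnb_size))
    for (t in seq(cfg$transition_index, cfg$n_timepoints)) {
      lambda <- cfg$dnb_variance_ramp * cfg$noise_sd *
        (t - cfg$transition_index + 1L)
      course[dnb, t] <- course[dnb, t] + lambda * (1 + rnorm(1L))
    }
    study <- new_sim_study(normal, course, cfg$transition_index, dnb, cfg)
    if (n_null_subjects > 0L) {
      study$null_courses <- lapply(seq_len(n_null_subjects), function(i) {
        draw_course(as.character(seq_len(cfg$n_timepoints)))
      })
      names(study$null_courses) <- sprintf("null%02d", seq_len(n_null_subjects))
    }
    study
  })
}

#' Null study: stationary noise, nothing planted
#'
#' Same marginal structure as [simulate_factor_study()] before its
#' transition, at every time point. Used for specificity (false-positive
#' rate) checks and for building normal-score pools; mirrors subjects that
#' never leave the normal state.
#'
#' @inheritParams simulate_factor_study
#' @return An `spcr_sim_study` with `truth_transition_index = NA` and an
#'   empty DNB set (plus `$null_courses` when `n_null_subjects > 0`).
#' @export
simulate_null_study <- function(config = simulation_config(),
                                n_null_subjects = 0L) {
  cfg <- as_sim_config(config)
  stopifnot(n_null_subjects >= 0L)
  with_seed(cfg$seed, {
    genes <- sprintf("g%03d", seq_len(cfg$n_genes))
    mu <- rnorm(cfg$n_genes, mean = 7, sd = 2)
    names(mu) <- genes
    draw_course <- function(labels) {
      m <- matrix(rnorm(cfg$n_genes * length(labels), sd = cfg$noise_sd),
                  cfg$n_genes, length(labels))
      dimnames(m) <- list(genes, labels)
      m + mu
    }
    normal <- draw_course(sprintf("n%02d", seq_len(cfg$n_normal_samples)))
    course <- draw_course(as.character(seq_len(cfg$n_timepoints)))
    study <- new_sim_study(normal, course, NA_integer_, character(0), cfg)
    if (n_null_subjects > 0L) {
      study$null_courses <- lapply(seq_len(n_null_subjects), function(i) {
        draw_course(as.character(seq_len(cfg$n_timepoints)))
      })
      names(study$null_courses) <- sprintf("null%02d", seq_len(n_null_subjects))
    }
    study
  })
}

# Saddle-node geometry of the driver node
#   dx = a + q + V x^2/(1 + x^2) - d x,  V = 8, d = 4.
# Fold points solve d = 2 V x/(1+x^2)^2, i.e. (1+x^2)^2 = 4x; the basal rate
# `a` is chosen so the fold that annihilates the low-expression branch sits
# exactly at q = 0 (the other fold then sits near q = -0.54, so the low
# state exists throughout q in (-0.54, 0)).
driver_basal_rate <- function() {
  xc <- uniroot(function(x) (1 + x^2)^2 - 4 * x, c(0.05, 0.9),
                tol = 1e-12)$root
  4 * xc - 8 * xc^2 / (1 + xc^2)
}

#' Michaelis-Menten stochastic network driven across a fold bifurcation
#'
#' A small gene regulatory network of Michaelis-Menten-form stochastic
#' differential equations, integrated by Euler-Maruyama while a control
#' parameter `q` is swept across a fold (saddle-node) bifurcation at
#' `q = 0`. Node 1 is a bistable auto-activator whose low-expression state
#' is annihilated exactly at `q = 0` (basal rate derived analytically);
#' the remaining nodes are alternately activated by node 1 and repressed in
#' a cascade, so the whole network reorganizes after the transition. As the
#' fold is approached from below the driver's restoring force vanishes, so
#' its fluctuations grow: critical slowing down, the dynamical signature
#' the scoring statistic is designed to detect.
#'
#' One sample (the network state) is recorded at each of `n_timepoints`
#' values of `q` on a grid from `q_min` to `q_max`; the ground-truth
#' transition index is the first grid point with `q >= 0`. The baseline
#' pool is `n_normal_samples` replicate states recorded at `q_min`.
#' `config$transition_index` is ignored in this mode (the grid determines
#' the truth) and `config$noise_sd` is the SDE diffusion coefficient.
#'
#' This network is a stand-in of the model class (it is not a reproduction
#' of any particular published system); its purpose is a ground-truthed
#' tipping-point time course with realistic dynamics.
#'
#' @inheritParams simulate_factor_study
#' @param q_min,q_max range of the control parameter (defaults -0.4 to 0.2);
#'   `q_min` must stay above about -0.54, where the low state is born.
#' @param dt Euler-Maruyama step size (default 0.01).
#' @param burn_in number of equilibration steps at `q_min` before any
#'   recording (default 1000).
#' @param steps_per_q integration steps between consecutive recorded
#'   samples (default 2000, i.e. 20 time units of relaxation per q).
#' @return An `spcr_sim_study`; `dnb_gene_ids` holds the driver and its
#'   direct targets (the nodes that shift first at the transition).
#' @export
simulate_network_study <- function(config = simulation_config(
                                     n_genes = 18L, dnb_size = 9L,
                                     noise_sd = 0.05, mode = "network_sde"),
                                   q_min = -0.4, q_max = 0.2, dt = 0.01,
                                   burn_in = 1000L, steps_per_q = 2000L) {
  cfg <- as_sim_config(config)
  p <- cfg$n_genes
  if (p < 6L) stop("network mode needs at least 6 nodes", call. = FALSE)
  if (q_min >= 0 || q_max <= 0) {
    stop("the q grid must straddle the critical point q = 0", call. = FALSE)
  }
  stopifnot(dt > 0, burn_in >= 0, steps_per_q >= 1)
  a <- driver_basal_rate()
  if (q_min <= -a) {
    stop("q_min must exceed ", format(-a, digits = 4),
         " for the low-expression state to exist", call. = FALSE)
  }
  sigma <- cfg$noise_sd
  genes <- sprintf("g%02d", seq_len(p))
  # direct targets of the driver: even-numbered nodes (activated by node 1)
  direct <- seq(2L, p, by = 2L)
  K2 <- 0.25                                  # MM constant squared (K = 0.5)

  drift <- function(x, q) {
    dx <- numeric(p)
    dx[1L] <- a + q + 8 * x[1L]^2 / (1 + x[1L]^2) - 4 * x[1L]
    for (j in 2L:p) {
      if (j %% 2L == 0L) {                    # activated by the driver
        dx[j] <- 0.1 + 2 * x[1L]^2 / (K2 + x[1L]^2) - x[j]
      } else {                                # repressed by its predecessor
        dx[j] <- 0.1 + 2 * K2 / (K2 + x[j - 1L]^2) - x[j]
      }
    }
    dx
  }

  integrate_segment <- function(x, q, n_steps) {
    sq <- sigma * sqrt(dt)
    for (i in seq_len(n_steps)) {
      x <- x + drift(x, q) * dt
      if (sigma > 0) x <- x + sq * rnorm(p)
      x <- abs(x)                             # reflect at 0 (concentrations)
      if (any(!is.finite(x)) || any(x > 1e6)) {
        stop("SDE integration blew up; use a smaller `dt`", call. = FALSE)
      }
    }
    x
  }

  with_seed(cfg$seed, {
    qs <- round(seq(q_min, q_max, length.out = cfg$n_timepoints), 10L)
    x <- rep(0.2, p)
    x <- integrate_segment(x, q_min, burn_in)

    normal <- matrix(NA_real_, p, cfg$n_normal_samples,
                     dimnames = list(genes, sprintf("n%02d", seq_len(cfg$n_normal_samples))))
    for (s in seq_len(cfg$n_normal_samples)) {
      x <- integrate_segment(x, q_min, steps_per_q)
      normal[, s] <- x
    }

    course <- matrix(NA_real_, p, cfg$n_timepoints,
                     dimnames = list(genes, formatC(qs, format = "g")))
    for (t in seq_along(qs)) {
      x <- integrate_segment(x, qs[t], steps_per_q)
      course[, t] <- x
    }
    truth <- which(qs >= -1e-12)[1L]
    new_sim_study(normal, course, truth, genes[sort(c(1L, direct))], cfg)
  })
}
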