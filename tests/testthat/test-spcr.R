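# Build a small cohort (one case subject, a few normal subjects, shared
# per-subject baselines) as matrix + metadata, from the factor generator.
cohort_fixture <- function(seed = 1, n_genes = 80, dnb = 10, T = 8, ti = 5,
                           n_norm_subjects = 3, n_base = 4) {
  st <- simulate_factor_study(
    simulation_config(n_genes = n_genes, dnb_size = dnb, n_timepoints = T,
                      transition_index = ti, n_normal_samples = n_base,
                      seed = seed),
    n_null_subjects = n_norm_subjects)
  cols <- list(); meta <- list()
  add <- function(m, subject, times, group) {
    ids <- paste0(subject, "_", times)
    colnames(m) <- ids
    cols[[length(cols) + 1]] <<- m
    meta[[length(meta) + 1]] <<- data.frame(
      sample_id = ids, subject_id = subject, time = times, group = group,
      stringsAsFactors = FALSE)
  }
  add(st$normal_matrix, "case1", colnames(st$normal_matrix), "baseline")
  add(st$course, "case1", colnames(st$course), "case")
  for (i in seq_along(st$null_courses)) {
    sid <- sprintf("asx%d", i)
    # each normal subject reuses the shared pool as its own baseline samples
    bl <- st$normal_matrix + 0
    add(bl, sid, colnames(st$normal_matrix), "baseline")
    add(st$null_courses[[i]], sid, colnames(st$course), "normal")
  }
  list(x = do.call(cbind, cols), md = do.call(rbind, meta), study = st)
}

test_that("the fitted model scores every subject and calibrates theta", {
  fx <- cohort_fixture(seed = 21)
  fit <- spcr(fx$x, fx$md, m = 15)
  expect_s3_class(fit, "spcr")
  expect_length(fit$series, 4L)
  expect_s3_class(fit$threshold, "spcr_threshold")
  # pool excludes each normal series' structural zero
  expect_length(fit$normal_score_pool, 3L * (8L - 1L))
  expect_identical(sort(fit$subjects$group),
                   sort(c("case", "normal", "normal", "normal")))

  cm <- coef(fit)
  expect_identical(dim(cm), c(4L, 8L))
  expect_true(all(cm[, 1] == 0))

  s <- summary(fit)
  expect_s3_class(s, "summary.spcr")
  expect_output(print(s), "theta")
  expect_output(print(fit), "subject")
})

test_that("fitted series match the low-level scoring path", {
  fx <- cohort_fixture(seed = 22)
  fit <- spcr(fx$x, fx$md, m = 15)
  bl <- compute_baseline(fx$study$normal_matrix)
  direct <- score_series(fx$study$course, bl, m = 15)
  expect_equal(fit$series[["case1"]]$score, direct$score)
  expect_equal(fit$series[["case1"]]$ranking_score, direct$ranking_score)

  pred <- predict(fit, fx$study$course, subject = "case1")
  expect_equal(pred$score, direct$score)
})

test_that("metadata/matrix mismatches are rejected", {
  fx <- cohort_fixture(seed = 23)
  expect_error(spcr(fx$x[, -1], fx$md, m = 15), "absent from the matrix")
  expect_error(spcr(fx$x, fx$md[-1, ], m = 15), "absent from the metadata")
  md_nobase <- fx$md
  md_nobase$group[md_nobase$group == "baseline"] <- "normal"
  expect_error(spcr(fx$x, md_nobase, m = 15), "baseline")
})

test_that("a fixed theta bypasses calibration and is used for calls", {
  fx <- cohort_fixture(seed = 24)
  fit <- spcr(fx$x, fx$md, m = 15, theta = 1e9)
  expect_null(fit$threshold)
  expect_true(all(is.na(fit$subjects$signal_index)))
})

test_that("plot method draws without error", {
  fx <- cohort_fixture(seed = 25)
  fit <- spcr(fx$x, fx$md, m = 15)
  pdf(NULL)
  on.exit(dev.off())
  expect_no_error(plot(fit))
})

test_that("signaling genes are selected at each subject's signal time", {
  fx <- cohort_fixture(seed = 26)
  fit <- spcr(fx$x, fx$md, m = 15,
              alpha = 0.05 / 7)           # family-wise over 7 tested points
  gs <- signaling_genes(fit, fx$x, fx$md, fraction = 0.1, min_subjects = 2)
  if (!is.na(fit$subjects$signal_index[fit$subjects$subject == "case1"])) {
    sel <- gs$per_subject[["case1"]]
    expect_length(sel, ceiling(0.1 * 80))
    # planted module dominates the selection at the signal point
    expect_gt(length(intersect(sel, fx$study$dnb_gene_ids)), 2)
  }
  for (sel in gs$per_subject) expect_false(anyDuplicated(sel) > 0)
})

test_that("stage mode averages stages and calls the planted jump", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:60)
  n_base <- 6
  base <- matrix(rnorm(60 * n_base, 7, 1), 60,
                 dimnames = list(genes, paste0("adj", 1:n_base)))
  stages <- c("I", "IA", "IB", "II", "IIA")
  reps <- 3
  mu <- rowMeans(base)
  cols <- list(); meta <- list()
  for (si in seq_along(stages)) {
    ids <- paste0("t", si, "_", seq_len(reps))
    m <- matrix(rnorm(60 * reps, 0, 0.4), 60) + mu
    # plant a drastic coordinated shift in 8 genes from stage II onward
    if (si >= 4) m[1:8, ] <- m[1:8, ] + 3 * (si - 3)
    colnames(m) <- ids
    cols[[si]] <- m
    meta[[si]] <- data.frame(sample_id = ids, subject_id = "cohort",
                             time = stages[si], group = "case")
  }
  x <- cbind(base, do.call(cbind, cols))
  md <- rbind(data.frame(sample_id = colnames(base), subject_id = "cohort",
                         time = "adjacent", group = "baseline"),
              do.call(rbind, meta))
  fit <- spcr_stages(x, md, m = 8, stage_order = stages)
  expect_s3_class(fit, "spcr_stages")
  expect_identical(fit$series$time, stages)
  expect_true(fit$stage_call$called_stage %in% c("II", "IIA"))
})
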