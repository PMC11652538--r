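test_that("simulation configs are validated", {
  expect_s3_class(simulation_config(), "spcr_sim_config")
  expect_error(simulation_config(dnb_size = 200, n_genes = 200), "dnb_size")
  expect_error(simulation_config(transition_index = 16, n_timepoints = 16),
               "transition_index")
  expect_error(simulation_config(transition_index = 0), "transition_index")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(mode = "magic"), "arg")
})

test_that("factor studies have the declared shape, truth and reproducibility", {
  cfg <- simulation_config(n_genes = 200, dnb_size = 20, n_timepoints = 16,
                           transition_index = 10, seed = 1)
  st <- simulate_factor_study(cfg)
  expect_identical(dim(st$course), c(200L, 16L))
  expect_identical(dim(st$normal_matrix), c(200L, 10L))
  expect_identical(st$truth_transition_index, 10L)
  expect_length(st$dnb_gene_ids, 20L)
  expect_true(all(st$dnb_gene_ids %in% rownames(st$course)))

  # identical config + seed => identical study
  st2 <- simulate_factor_study(cfg)
  expect_identical(st, st2)
  # generators restore the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(simulate_factor_study(cfg)); after <- rnorm(3)
  expect_identical(after, before)
})

test_that("a zero variance ramp plants nothing", {
  cfg0 <- simulation_config(seed = 3, dnb_variance_ramp = 0)
  st0 <- simulate_factor_study(cfg0)
  null0 <- simulate_null_study(cfg0)
  # same seed, same draws, no displacement anywhere
  expect_identical(st0$course, null0$course)
  expect_identical(st0$normal_matrix, null0$normal_matrix)
})

test_that("planted DNB genes gain intra-module correlation after the transition", {
  mean_abs_pcc <- function(x) {
    cc <- suppressWarnings(cor(t(x)))
    mean(abs(cc[upper.tri(cc)]))
  }
  wins <- 0L
  for (s in 1:100) {
    st <- simulate_factor_study(simulation_config(seed = 400 + s))
    ti <- st$truth_transition_index
    dnb <- st$dnb_gene_ids
    pre <- mean_abs_pcc(st$course[dnb, 1:(ti - 1)])
    post <- mean_abs_pcc(st$course[dnb, ti:ncol(st$course)])
    if (post > pre) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("null studies are reproducible and carry no planted structure", {
  cfg <- simulation_config(seed = 5)
  a <- simulate_null_study(cfg)
  b <- simulate_null_study(cfg)
  expect_identical(a, b)
  expect_true(is.na(a$truth_transition_index))
  expect_length(a$dnb_gene_ids, 0L)
  # same-cohort null subjects share the gene-mean configuration
  c3 <- simulate_null_study(cfg, n_null_subjects = 2)
  expect_length(c3$null_courses, 2L)
  expect_identical(rownames(c3$null_courses[[1]]), rownames(c3$course))
})

test_that("network studies place the truth at the first q >= 0", {
  cfg <- simulation_config(n_genes = 8, dnb_size = 4, n_timepoints = 13,
                           transition_index = 6, noise_sd = 0.05,
                           mode = "network_sde", seed = 2)
  st <- simulate_network_study(cfg, steps_per_q = 500, burn_in = 500)
  qs <- as.numeric(colnames(st$course))
  expect_identical(st$truth_transition_index,
                   which(qs >= 0)[1])
  expect_equal(qs[1], -0.4)
  expect_equal(qs[length(qs)], 0.2)
  # the driver jumps to the high branch after the fold
  expect_gt(st$course[1, ncol(st$course)], 1)
  expect_lt(st$course[1, 1], 0.5)
})

test_that("zero-noise network trajectories are deterministic across seeds", {
  mk <- function(seed) simulate_network_study(
    simulation_config(n_genes = 6, dnb_size = 3, n_timepoints = 7,
                      transition_index = 4, noise_sd = 0,
                      mode = "network_sde", seed = seed),
    steps_per_q = 300, burn_in = 300)
  expect_identical(mk(1)$course, mk(77)$course)
})

test_that("driver variance grows approaching the fold (critical slowing down)", {
  vals <- vapply(1:50, function(s) {
    st <- simulate_network_study(
      simulation_config(n_genes = 6, dnb_size = 3, n_timepoints = 11,
                        transition_index = 6, noise_sd = 0.05,
                        mode = "network_sde", seed = 700 + s),
      steps_per_q = 400, burn_in = 400)
    near <- st$truth_transition_index - 1L
    c(far = st$course[1, 1], near = st$course[1, near])
  }, numeric(2))
  expect_gt(var(vals["near", ]), var(vals["far", ]))
})

test_that("network mode rejects grids that miss the critical point", {
  cfg <- simulation_config(n_genes = 6, dnb_size = 3, noise_sd = 0.05,
                           mode = "network_sde")
  expect_error(simulate_network_study(cfg, q_min = 0.1), "straddle")
  expect_error(simulate_network_study(cfg, q_min = -0.7), "q_min")
})
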