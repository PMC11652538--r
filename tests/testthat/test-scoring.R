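test_that("baseline is the per-gene mean with fractional ranks", {
  m <- mat3(c(1, 3, 2, 2, 5, 1), c("g1", "g2", "g3"), c("s1", "s2"))
  b <- compute_baseline(m)
  expect_equal(unname(b$baseline_expression), c(2, 2, 3))
  expect_equal(unname(b$baseline_rank), c(1.5, 1.5, 3))
  expect_equal(b$n_normal, 2L)

  # one normal sample: baseline equals that sample
  one <- m[, 1, drop = FALSE]
  expect_equal(compute_baseline(one)$baseline_expression, one[, 1])

  # identical samples: baseline equals any column
  same <- cbind(m[, 1], m[, 1], m[, 1])
  colnames(same) <- paste0("s", 1:3)
  expect_equal(compute_baseline(same)$baseline_expression, m[, 1])
})

test_that("degenerate baseline inputs are rejected with informative errors", {
  expect_error(compute_baseline(matrix(1, 1, 1)), "at least")
  bad <- mat3(c(1, 2, NaN, 4), c("gA", "gB"), c("s1", "s2"))
  expect_error(compute_baseline(bad), "gB")
  nn <- mat3(1:4, c("g1", "g2"), c("s1", "s2"))
  rownames(nn) <- NULL
  expect_error(compute_baseline(nn), "gene identifiers")
})

test_that("ranking uses the ascending average-tie convention", {
  expect_equal(unname(rank_expressions(c(a = 0.5, b = 2.0, c = 1.0))),
               c(1, 3, 2))
  expect_equal(unname(rank_expressions(c(a = 1, b = 1, c = 2))),
               c(1.5, 1.5, 3))
  expect_equal(unname(rank_expressions(rep(7, 4))), rep(2.5, 4))
  expect_error(rank_expressions(c(a = 1)), "at least 2")
  expect_error(rank_expressions(c(a = 1, b = NaN)), "non-finite")
})

test_that("rank vectors always sum to N(N+1)/2 and stay within [1, N]", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(2:200, 1)
    v <- sample(c(rnorm(n), rep(0, n %/% 3)))[seq_len(n)]  # inject ties
    r <- rank_expressions(setNames(v, paste0("g", seq_len(n))))
    expect_equal(sum(r), n * (n + 1) / 2)
    expect_gte(min(r), 1)
    expect_lte(max(r), n)
  }
})

test_that("local scores combine expression change and ranking change", {
  b <- compute_baseline(mat3(c(1, 2, 3), c("g1", "g2", "g3"), "n1"))
  tab <- local_scores(c(g1 = 3, g2 = 2, g3 = 1), b)
  expect_equal(tab$delta_expression, c(2, 0, -2))
  expect_equal(tab$delta_rank, c(2, 0, -2))
  expect_equal(tab$local_score, c(4, 0, 4))
  expect_equal(tab$local_score, tab$delta_expression * tab$delta_rank)

  # self-comparison nullity
  self <- local_scores(b$baseline_expression, b)
  expect_equal(self$local_score, rep(0, 3))

  # constant shift: ranks unchanged, scores identically zero
  shifted <- local_scores(b$baseline_expression + 4.2, b)
  expect_equal(shifted$delta_expression, rep(4.2, 3))
  expect_equal(shifted$delta_rank, rep(0, 3))
  expect_equal(shifted$local_score, rep(0, 3))
})

test_that("gene-universe mismatches intersect with a warning, tiny overlap errors", {
  b <- compute_baseline(mat3(c(1, 2, 3, 4), paste0("g", 1:4), "n1"))
  s <- c(g2 = 5, g3 = 1, g9 = 2)
  expect_warning(tab <- local_scores(s, b), "intersection")
  expect_setequal(tab$gene_id, c("g2", "g3"))
  # ranks recomputed on the 2-gene intersection
  expect_equal(tab$delta_rank, c(1, -1))
  expect_error(local_scores(c(x1 = 1, x2 = 2), b), "no genes")
  expect_error(suppressWarnings(local_scores(c(g1 = 1, zz = 2), b)),
               "fewer than 2")
})

test_that("sample_score averages the top-m signed products over m * N", {
  tab <- structure(
    data.frame(gene_id = c("a", "b", "c"),
               delta_expression = c(2, 0, -2),
               delta_rank = c(2, 0, -2),
               local_score = c(4, 0, 4), stringsAsFactors = FALSE),
    class = c("spcr_local_scores", "data.frame"))
  expect_equal(sample_score(tab, m = 2), (4 + 4) / (2 * 3))
  expect_equal(sample_score(tab, m = 3), mean(c(4, 0, 4)) / 3)

  zero <- tab; zero$local_score <- rep(0, 3)
  expect_equal(sample_score(zero, m = 2), 0)

  expect_error(sample_score(tab, m = 4), "exceeds")
  expect_error(sample_score(tab, m = 0), "positive integer")
  expect_error(sample_score(tab[0, ], m = 1), "non-empty")
})

test_that("signed vs absolute top-m selection differ as intended", {
  tab <- structure(
    data.frame(gene_id = c("a", "b", "c"),
               delta_expression = 1, delta_rank = 1,
               local_score = c(-9, 3, 1), stringsAsFactors = FALSE),
    class = c("spcr_local_scores", "data.frame"))
  expect_equal(sample_score(tab, m = 1), 3 / 3)
  expect_equal(sample_score(tab, m = 1, use_absolute = TRUE), -9 / 3)
})

test_that("score series subtracts the initial post-baseline score", {
  set.seed(7)
  genes <- paste0("g", 1:30)
  base <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(genes, paste0("n", 1:4)))
  b <- compute_baseline(base)
  course <- matrix(rnorm(30 * 5), 30, 5,
                   dimnames = list(genes, as.character(1:5)))
  ser <- score_series(course, b, m = 5)
  expect_s3_class(ser, "spcr_score_series")
  expect_equal(ser$ranking_score, ser$score - ser$score[1])
  expect_identical(ser$ranking_score[1], 0)

  single <- score_series(course[, 1, drop = FALSE], b, m = 5)
  expect_equal(single$ranking_score, 0)

  # a course of baseline copies scores exactly zero everywhere
  flat <- matrix(rep(b$baseline_expression, 3), 30, 3,
                 dimnames = list(genes, as.character(1:3)))
  fs <- score_series(flat, b, m = 5)
  expect_equal(fs$score, rep(0, 3))
  expect_equal(fs$ranking_score, rep(0, 3))
})

test_that("score series rejects duplicate or disordered time labels", {
  genes <- paste0("g", 1:10)
  b <- compute_baseline(matrix(rnorm(20), 10, 2,
                               dimnames = list(genes, c("n1", "n2"))))
  course <- matrix(rnorm(30), 10, 3,
                   dimnames = list(genes, c("1", "1", "2")))
  expect_error(score_series(course, b, m = 2), "unique|duplicate")
  colnames(course) <- c("5", "2", "9")
  expect_error(score_series(course, b, m = 2), "strictly increasing")
})

test_that("min-normalization divides by the minimum and rejects <= 0", {
  expect_equal(normalize_by_min(c(2, 4, 8)), c(1, 2, 4))
  expect_equal(normalize_by_min(5), 1)
  expect_equal(normalize_by_min(c(1, 1, 1)), c(1, 1, 1))
  expect_error(normalize_by_min(c(2, 0, 1)), "strictly positive")
  expect_error(normalize_by_min(c(-1, 3)), "strictly positive")
})
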