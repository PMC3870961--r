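make_ct <- function(target_by_line, ref_by_line, n = 3) {
  dplyr::bind_rows(
    tibble::tibble(
      target_id = "g1",
      line = rep(names(target_by_line), each = n),
      replicate = rep(seq_len(n), length(target_by_line)),
      ct = rep(unlist(target_by_line), each = n)
    ),
    tibble::tibble(
      target_id = "beta_actin",
      line = rep(names(ref_by_line), each = n),
      replicate = rep(seq_len(n), length(ref_by_line)),
      ct = rep(unlist(ref_by_line), each = n)
    )
  )
}

test_that("2^-ddCt follows the closed form and fixes the calibrator at 1", {
  ct <- make_ct(
    c(ALHF = 20, aabys = 22), # dCt 5 vs 6 after reference subtraction
    c(ALHF = 15, aabys = 16)
  )
  r <- ddct(ct, "g1", calibrator = "aabys")$per_sample
  expect_equal(r$rel_expr[r$line == "ALHF"], 2) # 2^-(5-6)
  expect_equal(r$rel_expr[r$line == "aabys"], 1)
  # sample identical to calibrator gives exactly 1
  ct2 <- make_ct(c(ALHF = 21, aabys = 21), c(ALHF = 16, aabys = 16))
  r2 <- ddct(ct2, "g1", calibrator = "aabys")$per_sample
  expect_equal(r2$rel_expr, c(1, 1))
})

test_that("ddCt is invariant to shifting a sample's target and reference Cts together", {
  base <- make_ct(c(ALHF = 20, aabys = 22), c(ALHF = 15, aabys = 16))
  shifted <- base
  shift <- base$line == "ALHF"
  shifted$ct[shift] <- shifted$ct[shift] + 3.7
  expect_equal(
    ddct(base, "g1", calibrator = "aabys")$per_sample$rel_expr,
    ddct(shifted, "g1", calibrator = "aabys")$per_sample$rel_expr
  )
})

test_that("ddCt raises named errors for missing reference or calibrator", {
  ct <- make_ct(c(ALHF = 20, aabys = 22), c(ALHF = 15, aabys = 16))
  expect_error(
    ddct(ct[ct$target_id != "beta_actin", ], "g1", calibrator = "aabys"),
    class = "muscalink_normalization_error"
  )
  expect_error(
    ddct(ct, "g1", calibrator = "CS"),
    class = "muscalink_normalization_error"
  )
})

test_that("Welch test reproduces the summary-statistic formulas", {
  # identical summaries: t = 0, p = 1
  same <- welch_test(1.5, 0.2, 3, 1.5, 0.2, 3)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # worked closed form: t = 1/sqrt(0.05), Welch-Satterthwaite df
  w <- welch_test(2.0, 0.2, 3, 1.0, 0.1, 3)
  expect_equal(w$t, 1 / sqrt(0.05), tolerance = 1e-12)
  expect_equal(w$df, 0.05^2 / (0.2^4 / 2 + 0.1^4 / 2), tolerance = 1e-12)
  expect_equal(w$p, 2 * stats::pt(-abs(w$t), w$df), tolerance = 1e-12)
  # degenerate zero-variance cases
  d0 <- welch_test(2, 0, 3, 2, 0, 3)
  expect_equal(d0$p, 1)
  d1 <- welch_test(2, 0, 3, 1, 0, 3)
  expect_equal(d1$p, 0)
  expect_true(d1$degenerate)
})

test_that("Welch test is antisymmetric and agrees with t.test on replicate data", {
  a <- welch_test(2.0, 0.3, 3, 1.2, 0.1, 4)
  b <- welch_test(1.2, 0.1, 4, 2.0, 0.3, 3)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  # replicate-level agreement with the reference implementation
  set.seed(101)
  for (i in 1:25) {
    x <- rnorm(3, 2, 0.4)
    y <- rnorm(3, 1.4, 0.2)
    ours <- welch_test(
      mean(x), sd(x) / sqrt(3), 3,
      mean(y), sd(y) / sqrt(3), 3
    )
    ref <- stats::t.test(x, y)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Welch flag matches the exact permutation test's decision on most replicate pairs", {
  # five replicates per group: the coarsest design whose exact permutation
  # distribution resolves p-values well below 0.05 (at n = 3 the 10 distinct
  # relabelings bottom out at p = 0.1 and the test can never reject)
  set.seed(202)
  n_cases <- 400
  agree <- logical(n_cases)
  perms <- utils::combn(10, 5)
  for (i in seq_len(n_cases)) {
    shift <- sample(c(0, 0.8), 1)
    x <- rnorm(5, 1 + shift, 0.3)
    y <- rnorm(5, 1, 0.3)
    w <- welch_test(mean(x), sd(x) / sqrt(5), 5, mean(y), sd(y) / sqrt(5), 5)
    obs <- abs(mean(x) - mean(y))
    pool <- c(x, y)
    stats_perm <- apply(perms, 2, function(idx) {
      abs(mean(pool[idx]) - mean(pool[-idx]))
    })
    p_perm <- mean(stats_perm >= obs - 1e-12)
    agree[i] <- (w$p <= 0.05) == (p_perm <= 0.05)
  }
  expect_gte(mean(agree), 0.95)
})

test_that("line summaries flag exactly the factor-substituting lines at zero noise", {
  specs <- toy_specs()
  reps <- simulate_replicates(specs, n_reps = 3, noise_sd = 0, seed = 1)
  summ <- summarize_lines(reps)
  # gene with factors {2,5}: significant only in A1345 and A1234, direction down
  gA <- summ[summ$gene_id == "gA" & summ$line %in% substitution_lines(), ]
  expect_equal(gA$significant, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(gA$direction[gA$significant], c("down", "down"))
  # unregulated gene: no flags anywhere
  gB <- summ[summ$gene_id == "gB" & summ$line %in% substitution_lines(), ]
  expect_true(all(!gB$significant))
})

test_that("a line identical to ALHF is never flagged and missing genes are kept", {
  set.seed(33)
  vals <- rnorm(3, 10, 0.5)
  reps <- tibble::tibble(
    gene_id = "g1",
    line = rep(c("ALHF", "A2345"), each = 3),
    replicate = rep(1:3, 2),
    value = rep(vals, 2)
  )
  summ <- summarize_lines(reps)
  expect_true(all(!summ$significant[summ$line == "A2345"]))
  # a gene absent from one line appears as a missing record, not dropped
  reps2 <- dplyr::bind_rows(
    reps,
    tibble::tibble(gene_id = "g2", line = "ALHF", replicate = 1:3, value = 1:3),
    tibble::tibble(gene_id = "g2", line = "A1345", replicate = 1:3, value = 4:6)
  )
  summ2 <- summarize_lines(reps2)
  row <- summ2[summ2$gene_id == "g2" & summ2$line == "A2345", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$status, "missing")
  # every gene needs comparator records
  expect_error(
    summarize_lines(tibble::tibble(
      gene_id = "g9", line = "A1345", replicate = 1:3, value = 1:3
    )),
    class = "muscalink_normalization_error"
  )
})

test_that("Welch flag type-I error at alpha 0.05, n = 3 stays in the small-n band", {
  pri <- architecture_priors(classes = stats::setNames(1, ""))
  specs <- sample_architectures(1200, pri, seed = 71)
  reps <- simulate_replicates(specs, n_reps = 3, noise_sd = 0.15, seed = 72)
  summ <- summarize_lines(reps)
  null_tests <- summ[summ$line != "ALHF" & summ$status == "ok", ]
  rate <- mean(null_tests$significant)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})
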