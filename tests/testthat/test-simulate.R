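test_that("architecture sampling is reproducible and follows the priors", {
  specs1 <- sample_architectures(50, seed = 42)
  specs2 <- sample_architectures(50, seed = 42)
  expect_identical(specs1, specs2)
  expect_true(all(specs1$length_nt >= 300L))
  expect_true(all(vapply(specs1$effects, function(e) all(e > 0), logical(1))))

  # mass concentrated on one class pins every gene to that subset
  pri <- architecture_priors(classes = stats::setNames(1, "2,5"))
  all25 <- sample_architectures(20, pri, seed = 1)
  expect_true(all(all25$factor_autosomes == "2,5"))

  # uniform priors over 4 classes: realized frequencies within 3 SE of 0.25
  pri4 <- architecture_priors(
    classes = stats::setNames(rep(0.25, 4), c("2,5", "1,2,5", "2", "5"))
  )
  big <- sample_architectures(10000, pri4, seed = 9)
  freqs <- table(big$factor_autosomes) / nrow(big)
  se <- sqrt(0.25 * 0.75 / nrow(big))
  expect_true(all(abs(freqs - 0.25) < 3 * se))

  expect_error(
    architecture_priors(classes = stats::setNames(c(0.5, 0.6), c("2", "5"))),
    class = "muscalink_config_error"
  )
  expect_error(
    architecture_priors(classes = stats::setNames(1, "2,7")),
    class = "muscalink_config_error"
  )
})

test_that("expected log2 expression is additive over present factor autosomes", {
  specs <- toy_specs()
  designs <- line_designs()
  # factors {2,5}, beta = 1 each, baseline 3: ALHF 5, A1345 4, aabys 3
  expect_equal(expected_log2_expression(specs, designs$ALHF)[1], 5)
  expect_equal(expected_log2_expression(specs, designs$A1345)[1], 4)
  expect_equal(expected_log2_expression(specs, designs$aabys)[1], 3)
  # empty factor set: baseline everywhere
  for (d in designs) expect_equal(expected_log2_expression(specs, d)[2], 4)
  # ALHF:aabys linear fold-change is 2^(sum beta)
  fc <- 2^(expected_log2_expression(specs, designs$ALHF) -
    expected_log2_expression(specs, designs$aabys))
  expect_equal(fc, c(4, 1, 2^1.2))
})

test_that("no substitution line exceeds ALHF; equality iff autosome is not a factor", {
  specs <- sample_architectures(40, seed = 5)
  designs <- line_designs()
  e_alhf <- expected_log2_expression(specs, designs$ALHF)
  for (l in substitution_lines()) {
    e_line <- expected_log2_expression(specs, designs[[l]])
    expect_true(all(e_line <= e_alhf + 1e-12))
    a <- substituted_autosome(l)
    is_factor <- vapply(specs$effects, function(e) as.character(a) %in% names(e), logical(1))
    expect_equal(e_line == e_alhf, !is_factor)
  }
})

test_that("AND-model expression collapses to baseline unless all factors present", {
  specs <- toy_specs()
  designs <- line_designs()
  expect_equal(expected_log2_expression(specs, designs$ALHF, model = "and")[1], 5)
  # removing either factor autosome loses the whole effect
  expect_equal(expected_log2_expression(specs, designs$A1345, model = "and")[1], 3)
  expect_equal(expected_log2_expression(specs, designs$A1234, model = "and")[1], 3)
})

test_that("replicate simulation is exact at zero noise and unbiased on log2 scale", {
  specs <- toy_specs()
  reps0 <- simulate_replicates(specs, n_reps = 3, noise_sd = 0, seed = 1)
  designs <- line_designs()
  for (l in names(designs)) {
    vals <- reps0$value[reps0$gene_id == "gA" & reps0$line == l]
    expect_equal(vals, rep(2^expected_log2_expression(specs, designs[[l]])[1], 3))
  }
  expect_identical(
    simulate_replicates(specs, seed = 7),
    simulate_replicates(specs, seed = 7)
  )
  # Monte-Carlo: mean log2 over many draws within 4 SE of the expectation
  one <- specs[1, ]
  reps <- simulate_replicates(one, designs["ALHF"], n_reps = 1e4, noise_sd = 0.3, seed = 2)
  mc <- mean(log2(reps$value))
  expect_lt(abs(mc - 5), 4 * 0.3 / sqrt(1e4))
})

test_that("count simulation matches Poisson moments and scales with depth", {
  one <- toy_specs()[1, ]
  cm <- simulate_counts(one, line_designs()["ALHF"],
    mean_depth = 200, dispersion = 0, n_reps = 1e4, seed = 3
  )
  x <- as.numeric(cm$counts)
  # Poisson: variance equals the mean (relative tolerance from 1e4 draws)
  expect_lt(abs(stats::var(x) / mean(x) - 1), 0.1)
  expect_true(all(cm$counts >= 0))
  expect_equal(unname(cm$library_size[1]), 200)
  cm2 <- simulate_counts(one, line_designs()["ALHF"],
    mean_depth = 400, dispersion = 0, n_reps = 1e4, seed = 4
  )
  expect_lt(abs(mean(cm2$counts) / mean(cm$counts) - 2), 0.1)
  expect_error(
    simulate_counts(one, dispersion = -1),
    class = "muscalink_config_error"
  )
})

test_that("Ct simulation is the exact inverse of 2^-ddCt at zero noise", {
  specs <- toy_specs()
  ct <- simulate_ct(specs, n_reps = 3, ct_noise_sd = 0, seed = 1)
  designs <- line_designs()
  # reference Ct identical across samples at zero noise
  ref <- ct[ct$target_id == "beta_actin", ]
  expect_equal(length(unique(ref$ct)), 1L)
  # a gene 2-fold up shows Ct exactly one cycle lower
  e <- expected_log2_expression(specs, designs$ALHF)[1] -
    expected_log2_expression(specs, designs$A1345)[1]
  ct_alhf <- unique(ct$ct[ct$target_id == "gA" & ct$line == "ALHF"])
  ct_a1345 <- unique(ct$ct[ct$target_id == "gA" & ct$line == "A1345"])
  expect_equal(ct_a1345 - ct_alhf, e)
  # full round trip through ddct recovers simulated fold-changes exactly
  for (g in specs$gene_id) {
    r <- ddct(ct, g, calibrator = "aabys")$per_sample
    want <- 2^(vapply(
      designs[r$line], function(d) expected_log2_expression(specs[specs$gene_id == g, ], d),
      numeric(1)
    ) - expected_log2_expression(specs[specs$gene_id == g, ], designs$aabys))
    expect_equal(r$rel_expr, unname(want), tolerance = 1e-12)
  }
})

test_that("band patterns reflect the physical autosome deterministically", {
  specs <- toy_specs()
  bands <- bands_to_wide(simulate_bands(specs))
  # physical autosome 5: absent only in A1234 and aabys
  gA <- bands[bands$gene_id == "gA", ]
  expect_equal(gA$A1234, "absent")
  expect_equal(gA$aabys, "absent")
  expect_true(all(gA[, c("ALHF", "A2345", "A1345", "A1245", "A1235")] == "present"))
  # physical autosome 2: absent only in A1345 and aabys
  gB <- bands[bands$gene_id == "gB", ]
  expect_equal(gB$A1345, "absent")
  expect_true(all(gB[, c("ALHF", "A2345", "A1245", "A1235", "A1234")] == "present"))
  # ALHF always has every band
  expect_true(all(bands$ALHF == "present"))
})

test_that("scenario config files parse into generator arguments", {
  cfg_file <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c(
    "# default-like scenario, two classes",
    "n_genes = 50",
    "noise_sd = 0.2",
    "model = and",
    "seed = 9",
    "class.2,5 = 0.75",
    "class.none = 0.25"
  ), cfg_file)
  cfg <- read_scenario_config(cfg_file)
  expect_identical(cfg$n_genes, 50L)
  expect_equal(cfg$noise_sd, 0.2)
  expect_identical(cfg$model, "and")
  expect_equal(unname(cfg$priors$classes), c(0.75, 0.25))
  expect_equal(names(cfg$priors$classes), c("2,5", ""))
  specs <- sample_architectures(cfg$n_genes, cfg$priors, seed = cfg$seed)
  expect_true(all(specs$factor_autosomes %in% c("2,5", "")))
  # weights that do not sum to one are a config error
  bad <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("class.2 = 0.5", "class.5 = 0.6"), bad)
  expect_error(read_scenario_config(bad), class = "muscalink_config_error")
  malformed <- withr::local_tempfile(fileext = ".cfg")
  writeLines("n_genes 50", malformed)
  expect_error(read_scenario_config(malformed), class = "muscalink_config_error")
})
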