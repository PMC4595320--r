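test_that("resampling draws whole experiments with replacement", {
  d <- noiseless_data(n = 30, seed = 1)
  set.seed(2)
  rs <- resample_experiments(d)
  expect_equal(nrow(rs), 30)
  expect_true(all(rs$exp_id %in% d$exp_id))
  key <- function(x) paste(x$exp_id, x$a_1, x$b_1, x$v)
  expect_true(all(key(rs) %in% key(d)))
})

test_that("expected fraction of distinct rows matches 1 - (1 - 1/n)^n", {
  n <- 30
  set.seed(3)
  frac <- mean(replicate(1e4, length(unique(sample.int(n, n, TRUE))) / n))
  expect_lt(abs(frac - (1 - (1 - 1 / n)^n)), 0.01)
})

test_that("SE_B and Bias follow the printed formulas", {
  # hand example: replicates {1, 3} about a point estimate of 2
  s <- invivokin:::boot_summary(matrix(c(1, 3), ncol = 1), 2)
  expect_equal(as.numeric(s$se_b), 1)
  expect_equal(as.numeric(s$bias), 0)
  expect_equal(as.numeric(s$rel_se), 0.5)
  # degenerate: all replicates at the point estimate
  s0 <- invivokin:::boot_summary(matrix(2, 5, 1), 2)
  expect_equal(as.numeric(s0$se_b), 0)
  expect_equal(as.numeric(s0$bias), 0)
})

test_that("bootstrap results reproduce their own summary statistics", {
  sp <- arg8_spec()
  d <- simulate_experiments(arg8_truth(), sp, design_spec(10), noise_model(),
                            seed = 11)
  fit <- fit_kinetics(d, sp, noise_model(), fit_options(n_starts = 1))
  b <- bootstrap_fit(fit, n_samples = 40, seed = 12)
  reps <- as.matrix(b$replicate_estimates)
  point <- as.numeric(b$point_estimate)
  # independent direct summation over the stored replicate estimates
  expect_equal(as.numeric(b$se_b),
               sqrt(colMeans(sweep(reps, 2, point)^2)), ignore_attr = TRUE)
  expect_equal(as.numeric(b$bias), colMeans(reps) - point,
               ignore_attr = TRUE)
  expect_equal(as.numeric(b$rel_se), as.numeric(b$se_b) / point)
  expect_equal(as.numeric(b$rel_bias), as.numeric(b$bias) / point)
})

test_that("bootstrap is deterministic under a fixed seed", {
  sp <- arg8_spec()
  d <- simulate_experiments(arg8_truth(), sp, design_spec(10), noise_model(),
                            seed = 21)
  fit <- fit_kinetics(d, sp, noise_model(), fit_options(n_starts = 1))
  b1 <- bootstrap_fit(fit, n_samples = 25, seed = 5)
  b2 <- bootstrap_fit(fit, n_samples = 25, seed = 5)
  expect_identical(b1$replicate_estimates, b2$replicate_estimates)
  expect_identical(b1$se_b, b2$se_b)
})

test_that("widespread replicate failures flag the result as unreliable", {
  sp <- arg8_spec()
  d <- simulate_experiments(arg8_truth(), sp, design_spec(10), noise_model(),
                            seed = 31)
  fit <- fit_kinetics(d, sp, noise_model(), fit_options(n_starts = 1))
  # starve the replicate optimiser so every refit stops unconverged
  fit$options$max_iterations <- 1L
  expect_error(bootstrap_fit(fit, n_samples = 10, seed = 6), "Too few")
})

test_that("tidy and glance summarise a bootstrap", {
  sp <- arg8_spec()
  d <- simulate_experiments(arg8_truth(), sp, design_spec(10), noise_model(),
                            seed = 41)
  fit <- fit_kinetics(d, sp, noise_model(), fit_options(n_starts = 1))
  b <- bootstrap_fit(fit, n_samples = 20, seed = 7)
  td <- tidy(b)
  expect_named(td, c("term", "estimate", "std_error", "bias", "rel_se",
                     "rel_bias"))
  expect_true(glance(b)$reliable)
  expect_s3_class(autoplot(b), "ggplot")
})
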