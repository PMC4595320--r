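test_that("relative noise has the requested coefficient of variation", {
  expect_identical(apply_relative_noise(c(1, 2, 3), 0), c(1, 2, 3))
  set.seed(1)
  draws <- apply_relative_noise(rep(1, 1e5), 0.2)
  expect_lt(abs(mean(draws) - 1), 0.002)          # 3 sigma / sqrt(N) band
  draws5 <- apply_relative_noise(rep(5, 1e5), 0.2)
  expect_lt(abs(sd(draws5) / mean(draws5) - 0.2), 0.002)
  # sign of a negative rate is preserved
  set.seed(2)
  expect_true(all(apply_relative_noise(rep(-2, 100), 0.5) < 0))
})

test_that("noise multipliers of different cells are uncorrelated", {
  set.seed(4)
  e1 <- apply_relative_noise(rep(1, 1e4), 0.2)
  e2 <- apply_relative_noise(rep(1, 1e4), 0.2)
  expect_lt(abs(cor(e1, e2)), 0.05)
})

test_that("zero-noise data satisfy the rate law exactly", {
  sp <- arg8_spec()
  th <- arg8_truth()
  d <- noiseless_data(n = 30, seed = 5)
  expect_equal(nrow(d), 30)
  v_model <- reaction_rate(th, sp, as.matrix(d[c("a_1", "a_2")]),
                           as.matrix(d[c("b_1", "b_2")]))
  expect_equal(d$v, v_model, tolerance = 1e-14)
})

test_that("generation is deterministic under a fixed seed", {
  sp <- arg8_spec()
  th <- arg8_truth()
  d1 <- simulate_experiments(th, sp, design_spec(12), noise_model(), seed = 9)
  d2 <- simulate_experiments(th, sp, design_spec(12), noise_model(), seed = 9)
  expect_identical(d1, d2)
  d3 <- simulate_experiments(th, sp, design_spec(12), noise_model(), seed = 10)
  expect_false(identical(d1, d3))
})

test_that("default design covers all three denominator regimes", {
  sp <- arg8_spec()
  th <- arg8_truth()
  tv <- as.numeric(th)
  for (seed in 1:5) {
    d <- noiseless_data(n = 30, seed = seed)
    A <- exp(rowSums(log(as.matrix(d[c("a_1", "a_2")]))))
    B <- exp(rowSums(log(as.matrix(d[c("b_1", "b_2")]))))
    dominant <- apply(cbind(tv[1], tv[2] * A, tv[3] * B), 1, which.max)
    expect_setequal(unique(dominant), 1:3)
  }
})

test_that("regenerated measurements average to the latent values", {
  sp <- arg8_spec()
  th <- arg8_truth()
  set.seed(11)
  lat <- invivokin:::draw_latents(design_spec(5), sp, 5)
  design_fixed <- design_spec(5, sampling = "fixed_list",
                              fixed = list(substrates = lat$A0,
                                           products = lat$B0))
  acc <- matrix(0, 5, 2)
  reps <- 4000  # 3 * sigma / sqrt(reps) < 1%
  set.seed(12)
  for (r in seq_len(reps)) {
    d <- simulate_experiments(th, sp, design_fixed, noise_model())
    acc <- acc + as.matrix(d[c("a_1", "a_2")])
  }
  expect_true(all(abs(acc / reps / lat$A0 - 1) < 0.01))
})

test_that("forward-only designs keep every noise-free rate positive", {
  sp <- arg8_spec()
  th <- arg8_truth()
  des <- design_spec(20, forward_only = TRUE)
  expect_named(des$regimes, c("linear", "forward"))
  d <- simulate_experiments(th, sp, des, noise_model(0, 0, 0), seed = 2)
  expect_true(all(d$v > 0))
  # default (two-sided) designs include net-reverse experiments
  d2 <- noiseless_data(n = 30, seed = 2)
  expect_true(any(d2$v < 0) && any(d2$v > 0))
})

test_that("design validation rejects inconsistent regimes", {
  expect_error(design_spec(10, regimes = list(
    bad = list(substrate = c(2, 1), ratio = c(0.1, 0.5)))), "lo < hi")
  expect_error(design_spec(10, regimes = list(
    bad = list(substrate = c(1, 2), ratio = c(0.5, 2)))), "straddle")
  expect_error(design_spec(10, sampling = "fixed_list"), "fixed")
})
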