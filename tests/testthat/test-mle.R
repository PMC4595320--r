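test_that("objective matches hand-computed values", {
  sp <- arg8_spec()
  th <- arg8_truth()
  v_exact <- reaction_rate(th, sp, c(1, 1), c(1, 1))
  d <- tibble::tibble(exp_id = 1L, a_1 = 1, a_2 = 1, b_1 = 1, b_2 = 1,
                      v = v_exact)
  lat <- list(substrates0 = matrix(1, 1, 2), products0 = matrix(1, 1, 2))
  # all residuals zero: objective = 4*log(1) + log(v0)
  obj0 <- negative_log_likelihood(th, lat, d, sp, noise_model())
  expect_equal(obj0, log(v_exact), tolerance = 1e-10)
  expect_equal(obj0, -2.6035, tolerance = 1e-4)
  # inflating the measured rate to 1.2x adds (1.2 - 1)^2 / (2 * 0.2^2) = 0.5
  d12 <- d
  d12$v <- 1.2 * v_exact
  obj12 <- negative_log_likelihood(th, lat, d12, sp, noise_model())
  expect_equal(obj12 - obj0, 0.5, tolerance = 1e-10)
})

test_that("objective residual blocks vanish on zero-noise data", {
  sp <- arg8_spec()
  th <- arg8_truth()
  d <- noiseless_data(n = 8, seed = 21)
  lat <- list(substrates0 = as.matrix(d[c("a_1", "a_2")]),
              products0 = as.matrix(d[c("b_1", "b_2")]))
  obj <- negative_log_likelihood(th, lat, d, sp, noise_model())
  log_terms <- sum(log(lat$substrates0)) + sum(log(lat$products0)) +
    sum(log(abs(d$v)))
  expect_equal(obj, log_terms, tolerance = 1e-10)
})

test_that("analytic gradient matches the numeric gradient", {
  sp <- arg8_spec()
  d <- simulate_experiments(arg8_truth(), sp, design_spec(6), noise_model(),
                            seed = 31)
  mats <- invivokin:::xp_matrices(d, sp)
  init <- initialize_fit(d, sp)
  theta <- c(log(as.numeric(init$params)),
             log(as.numeric(init$latents$substrates0)),
             log(as.numeric(init$latents$products0)))
  obj <- invivokin:::make_eiv_objective(mats$A, mats$B, mats$v, sp$keq,
                                        0.2, 0.2, 0.2)
  num <- numDeriv::grad(obj$fn, theta)
  expect_lt(max(abs(obj$gr(theta) - num)) / max(abs(num)), 1e-6)
  # irreversible two-parameter branch
  dm <- simulate_mm_experiments(1.5, 0.8, 1, 8, seed = 32)
  obj2 <- invivokin:::make_eiv_objective(matrix(dm$a_1, ncol = 1), NULL,
                                         dm$v, 1, 0.2, NA_real_, 0.2)
  theta2 <- c(log(c(1.4, 0.9)), log(dm$a_1))
  num2 <- numDeriv::grad(obj2$fn, theta2)
  expect_lt(max(abs(obj2$gr(theta2) - num2)) / max(abs(num2)), 1e-6)
})

test_that("initialization is exact on noiseless data and starts at the measurements", {
  sp <- arg8_spec()
  d <- noiseless_data(n = 12, seed = 41)
  init <- initialize_fit(d, sp)
  expect_lt(max(rel_err(as.numeric(init$params), as.numeric(arg8_truth()))),
            1e-6)
  dn <- simulate_experiments(arg8_truth(), sp, design_spec(12), noise_model(),
                             seed = 42)
  initn <- initialize_fit(dn, sp)
  expect_equal(unname(initn$latents$substrates0),
               unname(as.matrix(dn[c("a_1", "a_2")])))
})

test_that("degenerate all-identical designs fall back with a warning", {
  sp <- arg8_spec()
  row <- tibble::tibble(a_1 = 1, a_2 = 2, b_1 = 0.5, b_2 = 0.3, v = 0.2)
  d <- dplyr::bind_cols(tibble::tibble(exp_id = 1:4),
                        dplyr::bind_rows(row, row, row, row))
  expect_warning(init <- initialize_fit(d, sp), "Degenerate")
  expect_equal(as.numeric(init$params), c(1, 1, 1))
})

test_that("noiseless data are recovered to high relative accuracy", {
  sp <- arg8_spec()
  d <- noiseless_data(n = 30, seed = 51)
  fit <- fit_kinetics(d, sp, tiny_noise(), fit_options(n_starts = 1))
  expect_true(fit$converged)
  expect_lt(max(rel_err(as.numeric(fit$params), as.numeric(arg8_truth()))),
            1e-4)
})

test_that("fitted objective never exceeds the objective at initialization", {
  sp <- arg8_spec()
  for (seed in 61:64) {
    d <- simulate_experiments(arg8_truth(), sp, design_spec(12),
                              noise_model(), seed = seed)
    init <- initialize_fit(d, sp)
    obj0 <- negative_log_likelihood(init$params, init$latents, d, sp,
                                    noise_model())
    fit <- fit_kinetics(d, sp, noise_model(), fit_options(n_starts = 1))
    expect_true(fit$converged)
    expect_lte(fit$objective, obj0 + 1e-8)
  }
})

test_that("estimates are scale-equivariant in the concentrations", {
  sp <- reaction_spec(1, 1, keq = 1.7281)
  th <- kinetic_params(2.5783, 3.7327, 3.5238)
  d <- simulate_experiments(th, sp, design_spec(20), noise_model(), seed = 71)
  fit <- fit_kinetics(d, sp, noise_model(), fit_options(n_starts = 1))
  s <- 4
  ds <- dplyr::mutate(d, a_1 = s * a_1, b_1 = s * b_1)
  fits <- fit_kinetics(ds, sp, noise_model(), fit_options(n_starts = 1))
  expect_equal(fits$params[["c1"]], s * fit$params[["c1"]], tolerance = 1e-4)
  expect_equal(fits$params[["c2"]], fit$params[["c2"]], tolerance = 1e-4)
  expect_equal(fits$params[["c3"]], fit$params[["c3"]], tolerance = 1e-4)
})

test_that("estimator is consistent as the noise vanishes", {
  sp <- arg8_spec()
  th <- arg8_truth()
  rep_small <- run_replication(th, sp, design_spec(30),
                               noise_model(0.05, 0.05, 0.05),
                               replicates = 60, seed = 100)
  expect_true(all(abs(rep_small$rel_bias) < 0.01))
})

test_that("precision improves with the number of experiments", {
  sp <- arg8_spec()
  th <- arg8_truth()
  r12 <- run_replication(th, sp, design_spec(12), noise_model(),
                         replicates = 150, seed = 100)
  r24 <- run_replication(th, sp, design_spec(24), noise_model(),
                         replicates = 150, seed = 100)
  r30 <- run_replication(th, sp, design_spec(30), noise_model(),
                         replicates = 150, seed = 100)
  expect_true(all(r12$rel_se > r24$rel_se))
  expect_true(all(r24$rel_se > r30$rel_se))
})

test_that("fit accessors expose tidy summaries", {
  sp <- arg8_spec()
  d <- simulate_experiments(arg8_truth(), sp, design_spec(12), noise_model(),
                            seed = 81)
  fit <- fit_kinetics(d, sp, noise_model(), fit_options(n_starts = 1))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$term, c("c1", "c2", "c3"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_experiments, 12)
  expect_s3_class(autoplot(fit), "ggplot")
})
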