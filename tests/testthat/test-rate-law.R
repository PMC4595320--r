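test_that("rate law reproduces hand-computed values and equilibrium zero", {
  sp <- arg8_spec()
  th <- arg8_truth()
  # direct substitution: (1.7281*1 - 1) / (2.5783 + 3.7327 + 3.5238)
  expect_equal(reaction_rate(th, sp, c(1, 1), c(1, 1)),
               0.7281 / 9.8348, tolerance = 1e-6)
  # rate is exactly zero when prod(b) = Keq * prod(a)
  expect_identical(reaction_rate(th, sp, c(1, 1), c(sp$keq, 1)), 0)
  sp1 <- reaction_spec(1, 1, keq = 3.3)
  expect_identical(reaction_rate(kinetic_params(2, 5, 7), sp1, 2, 6.6), 0)
})

test_that("rate law reduces to irreversible Michaelis-Menten in the limit", {
  keq <- 1e8
  sp <- reaction_spec(1, 1, keq = keq)
  c1 <- 2; c2 <- 0.5; c3 <- 1e-12
  a <- c(0.3, 1, 5, 40)
  v <- vapply(a, function(ai)
    reaction_rate(kinetic_params(c1, c2, c3), sp, ai, 1), numeric(1))
  expect_equal(v, keq * a / (c1 + c2 * a), tolerance = 1e-6)
})

test_that("lumped parameters follow the printed rate-constant combinations", {
  pk <- params_from_rate_constants(mechanistic_constants(1, 1, 1, 1, 1, 1))
  expect_equal(as.numeric(pk$params), c(3, 3, 3))
  expect_equal(pk$keq, 1)
  pk2 <- params_from_rate_constants(mechanistic_constants(2, 1, 1, 1, 1, 1))
  expect_equal(as.numeric(pk2$params), c(3, 6, 3))
  expect_equal(pk2$keq, 2)
  # all c_i scale as 1 / E_tot; Keq is unaffected
  half <- params_from_rate_constants(
    mechanistic_constants(2, 1, 1, 1, 1, 1, e_tot = 2))
  expect_equal(as.numeric(half$params), c(3, 6, 3) / 2)
  expect_equal(half$keq, 2)
})

test_that("equilibrium constant follows from Gibbs formation energies", {
  expect_equal(keq_from_gibbs(-10, -10), 1)
  rt <- 0.008314 * 298.15
  expect_equal(keq_from_gibbs(0, -rt * log(2)), 2)
  expect_equal(keq_from_gibbs(0, -5.708), 10, tolerance = 1e-3)
  expect_error(keq_from_gibbs(numeric(0), -1), "non-empty")
  expect_error(keq_from_gibbs(-1, -2, temperature = -5), "positive")
})

test_that("mass-action ODE steady state agrees with the closed form", {
  mech <- mechanistic_constants(1, 1, 1, 1, 1, 1)
  expect_equal(steady_state_rate(mech, 2, 1), 1 / 12, tolerance = 1e-8)
  # equilibrium concentrations give zero net rate
  expect_equal(steady_state_rate(mech, 1.5, 1.5), 0, tolerance = 1e-10)
  set.seed(3)
  for (i in 1:20) {
    ks <- exp(runif(6, -1.5, 1.5))
    mech <- mechanistic_constants(ks[1], ks[2], ks[3], ks[4], ks[5], ks[6],
                                  e_tot = exp(runif(1, -1, 1)))
    a <- exp(runif(1, -1, 1)); b <- exp(runif(1, -1, 1))
    pk <- params_from_rate_constants(mech)
    closed <- reaction_rate(pk$params, reaction_spec(1, 1, pk$keq), a, b)
    expect_lt(rel_err(steady_state_rate(mech, a, b), closed), 1e-6)
  }
})

test_that("rate is monotone in substrates and products", {
  set.seed(7)
  sp <- reaction_spec(2, 2, keq = exp(runif(1, -1, 1)))
  for (i in 1:25) {
    th <- kinetic_params(exp(runif(1, -1, 1)), exp(runif(1, -1, 1)),
                         exp(runif(1, -1, 1)))
    a <- exp(runif(2, -1.5, 1.5)); b <- exp(runif(2, -1.5, 1.5))
    v <- reaction_rate(th, sp, a, b)
    h <- 1e-6
    for (j in 1:2) {
      up <- a; up[j] <- a[j] * (1 + h)
      expect_gt(reaction_rate(th, sp, up, b), v)
      upb <- b; upb[j] <- b[j] * (1 + h)
      expect_lt(reaction_rate(th, sp, a, upb), v)
    }
  }
})

test_that("rate is scale-equivariant and proportional to total enzyme", {
  sp <- reaction_spec(1, 1, keq = 2.5)
  th <- kinetic_params(1.2, 0.7, 0.9)
  s <- 5.5
  v1 <- reaction_rate(th, sp, 2, 1.4)
  v2 <- reaction_rate(kinetic_params(s * 1.2, 0.7, 0.9), sp, s * 2, s * 1.4)
  expect_equal(v1, v2, tolerance = 1e-12)
  # v scales linearly with e_tot at fixed rate constants
  m1 <- mechanistic_constants(1.3, 0.8, 2, 1, 0.5, 1.1, e_tot = 1)
  m3 <- mechanistic_constants(1.3, 0.8, 2, 1, 0.5, 1.1, e_tot = 3)
  expect_equal(3 * steady_state_rate(m1, 2, 0.5),
               steady_state_rate(m3, 2, 0.5), tolerance = 1e-8)
})

test_that("invalid inputs are rejected", {
  sp <- arg8_spec()
  th <- arg8_truth()
  expect_error(reaction_rate(th, sp, c(1, 1, 1), c(1, 1)), "length")
  expect_error(reaction_rate(th, sp, c(1, -1), c(1, 1)), "positive")
  expect_error(kinetic_params(1, 0, 1), "positive")
  expect_error(reaction_spec(0, 1, 1), "positive integers")
  expect_error(reaction_spec(1, 1, -2), "positive")
  expect_error(mechanistic_constants(1, 1, 1, 1, 1, -1), "positive")
})
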