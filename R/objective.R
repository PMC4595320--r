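# Errors-in-variables objective for the steady-state rate law.
#
# The negated log-likelihood (constants dropped) over kinetic parameters c
# and latent noise-free measurements, with the latent rate v_i0 eliminated
# through the rate law:
#
#   F = sum_ij log a_ij0 + sum_ij log b_ij0 + sum_i log |v_i0|
#     + 1/(2 sa^2) sum_ij (a_ij/a_ij0 - 1)^2
#     + 1/(2 sb^2) sum_ij (b_ij/b_ij0 - 1)^2
#     + 1/(2 sv^2) sum_i  (v_i /v_i0  - 1)^2
#
# The relative-error density of a rate measurement is N(v_i0, v_i0^2 sv^2),
# whose normalisation involves |v_i0|, so net-reverse experiments
# (v_i0 < 0, product pool above its equilibrium value) are handled by the
# same expression. Everything is optimised on the log scale (positivity of
# concentrations by parameterisation). Writing t_i = s_i v_i0 with
# s_i = sign(v_i), the rate block g(t) = log t + (|v_i|/t - 1)^2/(2 sv^2)
# diverges to +Inf as t -> 0+, so each latent rate is barred from crossing
# equilibrium away from its measured direction; for t at or below a small
# positive floor the block is extended linearly (C^1) so the objective
# stays finite and strongly increasing if a line-search step oversteps.

# Value and gradient in one pass. B_obs = NULL selects the irreversible
# two-parameter model v0 = keq*A/(c1 + c2*A) with no product block.
eiv_value_grad <- function(theta, A_obs, B_obs, v_obs, keq,
                           sigma_a, sigma_b, sigma_v) {
  n <- nrow(A_obs)
  m <- ncol(A_obs)
  reversible <- !is.null(B_obs)
  p <- if (reversible) ncol(B_obs) else 0L
  nc <- if (reversible) 3L else 2L

  cpar <- exp(theta[seq_len(nc)])
  la0 <- matrix(theta[nc + seq_len(n * m)], n, m)
  a0 <- exp(la0)
  Aprod <- exp(rowSums(la0))
  if (reversible) {
    lb0 <- matrix(theta[nc + n * m + seq_len(n * p)], n, p)
    b0 <- exp(lb0)
    Bprod <- exp(rowSums(lb0))
    D <- cpar[1] + cpar[2] * Aprod + cpar[3] * Bprod
    v0 <- (keq * Aprod - Bprod) / D
  } else {
    D <- cpar[1] + cpar[2] * Aprod
    v0 <- keq * Aprod / D
  }

  # rate block on t = sign(v) * v0, with C^1 linear extension below t_min
  sgn <- sign(v_obs)
  va <- abs(v_obs)
  t_i <- sgn * v0
  t_min <- 1e-3 * va
  g_val <- function(t, v) log(t) + (v / t - 1)^2 / (2 * sigma_v^2)
  g_deriv <- function(t, v) 1 / t - (v^2 / t^3 - v / t^2) / sigma_v^2
  low <- t_i <= t_min
  gv <- numeric(n)
  gp <- numeric(n)
  if (any(!low)) {
    gv[!low] <- g_val(t_i[!low], va[!low])
    gp[!low] <- g_deriv(t_i[!low], va[!low])
  }
  if (any(low)) {
    gv[low] <- g_val(t_min[low], va[low]) +
      g_deriv(t_min[low], va[low]) * (t_i[low] - t_min[low])
    gp[low] <- g_deriv(t_min[low], va[low])
  }
  w <- sgn * gp  # dF/dv0_i

  ua <- A_obs / a0
  value <- sum(la0) + sum(gv) + sum((ua - 1)^2) / (2 * sigma_a^2)
  if (reversible) {
    ub <- B_obs / b0
    value <- value + sum(lb0) + sum((ub - 1)^2) / (2 * sigma_b^2)
  }

  # chain rule through v0
  dv_dA <- (keq - cpar[2] * v0) / D
  grad_la0 <- 1 - (ua - 1) * ua / sigma_a^2 + (w * dv_dA * Aprod)
  g_c <- c(-cpar[1] * sum(w * v0 / D),
           -cpar[2] * sum(w * v0 * Aprod / D))
  if (reversible) {
    dv_dB <- (-1 - cpar[3] * v0) / D
    grad_lb0 <- 1 - (ub - 1) * ub / sigma_b^2 + (w * dv_dB * Bprod)
    g_c <- c(g_c, -cpar[3] * sum(w * v0 * Bprod / D))
    grad <- c(g_c, as.numeric(grad_la0), as.numeric(grad_lb0))
  } else {
    grad <- c(g_c, as.numeric(grad_la0))
  }
  list(value = value, grad = grad)
}

# fn/gr pair for optim() sharing one evaluation per point.
make_eiv_objective <- function(A_obs, B_obs, v_obs, keq,
                               sigma_a, sigma_b, sigma_v) {
  cache_theta <- NULL
  cache <- NULL
  eval_at <- function(theta) {
    if (is.null(cache_theta) || !identical(theta, cache_theta)) {
      cache_theta <<- theta
      cache <<- eiv_value_grad(theta, A_obs, B_obs, v_obs, keq,
                               sigma_a, sigma_b, sigma_v)
    }
    cache
  }
  list(fn = function(theta) eval_at(theta)$value,
       gr = function(theta) eval_at(theta)$grad)
}

#' Negated log-likelihood of an errors-in-variables kinetic model
#'
#' Evaluates the objective minimised by [fit_kinetics()]: the negated
#' log-likelihood (additive constants dropped) of the measurements given
#' kinetic parameters and latent noise-free concentrations, with each
#' latent rate computed from the rate law at the latent concentrations.
#' The latent rate of every experiment must have the same sign as its
#' measured rate (the relative-error model cannot move a measurement
#' across zero). Exposed for diagnostics and gradient checking.
#'
#' @param params [kinetic_params()] (or positive 3-vector).
#' @param latents A list with matrices `substrates0` (`n x m`) and
#'   `products0` (`n x p`) of latent noise-free concentrations.
#' @param data Experiment tibble with columns `a_1..a_m`, `b_1..b_p`, `v`.
#' @param spec A [reaction_spec()].
#' @param noise A [noise_model()] with all sigmas strictly positive.
#' @return The scalar objective value (finite; smaller is better).
#' @export
negative_log_likelihood <- function(params, latents, data, spec,
                                    noise = noise_model()) {
  mats <- xp_matrices(data, spec)
  A0 <- conc_matrix(latents$substrates0, spec$m, "substrates0")
  B0 <- conc_matrix(latents$products0, spec$p, "products0")
  if (nrow(A0) != mats$n || nrow(B0) != mats$n) {
    abort("Latent matrices must have one row per experiment.")
  }
  if (noise$sigma_a <= 0 || noise$sigma_b <= 0 || noise$sigma_v <= 0) {
    abort("All sigmas must be strictly positive to evaluate the likelihood.")
  }
  pvec <- as_param_vector(params, 3L)
  v0 <- rate_law(row_prod(A0), row_prod(B0), pvec[1], pvec[2], pvec[3],
                 spec$keq)
  if (any(v0 * mats$v <= 0)) {
    abort("Latent rate is zero or opposes the measured direction for some experiment.")
  }
  sum(log(A0)) + sum(log(B0)) + sum(log(abs(v0))) +
    sum((mats$A / A0 - 1)^2) / (2 * noise$sigma_a^2) +
    sum((mats$B / B0 - 1)^2) / (2 * noise$sigma_b^2) +
    sum((mats$v / v0 - 1)^2) / (2 * noise$sigma_v^2)
}
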