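# Classical two-parameter Michaelis-Menten estimators, used as benchmarks
# for the errors-in-variables fit on irreversible single-substrate data
# following v = keq * a / (c1 + c2 * a), i.e. Vmax = keq/c2, Km = c1/c2.

#' Convert between (Vmax, Km) and the lumped parameters
#'
#' For the irreversible two-parameter law \eqn{v = K_{eq} a/(c_1 + c_2 a)}:
#' \eqn{V_{max} = K_{eq}/c_2} and \eqn{K_m = c_1/c_2}. The round trip is
#' exact given `keq`.
#'
#' @param vmax,km Michaelis-Menten parameters (positive).
#' @param c1,c2 Lumped parameters (positive).
#' @param keq Numerator scale constant.
#' @return A named numeric vector (`c1`, `c2`) or (`vmax`, `km`).
#' @export
mm_to_c <- function(vmax, km, keq = 1) {
  if (vmax <= 0 || km <= 0) abort("`vmax` and `km` must be positive.")
  c(c1 = keq * km / vmax, c2 = keq / vmax)
}

#' @rdname mm_to_c
#' @export
c_to_mm <- function(c1, c2, keq = 1) {
  if (c1 <= 0 || c2 <= 0) abort("`c1` and `c2` must be positive.")
  c(vmax = keq / c2, km = c1 / c2)
}

mm_data <- function(data) {
  mats <- xp_matrices(data)
  if (mats$m != 1 || mats$p != 0) {
    abort("Two-parameter estimators expect columns `a_1` and `v` only.")
  }
  list(a = as.numeric(mats$A), v = mats$v, n = mats$n)
}

mm_fit_result <- function(method, c1, c2, converged = TRUE, objective = NA_real_) {
  structure(list(method = method,
                 params = c(c1 = as.numeric(c1), c2 = as.numeric(c2)),
                 converged = converged, objective = objective),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit: %s> c1 = %.6g, c2 = %.6g\n",
              x$method, x$params["c1"], x$params["c2"]))
  invisible(x)
}

#' @rdname fit_mm_ols
#' @param x A fitted `mm_fit` object.
#' @param ... Unused.
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(method = x$method, term = names(x$params),
                 estimate = as.numeric(x$params))
}

#' Classical and errors-in-variables Michaelis-Menten estimators
#'
#' Five estimators of `(c1, c2)` for the irreversible law
#' \eqn{v = K_{eq} a / (c_1 + c_2 a)} from `n` experiments `(a_i, v_i)`:
#'
#' * `fit_mm_ols()`: nonlinear least squares on rate residuals
#'   \eqn{\sum_i (v_i - K_{eq} a_i/(c_1 + c_2 a_i))^2} (assumes additive
#'   error in `v` only).
#' * `fit_mm_tls()`: total least squares as orthogonal-distance regression,
#'   \eqn{\sum_i (a_i - a_{i0})^2 + (v_i - v_{i0})^2} with \eqn{v_{i0}} on
#'   the curve (additive error in both variables).
#' * `fit_mm_dlp()`: the direct linear plot — for every pair of
#'   observations the intersection
#'   \eqn{K_m = (v_j - v_i)/(v_i/a_i - v_j/a_j)},
#'   \eqn{V_{max} = v_i + (v_i/a_i) K_m}; component-wise medians over all
#'   pairs (near-parallel pairs skipped).
#' * `fit_mm_drp()`: the double-reciprocal (Lineweaver-Burk) plot —
#'   ordinary regression of `1/v` on `1/a`; `c1 = slope * keq`,
#'   `c2 = intercept * keq`.
#' * `fit_mm_mle()`: the errors-in-variables maximum-likelihood fit with
#'   multiplicative noise on both `a` and `v` (same machinery as
#'   [fit_kinetics()] with the product block absent).
#'
#' All five recover the truth exactly on noiseless data.
#'
#' @param data Tibble with columns `exp_id`, `a_1`, `v` (at least 2 rows).
#' @param keq Numerator scale constant of the rate law.
#' @param noise A [noise_model()]; `sigma_a` and `sigma_v` must be positive
#'   (MLE only).
#' @param options A [fit_options()] (MLE and TLS optimiser settings).
#' @return An `mm_fit` object; use [tidy()] for a tibble of estimates.
#' @export
fit_mm_ols <- function(data, keq = 1) {
  d <- mm_data(data)
  if (d$n < 2) abort("At least 2 experiments are required.")
  start <- mm_start(d, keq)
  ft <- minpack.lm::nlsLM(
    v ~ keq * a / (c1 + c2 * a),
    data = data.frame(a = d$a, v = d$v, keq = keq),
    start = list(c1 = start[1], c2 = start[2]),
    lower = c(1e-12, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(ft)
  mm_fit_result("ols", cf[["c1"]], cf[["c2"]],
                objective = sum(stats::resid(ft)^2))
}

# crude positive starting point shared by OLS/TLS/MLE: double-reciprocal
# regression, floored; falls back to (1, 1)
mm_start <- function(d, keq, floor = 1e-6) {
  cf <- tryCatch(coef(lm(I(1 / d$v) ~ I(1 / d$a))), error = function(e) c(NA, NA))
  c1 <- keq * cf[2]
  c2 <- keq * cf[1]
  if (!all(is.finite(c(c1, c2))) || c1 <= 0 || c2 <= 0) c(1, 1)
  else unname(pmax(c(c1, c2), floor))
}

#' @rdname fit_mm_ols
#' @export
fit_mm_tls <- function(data, keq = 1, options = fit_options()) {
  d <- mm_data(data)
  if (d$n < 2) abort("At least 2 experiments are required.")
  start <- mm_start(d, keq)
  # orthogonal-distance objective over log(c) and log(a0)
  fn_gr <- function(theta) {
    cpar <- exp(theta[1:2])
    a0 <- exp(theta[-(1:2)])
    D <- cpar[1] + cpar[2] * a0
    v0 <- keq * a0 / D
    ra <- d$a - a0
    rv <- d$v - v0
    dv_da0 <- keq * cpar[1] / D^2
    list(value = sum(ra^2) + sum(rv^2),
         grad = c(-2 * cpar[1] * sum(rv * (-v0 / D)) * 1,
                  -2 * cpar[2] * sum(rv * (-v0 * a0 / D)),
                  (-2 * ra - 2 * rv * dv_da0) * a0))
  }
  cache <- local({
    th <- NULL; val <- NULL
    function(theta) {
      if (is.null(th) || !identical(th, theta)) {
        th <<- theta; val <<- fn_gr(theta)
      }
      val
    }
  })
  res <- optim(c(log(start), log(d$a)),
               fn = function(t) cache(t)$value,
               gr = function(t) cache(t)$grad,
               method = "L-BFGS-B",
               control = list(maxit = options$max_iterations,
                              pgtol = options$gradient_tolerance,
                              factr = 1e7))
  cpar <- exp(res$par[1:2])
  mm_fit_result("tls", cpar[1], cpar[2], converged = res$convergence == 0,
                objective = res$value)
}

#' @rdname fit_mm_ols
#' @export
fit_mm_dlp <- function(data, keq = 1) {
  d <- mm_data(data)
  if (d$n < 2) abort("At least 2 experiments are required.")
  s <- d$v / d$a  # slope of each observation line
  idx <- combn(d$n, 2)
  i <- idx[1, ]; j <- idx[2, ]
  ok <- abs(s[i] - s[j]) >= 1e-12
  if (!any(ok)) abort("All observation-line pairs are parallel; cannot intersect.")
  km <- (d$v[j[ok]] - d$v[i[ok]]) / (s[i[ok]] - s[j[ok]])
  vmax <- d$v[i[ok]] + s[i[ok]] * km
  cpar <- mm_to_c(median(vmax), median(km), keq)
  mm_fit_result("dlp", cpar["c1"], cpar["c2"])
}

#' @rdname fit_mm_ols
#' @export
fit_mm_drp <- function(data, keq = 1) {
  d <- mm_data(data)
  if (d$n < 2) abort("At least 2 experiments are required.")
  if (any(d$v <= 0)) abort("Double-reciprocal plot requires all rates positive.")
  cf <- coef(lm(I(1 / d$v) ~ I(1 / d$a)))
  mm_fit_result("drp", keq * cf[[2]], keq * cf[[1]])
}

#' @rdname fit_mm_ols
#' @export
fit_mm_mle <- function(data, keq = 1, noise = noise_model(),
                       options = fit_options()) {
  d <- mm_data(data)
  if (d$n < 2) abort("At least 2 experiments are required.")
  if (noise$sigma_a <= 0 || noise$sigma_v <= 0) {
    abort("`sigma_a` and `sigma_v` must be strictly positive.")
  }
  A_obs <- matrix(d$a, ncol = 1)
  obj <- make_eiv_objective(A_obs, NULL, d$v, keq,
                            noise$sigma_a, NA_real_, noise$sigma_v)
  start <- mm_start(d, keq)
  if (!is.null(options$seed)) set.seed(options$seed)
  best <- NULL
  for (s in seq_len(options$n_starts)) {
    c_start <- if (s == 1) start else start * rlnorm(2, 0, 0.5)
    res <- optim(c(log(c_start), log(d$a)), obj$fn, obj$gr,
                 method = "L-BFGS-B",
                 control = list(maxit = options$max_iterations,
                                pgtol = options$gradient_tolerance,
                                factr = 1e7))
    if (is.null(best) || res$value < best$value - 1e-12) best <- res
  }
  cpar <- exp(best$par[1:2])
  mm_fit_result("mle", cpar[1], cpar[2], converged = best$convergence == 0,
                objective = best$value)
}

#' Monte-Carlo comparison of the five two-parameter estimators
#'
#' Generates `replicates` synthetic irreversible data sets (relative noise
#' on both `a` and `v`), applies all five estimators to each, and
#' summarises mean estimates and relative standard errors (SD of the
#' replicate estimates divided by the true value) per method.
#'
#' @param truth Named vector `c(c1 = , c2 = )` of true parameters.
#' @param keq Numerator scale constant (default 1).
#' @param n Experiments per data set.
#' @param replicates Number of simulated data sets.
#' @param a_range Substrate sampling range (log-uniform).
#' @param noise A [noise_model()]; `sigma_a`/`sigma_v` are applied.
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @return A tibble with one row per method: `mean_c1`, `mean_c2`,
#'   `rel_se_c1`, `rel_se_c2`, `n_failed`.
#' @export
compare_estimators <- function(truth = c(c1 = 1.5, c2 = 0.8), keq = 1,
                               n = 30, replicates = 1000,
                               a_range = c(0.1, 20),
                               noise = noise_model(), seed = 1) {
  methods <- list(tls = fit_mm_tls, ols = fit_mm_ols, dlp = fit_mm_dlp,
                  drp = fit_mm_drp, mle = fit_mm_mle)
  opts <- fit_options(n_starts = 1)
  draws <- purrr::map(seq_len(replicates), function(r) {
    d <- simulate_mm_experiments(truth[["c1"]], truth[["c2"]], keq = keq,
                                 n = n, a_range = a_range, noise = noise,
                                 seed = seed + r)
    purrr::imap(methods, function(f, nm) {
      est <- tryCatch({
        ft <- if (nm == "mle") f(d, keq, noise, opts)
              else if (nm == "tls") f(d, keq, opts)
              else f(d, keq)
        if (isFALSE(ft$converged)) c(NA_real_, NA_real_) else ft$params
      }, error = function(e) c(NA_real_, NA_real_))
      tibble::tibble(method = nm, c1 = est[1], c2 = est[2])
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  draws |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mean_c1 = mean(.data$c1, na.rm = TRUE),
      mean_c2 = mean(.data$c2, na.rm = TRUE),
      rel_se_c1 = sd(.data$c1, na.rm = TRUE) / truth[["c1"]],
      rel_se_c2 = sd(.data$c2, na.rm = TRUE) / truth[["c2"]],
      n_failed = sum(is.na(.data$c1)),
      .groups = "drop") |>
    dplyr::arrange(match(.data$method, names(methods)))
}
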