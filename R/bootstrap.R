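#' Resample experiments with replacement
#'
#' Draws `n` whole experiments (rows) uniformly with replacement; each
#' resampled row keeps its substrate, product and rate values together.
#'
#' @param data Experiment tibble with at least 2 rows.
#' @return A tibble of the same shape with resampled rows.
#' @export
resample_experiments <- function(data) {
  n <- nrow(data)
  if (n < 2) abort("Need at least 2 experiments to resample.")
  data[sample.int(n, n, replace = TRUE), , drop = FALSE]
}

#' Bootstrap standard errors and bias of a kinetic fit
#'
#' Refits the model on `n_samples` resamples of the experiments (rows drawn
#' with replacement) and summarises the replicate estimates
#' \eqn{\hat{c}_i^*} against the point estimate \eqn{\hat{c}}:
#' \deqn{SE_B(\hat{c}) = \left[\tfrac{1}{N}\sum(\hat{c}_i^* -
#'   \hat{c})^2\right]^{1/2}, \qquad
#'   Bias = \tfrac{1}{N}\sum \hat{c}_i^* - \hat{c},}
#' reported both absolutely and relative to \eqn{\hat{c}}. The usual
#' recommendation for the number of resamples is \eqn{N = n^2}, the default
#' here; `n_samples` may be reduced for speed. Replicate fits are
#' warm-started at the point estimate; resamples with fewer than 3 distinct
#' experiments are redrawn (the fit is under-determined below 3 design
#' points), and failed replicate fits are excluded and counted.
#'
#' @param fit A converged [fit_kinetics()] result.
#' @param n_samples Number of bootstrap resamples (default `n^2`).
#' @param seed Optional integer seed for the resampling.
#' @return An object of class `kinetic_bootstrap` with the replicate
#'   estimate matrix, `se_b`, `bias`, `rel_se`, `rel_bias`, `n_failed` and
#'   a `reliable` flag (`FALSE` when more than 20% of replicate fits
#'   failed). Supports [tidy()], [glance()] and [autoplot()].
#' @export
bootstrap_fit <- function(fit, n_samples = NULL, seed = NULL) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (!fit$converged) abort("Bootstrap requires a converged point fit.")
  n <- nrow(fit$data)
  if (is.null(n_samples)) n_samples <- n^2
  if (n_samples < 2) abort("`n_samples` must be at least 2.")
  if (!is.null(seed)) set.seed(seed)

  point <- as.numeric(fit$params)
  opts <- fit$options
  opts$n_starts <- 1L
  reps <- matrix(NA_real_, n_samples, 3,
                 dimnames = list(NULL, names(fit$params)))
  n_failed <- 0L
  for (i in seq_len(n_samples)) {
    repeat {
      d <- resample_experiments(fit$data)
      if (dplyr::n_distinct(d$exp_id) >= 3) break
    }
    ft <- tryCatch(
      fit_warm(d, fit$spec, fit$noise, opts, point),
      error = function(e) NULL)
    if (is.null(ft) || !ft$converged) {
      n_failed <- n_failed + 1L
    } else {
      reps[i, ] <- as.numeric(ft$params)
    }
  }
  ok <- stats::complete.cases(reps)
  reps_ok <- reps[ok, , drop = FALSE]
  if (nrow(reps_ok) < 2) abort("Too few successful bootstrap replicate fits.")
  s <- boot_summary(reps_ok, point)
  structure(list(
    point_estimate = fit$params,
    replicate_estimates = tibble::as_tibble(reps_ok),
    se_b = s$se_b, bias = s$bias,
    rel_se = s$rel_se, rel_bias = s$rel_bias,
    n_samples = n_samples, n_failed = n_failed,
    reliable = n_failed <= 0.2 * n_samples,
    seed = seed),
    class = "kinetic_bootstrap")
}

# SE_B = [1/N sum (c* - c_hat)^2]^(1/2), Bias = 1/N sum c* - c_hat,
# and their forms relative to the point estimate
boot_summary <- function(reps, point) {
  se_b <- sqrt(colMeans(sweep(reps, 2, point)^2))
  bias <- colMeans(reps) - point
  list(se_b = se_b, bias = bias, rel_se = se_b / point, rel_bias = bias / point)
}

# single warm start at given parameters, latents at the (resampled) data
fit_warm <- function(data, spec, noise, options, c_start) {
  mats <- xp_matrices(data, spec)
  init <- initialize_fit(data, spec, options$parameter_floor)
  obj <- make_eiv_objective(mats$A, mats$B, mats$v, spec$keq,
                            noise$sigma_a, noise$sigma_b, noise$sigma_v)
  theta0 <- c(log(c_start),
              log(as.numeric(init$latents$substrates0)),
              log(as.numeric(init$latents$products0)))
  res <- optim(theta0, obj$fn, obj$gr, method = "L-BFGS-B",
               control = list(maxit = options$max_iterations,
                              pgtol = options$gradient_tolerance,
                              factr = 1e7))
  cpar <- exp(res$par[1:3])
  list(params = kinetic_params(cpar[1], cpar[2], cpar[3]),
       objective = res$value, converged = res$convergence == 0)
}

#' @export
print.kinetic_bootstrap <- function(x, ...) {
  cat(sprintf("<kinetic_bootstrap> %d resamples (%d failed)%s\n",
              x$n_samples, x$n_failed,
              if (x$reliable) "" else " [UNRELIABLE]"))
  print(tidy(x))
  invisible(x)
}

#' @rdname bootstrap_fit
#' @param x,object A `kinetic_bootstrap`.
#' @param ... Unused.
#' @method tidy kinetic_bootstrap
#' @export
tidy.kinetic_bootstrap <- function(x, ...) {
  tibble::tibble(
    term = names(x$point_estimate),
    estimate = as.numeric(x$point_estimate),
    std_error = as.numeric(x$se_b),
    bias = as.numeric(x$bias),
    rel_se = as.numeric(x$rel_se),
    rel_bias = as.numeric(x$rel_bias))
}

#' @rdname bootstrap_fit
#' @method glance kinetic_bootstrap
#' @export
glance.kinetic_bootstrap <- function(x, ...) {
  tibble::tibble(n_samples = x$n_samples, n_failed = x$n_failed,
                 reliable = x$reliable)
}

#' @rdname bootstrap_fit
#' @method autoplot kinetic_bootstrap
#' @export
autoplot.kinetic_bootstrap <- function(object, ...) {
  df <- tidyr::pivot_longer(object$replicate_estimates,
                            dplyr::everything(),
                            names_to = "term", values_to = "estimate")
  pt <- tidy(object)[c("term", "estimate")]
  names(pt)[2] <- "point"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(data = pt, ggplot2::aes(xintercept = .data$point),
                        colour = "red", linetype = 2) +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = "bootstrap replicate estimate", y = "count",
                  title = "Bootstrap distributions of the kinetic parameters")
}
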