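#' Multiply values by Gaussian relative noise
#'
#' Applies the multiplicative error model \eqn{x_{meas} = x \cdot \epsilon}
#' with \eqn{\epsilon \sim N(1, \sigma^2)}, so `sigma` plays the role of
#' the coefficient of variation. Draws with \eqn{\epsilon \le 0} (relevant
#' only at large `sigma`) are rejected and redrawn: concentrations must
#' stay positive for the log-likelihood, and a rate measurement is assumed
#' to preserve the true flux direction.
#'
#' @param x Numeric vector of non-zero true values (typically positive
#'   concentrations; rates may be negative, their sign is preserved).
#' @param sigma Relative standard deviation (non-negative scalar).
#' @return `x` perturbed element-wise; identical to `x` when `sigma = 0`.
#' @export
#' @examples
#' set.seed(1)
#' apply_relative_noise(c(1, 5, 10), sigma = 0.2)
apply_relative_noise <- function(x, sigma) {
  if (any(x == 0)) abort("`x` must be non-zero.")
  if (sigma < 0) abort("`sigma` must be non-negative.")
  if (sigma == 0) return(x)
  eps <- rnorm(length(x), mean = 1, sd = sigma)
  bad <- which(eps <= 0)
  while (length(bad)) {
    eps[bad] <- rnorm(length(bad), mean = 1, sd = sigma)
    bad <- bad[eps[bad] <= 0]
  }
  x * eps
}

#' Sampling design for synthetic steady-state experiments
#'
#' Describes how the noise-free concentrations of a simulated experiment
#' set are drawn. The default emulates a "well-distributed" design spanning
#' the whole kinetic curve in three regimes of equal weight, named by the
#' denominator term (`c1 + c2 prod(a) + c3 prod(b)`) that dominates there:
#'
#' * `linear` — small substrate pools far from equilibrium; the rate grows
#'   linearly and pins down `c1`;
#' * `forward` — large substrate pools far below equilibrium (forward
#'   saturation); pins down `c2`;
#' * `reverse` — product pools far above equilibrium (reverse saturation,
#'   negative net rate); pins down `c3`.
#'
#' Within a regime each substrate is log-uniform over its `substrate`
#' range, the pooled-product-to-equilibrium ratio
#' \eqn{\rho = \prod b / (K_{eq} \prod a)} is log-uniform over its `ratio`
#' range, and the product pool is split log-uniformly across the `p`
#' product species. No `ratio` range may touch 1 (exact equilibrium, zero
#' rate); ranges above 1 give net-reverse experiments.
#'
#' @param n_experiments Number of experiments (divided across regimes by
#'   weight, largest-remainder rounding).
#' @param regimes Named list of regimes, each `list(substrate = c(lo, hi),
#'   ratio = c(lo, hi))` with positive bounds, `lo < hi`.
#' @param weights Non-negative regime weights (default equal).
#' @param split_range Range of the log-share taken by each product species
#'   when splitting the product pool (default `c(0.3, 0.7)`).
#' @param sampling `"log_uniform"` (default) or `"fixed_list"` (use the
#'   concentrations supplied in `fixed`).
#' @param fixed For `sampling = "fixed_list"`: a list with matrices
#'   `substrates` (`n x m`) and `products` (`n x p`).
#' @param forward_only If `TRUE`, regimes whose ratio range lies above 1
#'   are dropped (all net rates positive). Default `FALSE`: the default
#'   regimes deliberately include reverse-saturated experiments, without
#'   which `c3` is only weakly identifiable.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_experiments = 30,
                        regimes = list(
                          linear = list(substrate = c(0.1, 0.7),
                                        ratio = c(0.02, 0.2)),
                          forward = list(substrate = c(3, 10),
                                         ratio = c(0.02, 0.2)),
                          reverse = list(substrate = c(0.5, 5),
                                         ratio = c(5, 50))),
                        weights = NULL, split_range = c(0.3, 0.7),
                        sampling = c("log_uniform", "fixed_list"),
                        fixed = NULL, forward_only = FALSE) {
  sampling <- match.arg(sampling)
  if (!is_count(n_experiments)) abort("`n_experiments` must be a positive integer.")
  if (sampling == "fixed_list") {
    if (is.null(fixed) || is.null(fixed$substrates) || is.null(fixed$products)) {
      abort("`fixed` must supply `substrates` and `products` matrices.")
    }
  } else {
    for (nm in names(regimes)) {
      rg <- regimes[[nm]]
      for (fld in c("substrate", "ratio")) {
        rng <- rg[[fld]]
        if (length(rng) != 2 || any(rng <= 0) || rng[1] >= rng[2]) {
          abort(sprintf("Regime `%s`: `%s` must be positive bounds with lo < hi.", nm, fld))
        }
      }
      if (rg$ratio[1] < 1 && rg$ratio[2] >= 1) {
        abort(sprintf("Regime `%s`: `ratio` range must not straddle 1 (equilibrium).", nm))
      }
    }
    if (isTRUE(forward_only)) {
      keep <- vapply(regimes, function(r) r$ratio[2] < 1, logical(1))
      if (!any(keep)) abort("`forward_only` removed every regime.")
      if (!is.null(weights)) weights <- weights[keep]
      regimes <- regimes[keep]
    }
    if (is.null(weights)) weights <- rep(1, length(regimes))
    if (length(weights) != length(regimes) || any(weights < 0) || sum(weights) == 0) {
      abort("`weights` must be non-negative, one per regime, not all zero.")
    }
  }
  structure(list(n_experiments = as.integer(n_experiments), regimes = regimes,
                 weights = weights, split_range = as.numeric(split_range),
                 sampling = sampling, fixed = fixed,
                 forward_only = isTRUE(forward_only)),
            class = "design_spec")
}

# largest-remainder apportionment of n rows across regime weights
regime_counts <- function(n, weights) {
  q <- n * weights / sum(weights)
  k <- floor(q)
  left <- n - sum(k)
  if (left > 0) {
    extra <- order(q - k, decreasing = TRUE)[seq_len(left)]
    k[extra] <- k[extra] + 1
  }
  as.integer(k)
}

draw_latents <- function(design, spec, n) {
  m <- spec$m
  p <- spec$p
  if (design$sampling == "fixed_list") {
    A0 <- conc_matrix(design$fixed$substrates, m, "substrates")
    B0 <- conc_matrix(design$fixed$products, p, "products")
    if (nrow(A0) != n || nrow(B0) != n) {
      abort("Fixed concentration matrices must have `n_experiments` rows.")
    }
    return(list(A0 = A0, B0 = B0))
  }
  counts <- regime_counts(n, design$weights)
  A0 <- matrix(0, n, m)
  rho <- numeric(n)
  at <- 0
  for (i in seq_along(design$regimes)) {
    if (counts[i] == 0) next
    rg <- design$regimes[[i]]
    rows <- at + seq_len(counts[i])
    A0[rows, ] <- exp(runif(counts[i] * m, log(rg$substrate[1]),
                            log(rg$substrate[2])))
    rho[rows] <- exp(runif(counts[i], log(rg$ratio[1]), log(rg$ratio[2])))
    at <- at + counts[i]
  }
  Bpool <- rho * spec$keq * row_prod(A0)
  B0 <- matrix(0, n, p)
  if (p == 1) {
    B0[, 1] <- Bpool
  } else {
    # log-split the pool: species j takes exponent share w_j, sum(w) = 1
    w <- matrix(runif(n * p, design$split_range[1], design$split_range[2]), n, p)
    w <- w / rowSums(w)
    B0 <- exp(w * log(Bpool))
  }
  list(A0 = A0, B0 = B0)
}

#' Generate a synthetic steady-state experiment set
#'
#' Draws noise-free concentrations according to `design`, computes each
#' noise-free rate exactly from the steady-state rate law at `truth`, then
#' multiplies every substrate, product and rate value by an independent
#' \eqn{N(1, \sigma^2)} draw. With all sigmas zero the returned rates
#' satisfy the rate law exactly.
#'
#' @param truth True [kinetic_params()] generating the data.
#' @param spec A [reaction_spec()].
#' @param design A [design_spec()]; its `n_experiments` sets the number of
#'   rows.
#' @param noise A [noise_model()].
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `exp_id`, `a_1..a_m`, `b_1..b_p`, `v`.
#' @export
#' @examples
#' sp <- reaction_spec(2, 2, keq = 1.7281)
#' th <- kinetic_params(2.5783, 3.7327, 3.5238)
#' simulate_experiments(th, sp, design_spec(5), noise_model(), seed = 1)
simulate_experiments <- function(truth, spec, design = design_spec(),
                                 noise = noise_model(), seed = NULL) {
  stopifnot(inherits(spec, "reaction_spec"), inherits(design, "design_spec"),
            inherits(noise, "noise_model"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_experiments
  lat <- draw_latents(design, spec, n)
  A0 <- lat$A0
  B0 <- lat$B0
  v0 <- reaction_rate(truth, spec, A0, B0)
  if (any(v0 == 0)) abort("Design produced an exact-equilibrium (zero-rate) experiment.")
  if (design$forward_only && any(v0 <= 0)) {
    abort("Design produced a non-positive noise-free rate despite `forward_only`.")
  }
  A <- matrix(apply_relative_noise(as.numeric(A0), noise$sigma_a), n, spec$m)
  B <- matrix(apply_relative_noise(as.numeric(B0), noise$sigma_b), n, spec$p)
  v <- apply_relative_noise(v0, noise$sigma_v)
  out <- tibble::as_tibble(cbind(
    as.data.frame(A) |> setNames(paste0("a_", seq_len(spec$m))),
    as.data.frame(B) |> setNames(paste0("b_", seq_len(spec$p))),
    v = v))
  tibble::add_column(out, exp_id = seq_len(n), .before = 1)
}

#' Generate irreversible single-substrate (Michaelis-Menten) experiments
#'
#' Companion generator for the two-parameter model
#' \eqn{v = K_{eq} a / (c_1 + c_2 a)} used when benchmarking against
#' classical Michaelis-Menten estimators: substrate concentrations are
#' drawn log-uniformly over `a_range`, the rate is computed exactly, and
#' relative noise is applied to both `a` and `v` (there are no product
#' measurements).
#'
#' @param c1,c2 True parameters (positive).
#' @param keq Equilibrium-constant scale factor of the numerator (default 1).
#' @param n Number of experiments.
#' @param a_range Positive bounds for the substrate concentration; the
#'   default spans well below and above \eqn{K_m = c_1/c_2}.
#' @param noise A [noise_model()]; only `sigma_a` and `sigma_v` are used.
#' @param seed Optional integer seed.
#' @return A tibble with columns `exp_id`, `a_1`, `v`.
#' @export
simulate_mm_experiments <- function(c1, c2, keq = 1, n = 30,
                                    a_range = c(0.1, 20),
                                    noise = noise_model(), seed = NULL) {
  if (!is_positive_scalar(c1) || !is_positive_scalar(c2)) {
    abort("`c1` and `c2` must be positive scalars.")
  }
  if (!is.null(seed)) set.seed(seed)
  a0 <- exp(runif(n, log(a_range[1]), log(a_range[2])))
  v0 <- keq * a0 / (c1 + c2 * a0)
  tibble::tibble(
    exp_id = seq_len(n),
    a_1 = apply_relative_noise(a0, noise$sigma_a),
    v = apply_relative_noise(v0, noise$sigma_v))
}
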