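#' Describe a reversible single-displacement reaction
#'
#' A reaction specification fixes the mechanism dimensions and the
#' thermodynamic equilibrium constant of the reaction
#' \deqn{a_1 + \dots + a_m \rightleftharpoons b_1 + \dots + b_p.}
#' All substrates bind before any product is released (single displacement),
#' so the steady-state rate depends on the concentrations only through the
#' products \eqn{\prod_j [a_j]} and \eqn{\prod_j [b_j]}.
#'
#' @param m Number of substrates (positive integer).
#' @param p Number of products (positive integer).
#' @param keq Dimensionless equilibrium constant \eqn{K_{eq}}; the net rate
#'   is zero exactly when \eqn{\prod [b_j] = K_{eq} \prod [a_j]}.
#'
#' @return An object of class `reaction_spec`.
#' @seealso [keq_from_gibbs()] to derive `keq` from formation energies.
#' @export
#' @examples
#' reaction_spec(m = 2, p = 2, keq = 1.7281)
reaction_spec <- function(m, p, keq) {
  if (!is_count(m) || !is_count(p)) {
    abort("`m` and `p` must be positive integers.")
  }
  if (!is_positive_scalar(keq)) {
    abort("`keq` must be a positive, finite number.")
  }
  structure(list(m = as.integer(m), p = as.integer(p), keq = as.numeric(keq)),
            class = "reaction_spec")
}

#' @export
print.reaction_spec <- function(x, ...) {
  cat(sprintf(
    "<reaction_spec> %d substrate(s) + %d product(s), Keq = %g\n",
    x$m, x$p, x$keq
  ))
  invisible(x)
}

#' Lumped kinetic parameters of the steady-state rate law
#'
#' The three positive constants `c1`, `c2`, `c3` appearing in the denominator
#' of the rate law
#' \deqn{v = \frac{K_{eq}\prod_j [a_j] - \prod_j [b_j]}
#'           {c_1 + c_2 \prod_j [a_j] + c_3 \prod_j [b_j]}.}
#' Each is a combination of elementary rate constants divided by the total
#' enzyme concentration, so all three scale as \eqn{1/[E_{tot}]}.
#'
#' @param c1,c2,c3 Strictly positive, finite numbers.
#' @return A named numeric vector of class `kinetic_params`.
#' @export
#' @examples
#' kinetic_params(2.5783, 3.7327, 3.5238)
kinetic_params <- function(c1, c2, c3) {
  vals <- c(c1 = c1, c2 = c2, c3 = c3)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    abort("Kinetic parameters must all be strictly positive and finite.")
  }
  structure(as.numeric(vals), names = names(vals), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Elementary rate constants of the three-step mechanism
#'
#' The mechanism binding -> conversion -> release has forward constants
#' `k1`, `k2`, `k3` and reverse constants `km1`, `km2`, `km3`; together with
#' the total enzyme concentration `e_tot` (free enzyme plus both
#' intermediate complexes) they determine the lumped parameters and
#' \eqn{K_{eq} = k_1 k_2 k_3 / (k_{-1} k_{-2} k_{-3})}.
#'
#' @param k1,k2,k3 Forward rate constants (positive).
#' @param km1,km2,km3 Reverse rate constants (positive).
#' @param e_tot Total enzyme concentration (positive).
#' @return An object of class `mechanistic_constants`.
#' @seealso [params_from_rate_constants()], [steady_state_rate()]
#' @export
mechanistic_constants <- function(k1, k2, k3, km1, km2, km3, e_tot = 1) {
  vals <- c(k1 = k1, k2 = k2, k3 = k3, km1 = km1, km2 = km2, km3 = km3,
            e_tot = e_tot)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    abort("All rate constants and `e_tot` must be strictly positive and finite.")
  }
  structure(as.list(vals), class = "mechanistic_constants")
}

#' Relative-error magnitudes of the measurements
#'
#' Every measurement is modelled as its true value times an independent
#' Gaussian multiplier \eqn{\epsilon \sim N(1, \sigma^2)}; \eqn{\sigma} is
#' the coefficient of variation of the measurement platform. The default of
#' 0.2 for concentrations and rates reflects the CV typically quoted for
#' quantitative mass-spectrometry metabolomics.
#'
#' @param sigma_a,sigma_b,sigma_v Relative standard deviations in `[0, 1)`
#'   for substrate concentrations, product concentrations and reaction
#'   rates.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_a = 0.2, sigma_b = 0.2, sigma_v = 0.2) {
  vals <- c(sigma_a = sigma_a, sigma_b = sigma_b, sigma_v = sigma_v)
  if (!all(is.finite(vals)) || any(vals < 0) || any(vals >= 1)) {
    abort("Each sigma must lie in [0, 1).")
  }
  structure(as.list(vals), class = "noise_model")
}

#' Optimiser settings for the maximum-likelihood fit
#'
#' @param n_starts Number of optimisation starts; the first uses the
#'   algebraic initialisation, the rest perturb it log-normally.
#' @param max_iterations Iteration cap per start (quasi-Newton L-BFGS-B).
#' @param gradient_tolerance Projected-gradient tolerance declaring
#'   convergence.
#' @param parameter_floor Lower floor applied to the initial parameter
#'   guess before log-transforming.
#' @param seed Optional integer seed controlling the multi-start
#'   perturbations.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(n_starts = 5, max_iterations = 2000,
                        gradient_tolerance = 1e-8, parameter_floor = 1e-8,
                        seed = NULL) {
  if (!is_count(n_starts)) abort("`n_starts` must be a positive integer.")
  if (!is_count(max_iterations)) abort("`max_iterations` must be a positive integer.")
  if (!is_positive_scalar(gradient_tolerance) ||
      !is_positive_scalar(parameter_floor)) {
    abort("Tolerances must be positive.")
  }
  structure(list(n_starts = as.integer(n_starts),
                 max_iterations = as.integer(max_iterations),
                 gradient_tolerance = gradient_tolerance,
                 parameter_floor = parameter_floor,
                 seed = seed),
            class = "fit_options")
}

## ---- internal validation helpers ----

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)
}

is_positive_scalar <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0
}

# Split an experiment tibble (exp_id, a_1..a_m, b_1..b_p, v) into matrices.
# p = 0 (no product columns) is allowed for irreversible two-parameter data.
xp_matrices <- function(data, spec = NULL) {
  nm <- names(data)
  a_cols <- grep("^a_[0-9]+$", nm, value = TRUE)
  b_cols <- grep("^b_[0-9]+$", nm, value = TRUE)
  if (length(a_cols) == 0) abort("No substrate columns `a_1`, `a_2`, ... found.")
  if (!"v" %in% nm) abort("No rate column `v` found.")
  a_cols <- a_cols[order(as.integer(sub("a_", "", a_cols)))]
  b_cols <- b_cols[order(as.integer(sub("b_", "", b_cols)))]
  A <- as.matrix(data[a_cols])
  B <- if (length(b_cols)) as.matrix(data[b_cols]) else NULL
  v <- as.numeric(data[["v"]])
  if (!is.null(spec)) {
    if (ncol(A) != spec$m) {
      abort(sprintf("Data have %d substrate columns but the reaction has m = %d.",
                    ncol(A), spec$m))
    }
    if (length(b_cols) != spec$p) {
      abort(sprintf("Data have %d product columns but the reaction has p = %d.",
                    length(b_cols), spec$p))
    }
  }
  bad <- which(!stats::complete.cases(A) | !is.finite(v) | v == 0 |
                 apply(A, 1, function(r) any(!is.finite(r) | r <= 0)) |
                 (if (is.null(B)) FALSE else apply(B, 1, function(r) any(!is.finite(r) | r <= 0))))
  if (length(bad)) {
    abort(sprintf(
      "Non-finite or non-positive measurement in row(s): %s.",
      paste(head(bad, 5), collapse = ", ")))
  }
  list(A = A, B = B, v = v, n = nrow(A), m = ncol(A),
       p = if (is.null(B)) 0L else ncol(B))
}
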