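#' Steady-state rate of a reversible single-displacement reaction
#'
#' Evaluates
#' \deqn{v = \frac{K_{eq}\prod_j [a_j] - \prod_j [b_j]}
#'           {c_1 + c_2 \prod_j [a_j] + c_3 \prod_j [b_j]}}
#' at the supplied concentrations. With one substrate and one product this is
#' the familiar reversible Michaelis-Menten-type law; in the limit of large
#' \eqn{K_{eq}} and negligible `c3` it reduces to the irreversible
#' Michaelis-Menten equation with \eqn{V_{max} = K_{eq}/c_2} and
#' \eqn{K_m = c_1/c_2}.
#'
#' @param params A [kinetic_params()] object (or positive numeric 3-vector).
#' @param spec A [reaction_spec()].
#' @param substrates Substrate concentrations: a positive numeric vector of
#'   length `m`, or an `n x m` matrix for several experiments at once.
#' @param products Product concentrations: vector of length `p`, or an
#'   `n x p` matrix conformable with `substrates`.
#'
#' @return The net rate (scalar, or vector of length `n`). Its sign equals
#'   the sign of \eqn{K_{eq}\prod a - \prod b}; it is zero exactly at
#'   thermodynamic equilibrium.
#' @export
#' @examples
#' sp <- reaction_spec(2, 2, keq = 1.7281)
#' th <- kinetic_params(2.5783, 3.7327, 3.5238)
#' reaction_rate(th, sp, substrates = c(1, 1), products = c(1, 1))
reaction_rate <- function(params, spec, substrates, products) {
  params <- as_param_vector(params, 3L)
  A <- conc_matrix(substrates, spec$m, "substrates")
  B <- conc_matrix(products, spec$p, "products")
  if (nrow(A) != nrow(B)) {
    abort("`substrates` and `products` must describe the same number of experiments.")
  }
  v <- rate_law(row_prod(A), row_prod(B), params[1], params[2], params[3],
                spec$keq)
  if (any(!is.finite(v))) abort("Rate evaluated to a non-finite value.")
  if (length(v) == 1) as.numeric(v) else v
}

# Core algebraic form on pooled concentrations Aprod = prod_j a_j, etc.
rate_law <- function(Aprod, Bprod, c1, c2, c3, keq) {
  (keq * Aprod - Bprod) / (c1 + c2 * Aprod + c3 * Bprod)
}

row_prod <- function(M) {
  if (ncol(M) == 1) as.numeric(M) else exp(rowSums(log(M)))
}

conc_matrix <- function(x, k, what) {
  if (is.null(dim(x))) {
    if (length(x) != k) {
      abort(sprintf("`%s` must have length %d (one value per species).", what, k))
    }
    x <- matrix(x, nrow = 1)
  }
  x <- as.matrix(x)
  if (ncol(x) != k) {
    abort(sprintf("`%s` must have %d column(s).", what, k))
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("All `%s` concentrations must be positive and finite.", what))
  }
  x
}

as_param_vector <- function(params, k) {
  x <- as.numeric(unclass(params))
  if (length(x) != k || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("Expected %d strictly positive kinetic parameters.", k))
  }
  x
}

#' Lumped parameters from elementary rate constants
#'
#' Maps the six elementary rate constants and the total enzyme concentration
#' of the three-step mechanism onto the lumped rate-law parameters:
#' \deqn{c_1 = \left(\frac{k_2 k_3}{k_{-1}k_{-2}k_{-3}} +
#'   \frac{k_3}{k_{-2}k_{-3}} + \frac{1}{k_{-3}}\right)/[E_{tot}]}
#' \deqn{c_2 = \left(\frac{k_1 k_2}{k_{-1}k_{-2}k_{-3}} +
#'   \frac{k_1 k_3}{k_{-1}k_{-2}k_{-3}} +
#'   \frac{k_1}{k_{-1}k_{-3}}\right)/[E_{tot}]}
#' \deqn{c_3 = \left(\frac{1}{k_{-2}} + \frac{1}{k_{-1}} +
#'   \frac{k_2}{k_{-1}k_{-2}}\right)/[E_{tot}]}
#' together with \eqn{K_{eq} = k_1 k_2 k_3/(k_{-1}k_{-2}k_{-3})}. Because
#' each \eqn{c_i \propto 1/[E_{tot}]}, the ratio of corresponding parameters
#' between two conditions equals the inverse ratio of total enzyme.
#'
#' @param mech A [mechanistic_constants()] object.
#' @return A list with elements `params` ([kinetic_params()]) and `keq`.
#' @export
#' @examples
#' params_from_rate_constants(mechanistic_constants(1, 1, 1, 1, 1, 1))
params_from_rate_constants <- function(mech) {
  stopifnot(inherits(mech, "mechanistic_constants"))
  with(mech, {
    c1 <- (k2 * k3 / (km1 * km2 * km3) + k3 / (km2 * km3) + 1 / km3) / e_tot
    c2 <- (k1 * k2 / (km1 * km2 * km3) + k1 * k3 / (km1 * km2 * km3) +
             k1 / (km1 * km3)) / e_tot
    c3 <- (1 / km2 + 1 / km1 + k2 / (km1 * km2)) / e_tot
    list(params = kinetic_params(c1, c2, c3),
         keq = k1 * k2 * k3 / (km1 * km2 * km3))
  })
}

#' Equilibrium constant from standard Gibbs free energies of formation
#'
#' \eqn{\Delta G^\circ_{rxn} = \sum_j \Delta G_f^\circ(b_j) -
#' \sum_j \Delta G_f^\circ(a_j)} and
#' \eqn{K_{eq} = \exp(-\Delta G^\circ_{rxn} / RT)}.
#'
#' @param dgf_substrates,dgf_products Standard Gibbs free energies of
#'   formation (kJ/mol) of the substrates and products.
#' @param temperature Absolute temperature in kelvin (default 298.15).
#' @param gas_constant Gas constant in kJ/mol/K (default 0.008314).
#' @return The dimensionless equilibrium constant.
#' @export
#' @examples
#' keq_from_gibbs(-10, -10)  # Delta G = 0 -> Keq = 1
keq_from_gibbs <- function(dgf_substrates, dgf_products,
                           temperature = 298.15, gas_constant = 0.008314) {
  if (length(dgf_substrates) == 0 || length(dgf_products) == 0) {
    abort("Both formation-energy lists must be non-empty.")
  }
  if (!is_positive_scalar(temperature)) abort("`temperature` must be positive.")
  dg_rxn <- sum(dgf_products) - sum(dgf_substrates)
  exp(-dg_rxn / (gas_constant * temperature))
}

#' Steady-state rate by mass-action ODE integration
#'
#' Independent numerical oracle for the closed-form rate law: builds the
#' mass-action system for free enzyme `E` and the two intermediate
#' complexes over the three elementary steps, holding the substrate and
#' product pools fixed (buffered), integrates to steady state, and returns
#' the net conversion rate. Used to validate [reaction_rate()] composed with
#' [params_from_rate_constants()]; the two must agree to high relative
#' accuracy.
#'
#' @param mech A [mechanistic_constants()] object.
#' @param substrates,products Fixed external concentrations (vectors; their
#'   products drive binding/release under the single-displacement scheme).
#' @param tolerance Steady state is declared when every complex derivative
#'   falls below `tolerance * e_tot`; on non-convergence within the time
#'   budget the 3x3 linear steady-state system is solved directly.
#' @return The net steady-state rate (rate of product release).
#' @export
steady_state_rate <- function(mech, substrates, products, tolerance = 1e-10) {
  stopifnot(inherits(mech, "mechanistic_constants"))
  if (any(substrates <= 0) || any(products <= 0)) {
    abort("External concentrations must be strictly positive.")
  }
  Ap <- prod(substrates)
  Bp <- prod(products)
  k <- mech
  deriv <- function(t, y, parms) {
    E <- y[1]; aE <- y[2]; bE <- y[3]
    dE <- -k$k1 * Ap * E + k$km1 * aE + k$k3 * bE - k$km3 * Bp * E
    daE <- k$k1 * Ap * E - (k$km1 + k$k2) * aE + k$km2 * bE
    dbE <- k$k2 * aE + k$km3 * Bp * E - (k$km2 + k$k3) * bE
    list(c(dE, daE, dbE))
  }
  y <- c(E = k$e_tot, aE = 0, bE = 0)
  t_end <- 10 / min(unlist(k[c("k1", "k2", "k3", "km1", "km2", "km3")]))
  converged <- FALSE
  for (i in 1:60) {
    sol <- deSolve::lsoda(y, c(0, t_end), deriv, parms = NULL,
                          rtol = 1e-12, atol = 1e-14 * k$e_tot)
    y <- sol[nrow(sol), -1]
    if (max(abs(unlist(deriv(0, y, NULL)))) < tolerance * k$e_tot) {
      converged <- TRUE
      break
    }
    t_end <- t_end * 2
  }
  if (!converged) {
    # Direct algebraic steady state: two balance equations + conservation.
    M <- rbind(
      c(-(k$k1 * Ap + k$km3 * Bp), k$km1, k$k3),
      c(k$k1 * Ap, -(k$km1 + k$k2), k$km2),
      c(1, 1, 1))
    y <- solve(M, c(0, 0, k$e_tot))
    names(y) <- c("E", "aE", "bE")
  }
  as.numeric(k$k3 * y[["bE"]] - k$km3 * Bp * y[["E"]])
}
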