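#' Identifiability screening of the fitted parameters
#'
#' The rate is insensitive to a parameter whose denominator term is much
#' smaller than the others: with denominator
#' \eqn{c_1 + c_2 \prod a + c_3 \prod b}, data gathered in the saturation
#' region (large substrate pools) carry little information about `c1` and
#' `c3`, and data in the linear region (small substrate pools) little about
#' `c2`. This report computes, per experiment, each term's share of the
#' denominator and flags a parameter when its share falls below `threshold`
#' in at least a `fraction` of experiments. Flags are advisory; they
#' annotate but never suppress estimates (bootstrap SEs remain the
#' authoritative uncertainty).
#'
#' @param data Experiment tibble.
#' @param params [kinetic_params()] — typically the fitted values.
#' @param spec A [reaction_spec()].
#' @param threshold Share below which a term counts as dominated
#'   (default 0.05).
#' @param fraction Minimum fraction of experiments that must be dominated
#'   for the parameter to be flagged (default 0.9).
#' @return An object of class `identifiability_report`: tibble
#'   `term_shares` (rows sum to 1), logical `flagged` per parameter, and
#'   the cutoffs used. Supports [autoplot()].
#' @export
#' @examples
#' sp <- reaction_spec(1, 1, keq = 10)
#' d <- tibble::tibble(exp_id = 1:3, a_1 = c(100, 150, 120),
#'                     b_1 = 0.01, v = 1)
#' identifiability_report(d, kinetic_params(1, 1, 1), sp)
identifiability_report <- function(data, params, spec, threshold = 0.05,
                                   fraction = 0.9) {
  mats <- xp_matrices(data, spec)
  pvec <- as_param_vector(params, 3L)
  terms <- cbind(pvec[1],
                 pvec[2] * row_prod(mats$A),
                 pvec[3] * row_prod(mats$B))
  shares <- terms / rowSums(terms)
  colnames(shares) <- c("share_c1", "share_c2", "share_c3")
  dominated_frac <- colMeans(shares < threshold)
  structure(list(
    term_shares = tibble::as_tibble(cbind(
      tibble::tibble(exp_id = seq_len(mats$n)), as.data.frame(shares))),
    flagged = setNames(dominated_frac >= fraction, c("c1", "c2", "c3")),
    dominated_fraction = setNames(dominated_frac, c("c1", "c2", "c3")),
    threshold = threshold, fraction = fraction),
    class = "identifiability_report")
}

#' @export
print.identifiability_report <- function(x, ...) {
  flagged <- names(x$flagged)[x$flagged]
  cat(sprintf(
    "<identifiability_report> share threshold %.2g in >= %.0f%% of experiments\n",
    x$threshold, 100 * x$fraction))
  if (length(flagged)) {
    cat("Flagged (likely poorly identified):", paste(flagged, collapse = ", "), "\n")
  } else {
    cat("No parameter flagged.\n")
  }
  invisible(x)
}

#' @rdname identifiability_report
#' @param object An `identifiability_report`.
#' @param ... Unused.
#' @method autoplot identifiability_report
#' @export
autoplot.identifiability_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$term_shares, -"exp_id",
                            names_to = "term", values_to = "share")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$exp_id), y = .data$share,
                                   fill = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "experiment", y = "denominator share",
                  title = "Per-experiment denominator term shares")
}
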