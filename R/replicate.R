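#' Monte-Carlo replication study of the estimator
#'
#' Generates `replicates` independent synthetic data sets from known true
#' parameters, fits each, and aggregates the estimates against the truth:
#' mean estimate, relative standard error (SD of the replicate estimates
#' divided by the true value) and relative bias
#' (`(mean - true) / true`) per parameter. Replicate `r` is seeded with
#' `seed + r`, so reports are fully reproducible; unconverged replicates
#' are excluded and counted.
#'
#' @param truth True [kinetic_params()].
#' @param spec A [reaction_spec()].
#' @param design A [design_spec()].
#' @param noise A [noise_model()]; also supplies the sigmas assumed known
#'   by the fit.
#' @param replicates Number of simulated data sets.
#' @param options A [fit_options()] for each replicate fit.
#' @param seed Base integer seed.
#' @return A `replication_report`: a tibble with one row per parameter
#'   (`term`, `true`, `mean_est`, `rel_se`, `rel_bias`) carrying attributes
#'   `replicates`, `n_failed`, `seed` and `estimates` (the full replicate
#'   estimate matrix, for audit).
#' @export
#' @examples
#' sp <- reaction_spec(2, 2, keq = 1.7281)
#' th <- kinetic_params(2.5783, 3.7327, 3.5238)
#' run_replication(th, sp, design_spec(12), replicates = 3, seed = 1,
#'                 options = fit_options(n_starts = 1))
run_replication <- function(truth, spec, design = design_spec(),
                            noise = noise_model(), replicates = 100,
                            options = fit_options(n_starts = 1), seed = 1) {
  stopifnot(inherits(spec, "reaction_spec"))
  est <- matrix(NA_real_, replicates, 3,
                dimnames = list(NULL, names(truth)))
  for (r in seq_len(replicates)) {
    d <- simulate_experiments(truth, spec, design, noise, seed = seed + r)
    ft <- tryCatch(fit_kinetics(d, spec, noise, options),
                   error = function(e) NULL)
    if (!is.null(ft) && ft$converged) est[r, ] <- as.numeric(ft$params)
  }
  ok <- stats::complete.cases(est)
  est_ok <- est[ok, , drop = FALSE]
  if (nrow(est_ok) < 2) abort("Fewer than 2 replicates converged.")
  tv <- as.numeric(truth)
  out <- tibble::tibble(
    term = names(truth),
    true = tv,
    mean_est = unname(colMeans(est_ok)),
    rel_se = unname(apply(est_ok, 2, sd)) / tv,
    rel_bias = (unname(colMeans(est_ok)) - tv) / tv)
  structure(out, replicates = replicates, n_failed = sum(!ok), seed = seed,
            estimates = est_ok,
            class = c("replication_report", class(out)))
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf("<replication_report> %d replicates (%d failed), base seed %d\n",
              attr(x, "replicates"), attr(x, "n_failed"), attr(x, "seed")))
  NextMethod()
}

#' Paired wild-type/mutant simulation of enzyme-change recovery
#'
#' Simulates `pairs` independent wild-type and perturbed-condition data
#' sets (the perturbed condition's parameters are the wild-type's times
#' `fold`, i.e. a `1/fold` change in total enzyme), fits both members of
#' each pair, and forms the per-pair total-enzyme ratio from each
#' parameter. The reported ratio uses the parameter with the smallest
#' Monte-Carlo relative SE across pairs (the selection rule of
#' [enzyme_change()] with simulation-mode SEs).
#'
#' @param truth_wt Wild-type [kinetic_params()].
#' @param fold True parameter fold-change (mutant c = `fold` times
#'   wild-type c; the true enzyme ratio equals `fold`).
#' @param spec A [reaction_spec()].
#' @param design,noise,options Passed to the simulation and fits.
#' @param pairs Number of wild-type/mutant dataset pairs.
#' @param seed Base seed; pair `r` uses seeds `seed + r` (wt) and
#'   `seed + 100000 + r` (mt).
#' @return A list: `ratios` (tibble of per-pair per-parameter ratios),
#'   `summary` (per-parameter mean ratio, rel SE, rel bias vs `fold`),
#'   `selected_index` and `mean_selected_ratio`.
#' @export
replicate_enzyme_change <- function(truth_wt, fold = 10, spec,
                                    design = design_spec(),
                                    noise = noise_model(),
                                    options = fit_options(n_starts = 1),
                                    pairs = 100, seed = 1) {
  tw <- as.numeric(truth_wt)
  truth_mt <- kinetic_params(tw[1] * fold, tw[2] * fold, tw[3] * fold)
  ratios <- matrix(NA_real_, pairs, 3, dimnames = list(NULL, c("c1", "c2", "c3")))
  for (r in seq_len(pairs)) {
    d_wt <- simulate_experiments(truth_wt, spec, design, noise, seed = seed + r)
    d_mt <- simulate_experiments(truth_mt, spec, design, noise,
                                 seed = seed + 100000 + r)
    f_wt <- tryCatch(fit_kinetics(d_wt, spec, noise, options), error = function(e) NULL)
    f_mt <- tryCatch(fit_kinetics(d_mt, spec, noise, options), error = function(e) NULL)
    if (!is.null(f_wt) && !is.null(f_mt) && f_wt$converged && f_mt$converged) {
      ratios[r, ] <- as.numeric(f_mt$params) / as.numeric(f_wt$params)
    }
  }
  ok <- stats::complete.cases(ratios)
  ratios_ok <- ratios[ok, , drop = FALSE]
  if (nrow(ratios_ok) < 2) abort("Fewer than 2 pairs converged.")
  summ <- tibble::tibble(
    term = colnames(ratios_ok),
    true_ratio = fold,
    mean_ratio = colMeans(ratios_ok),
    rel_se = apply(ratios_ok, 2, sd) / fold,
    rel_bias = (colMeans(ratios_ok) - fold) / fold)
  sel <- which.min(summ$rel_se)
  list(ratios = tibble::as_tibble(ratios_ok), summary = summ,
       selected_index = sel,
       mean_selected_ratio = summ$mean_ratio[[sel]],
       n_failed = sum(!ok))
}
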