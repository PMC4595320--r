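#' Read and write steady-state experiment tables
#'
#' Experiments are stored as plain CSV with header
#' `exp_id,a_1..a_m,b_1..b_p,v` (comma-separated, decimal point, UTF-8).
#' The mechanism dimensions `m` and `p` are inferred from the header;
#' a file without `b_*` columns is read as irreversible two-parameter data.
#' Reading validates that every concentration is positive and every cell
#' numeric, naming the offending rows otherwise.
#'
#' @param path File path.
#' @param data Experiment tibble to write.
#' @return `read_experiments()` returns the validated tibble;
#'   `write_experiments()` returns `data` invisibly.
#' @export
read_experiments <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  nm <- names(raw)
  need <- c("exp_id", "v")
  if (!all(need %in% nm)) {
    abort(sprintf("Missing required column(s): %s.",
                  paste(setdiff(need, nm), collapse = ", ")))
  }
  if (!any(grepl("^a_[0-9]+$", nm))) abort("Missing substrate columns `a_1`, ...")
  num_cols <- setdiff(nm, "exp_id")
  out <- raw
  for (cl in num_cols) {
    x <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(x) & !is.na(raw[[cl]]))
    if (length(bad)) {
      abort(sprintf("Non-numeric value in column `%s`, row(s): %s.",
                    cl, paste(head(bad, 5), collapse = ", ")))
    }
    out[[cl]] <- x
  }
  out$exp_id <- utils::type.convert(raw$exp_id, as.is = TRUE)
  conc_cols <- grep("^[ab]_[0-9]+$", nm, value = TRUE)
  for (cl in conc_cols) {
    bad <- which(!is.finite(out[[cl]]) | out[[cl]] <= 0)
    if (length(bad)) {
      abort(sprintf("Non-positive concentration in column `%s`, row(s): %s.",
                    cl, paste(head(bad, 5), collapse = ", ")))
    }
  }
  xp_matrices(out)  # consistency check (ordering, finiteness)
  out
}

#' @rdname read_experiments
#' @export
write_experiments <- function(data, path) {
  xp_matrices(data)
  readr::write_csv(data, path)
  invisible(data)
}

#' Serialise and restore a run configuration
#'
#' A run configuration bundles everything needed to reproduce a simulation
#' or fit: the reaction specification, noise model, fit options, design,
#' the true parameters (simulation mode) and the base seed. The JSON
#' round trip `write_run_config()` then `read_run_config()` restores an
#' identical object.
#'
#' @param spec A [reaction_spec()].
#' @param noise A [noise_model()].
#' @param options A [fit_options()].
#' @param design A [design_spec()] (simulation mode).
#' @param truth A [kinetic_params()] (simulation mode).
#' @param seed Base integer seed recorded in every derived output.
#' @param config A `run_config` object.
#' @param path JSON file path.
#' @return A `run_config` list; `read_run_config()` restores classes.
#' @export
run_config <- function(spec, noise = noise_model(), options = fit_options(),
                       design = design_spec(), truth = NULL, seed = 1) {
  stopifnot(inherits(spec, "reaction_spec"))
  structure(list(spec = spec, noise = noise, options = options,
                 design = design, truth = truth, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  payload <- list(
    spec = unclass(config$spec),
    noise = unclass(config$noise),
    options = unclass(config$options),
    design = list(
      n_experiments = config$design$n_experiments,
      regimes = config$design$regimes,
      weights = as.numeric(config$design$weights),
      split_range = config$design$split_range,
      sampling = config$design$sampling,
      forward_only = config$design$forward_only),
    truth = if (!is.null(config$truth)) as.numeric(config$truth),
    seed = config$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(config)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(
    spec = reaction_spec(x$spec$m, x$spec$p, x$spec$keq),
    noise = noise_model(x$noise$sigma_a, x$noise$sigma_b, x$noise$sigma_v),
    options = fit_options(x$options$n_starts, x$options$max_iterations,
                          x$options$gradient_tolerance,
                          x$options$parameter_floor,
                          x$options$seed),
    design = design_spec(
      x$design$n_experiments,
      regimes = lapply(x$design$regimes, function(r)
        list(substrate = as.numeric(r$substrate),
             ratio = as.numeric(r$ratio))),
      weights = as.numeric(x$design$weights),
      split_range = as.numeric(x$design$split_range),
      sampling = x$design$sampling,
      forward_only = isTRUE(x$design$forward_only)),
    truth = if (!is.null(x$truth)) kinetic_params(x$truth[1], x$truth[2], x$truth[3]),
    seed = x$seed)
}

#' Serialise a fit (with optional companions) to JSON
#'
#' @param fit A [fit_kinetics()] result.
#' @param path JSON file path.
#' @param bootstrap Optional [bootstrap_fit()] result to embed.
#' @param identifiability Optional [identifiability_report()] to embed.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path, bootstrap = NULL, identifiability = NULL) {
  stopifnot(inherits(fit, "kinetic_fit"))
  payload <- list(
    estimates = as.list(setNames(as.numeric(fit$params), names(fit$params))),
    objective = fit$objective,
    converged = fit$converged,
    n_function_evals = fit$n_function_evals,
    start_used = fit$start_used,
    options = unclass(fit$options),
    noise = unclass(fit$noise))
  if (!is.null(bootstrap)) {
    payload$bootstrap <- list(
      se_b = as.numeric(bootstrap$se_b),
      bias = as.numeric(bootstrap$bias),
      rel_se = as.numeric(bootstrap$rel_se),
      rel_bias = as.numeric(bootstrap$rel_bias),
      n_samples = bootstrap$n_samples,
      n_failed = bootstrap$n_failed,
      reliable = bootstrap$reliable,
      replicate_estimates = as.data.frame(bootstrap$replicate_estimates))
  }
  if (!is.null(identifiability)) {
    payload$identifiability <- list(
      flagged = as.list(identifiability$flagged),
      dominated_fraction = as.list(identifiability$dominated_fraction),
      threshold = identifiability$threshold,
      fraction = identifiability$fraction)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
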