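#' Run the full cross-sectional replication study on synthetic data
#'
#' Convenience pipeline chaining the package's stages: generate a synthetic
#' longitudinal population, elicit trait-specific prior means from the
#' pooled observations, fit the longitudinal reference model, run the
#' cross-sectional subsampling experiment, and compare the replicate fits to
#' the longitudinal reference.
#'
#' @param config a \code{\link{population_config}} describing the synthetic
#'   population (its seed drives the data generation).
#' @param sizes subsample sizes for \code{\link{run_experiment}}.
#' @param reps replicates per size.
#' @param master_seed seed for the resampling experiment (replicate seeds
#'   are derived from it) and for prior elicitation.
#' @param reference_mode \code{"map"} (fast, deterministic) or
#'   \code{"mcmc"} for the longitudinal reference fit.
#' @param reference_control \code{\link{mcmc_control}} for a MCMC reference.
#' @param fit_ctrl \code{\link{fit_control}} for the per-replicate
#'   cross-sectional fits.
#' @param ga \code{\link{ga_control}} for prior elicitation.
#' @param age_grid shared comparison grid (default 5-20 y by 0.25).
#' @return list of class \code{study_result}: \code{data}, \code{prior},
#'   \code{reference} (longitudinal \code{posterior_samples}),
#'   \code{experiment}, \code{report} (a \code{comparison_report}).
#' @export
run_study <- function(config = population_config(),
                      sizes = c(5, 10, 20, 50, 100, 200, 300, 500, "full"),
                      reps = 200,
                      master_seed = 1L,
                      reference_mode = c("map", "mcmc"),
                      reference_control = mcmc_control(),
                      fit_ctrl = fit_control(mode = "map"),
                      ga = ga_control(seed = master_seed),
                      age_grid = seq(5, 20, by = 0.25)) {
  reference_mode <- match.arg(reference_mode)
  data <- generate_population(config)
  prior <- elicit_prior_means(data, ga)
  reference <- if (reference_mode == "mcmc")
    fit_longitudinal(data, prior, reference_control)
  else fit_longitudinal(data, prior, mode = "map")
  experiment <- run_experiment(data, prior, sizes = sizes, reps = reps,
                               control = fit_ctrl,
                               master_seed = master_seed,
                               age_grid = age_grid,
                               keep_draws = FALSE)
  report <- compare_to_longitudinal(experiment, reference)
  structure(list(data = data, prior = prior, reference = reference,
                 experiment = experiment, report = report),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  print(x$data)
  print(x$report)
  invisible(x)
}
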