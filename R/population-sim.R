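#' Configuration for the synthetic longitudinal population
#'
#' Defines the data-generating process used in place of PHI-restricted
#' growth-study data: a population double-logistic growth curve, an
#' individual-level random intercept (between-individual size variation),
#' and Gaussian residual measurement error, observed on a radiograph-style
#' visit schedule (enrollment, then annual visits with per-visit retention).
#'
#' @param params \code{\link{growth_params}} truth for the population curve.
#'   Defaults describe a mid-sized craniofacial distance (adult size
#'   ~101 mm, ~87% of adult size reached by age 4, adolescent peak growth
#'   velocity ~1.8 mm/y at ~11.5 y).
#' @param sigma residual measurement-error SD (mm); default 0.87, the median
#'   measurement error for craniofacial linear traits estimated by
#'   multilevel longitudinal modeling.
#' @param sigma_id SD of the individual-level size intercept (mm).
#' @param n_individuals number of individuals (default 959).
#' @param age_range observable age range in years, \code{c(min, max)}.
#' @param retention probability a scheduled annual follow-up visit occurs;
#'   calibrated so the median visit count is 9 (range capped at 2-22).
#' @param min_visits,max_visits bounds on per-individual visit counts.
#' @param missingness probability each observation is independently dropped
#'   after scheduling (default 0). Individuals left with fewer than
#'   \code{min_visits} observations are excluded, mirroring the inclusion
#'   rule of at least two radiographs.
#' @param sex sex label recorded on the generated observations.
#' @param trait trait name recorded on the generated observations.
#' @param seed integer seed making the generated dataset reproducible.
#' @return An object of class \code{population_config}.
#' @export
population_config <- function(params = growth_params(f = 101, a1 = 88,
                                                     b1 = 1.6, c1 = 1,
                                                     b2 = 0.55, c2 = 11.5),
                              sigma = 0.87,
                              sigma_id = 3,
                              n_individuals = 959,
                              age_range = c(4, 22),
                              retention = 0.915,
                              min_visits = 2,
                              max_visits = 22,
                              missingness = 0,
                              sex = "F",
                              trait = "synthetic_trait",
                              seed = 1L) {
  params <- as_growth_params(params)
  if (sigma < 0 || sigma_id < 0) stop("sigma and sigma_id must be >= 0")
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (length(age_range) != 2 || age_range[1] >= age_range[2])
    stop("age_range must be c(min, max) with min < max")
  if (retention < 0 || retention > 1) stop("retention must be in [0, 1]")
  if (min_visits < 2) stop("min_visits must be >= 2")
  if (max_visits < min_visits) stop("max_visits must be >= min_visits")
  if (missingness < 0 || missingness >= 1)
    stop("missingness must be in [0, 1)")
  structure(list(params = params, sigma = sigma, sigma_id = sigma_id,
                 n_individuals = as.integer(n_individuals),
                 age_range = age_range, retention = retention,
                 min_visits = as.integer(min_visits),
                 max_visits = as.integer(max_visits),
                 missingness = missingness, sex = sex, trait = trait,
                 seed = as.integer(seed)),
            class = "population_config")
}

#' @export
print.population_config <- function(x, ...) {
  cat(sprintf("Synthetic population config: %d individuals, ages %.1f-%.1f y,\n",
              x$n_individuals, x$age_range[1], x$age_range[2]))
  cat(sprintf("  sigma = %.3f mm, sigma_id = %.3f mm, retention = %.2f, missingness = %.2f, seed = %d\n",
              x$sigma, x$sigma_id, x$retention, x$missingness, x$seed))
  print(x$params)
  invisible(x)
}

# One visit schedule drawn under the active RNG: enrollment uniform in the
# lower third of the age range, a guaranteed second visit one year later
# (every retained individual has >= 2 radiographs), then further annual
# visits each retained with probability `retention`, stopping at the age
# maximum or the visit cap.
draw_schedule <- function(config) {
  lo <- config$age_range[1]
  hi <- config$age_range[2]
  enroll <- stats::runif(1, lo, lo + (hi - lo) / 3)
  ages <- c(enroll, enroll + 1)
  while (length(ages) < config$max_visits &&
         ages[length(ages)] + 1 <= hi &&
         stats::runif(1) < config$retention) {
    ages <- c(ages, ages[length(ages)] + 1)
  }
  ages
}

#' Draw per-individual visit schedules
#'
#' Samples radiograph visit ages for each individual: enrollment age uniform
#' in the lower third of the age range, then annual visits with the
#' configured retention probability until dropout, the age maximum, or the
#' visit cap. Every individual gets at least two visits. With default
#' settings the visit-count distribution has median 9 and range 2-22.
#'
#' @param config a \code{\link{population_config}}.
#' @param n number of individuals (defaults to the config's count).
#' @return list of length \code{n}; each element a strictly increasing
#'   numeric vector of visit ages (years).
#' @export
sample_visit_schedule <- function(config, n = config$n_individuals) {
  stopifnot(inherits(config, "population_config"))
  if (config$max_visits < 2)
    stop("visit model cannot produce the required minimum of 2 visits")
  old <- local_seed(config$seed)
  on.exit(restore_seed(old), add = TRUE)
  lapply(seq_len(n), function(i) draw_schedule(config))
}

#' Generate a synthetic longitudinal dataset
#'
#' Runs the growth model forward: for each individual \eqn{j}, draws a size
#' intercept \eqn{a_{ID,j} \sim N(0, \sigma_{ID})}; each observed value at a
#' visit age is the population double-logistic curve plus the intercept plus
#' measurement noise \eqn{N(0, \sigma)}. Fully reproducible from the
#' config's seed.
#'
#' @param config a \code{\link{population_config}}.
#' @return a \code{longitudinal_dataset}: data.frame with columns
#'   \code{individual_id}, \code{sex}, \code{age}, \code{trait},
#'   \code{value}, carrying the generating config as attribute
#'   \code{"truth"}.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  old <- local_seed(config$seed)
  on.exit(restore_seed(old), add = TRUE)

  schedules <- lapply(seq_len(config$n_individuals),
                      function(i) draw_schedule(config))
  intercepts <- stats::rnorm(config$n_individuals, 0, config$sigma_id)
  obs <- lapply(seq_len(config$n_individuals), function(j) {
    ages <- schedules[[j]]
    mu <- double_logistic(ages, config$params) + intercepts[j]
    data.frame(individual_id = sprintf("ID%04d", j),
               sex = config$sex,
               age = ages,
               trait = config$trait,
               value = mu + stats::rnorm(length(ages), 0, config$sigma),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, obs)
  if (config$missingness > 0) {
    keep <- stats::runif(nrow(df)) >= config$missingness
    df <- df[keep, , drop = FALSE]
    counts <- table(df$individual_id)
    ok <- names(counts)[counts >= config$min_visits]
    df <- df[df$individual_id %in% ok, , drop = FALSE]
    rownames(df) <- NULL
  }
  as_longitudinal_dataset(df, truth = config)
}

#' Construct / validate a longitudinal dataset
#'
#' @param df data.frame with columns \code{individual_id}, \code{sex},
#'   \code{age}, \code{trait}, \code{value}. Every individual must have at
#'   least two observations with strictly increasing ages.
#' @param truth optional \code{\link{population_config}} provenance when the
#'   data are synthetic.
#' @return the validated data.frame with class \code{longitudinal_dataset}.
#' @export
as_longitudinal_dataset <- function(df, truth = NULL) {
  required <- c("individual_id", "sex", "age", "trait", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (!is.numeric(df$age) || !is.numeric(df$value))
    stop("age and value must be numeric")
  if (any(!is.finite(df$age)) || any(!is.finite(df$value)))
    stop("age and value must be finite")
  counts <- table(df$individual_id)
  if (any(counts < 2))
    stop("every individual must have at least 2 observations; offending: ",
         paste(utils::head(names(counts)[counts < 2], 5), collapse = ", "))
  ord <- order(df$individual_id, df$age)
  df <- df[ord, , drop = FALSE]
  same <- df$individual_id[-1] == df$individual_id[-nrow(df)]
  if (any(same & diff(df$age) <= 0))
    stop("ages must be strictly increasing within an individual")
  rownames(df) <- NULL
  structure(df, truth = truth,
            class = c("longitudinal_dataset", "data.frame"))
}

#' @export
print.longitudinal_dataset <- function(x, ...) {
  counts <- table(x$individual_id)
  cat(sprintf("Longitudinal dataset: %d observations of %d individuals (visits: median %s, range %d-%d)\n",
              nrow(x), length(counts), stats::median(as.numeric(counts)),
              min(counts), max(counts)))
  cat(sprintf("  traits: %s | sexes: %s | ages %.2f-%.2f y\n",
              paste(unique(x$trait), collapse = ", "),
              paste(unique(x$sex), collapse = ", "),
              min(x$age), max(x$age)))
  if (!is.null(attr(x, "truth"))) cat("  provenance: synthetic (truth config attached)\n")
  invisible(x)
}
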