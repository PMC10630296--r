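#' Draw a cross-sectional subset from a longitudinal dataset
#'
#' Samples \code{n} individuals without replacement, then one observation
#' uniformly at random from each sampled individual's series — mimicking a
#' cross-sectional study. No restriction is placed on age or series length,
#' so an individual contributes one point regardless of how many visits they
#' have.
#'
#' @param data a \code{longitudinal_dataset}.
#' @param n number of individuals to sample (\code{"full"} or \code{NULL}
#'   for all of them).
#' @param seed integer RNG seed.
#' @return a \code{cross_section}: data.frame with one row per sampled
#'   individual and attributes \code{n_target} and \code{seed}.
#' @export
draw_cross_section <- function(data, n = NULL, seed = 1L) {
  ids <- unique(data$individual_id)
  if (is.null(n) || identical(n, "full")) n <- length(ids)
  n <- as.integer(n)
  if (n > length(ids))
    stop("requested ", n, " individuals but only ", length(ids),
         " are available")
  if (n < 1) stop("n must be >= 1")
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  chosen <- sample(ids, n)
  rows <- vapply(chosen, function(i) {
    idx <- which(data$individual_id == i)
    if (length(idx) == 1) idx else sample(idx, 1)
  }, integer(1))
  out <- as.data.frame(data)[rows, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_target = n, seed = as.integer(seed),
            class = c("cross_section", "data.frame"))
}

#' Run the cross-sectional subsampling experiment
#'
#' For each subsample size and replicate, draws a cross-section (with a
#' replicate-specific seed derived deterministically from the master seed)
#' and fits the single-level growth model. Collects posterior medians of all
#' parameters, the predicted median curve on a shared age grid, growth
#' milestones, and fit diagnostics per replicate. Failed fits are recorded
#' with their reason, never dropped silently.
#'
#' @param data a \code{longitudinal_dataset}.
#' @param prior a \code{\link{prior_spec}}.
#' @param sizes integer vector of subsample sizes; the string \code{"full"}
#'   means all individuals. Default matches the published design
#'   \code{c(5, 10, 20, 50, 100, 200, 300, 500, "full")}.
#' @param reps replicates per size (default 200).
#' @param control a \code{\link{fit_control}}; map mode is the desk-scale
#'   default.
#' @param master_seed seed from which all replicate seeds are derived.
#' @param age_grid shared grid for the stored median curves.
#' @param milestone_window age window for \code{\link{find_milestones}}.
#' @param keep_draws keep each replicate's pooled posterior draws (needed
#'   for pooled predictive bands; map mode stores the single point
#'   estimate).
#' @return object of class \code{experiment_result}: \code{records}
#'   (data.frame, one row per size x replicate), \code{curves} (matrix, one
#'   row per record, median curve on \code{age_grid}), \code{draws} (list of
#'   per-record draw matrices if kept), \code{age_grid}, \code{design}.
#' @export
run_experiment <- function(data, prior,
                           sizes = c(5, 10, 20, 50, 100, 200, 300, 500,
                                     "full"),
                           reps = 200,
                           control = fit_control(mode = "map"),
                           master_seed = 1L,
                           age_grid = seq(5, 20, by = 0.25),
                           milestone_window = range(age_grid),
                           keep_draws = TRUE) {
  if (!length(sizes)) stop("sizes must be non-empty")
  if (reps < 1) stop("reps must be >= 1")
  n_full <- length(unique(data$individual_id))
  size_n <- vapply(sizes, function(s)
    if (identical(s, "full")) n_full else as.integer(s), integer(1))
  size_label <- vapply(sizes, as.character, character(1))

  records <- list()
  curves <- list()
  draws <- list()
  k <- 0L
  for (si in seq_along(sizes)) {
    for (r in seq_len(reps)) {
      k <- k + 1L
      seed <- derive_seed(master_seed, size_n[si], r)
      cs <- draw_cross_section(data, size_n[si], seed = seed)
      fit <- try(fit_cross_sectional(cs, prior, control), silent = TRUE)
      if (inherits(fit, "try-error")) {
        records[[k]] <- data.frame(
          size = size_n[si], size_label = size_label[si], replicate = r,
          seed = seed, ok = FALSE,
          reason = conditionMessage(attr(fit, "condition")),
          f = NA, a1 = NA, b1 = NA, c1 = NA, b2 = NA, c2 = NA, sigma = NA,
          pgv = NA, apgv = NA, converged = NA, caution = NA,
          stringsAsFactors = FALSE)
        curves[[k]] <- rep(NA_real_, length(age_grid))
        draws[[k]] <- NULL
        next
      }
      med <- posterior_median(fit)
      gp <- median_growth_params(fit)
      ms <- find_milestones(gp, age_window = milestone_window)
      records[[k]] <- data.frame(
        size = size_n[si], size_label = size_label[si], replicate = r,
        seed = seed, ok = TRUE, reason = "",
        f = med[["f"]], a1 = med[["a1"]], b1 = med[["b1"]],
        c1 = med[["c1"]], b2 = med[["b2"]], c2 = med[["c2"]],
        sigma = med[["sigma"]],
        pgv = ms$pgv, apgv = ms$apgv,
        converged = isTRUE(fit$converged), caution = isTRUE(fit$caution),
        stringsAsFactors = FALSE)
      curves[[k]] <- double_logistic(age_grid, gp)
      draws[[k]] <- if (keep_draws)
        posterior_draws(fit, c(curve_param_names, "sigma")) else NULL
    }
  }
  records <- do.call(rbind, records)
  curves <- do.call(rbind, curves)
  structure(list(records = records, curves = curves, draws = draws,
                 age_grid = age_grid,
                 design = list(sizes = size_label, size_n = size_n,
                               reps = reps, master_seed = master_seed,
                               mode = control$mode,
                               milestone_window = milestone_window)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Cross-sectional resampling experiment: sizes {%s} x %d replicates (%s mode)\n",
              paste(x$design$sizes, collapse = ", "), x$design$reps,
              x$design$mode))
  cat(sprintf("  %d/%d fits succeeded; age grid %.2f-%.2f y (%d points)\n",
              sum(x$records$ok), nrow(x$records),
              min(x$age_grid), max(x$age_grid), length(x$age_grid)))
  invisible(x)
}

#' Aggregate replicate fits at one subsample size
#'
#' Summarizes the replicates of one subsample size three ways: (i) the
#' distribution of per-replicate posterior medians for every parameter,
#' (ii) the "median cross-sectional model" — the parameter-wise median
#' across replicates — and, because the construction is ambiguous, also the
#' pointwise median of the replicate median curves, and (iii) the pooled
#' posterior draws concatenated across replicates.
#'
#' @param result an \code{experiment_result}.
#' @param size subsample size to aggregate (integer, or \code{"full"}).
#' @return list of class \code{replicate_aggregate}: \code{medians}
#'   (data.frame of per-replicate medians), \code{median_params}
#'   (parameter-wise median \code{\link{growth_params}} plus sigma),
#'   \code{median_curve} (curve of \code{median_params} on the grid),
#'   \code{pointwise_median_curve}, \code{pooled_draws}, \code{age_grid},
#'   \code{n_replicates}.
#' @export
aggregate_replicates <- function(result, size) {
  stopifnot(inherits(result, "experiment_result"))
  rec <- result$records
  sel <- if (identical(size, "full")) rec$size_label == "full"
         else rec$size == as.integer(size) & rec$size_label != "full"
  if (!any(sel)) sel <- rec$size == as.integer(size)
  sel_ok <- sel & rec$ok
  if (!any(sel_ok))
    stop("no successful replicates at size ", size)
  pars <- c(curve_param_names, "sigma", "pgv", "apgv")
  medians <- rec[sel_ok, c("replicate", pars)]
  pw <- vapply(c(curve_param_names, "sigma"),
               function(p) stats::median(medians[[p]]), numeric(1))
  median_params <- suppressWarnings(
    as_growth_params(as.list(pw[curve_param_names])))
  idx <- which(sel_ok)
  pooled <- do.call(rbind, result$draws[idx])
  curves <- result$curves[idx, , drop = FALSE]
  structure(list(
    medians = medians,
    median_params = median_params,
    median_sigma = pw[["sigma"]],
    median_curve = double_logistic(result$age_grid, median_params),
    pointwise_median_curve = apply(curves, 2, stats::median),
    pooled_draws = pooled,
    age_grid = result$age_grid,
    n_replicates = sum(sel_ok)
  ), class = "replicate_aggregate")
}
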