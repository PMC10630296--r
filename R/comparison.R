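#' Mean absolute difference between predicted growth curves
#'
#' Pointwise mean over replicates of \eqn{|pred_a - pred_b|} on a shared age
#' grid, plus its scalar grid mean. \code{pred_a} may be a matrix of
#' replicate curves (rows) or a single curve; \code{pred_b} is the reference
#' curve.
#'
#' @param pred_a numeric vector, or matrix with one replicate curve per row,
#'   evaluated on \code{age_grid}.
#' @param pred_b reference curve on the identical grid.
#' @param age_grid the shared grid (used only for a length check and the
#'   returned curve's names).
#' @return list of class \code{mad_curve}: \code{curve} (per-age MAD),
#'   \code{scalar} (grid mean), \code{age_grid}.
#' @export
mean_abs_difference <- function(pred_a, pred_b, age_grid) {
  if (is.null(dim(pred_a))) pred_a <- matrix(pred_a, nrow = 1)
  if (ncol(pred_a) != length(age_grid) || length(pred_b) != length(age_grid))
    stop("curves must be evaluated on the identical age grid")
  if (any(!is.finite(pred_a)) || any(!is.finite(pred_b)))
    stop("curves contain non-finite values")
  diff <- abs(sweep(pred_a, 2, pred_b))
  curve <- colMeans(diff)
  structure(list(curve = curve, scalar = mean(curve), age_grid = age_grid),
            class = "mad_curve")
}

#' @export
print.mad_curve <- function(x, ...) {
  cat(sprintf("Mean absolute difference: %.4f mm averaged over %d ages (max %.4f at %.2f y)\n",
              x$scalar, length(x$age_grid), max(x$curve),
              x$age_grid[which.max(x$curve)]))
  invisible(x)
}

#' Milestone errors of replicate fits against a reference
#'
#' Mean absolute error and signed bias of peak growth velocity (PGV, mm/y)
#' and age at peak growth velocity (aPGV, y) per subsample size, relative to
#' reference milestones (typically from the longitudinal model).
#'
#' @param result an \code{experiment_result} with milestones per replicate.
#' @param reference a \code{milestones} object.
#' @return data.frame, one row per size: \code{size_label}, \code{size},
#'   \code{n_replicates}, \code{pgv_mae}, \code{pgv_bias}, \code{apgv_mae},
#'   \code{apgv_bias}.
#' @export
milestone_errors <- function(result, reference) {
  stopifnot(inherits(result, "experiment_result"),
            inherits(reference, "milestones"))
  rec <- result$records[result$records$ok, ]
  if (any(!is.finite(rec$pgv)) || any(!is.finite(rec$apgv)))
    stop("milestones missing for some replicates")
  groups <- split(rec, rec$size_label)
  out <- do.call(rbind, lapply(groups, function(g) data.frame(
    size_label = g$size_label[1],
    size = g$size[1],
    n_replicates = nrow(g),
    pgv_mae = mean(abs(g$pgv - reference$pgv)),
    pgv_bias = mean(g$pgv - reference$pgv),
    apgv_mae = mean(abs(g$apgv - reference$apgv)),
    apgv_bias = mean(g$apgv - reference$apgv),
    stringsAsFactors = FALSE)))
  out <- out[order(out$size), ]
  rownames(out) <- NULL
  out
}

#' Root-mean-square difference between two growth-velocity curves
#'
#' @param params_a,params_b \code{\link{growth_params}} objects.
#' @param age_grid shared evaluation grid (years).
#' @return RMSD of the velocities (mm/year).
#' @export
rate_rmsd <- function(params_a, params_b, age_grid = seq(5, 20, by = 0.25)) {
  va <- growth_velocity(age_grid, params_a)
  vb <- growth_velocity(age_grid, params_b)
  sqrt(mean((va - vb)^2))
}

#' Compare two sets of posterior predictive percentile bands
#'
#' Max and mean absolute discrepancy between corresponding percentile
#' curves (lower and upper endpoint of each central level, plus the median
#' curve) of two \code{prediction_bands} computed on the same grid and
#' levels.
#'
#' @param bands_a,bands_b \code{prediction_bands} objects.
#' @return data.frame with one row per percentile curve: \code{curve},
#'   \code{max_abs}, \code{mean_abs}.
#' @export
percentile_comparison <- function(bands_a, bands_b) {
  stopifnot(inherits(bands_a, "prediction_bands"),
            inherits(bands_b, "prediction_bands"))
  if (!isTRUE(all.equal(bands_a$age_grid, bands_b$age_grid)))
    stop("bands must share the age grid")
  if (!identical(bands_a$levels, bands_b$levels))
    stop("bands must share the interval levels")
  rows <- list(data.frame(curve = "median",
                          max_abs = max(abs(bands_a$median - bands_b$median)),
                          mean_abs = mean(abs(bands_a$median - bands_b$median)),
                          stringsAsFactors = FALSE))
  for (i in seq_along(bands_a$levels)) {
    dl <- abs(bands_a$lower[i, ] - bands_b$lower[i, ])
    du <- abs(bands_a$upper[i, ] - bands_b$upper[i, ])
    rows[[length(rows) + 1]] <- data.frame(
      curve = sprintf("lower%d", bands_a$levels[i]),
      max_abs = max(dl), mean_abs = mean(dl), stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      curve = sprintf("upper%d", bands_a$levels[i]),
      max_abs = max(du), mean_abs = mean(du), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full comparison of a resampling experiment against a longitudinal
#' reference
#'
#' Builds the per-size agreement report: MAD curves of replicate median
#' curves against the longitudinal median curve (with scalar grid means),
#' PGV/aPGV errors, and the growth-rate RMSD between each size's median
#' cross-sectional model and the reference.
#'
#' @param result an \code{experiment_result}.
#' @param reference_post the longitudinal \code{posterior_samples}.
#' @return object of class \code{comparison_report}: \code{by_size}
#'   (data.frame with scalar MAD, milestone errors, rate RMSD per size),
#'   \code{mad_curves} (one row per size), \code{reference} (milestones and
#'   median curve), \code{age_grid}.
#' @export
compare_to_longitudinal <- function(result, reference_post) {
  stopifnot(inherits(result, "experiment_result"),
            inherits(reference_post, "posterior_samples"))
  grid <- result$age_grid
  ref_params <- median_growth_params(reference_post)
  ref_curve <- double_logistic(grid, ref_params)
  ref_ms <- find_milestones(ref_params,
                            age_window = result$design$milestone_window)
  ms_err <- milestone_errors(result, ref_ms)

  labels <- unique(result$records$size_label)
  rows <- list(); mad_curves <- list()
  for (lab in labels) {
    agg <- aggregate_replicates(result, lab)
    idx <- which(result$records$size_label == lab & result$records$ok)
    mad <- mean_abs_difference(result$curves[idx, , drop = FALSE],
                               ref_curve, grid)
    me <- ms_err[ms_err$size_label == lab, ]
    rows[[lab]] <- data.frame(
      size_label = lab, size = result$records$size[idx[1]],
      n_replicates = agg$n_replicates,
      mad = mad$scalar,
      pgv_mae = me$pgv_mae, pgv_bias = me$pgv_bias,
      apgv_mae = me$apgv_mae, apgv_bias = me$apgv_bias,
      rate_rmsd = rate_rmsd(agg$median_params, ref_params, grid),
      stringsAsFactors = FALSE)
    mad_curves[[lab]] <- mad$curve
  }
  by_size <- do.call(rbind, rows)
  by_size <- by_size[order(by_size$size), ]
  rownames(by_size) <- NULL
  mad_curves <- do.call(rbind, mad_curves)
  structure(list(by_size = by_size, mad_curves = mad_curves,
                 reference = list(params = ref_params, curve = ref_curve,
                                  milestones = ref_ms),
                 age_grid = grid),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Cross-sectional vs longitudinal agreement by subsample size:\n")
  df <- x$by_size
  df[, sapply(df, is.numeric)] <- round(df[, sapply(df, is.numeric)], 4)
  print(df, row.names = FALSE)
  cat(sprintf("Reference milestones: PGV = %.3f mm/y at aPGV = %.3f y\n",
              x$reference$milestones$pgv, x$reference$milestones$apgv))
  invisible(x)
}
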