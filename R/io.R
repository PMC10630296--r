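#' Write a longitudinal dataset to CSV
#'
#' Canonical tabular format: header
#' \code{individual_id,sex,age,trait,value}, ages in decimal years, values
#' in mm.
#'
#' @param data a \code{longitudinal_dataset} (or compatible data.frame).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data)[, c("individual_id", "sex", "age",
                                           "trait", "value")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a longitudinal dataset from CSV
#'
#' Validates the schema and content; individuals with fewer than two
#' observations (after any trait/sex filtering) are excluded with a message,
#' mirroring the inclusion rule of at least two radiographs per individual.
#'
#' @param path CSV file with header
#'   \code{individual_id,sex,age,trait,value}.
#' @param trait optional trait name filter.
#' @param sex optional sex filter.
#' @return a \code{longitudinal_dataset}.
#' @export
read_dataset <- function(path, trait = NULL, sex = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("individual_id", "sex", "age", "trait", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  for (col in c("age", "value")) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & nzchar(df[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " at line ", bad[1] + 1, ": '",
           df[[col]][bad[1]], "'")
    bad <- which(!is.finite(x))
    if (length(bad))
      stop("missing/non-finite ", col, " at line ", bad[1] + 1)
    df[[col]] <- x
  }
  if (!is.null(trait)) df <- df[df$trait %in% trait, , drop = FALSE]
  if (!is.null(sex)) df <- df[df$sex %in% sex, , drop = FALSE]
  if (!nrow(df)) stop("no observations left after filtering")
  key <- paste(df$individual_id, df$age, df$trait, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop("duplicate (individual_id, age, trait) row at line ", d + 1)
  }
  counts <- table(df$individual_id)
  drop_ids <- names(counts)[counts < 2]
  if (length(drop_ids)) {
    message("excluding ", length(drop_ids),
            " individual(s) with fewer than 2 observations")
    df <- df[!df$individual_id %in% drop_ids, , drop = FALSE]
  }
  if (!nrow(df)) stop("no individuals with >= 2 observations")
  as_longitudinal_dataset(df)
}

#' Serialize / restore a prior specification
#'
#' Prior means are stored in YAML together with the model's fixed SDs and
#' exponential rates (written for transparency; on read they are checked
#' against the fixed model values).
#'
#' @param prior a \code{\link{prior_spec}}.
#' @param path YAML file path.
#' @return \code{write_prior_spec}: \code{path} invisibly;
#'   \code{read_prior_spec}: a \code{prior_spec}.
#' @export
write_prior_spec <- function(prior, path) {
  stopifnot(inherits(prior, "prior_spec"))
  yaml::write_yaml(list(means = prior$means, sds = prior$sds,
                        exp_rates = prior$exp_rates), path)
  invisible(path)
}

#' @rdname write_prior_spec
#' @export
read_prior_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- yaml::read_yaml(path)
  out <- prior_spec(f = x$means$f, a1 = x$means$a1, b1 = x$means$b1,
                    c1 = x$means$c1, b2 = x$means$b2, c2 = x$means$c2)
  if (!is.null(x$sds) && !isTRUE(all.equal(x$sds[names(out$sds)], out$sds)))
    stop("prior SDs in ", path, " do not match the model's fixed values")
  out
}

#' Serialize / restore a population configuration
#'
#' @param config a \code{\link{population_config}}.
#' @param path YAML file path.
#' @return \code{write_population_config}: \code{path} invisibly;
#'   \code{read_population_config}: a \code{population_config}.
#' @export
write_population_config <- function(config, path) {
  stopifnot(inherits(config, "population_config"))
  x <- unclass(config)
  x$params <- unclass(x$params)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_population_config
#' @export
read_population_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- yaml::read_yaml(path)
  population_config(params = as_growth_params(x$params), sigma = x$sigma,
                    sigma_id = x$sigma_id, n_individuals = x$n_individuals,
                    age_range = as.numeric(x$age_range),
                    retention = x$retention, min_visits = x$min_visits,
                    max_visits = x$max_visits, missingness = x$missingness,
                    sex = x$sex, trait = x$trait, seed = x$seed)
}

#' Write posterior draws to CSV
#'
#' One row per retained draw: \code{chain}, \code{iteration}, then one
#' column per monitored parameter — the interchange layout used for shared
#' posterior releases.
#'
#' @param post a \code{posterior_samples} object.
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @export
write_posterior_csv <- function(post, path) {
  stopifnot(inherits(post, "posterior_samples"))
  d <- post$draws
  n_iter <- dim(d)[1]; n_chain <- dim(d)[2]
  out <- data.frame(chain = rep(seq_len(n_chain), each = n_iter),
                    iteration = rep(seq_len(n_iter), n_chain))
  for (p in dimnames(d)[[3]]) out[[p]] <- as.vector(d[, , p])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export a comparison report
#'
#' Writes the per-size agreement table as CSV and a human-readable markdown
#' summary alongside it.
#'
#' @param report a \code{comparison_report}.
#' @param dir output directory (created if needed).
#' @param stem file name stem (default \code{"comparison"}).
#' @return named character vector of the written paths, invisibly.
#' @export
write_comparison_report <- function(report, dir, stem = "comparison") {
  stopifnot(inherits(report, "comparison_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, "_by_size.csv"))
  utils::write.csv(report$by_size, csv, row.names = FALSE)
  mad_csv <- file.path(dir, paste0(stem, "_mad_curves.csv"))
  mc <- data.frame(size_label = rownames(report$mad_curves),
                   report$mad_curves, check.names = FALSE)
  names(mc)[-1] <- sprintf("age_%.2f", report$age_grid)
  utils::write.csv(mc, mad_csv, row.names = FALSE)
  md <- file.path(dir, paste0(stem, ".md"))
  lines <- c("# Cross-sectional vs longitudinal agreement", "",
             sprintf("Reference milestones: PGV = %.3f mm/y at aPGV = %.3f y; asymptote f = %.2f mm.",
                     report$reference$milestones$pgv,
                     report$reference$milestones$apgv,
                     report$reference$milestones$asymptote), "",
             "| size | replicates | MAD (mm) | PGV MAE (mm/y) | aPGV MAE (y) | rate RMSD (mm/y) |",
             "|------|-----------:|---------:|---------------:|-------------:|-----------------:|",
             sprintf("| %s | %d | %.4f | %.4f | %.4f | %.4f |",
                     report$by_size$size_label, report$by_size$n_replicates,
                     report$by_size$mad, report$by_size$pgv_mae,
                     report$by_size$apgv_mae, report$by_size$rate_rmsd))
  writeLines(lines, md)
  invisible(c(by_size = csv, mad_curves = mad_csv, summary = md))
}
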