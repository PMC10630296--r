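#' Prior specification for the Bayesian growth model
#'
#' Trait-specific prior means for the six double-logistic parameters,
#' combined with the model's fixed prior scales: Normal SDs of 2 mm for the
#' size parameters (\code{f}, \code{a1}), 0.2 /y for the rates (\code{b1},
#' \code{b2}), 1 y for the timing parameters (\code{c1}, \code{c2}), and
#' Exponential(rate = 0.25) priors for the residual SD \code{sigma} and the
#' individual-intercept SD \code{sigma_id}. The rate priors are truncated at
#' zero so fitted growth curves increase monotonically.
#'
#' The SDs and exponential rates are fixed properties of the model, not free
#' arguments: only the means are trait-specific (usually elicited from
#' pooled data with \code{\link{elicit_prior_means}}).
#'
#' @param f,a1,b1,c1,b2,c2 prior means, in the units of their parameters
#'   (mm, mm, 1/y, y, 1/y, y). \code{b1} and \code{b2} means must be
#'   positive.
#' @return An object of class \code{prior_spec}.
#' @export
prior_spec <- function(f, a1, b1, c1, b2, c2) {
  means <- c(f = f, a1 = a1, b1 = b1, c1 = c1, b2 = b2, c2 = c2)
  if (any(!is.finite(means))) stop("prior means must be finite")
  if (b1 <= 0 || b2 <= 0) stop("prior means for b1 and b2 must be positive")
  structure(list(
    means = as.list(means),
    sds = list(f = 2, a1 = 2, b1 = 0.2, c1 = 1, b2 = 0.2, c2 = 1),
    exp_rates = list(sigma = 0.25, sigma_id = 0.25),
    truncated = c("b1", "b2")
  ), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Growth-model prior specification (Normal means +/- fixed SDs):\n")
  for (p in names(x$means))
    cat(sprintf("  %-3s ~ Normal(%8.3f, %.2f)%s\n", p, x$means[[p]],
                x$sds[[p]], if (p %in% x$truncated) "  [truncated at 0]" else ""))
  cat(sprintf("  sigma ~ Exponential(%.2f); sigma_id ~ Exponential(%.2f)\n",
              x$exp_rates$sigma, x$exp_rates$sigma_id))
  invisible(x)
}

#' Central prior interval for one parameter
#'
#' Closed-form central interval of the Normal prior for a curve parameter,
#' e.g. the 95% interval of a Normal(100 mm, 2 mm) prior for \code{f} is
#' 100 +/- 1.96 x 2, i.e. approximately [96, 104] mm.
#'
#' @param prior a \code{\link{prior_spec}}.
#' @param param one of \code{"f","a1","b1","c1","b2","c2"}.
#' @param level central probability (default 0.95).
#' @return numeric length-2 \code{c(lower, upper)}.
#' @export
prior_central_interval <- function(prior, param, level = 0.95) {
  stopifnot(inherits(prior, "prior_spec"))
  if (!param %in% names(prior$means)) stop("unknown parameter: ", param)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  a <- (1 - level) / 2
  stats::qnorm(c(a, 1 - a), prior$means[[param]], prior$sds[[param]])
}

#' Genetic-algorithm settings for prior elicitation
#'
#' @param pop_size population size per generation.
#' @param generations number of generations.
#' @param mutation_rate per-gene mutation probability.
#' @param mutation_scale mutation SD as a fraction of each gene's bound width.
#' @param elite number of elite candidates copied unchanged.
#' @param polish run an L-BFGS-B refinement from the GA optimum (recommended).
#' @param seed integer RNG seed for the search.
#' @param bounds optional 2 x 6 matrix (rows lower/upper, columns
#'   f, a1, b1, c1, b2, dc where \code{dc = c2 - c1 > 0}); by default derived
#'   from the pooled data's value and age ranges.
#' @return list of class \code{ga_control}.
#' @export
ga_control <- function(pop_size = 200, generations = 50,
                       mutation_rate = 0.2, mutation_scale = 0.1,
                       elite = 2, polish = TRUE, seed = 1L, bounds = NULL) {
  stopifnot(pop_size >= 10, generations >= 1)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 mutation_scale = mutation_scale,
                 elite = as.integer(elite), polish = polish,
                 seed = as.integer(seed), bounds = bounds),
            class = "ga_control")
}

# Default search bounds from the pooled data. Genes are
# (f, a1, b1, c1, b2, dc) with c2 = c1 + dc, which encodes the c1 < c2
# identifiability constraint directly; b1, b2 >= 0.01.
default_ga_bounds <- function(age, value) {
  vmax <- max(value); vmin <- max(min(value), 0)
  amin <- min(age); amax <- max(age)
  lower <- c(f = max(vmax * 0.7, vmin), a1 = max(vmin * 0.3, 1e-3),
             b1 = 0.01, c1 = amin - 10, b2 = 0.01, dc = 0.1)
  upper <- c(f = vmax * 1.5, a1 = vmax * 1.2,
             b1 = 5, c1 = amax, b2 = 5, dc = amax - amin + 10)
  rbind(lower = lower, upper = upper)
}

genes_to_params <- function(g) {
  growth_params(f = g[1], a1 = g[2], b1 = g[3], c1 = g[4],
                b2 = g[5], c2 = g[4] + g[6])
}

ga_objective <- function(age, value) {
  function(g) {
    s1 <- stats::plogis(g[3] * (age - g[4]))
    s2 <- stats::plogis(g[5] * (age - g[4] - g[6]))
    pred <- g[2] * s1 + (g[1] - g[2]) * s2
    sum((value - pred)^2)
  }
}

#' Elicit trait-specific prior means from pooled observations
#'
#' Fits the double-logistic curve to pooled (age, value) observations by
#' minimizing the residual sum of squares with a real-coded genetic
#' algorithm (tournament selection, blend crossover, Gaussian mutation,
#' elitism), optionally polished by bounded quasi-Newton refinement. The
#' best-fit parameters become the prior means of a \code{\link{prior_spec}};
#' the prior SDs and exponential rates stay at their fixed model values.
#' Search bounds keep \code{b1, b2 >= 0.01} and \code{c1 < c2} so the two
#' phases stay identified during elicitation.
#'
#' @param data a data.frame with numeric columns \code{age} and \code{value}
#'   (a \code{longitudinal_dataset} works as-is: observations are pooled,
#'   ignoring individual structure).
#' @param control a \code{\link{ga_control}}.
#' @return a \code{\link{prior_spec}} whose means are the fitted parameters,
#'   with the achieved sum of squared residuals in attribute \code{"ss"}.
#' @export
elicit_prior_means <- function(data, control = ga_control()) {
  stopifnot(inherits(control, "ga_control"))
  age <- data$age; value <- data$value
  if (length(age) < 20) stop("need at least 20 pooled observations")
  if (diff(range(age)) < 8)
    stop("pooled observations must span at least 8 years of age")

  bounds <- if (is.null(control$bounds)) default_ga_bounds(age, value)
            else control$bounds
  lower <- bounds[1, ]; upper <- bounds[2, ]
  width <- upper - lower
  obj <- ga_objective(age, value)

  old <- local_seed(control$seed)
  on.exit(restore_seed(old), add = TRUE)

  np <- control$pop_size
  ngene <- length(lower)
  pop <- matrix(stats::runif(np * ngene, rep(lower, each = np),
                             rep(upper, each = np)), nrow = np)
  fit <- apply(pop, 1, obj)

  for (gen in seq_len(control$generations)) {
    ord <- order(fit)
    newpop <- pop[ord[seq_len(control$elite)], , drop = FALSE]
    while (nrow(newpop) < np) {
      # binary tournament selection of two parents
      pick <- function() {
        ij <- sample.int(np, 2)
        if (fit[ij[1]] <= fit[ij[2]]) pop[ij[1], ] else pop[ij[2], ]
      }
      p1 <- pick(); p2 <- pick()
      w <- stats::runif(ngene)
      child <- w * p1 + (1 - w) * p2
      mut <- stats::runif(ngene) < control$mutation_rate
      child[mut] <- child[mut] +
        stats::rnorm(sum(mut), 0, control$mutation_scale * width[mut])
      child <- pmin(pmax(child, lower), upper)
      newpop <- rbind(newpop, child)
    }
    pop <- newpop
    fit <- apply(pop, 1, obj)
  }

  best <- pop[which.min(fit), ]
  if (isTRUE(control$polish)) {
    res <- try(stats::optim(best, obj, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 500)), silent = TRUE)
    if (!inherits(res, "try-error") && res$value <= obj(best)) best <- res$par
  }
  if (!all(is.finite(best)))
    stop("prior elicitation failed: no feasible candidate within bounds")
  gp <- genes_to_params(best)
  out <- prior_spec(f = gp$f, a1 = gp$a1, b1 = gp$b1, c1 = gp$c1,
                    b2 = gp$b2, c2 = gp$c2)
  attr(out, "ss") <- obj(best)
  out
}

#' Prior predictive growth curves
#'
#' Draws parameter sets from the prior distributions (rate parameters
#' truncated at zero by redrawing) and evaluates the growth curve on an age
#' grid, together with the curve at the prior means. Used to check that the
#' priors generate trait sizes on a plausible scale before the data enter
#' the model.
#'
#' @param prior a \code{\link{prior_spec}}.
#' @param n_draws number of prior draws (default 50).
#' @param age_grid ages (years) at which curves are evaluated.
#' @param seed integer RNG seed.
#' @return list of class \code{prior_predictive}: \code{curves}
#'   (\code{n_draws} x \code{length(age_grid)} matrix), \code{mean_curve}
#'   (curve at the prior means), \code{age_grid}, and \code{draws} (the
#'   sampled parameter sets, one row per draw).
#' @export
prior_predictive_curves <- function(prior, n_draws = 50,
                                    age_grid = seq(4, 22, by = 0.25),
                                    seed = 1L) {
  stopifnot(inherits(prior, "prior_spec"))
  if (n_draws < 1) stop("n_draws must be >= 1")
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  rtrunc_norm <- function(n, mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  draws <- data.frame(
    f = stats::rnorm(n_draws, prior$means$f, prior$sds$f),
    a1 = stats::rnorm(n_draws, prior$means$a1, prior$sds$a1),
    b1 = rtrunc_norm(n_draws, prior$means$b1, prior$sds$b1),
    c1 = stats::rnorm(n_draws, prior$means$c1, prior$sds$c1),
    b2 = rtrunc_norm(n_draws, prior$means$b2, prior$sds$b2),
    c2 = stats::rnorm(n_draws, prior$means$c2, prior$sds$c2)
  )
  curves <- t(apply(draws, 1, function(d) {
    d <- as.list(d)
    d$a1 * stats::plogis(d$b1 * (age_grid - d$c1)) +
      (d$f - d$a1) * stats::plogis(d$b2 * (age_grid - d$c2))
  }))
  mean_curve <- double_logistic(age_grid, as_growth_params(prior$means))
  structure(list(curves = curves, mean_curve = mean_curve,
                 age_grid = age_grid, draws = draws),
            class = "prior_predictive")
}
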