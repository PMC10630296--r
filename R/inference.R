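#' MCMC sampler settings
#'
#' @param chains number of parallel chains (default 4).
#' @param iter total iterations per chain including warmup (default 10000).
#' @param warmup warmup iterations discarded per chain (default
#'   \code{iter / 2}); proposal adaptation happens only during warmup.
#' @param thin thinning interval for retained draws.
#' @param seed integer seed controlling chain-specific starting values and
#'   the samplers' RNG streams.
#' @param monitor_intercepts keep the per-individual intercept draws
#'   (longitudinal model). Disable for very large populations to save
#'   memory; the intercept SD \code{sigma_id} is always monitored.
#' @return list of class \code{mcmc_control}.
#' @export
mcmc_control <- function(chains = 4, iter = 10000, warmup = floor(iter / 2),
                         thin = 1, seed = 1L,
                         monitor_intercepts = TRUE) {
  stopifnot(chains >= 1, iter > warmup, warmup >= 0, thin >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup),
                 thin = as.integer(thin), seed = as.integer(seed),
                 monitor_intercepts = isTRUE(monitor_intercepts)),
            class = "mcmc_control")
}

#' Fit settings for the cross-sectional model
#'
#' @param mode \code{"map"} (penalized-likelihood point estimate under the
#'   same priors; fast and deterministic, the workhorse for resampling
#'   designs) or \code{"mcmc"} (full posterior via JAGS).
#' @param mcmc an \code{\link{mcmc_control}} used when \code{mode = "mcmc"}.
#' @return list of class \code{fit_control}.
#' @export
fit_control <- function(mode = c("map", "mcmc"), mcmc = mcmc_control()) {
  mode <- match.arg(mode)
  structure(list(mode = mode, mcmc = mcmc), class = "fit_control")
}

curve_param_names <- c("f", "a1", "b1", "c1", "b2", "c2")

new_posterior_samples <- function(draws, mode, model, n_obs, n_individuals,
                                  warmup = 0L, caution = FALSE,
                                  converged = NA, prior = NULL) {
  structure(list(draws = draws, mode = mode, model = model,
                 n_obs = n_obs, n_individuals = n_individuals,
                 warmup = warmup, caution = caution, converged = converged,
                 prior = prior),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("Posterior samples (%s model, %s mode): %d draws x %d chain(s) x %d parameters\n",
              x$model, x$mode, d[1], d[2], d[3]))
  med <- posterior_median(x)
  show <- intersect(c(curve_param_names, "sigma", "sigma_id"), names(med))
  cat("  medians:", paste(sprintf("%s=%.3f", show, med[show]),
                          collapse = ", "), "\n")
  if (isTRUE(x$caution))
    cat("  NOTE: fitted at the minimum usable sample size; use with caution\n")
  if (identical(x$converged, FALSE))
    cat("  WARNING: fit flagged as non-converged\n")
  invisible(x)
}

#' Posterior medians of all monitored parameters
#'
#' @param post a \code{posterior_samples} object.
#' @return named numeric vector of per-parameter posterior medians (for map
#'   mode, the point estimate itself).
#' @export
posterior_median <- function(post) {
  stopifnot(inherits(post, "posterior_samples"))
  apply(post$draws, 3, stats::median)
}

#' Extract pooled draws of selected parameters
#'
#' @param post a \code{posterior_samples} object.
#' @param pars parameter names (default: all).
#' @return matrix with one row per retained draw (chains concatenated) and
#'   one column per parameter.
#' @export
posterior_draws <- function(post, pars = NULL) {
  stopifnot(inherits(post, "posterior_samples"))
  d <- post$draws
  if (is.null(pars)) pars <- dimnames(d)[[3]]
  miss <- setdiff(pars, dimnames(d)[[3]])
  if (length(miss)) stop("unknown parameters: ", paste(miss, collapse = ", "))
  out <- sapply(pars, function(p) as.vector(d[, , p]))
  matrix(out, ncol = length(pars), dimnames = list(NULL, pars))
}

#' Posterior-median growth parameters
#'
#' @param post a \code{posterior_samples} object.
#' @return a \code{\link{growth_params}} built from the posterior medians of
#'   the six curve parameters.
#' @export
median_growth_params <- function(post) {
  med <- posterior_median(post)
  suppressWarnings(as_growth_params(as.list(med[curve_param_names])))
}

# ---- log posterior densities (authored here; map mode maximizes these) ----

log_prior_curve <- function(theta, prior) {
  lp <- 0
  for (p in curve_param_names)
    lp <- lp + stats::dnorm(theta[[p]], prior$means[[p]], prior$sds[[p]],
                            log = TRUE)
  # truncation normalizers of b1, b2 are constants in the parameters
  if (theta[["b1"]] <= 0 || theta[["b2"]] <= 0) lp <- -Inf
  lp
}

# Cross-sectional model: y_i ~ N(mu_i, sigma), no individual intercept.
cs_log_posterior <- function(theta, sigma, age, value, prior) {
  if (sigma <= 0) return(-Inf)
  gp <- theta
  mu <- gp[["a1"]] * stats::plogis(gp[["b1"]] * (age - gp[["c1"]])) +
    (gp[["f"]] - gp[["a1"]]) * stats::plogis(gp[["b2"]] * (age - gp[["c2"]]))
  sum(stats::dnorm(value, mu, sigma, log = TRUE)) +
    log_prior_curve(theta, prior) +
    stats::dexp(sigma, prior$exp_rates$sigma, log = TRUE)
}

# Longitudinal model with the individual intercepts marginalized: within
# individual j the values are jointly normal with compound-symmetry
# covariance sigma^2 I + sigma_id^2 11'; both the log determinant and the
# quadratic form have closed forms (Woodbury), so the marginal posterior
# costs O(total observations). `id` is an integer factor 1..J, `nj` its
# per-individual counts.
long_log_posterior <- function(theta, sigma, sigma_id, age, value, id, nj,
                               prior) {
  if (sigma <= 0 || sigma_id < 0) return(-Inf)
  gp <- theta
  lp <- log_prior_curve(theta, prior) +
    stats::dexp(sigma, prior$exp_rates$sigma, log = TRUE) +
    stats::dexp(sigma_id, prior$exp_rates$sigma_id, log = TRUE)
  if (!is.finite(lp)) return(-Inf)
  s2 <- sigma^2; t2 <- sigma_id^2
  r <- value -
    (gp[["a1"]] * stats::plogis(gp[["b1"]] * (age - gp[["c1"]])) +
     (gp[["f"]] - gp[["a1"]]) *
       stats::plogis(gp[["b2"]] * (age - gp[["c2"]])))
  sj <- rowsum(r, id)[, 1]
  ssj <- rowsum(r^2, id)[, 1]
  logdet <- sum(nj * log(s2) + log1p(nj * t2 / s2))
  quad <- sum((ssj - t2 * sj^2 / (s2 + nj * t2)) / s2)
  lp - 0.5 * (sum(nj) * log(2 * pi) + logdet + quad)
}

# ---- MCMC engine: adaptive random-walk Metropolis ----
#
# The sampler works on an unconstrained scale eta (rates and SDs
# log-transformed, with the Jacobian added to the target), with a
# multivariate normal proposal whose covariance is adapted to the chain
# history during warmup (Haario-style) and whose global scale is tuned
# toward the 0.234 acceptance rate; adaptation freezes at the end of
# warmup. For the longitudinal model the individual intercepts are
# marginalized analytically in the target, which removes the
# (f, a1, intercept-mean) ridge that defeats one-at-a-time samplers;
# intercept draws are recovered afterwards by exact composition sampling
# from their conditional normal distribution.

amh_chain <- function(log_post, init, n_iter, warmup, init_sds, seed) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  d <- length(init)
  x <- init
  lx <- log_post(x)
  if (!is.finite(lx)) stop("non-finite log posterior at starting values")
  cl <- chol(diag(init_sds^2, d))
  lscale <- log(2.38 / sqrt(d))
  out <- matrix(NA_real_, n_iter, d)
  acc <- 0L; tries <- 0L
  for (i in seq_len(n_iter)) {
    prop <- x + exp(lscale) * drop(stats::rnorm(d) %*% cl)
    lpp <- log_post(prop)
    if (is.finite(lpp) && log(stats::runif(1)) < lpp - lx) {
      x <- prop; lx <- lpp; acc <- acc + 1L
    }
    tries <- tries + 1L
    out[i, ] <- x
    if (i <= warmup && i %% 100 == 0) {
      lscale <- lscale + (acc / tries - 0.234) / sqrt(i / 100)
      acc <- 0L; tries <- 0L
      if (i >= 300) {
        hist <- out[max(1, i - 999):i, , drop = FALSE]
        cl <- tryCatch(chol(stats::cov(hist) + diag(1e-10, d)),
                       error = function(e) cl)
      }
    }
  }
  out[(warmup + 1):n_iter, , drop = FALSE]
}

# starting values drawn from the priors (paper's scheme), on the eta scale
draw_start_eta <- function(prior, hierarchical, chain_seed) {
  old <- local_seed(chain_seed)
  on.exit(restore_seed(old), add = TRUE)
  rpos <- function(mean, sd) {
    x <- stats::rnorm(1, mean, sd)
    while (x <= 0) x <- stats::rnorm(1, mean, sd)
    x
  }
  eta <- c(stats::rnorm(1, prior$means$f, prior$sds$f),
           stats::rnorm(1, prior$means$a1, prior$sds$a1),
           log(rpos(prior$means$b1, prior$sds$b1)),
           stats::rnorm(1, prior$means$c1, prior$sds$c1),
           log(rpos(prior$means$b2, prior$sds$b2)),
           stats::rnorm(1, prior$means$c2, prior$sds$c2),
           log(stats::rexp(1, prior$exp_rates$sigma)))
  if (hierarchical) eta <- c(eta, log(stats::rexp(1, prior$exp_rates$sigma_id)))
  eta
}

eta_to_theta <- function(eta) {
  list(f = eta[1], a1 = eta[2], b1 = exp(eta[3]), c1 = eta[4],
       b2 = exp(eta[5]), c2 = eta[6])
}

# Exact composition sampling of the individual intercepts: given a draw of
# the curve parameters and SDs, a_id[j] | y ~ Normal over the shrunken mean
# residual. Appends a_id.<j> slices to the draws array.
add_intercept_draws <- function(draws, age, value, id, nj, seed) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  n_iter <- dim(draws)[1]; n_chain <- dim(draws)[2]
  J <- length(nj)
  out <- array(NA_real_, dim = c(n_iter, n_chain, dim(draws)[3] + J),
               dimnames = list(NULL, NULL, c(dimnames(draws)[[3]],
                                             paste0("a_id.", seq_len(J)))))
  out[, , seq_len(dim(draws)[3])] <- draws
  for (k in seq_len(n_chain)) {
    for (i in seq_len(n_iter)) {
      gp <- suppressWarnings(as_growth_params(
        as.list(draws[i, k, curve_param_names])))
      s2 <- draws[i, k, "sigma"]^2
      t2 <- draws[i, k, "sigma_id"]^2
      sj <- rowsum(value - double_logistic(age, gp), id)[, 1]
      post_var <- t2 * s2 / (s2 + nj * t2)
      out[i, k, dim(draws)[3] + seq_len(J)] <-
        stats::rnorm(J, t2 * sj / (s2 + nj * t2), sqrt(post_var))
    }
  }
  out
}

run_amh <- function(log_post_eta, prior, control, hierarchical) {
  d <- if (hierarchical) 8L else 7L
  init_sds <- c(prior$sds$f, prior$sds$a1, 0.2, prior$sds$c1, 0.2,
                prior$sds$c2, rep(0.3, d - 6)) * 0.3
  retained <- control$iter - control$warmup
  chains <- lapply(seq_len(control$chains), function(k) {
    init <- draw_start_eta(prior, hierarchical,
                           derive_seed(control$seed, 0L, k))
    amh_chain(log_post_eta, init, control$iter, control$warmup, init_sds,
              seed = derive_seed(control$seed, 1L, k))
  })
  keep <- seq(1, retained, by = control$thin)
  pars <- c(curve_param_names, "sigma", if (hierarchical) "sigma_id")
  draws <- array(NA_real_, dim = c(length(keep), control$chains, d),
                 dimnames = list(NULL, NULL, pars))
  log_idx <- c(3, 5, 7, if (hierarchical) 8)
  for (k in seq_len(control$chains)) {
    m <- chains[[k]][keep, , drop = FALSE]
    m[, log_idx] <- exp(m[, log_idx])
    draws[, k, ] <- m
  }
  draws
}

# ---- MAP optimization ----

pack <- function(theta, lsig, lsig_id = NULL) {
  c(unlist(theta[curve_param_names]), lsig, lsig_id)
}

map_fit <- function(neg_log_post, start_list, lower, upper) {
  best <- NULL
  for (s in start_list) {
    res <- try(stats::optim(s, neg_log_post, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 1000)), silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("MAP optimization failed from all starting points")
  # simplex polish: L-BFGS-B line searches can terminate abnormally on the
  # flat ridges that appear when the residual SD collapses toward zero
  nm <- try(stats::optim(best$par, function(p) {
    if (any(p < lower) || any(p > upper)) return(Inf)
    neg_log_post(p)
  }, method = "Nelder-Mead",
  control = list(maxit = 2000, reltol = 1e-12)), silent = TRUE)
  if (!inherits(nm, "try-error") && nm$value <= best$value) best <- nm
  best
}

map_starts <- function(prior) {
  base <- unlist(prior$means)[curve_param_names]
  list(base,
       base + c(1, -1, 0, 0, 0.05, 0.5),
       base + c(-1, 1, 0, 0, -0.05, -0.5))
}

curve_mu <- function(par, age) {
  par[2] * stats::plogis(par[3] * (age - par[4])) +
    (par[1] - par[2]) * stats::plogis(par[5] * (age - par[6]))
}

# profile of the residual SD for the single-level model: given the residual
# sum of squares, minimize n log(sigma) + ssr / (2 sigma^2) + rate * sigma
# over log sigma
profile_sigma <- function(ssr, n, rate) {
  stats::optimize(function(ls)
    n * ls + ssr / (2 * exp(2 * ls)) + rate * exp(ls),
    interval = c(log(1e-6), log(1e3)), tol = 1e-10)
}

# profile of (sigma, sigma_id) for the marginalized longitudinal model,
# given the per-individual residual sufficient statistics
profile_sigmas_long <- function(sj, ssj, nj, rates) {
  inner <- function(ls) {
    s2 <- exp(2 * ls[1]); t2 <- exp(2 * ls[2])
    0.5 * sum(nj * log(s2) + log1p(nj * t2 / s2) +
                (ssj - t2 * sj^2 / (s2 + nj * t2)) / s2) +
      rates$sigma * exp(ls[1]) + rates$sigma_id * exp(ls[2])
  }
  # moment-based start: within-individual variance and variance of means
  means <- sj / nj
  s2_0 <- max(sum(ssj - nj * means^2) / max(sum(nj) - length(nj), 1), 1e-6)
  t2_0 <- max(stats::var(means) - s2_0 * mean(1 / nj), 1e-4)
  stats::optim(c(log(s2_0) / 2, log(t2_0) / 2), inner,
               method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 1000))
}

#' Fit the multilevel longitudinal growth model
#'
#' Fits the Bayesian hierarchical model: observed values are Normal around
#' the double-logistic population curve shifted by an individual-specific
#' random intercept \eqn{a_{ID} \sim N(0, \sigma_{ID})}; priors are the
#' trait-specific Normal prior means with fixed SDs (rates truncated at 0)
#' and Exponential(0.25) priors on \eqn{\sigma} and \eqn{\sigma_{ID}}.
#'
#' Two modes: \code{"mcmc"} samples the full posterior with JAGS
#' (chain-specific starting values drawn from the priors); \code{"map"}
#' maximizes the posterior with the individual intercepts marginalized
#' analytically (compound-symmetry marginal likelihood), giving a fast
#' deterministic reference fit.
#'
#' @param data a \code{longitudinal_dataset} (every individual has at least
#'   two observations).
#' @param prior a \code{\link{prior_spec}}.
#' @param control an \code{\link{mcmc_control}} (mcmc mode) — or set
#'   \code{mode = "map"}.
#' @param mode \code{"mcmc"} or \code{"map"}.
#' @return a \code{posterior_samples} object; mcmc mode carries a
#'   \code{convergence} attribute with the \code{\link{check_convergence}}
#'   report and a \code{converged} flag.
#' @export
fit_longitudinal <- function(data, prior, control = mcmc_control(),
                             mode = c("mcmc", "map")) {
  mode <- match.arg(mode)
  stopifnot(inherits(prior, "prior_spec"))
  counts <- table(data$individual_id)
  if (any(counts < 2))
    stop("every individual needs >= 2 observations for the longitudinal model")
  ids <- as.integer(factor(data$individual_id))
  n_ind <- max(ids)
  nj <- as.vector(table(ids))

  if (mode == "mcmc") {
    stopifnot(inherits(control, "mcmc_control"))
    lp <- function(eta) {
      long_log_posterior(eta_to_theta(eta), exp(eta[7]), exp(eta[8]),
                         data$age, data$value, ids, nj, prior) +
        eta[3] + eta[5] + eta[7] + eta[8]
    }
    draws <- run_amh(lp, prior, control, hierarchical = TRUE)
    if (control$monitor_intercepts)
      draws <- add_intercept_draws(draws, data$age, data$value, ids, nj,
                                   seed = derive_seed(control$seed, 2L, 1L))
    post <- new_posterior_samples(draws, mode = "mcmc", model = "longitudinal",
                                  n_obs = nrow(data), n_individuals = n_ind,
                                  warmup = control$warmup, prior = prior)
    rep <- check_convergence(post)
    post$converged <- rep$pass
    attr(post, "convergence") <- rep
    if (!rep$pass)
      warning("longitudinal MCMC fit flagged as non-converged (see check_convergence)")
    return(post)
  }
  # outer optimization over the curve parameters with (sigma, sigma_id)
  # profiled out of the marginalized posterior at every step
  neg <- function(par) {
    theta <- as.list(par); names(theta) <- curve_param_names
    lpc <- log_prior_curve(theta, prior)
    if (!is.finite(lpc)) return(Inf)
    r <- data$value - curve_mu(par, data$age)
    profile_sigmas_long(rowsum(r, ids)[, 1], rowsum(r^2, ids)[, 1],
                        nj, prior$exp_rates)$value - lpc
  }
  lower <- c(-Inf, -Inf, 0.01, -Inf, 0.01, -Inf)
  upper <- rep(Inf, 6)
  best <- map_fit(neg, map_starts(prior), lower, upper)
  r <- data$value - curve_mu(best$par, data$age)
  prof <- profile_sigmas_long(rowsum(r, ids)[, 1], rowsum(r^2, ids)[, 1],
                              nj, prior$exp_rates)
  est <- c(best$par, exp(prof$par))
  names(est) <- c(curve_param_names, "sigma", "sigma_id")
  # posterior means of the intercepts given the point estimate (shrinkage)
  s2 <- est["sigma"]^2; t2 <- est["sigma_id"]^2
  gp <- suppressWarnings(as_growth_params(as.list(est[curve_param_names])))
  r <- data$value - double_logistic(data$age, gp)
  a_hat <- t2 * rowsum(r, ids)[, 1] / (s2 + nj * t2)
  names(a_hat) <- paste0("a_id.", seq_along(a_hat))
  est <- c(est, a_hat)
  draws <- array(est, dim = c(1, 1, length(est)),
                 dimnames = list(NULL, NULL, names(est)))
  new_posterior_samples(draws, mode = "map", model = "longitudinal",
                        n_obs = nrow(data), n_individuals = n_ind,
                        converged = best$convergence == 0, prior = prior)
}

#' Fit the single-level cross-sectional growth model
#'
#' Same model as \code{\link{fit_longitudinal}} but without the individual
#' intercept and its SD: with one observation per individual,
#' between-individual variation and measurement error are indistinguishable
#' and are absorbed into a single residual SD \eqn{\sigma}.
#'
#' @param data a \code{cross_section} (or data.frame with one observation
#'   per individual; columns \code{individual_id}, \code{age},
#'   \code{value}). Needs at least 5 observations; fits at exactly the
#'   minimum size are flagged \code{caution}.
#' @param prior a \code{\link{prior_spec}}.
#' @param control a \code{\link{fit_control}} choosing map (default) or
#'   mcmc mode.
#' @return a \code{posterior_samples} object.
#' @export
fit_cross_sectional <- function(data, prior, control = fit_control()) {
  stopifnot(inherits(prior, "prior_spec"), inherits(control, "fit_control"))
  if (anyDuplicated(data$individual_id))
    stop("cross-sectional data must contain exactly one observation per individual")
  n <- nrow(data)
  if (n < 5) stop("cross-sectional fit needs at least 5 observations")
  caution <- n <= 5

  if (control$mode == "mcmc") {
    lp <- function(eta) {
      cs_log_posterior(eta_to_theta(eta), exp(eta[7]),
                       data$age, data$value, prior) +
        eta[3] + eta[5] + eta[7]
    }
    draws <- run_amh(lp, prior, control$mcmc, hierarchical = FALSE)
    post <- new_posterior_samples(draws, mode = "mcmc",
                                  model = "cross-sectional",
                                  n_obs = n, n_individuals = n,
                                  warmup = control$mcmc$warmup,
                                  caution = caution, prior = prior)
    rep <- check_convergence(post)
    post$converged <- rep$pass
    attr(post, "convergence") <- rep
    return(post)
  }

  # outer optimization over the curve parameters, sigma profiled out
  neg <- function(par) {
    theta <- as.list(par); names(theta) <- curve_param_names
    lpc <- log_prior_curve(theta, prior)
    if (!is.finite(lpc)) return(Inf)
    ssr <- sum((data$value - curve_mu(par, data$age))^2)
    profile_sigma(ssr, n, prior$exp_rates$sigma)$objective - lpc
  }
  lower <- c(-Inf, -Inf, 0.01, -Inf, 0.01, -Inf)
  upper <- rep(Inf, 6)
  best <- map_fit(neg, map_starts(prior), lower, upper)
  ssr <- sum((data$value - curve_mu(best$par, data$age))^2)
  est <- c(best$par,
           exp(profile_sigma(ssr, n, prior$exp_rates$sigma)$minimum))
  names(est) <- c(curve_param_names, "sigma")
  draws <- array(est, dim = c(1, 1, length(est)),
                 dimnames = list(NULL, NULL, names(est)))
  new_posterior_samples(draws, mode = "map", model = "cross-sectional",
                        n_obs = n, n_individuals = n, caution = caution,
                        converged = best$convergence == 0, prior = prior)
}

#' Posterior predictive growth-percentile bands
#'
#' For each age on a grid, computes the median predicted size and central
#' quantile intervals from the posterior draws. \code{target =
#' "mean-curve"} summarizes uncertainty in the population curve itself;
#' \code{target = "new-observation"} adds per-draw residual noise
#' \eqn{N(0, \sigma)} (plus \eqn{N(0, \sigma_{ID})} for a new individual
#' under the longitudinal model), giving growth-standard style intervals in
#' which a stated fraction of new measurements is expected to fall.
#'
#' @param post a \code{posterior_samples} object.
#' @param age_grid ages (years).
#' @param levels central interval levels in percent (default 50, 80, 98).
#' @param target \code{"mean-curve"} or \code{"new-observation"}.
#' @param seed RNG seed for the predictive noise draws.
#' @return object of class \code{prediction_bands}: \code{age_grid},
#'   \code{levels}, \code{median} (numeric), \code{lower} and \code{upper}
#'   (level x age matrices), \code{target}.
#' @export
posterior_predict <- function(post, age_grid = seq(5, 20, by = 0.25),
                              levels = c(50, 80, 98),
                              target = c("mean-curve", "new-observation"),
                              seed = 1L) {
  stopifnot(inherits(post, "posterior_samples"))
  target <- match.arg(target)
  if (any(levels <= 0 | levels >= 100))
    stop("interval levels must be inside (0, 100)")
  pars <- c(curve_param_names, "sigma",
            if ("sigma_id" %in% dimnames(post$draws)[[3]]) "sigma_id")
  dr <- posterior_draws(post, pars)
  ndr <- nrow(dr)
  mu <- dr[, "a1"] * stats::plogis(outer(dr[, "b1"], age_grid) -
                                     dr[, "b1"] * dr[, "c1"]) +
    (dr[, "f"] - dr[, "a1"]) *
      stats::plogis(outer(dr[, "b2"], age_grid) - dr[, "b2"] * dr[, "c2"])
  if (target == "new-observation") {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    sd_new <- if ("sigma_id" %in% colnames(dr))
      sqrt(dr[, "sigma"]^2 + dr[, "sigma_id"]^2) else dr[, "sigma"]
    mu <- mu + matrix(stats::rnorm(length(mu), 0, rep(sd_new, ncol(mu))),
                      nrow = ndr)
  }
  probs_lo <- (1 - levels / 100) / 2
  probs_hi <- 1 - probs_lo
  med <- apply(mu, 2, stats::median)
  lower <- t(apply(mu, 2, stats::quantile, probs = probs_lo, names = FALSE))
  upper <- t(apply(mu, 2, stats::quantile, probs = probs_hi, names = FALSE))
  if (length(levels) == 1) {
    lower <- matrix(lower, nrow = 1)
    upper <- matrix(upper, nrow = 1)
  } else {
    lower <- t(lower); upper <- t(upper)
  }
  dimnames(lower) <- dimnames(upper) <- list(paste0("p", levels), NULL)
  structure(list(age_grid = age_grid, levels = levels, median = med,
                 lower = lower, upper = upper, target = target),
            class = "prediction_bands")
}

#' @export
print.prediction_bands <- function(x, ...) {
  cat(sprintf("Posterior predictive bands (%s): %d ages (%.2f-%.2f y), central levels %s%%\n",
              x$target, length(x$age_grid), min(x$age_grid), max(x$age_grid),
              paste(x$levels, collapse = "/")))
  invisible(x)
}

# ---- convergence diagnostics: rank-normalized split R-hat and bulk ESS ----

split_chains <- function(m) {
  n <- nrow(m)
  half <- floor(n / 2)
  cbind(m[seq_len(half), , drop = FALSE],
        m[(n - half + 1):n, , drop = FALSE])
}

rank_normalize <- function(m) {
  z <- stats::qnorm((rank(as.vector(m)) - 3 / 8) / (length(m) + 1 / 4))
  matrix(z, nrow = nrow(m))
}

rhat_basic <- function(m) {
  n <- nrow(m); nc <- ncol(m)
  if (stats::var(as.vector(m)) == 0) return(1)
  chain_means <- colMeans(m)
  chain_vars <- apply(m, 2, stats::var)
  w <- mean(chain_vars)
  b <- n * stats::var(chain_means)
  sqrt(((n - 1) / n * w + b / n) / w)
}

ess_basic <- function(m) {
  n <- nrow(m); nc <- ncol(m)
  if (stats::var(as.vector(m)) == 0) return(NA_real_)
  acov <- vapply(seq_len(nc), function(k) {
    stats::acf(m[, k], lag.max = n - 1, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1] * (n - 1) / n
  }, numeric(n))
  acov <- matrix(acov, nrow = n)
  chain_var <- acov[1, ] * n / (n - 1)
  w <- mean(chain_var)
  var_plus <- w * (n - 1) / n +
    (if (nc > 1) stats::var(colMeans(m)) else 0)
  rho <- 1 - (w - rowMeans(acov)) / var_plus
  # Geyer initial monotone positive sequence over lag pairs
  tau <- rho[1]
  t <- 1
  prev_pair <- Inf
  while (t + 1 < n) {
    pair <- rho[t + 1] + if (t + 2 <= n) rho[t + 2] else 0
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev_pair)
    prev_pair <- pair
    tau <- tau + 2 * pair
    t <- t + 2
  }
  max(n * nc / max(tau, 1e-12), 1)
}

#' MCMC convergence report
#'
#' Rank-normalized split R-hat and bulk effective sample size per monitored
#' parameter. The fit passes when every R-hat is below 1.01 and every ESS is
#' at least 400.
#'
#' @param post a \code{posterior_samples} object fitted by MCMC with at
#'   least two chains.
#' @param pars parameters to check (default: curve parameters and SDs,
#'   excluding individual intercepts).
#' @return object of class \code{convergence_report}: data.frame
#'   \code{diagnostics} (parameter, rhat, ess) and logical \code{pass}.
#' @export
check_convergence <- function(post, pars = NULL) {
  stopifnot(inherits(post, "posterior_samples"))
  if (post$mode != "mcmc")
    stop("convergence diagnostics require mcmc mode")
  if (dim(post$draws)[2] < 2)
    stop("convergence diagnostics require at least 2 chains")
  all_pars <- dimnames(post$draws)[[3]]
  if (is.null(pars))
    pars <- intersect(c(curve_param_names, "sigma", "sigma_id"), all_pars)
  stats_df <- do.call(rbind, lapply(pars, function(p) {
    m <- post$draws[, , p]
    sm <- split_chains(m)
    z <- rank_normalize(sm)
    data.frame(parameter = p, rhat = rhat_basic(z), ess = ess_basic(z))
  }))
  pass <- all(stats_df$rhat < 1.01, na.rm = TRUE) &&
    all(stats_df$ess >= 400, na.rm = TRUE)
  structure(list(diagnostics = stats_df, pass = pass),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("MCMC convergence (rank-normalized split R-hat, bulk ESS):\n")
  print(x$diagnostics, row.names = FALSE)
  cat(if (x$pass) "PASS: all R-hat < 1.01 and ESS >= 400\n"
      else "FAIL: diagnostics exceed thresholds\n")
  invisible(x)
}
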