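test_that("map mode recovers truth from a noiseless cross-section", {
  truth <- test_truth()
  cfg <- test_config(n_individuals = 400, sigma = 0, sigma_id = 0, seed = 1)
  d <- generate_population(cfg)
  cs <- draw_cross_section(d, "full", seed = 2)
  fit <- fit_cross_sectional(cs, truth_prior(), fit_control("map"))
  est <- posterior_median(fit)
  for (p in c("f", "a1"))
    expect_lt(abs(est[[p]] - truth[[p]]) / truth[[p]], 0.01)
  for (p in c("c1", "c2"))
    expect_lt(abs(est[[p]] - truth[[p]]), 0.1)
  expect_true(fit$converged)
})

test_that("cross-sectional fits validate their design", {
  d <- small_dataset()
  expect_error(fit_cross_sectional(d, small_prior()), "one observation")
  cs5 <- draw_cross_section(d, 5, seed = 3)
  fit5 <- fit_cross_sectional(cs5, small_prior())
  expect_true(fit5$caution)
  cs4 <- cs5[1:4, ]
  expect_error(fit_cross_sectional(cs4, small_prior()), "at least 5")
})

test_that("fits are reproducible from their seeds", {
  d <- small_dataset()
  cs <- draw_cross_section(d, 60, seed = 4)
  ctl <- fit_control("mcmc", mcmc_control(chains = 2, iter = 1200,
                                          warmup = 600, seed = 17))
  f1 <- fit_cross_sectional(cs, small_prior(), ctl)
  f2 <- fit_cross_sectional(cs, small_prior(), ctl)
  expect_identical(f1$draws, f2$draws)
  m1 <- fit_longitudinal(d, small_prior(), mode = "map")
  m2 <- fit_longitudinal(d, small_prior(), mode = "map")
  expect_identical(m1$draws, m2$draws)
})

test_that("implemented log posteriors match independently coded densities", {
  d <- small_dataset()
  cs <- draw_cross_section(d, 50, seed = 5)
  pr <- truth_prior()
  # hand-coded cross-sectional posterior (with truncation normalizers, which
  # the package drops as constants)
  hand_cs <- function(th, sigma) {
    mu <- th$a1 / (1 + exp(-th$b1 * (cs$age - th$c1))) +
      (th$f - th$a1) / (1 + exp(-th$b2 * (cs$age - th$c2)))
    sum(dnorm(cs$value, mu, sigma, log = TRUE)) +
      dnorm(th$f, pr$means$f, 2, log = TRUE) +
      dnorm(th$a1, pr$means$a1, 2, log = TRUE) +
      dnorm(th$b1, pr$means$b1, 0.2, log = TRUE) -
      pnorm(0, pr$means$b1, 0.2, lower.tail = FALSE, log.p = TRUE) +
      dnorm(th$c1, pr$means$c1, 1, log = TRUE) +
      dnorm(th$b2, pr$means$b2, 0.2, log = TRUE) -
      pnorm(0, pr$means$b2, 0.2, lower.tail = FALSE, log.p = TRUE) +
      dnorm(th$c2, pr$means$c2, 1, log = TRUE) +
      dexp(sigma, 0.25, log = TRUE)
  }
  set.seed(6)
  diffs <- replicate(20, {
    th <- list(f = rnorm(1, 100, 2), a1 = rnorm(1, 85, 2),
               b1 = runif(1, 0.2, 1.5), c1 = runif(1, 2, 8),
               b2 = runif(1, 0.2, 1.5), c2 = runif(1, 9, 15))
    sigma <- runif(1, 0.5, 4)
    hand_cs(th, sigma) -
      dlgrowth:::cs_log_posterior(th, sigma, cs$age, cs$value, pr)
  })
  expect_lt(max(abs(diffs - diffs[1])), 1e-8)
})

test_that("marginalized longitudinal likelihood matches dense linear algebra", {
  pr <- truth_prior()
  set.seed(7)
  ids <- c(1, 1, 2, 2, 2, 3, 3, 3, 3)
  age <- c(5, 9, 4, 8, 14, 6, 10, 15, 19)
  value <- double_logistic(age, test_truth()) + rnorm(9, 0, 2)
  nj <- as.vector(table(ids))
  hand_marginal <- function(th, sigma, sigma_id) {
    mu <- th$a1 / (1 + exp(-th$b1 * (age - th$c1))) +
      (th$f - th$a1) / (1 + exp(-th$b2 * (age - th$c2)))
    Z <- outer(ids, unique(ids), "==") * 1
    Sigma <- sigma^2 * diag(9) + sigma_id^2 * Z %*% t(Z)
    r <- value - mu
    ll <- -0.5 * (9 * log(2 * pi) + determinant(Sigma)$modulus[1] +
                    drop(r %*% solve(Sigma, r)))
    ll + dnorm(th$f, pr$means$f, 2, log = TRUE) +
      dnorm(th$a1, pr$means$a1, 2, log = TRUE) +
      dnorm(th$b1, pr$means$b1, 0.2, log = TRUE) +
      dnorm(th$c1, pr$means$c1, 1, log = TRUE) +
      dnorm(th$b2, pr$means$b2, 0.2, log = TRUE) +
      dnorm(th$c2, pr$means$c2, 1, log = TRUE) +
      dexp(sigma, 0.25, log = TRUE) + dexp(sigma_id, 0.25, log = TRUE)
  }
  for (i in 1:20) {
    th <- list(f = rnorm(1, 100, 2), a1 = rnorm(1, 85, 2),
               b1 = runif(1, 0.2, 1.5), c1 = runif(1, 2, 8),
               b2 = runif(1, 0.2, 1.5), c2 = runif(1, 9, 15))
    sigma <- runif(1, 0.5, 3); sigma_id <- runif(1, 0.5, 4)
    expect_equal(
      dlgrowth:::long_log_posterior(th, sigma, sigma_id, age, value,
                                    ids, nj, pr),
      hand_marginal(th, sigma, sigma_id), tolerance = 1e-10)
  }
})

test_that("hierarchical MCMC recovers the generating parameters", {
  truth <- test_truth()
  cfg <- attr(med_dataset(), "truth")
  fit <- med_mcmc_fit()
  est <- posterior_median(fit)
  for (p in c("f", "a1"))
    expect_lt(abs(est[[p]] - truth[[p]]) / truth[[p]], 0.05)
  for (p in c("c1", "c2"))
    expect_lt(abs(est[[p]] - truth[[p]]), 0.5)
  expect_lt(abs(est[["sigma"]] - cfg$sigma) / cfg$sigma, 0.1)
  # intercepts are centered at zero by construction
  a_id <- est[grep("^a_id\\.", names(est))]
  expect_length(a_id, 200)
  expect_lt(abs(mean(a_id)), 2 * cfg$sigma_id / sqrt(200))
  # truncation respected in every retained draw
  expect_true(all(posterior_draws(fit, c("b1", "b2")) > 0))
})

test_that("longitudinal fits separate measurement error from individual variation", {
  cfg <- test_config(n_individuals = 350, seed = 19)  # sigma_id >> sigma
  d <- generate_population(cfg)
  pr <- elicit_prior_means(d, ga_control(seed = 8))
  long_sigma <- posterior_median(fit_longitudinal(d, pr, mode = "map"))[["sigma"]]
  cs <- draw_cross_section(d, "full", seed = 20)
  cs_sigma <- posterior_median(fit_cross_sectional(cs, pr))[["sigma"]]
  total <- sqrt(cfg$sigma^2 + cfg$sigma_id^2)
  expect_lt(abs(long_sigma - cfg$sigma) / cfg$sigma, 0.15)
  expect_lt(abs(cs_sigma - total) / total, 0.15)
})

test_that("posterior predictive bands nest and collapse correctly", {
  fit <- small_mcmc_fit()
  grid <- seq(4, 20, by = 0.5)
  for (target in c("mean-curve", "new-observation")) {
    b <- posterior_predict(fit, grid, levels = c(50, 80, 98), target = target)
    expect_true(all(b$lower["p50", ] >= b$lower["p80", ]))
    expect_true(all(b$lower["p80", ] >= b$lower["p98", ]))
    expect_true(all(b$upper["p50", ] <= b$upper["p80", ]))
    expect_true(all(b$upper["p80", ] <= b$upper["p98", ]))
    expect_true(all(b$lower["p50", ] <= b$median & b$median <= b$upper["p50", ]))
  }
  expect_error(posterior_predict(fit, grid, levels = c(50, 100)), "levels")
  # point-mass posterior: all bands collapse onto the deterministic curve
  tr <- test_truth()
  row <- c(f = tr$f, a1 = tr$a1, b1 = tr$b1, c1 = tr$c1, b2 = tr$b2,
           c2 = tr$c2, sigma = 1e-12)
  deg <- manual_posterior(matrix(rep(row, each = 50), nrow = 50,
                                 dimnames = list(NULL, names(row))))
  bd <- posterior_predict(deg, grid, target = "new-observation")
  curve <- double_logistic(grid, tr)
  expect_lt(max(abs(bd$median - curve)), 1e-8)
  expect_lt(max(abs(bd$lower["p98", ] - curve)), 1e-6)
  expect_lt(max(abs(bd$upper["p98", ] - curve)), 1e-6)
})

test_that("98% new-observation bands cover held-out individuals", {
  fit <- small_mcmc_fit()
  # thin the pooled draws to keep the predictive matrix small
  dr <- posterior_draws(fit, c("f", "a1", "b1", "c1", "b2", "c2",
                               "sigma", "sigma_id"))
  thin <- manual_posterior(dr[seq(1, nrow(dr), by = 10), ])
  holdout <- generate_population(test_config(n_individuals = 150,
                                             seed = 1234))
  b <- posterior_predict(thin, holdout$age, levels = 98,
                         target = "new-observation", seed = 99)
  covered <- holdout$value >= b$lower["p98", ] &
    holdout$value <= b$upper["p98", ]
  expect_gt(length(covered), 1000)
  expect_gte(mean(covered), 0.96)
  expect_lte(mean(covered), 1)
})

test_that("convergence diagnostics match iid and divergent oracles", {
  set.seed(27)
  iid <- manual_posterior(matrix(rnorm(8000), ncol = 1,
                                 dimnames = list(NULL, "f")), n_chain = 4)
  rep_iid <- check_convergence(iid)
  expect_lt(rep_iid$diagnostics$rhat, 1.01)
  expect_lt(abs(rep_iid$diagnostics$ess - 8000) / 8000, 0.2)
  # two chains offset by 5 SD must be flagged
  x <- rnorm(4000)
  x[2001:4000] <- x[2001:4000] + 5
  off <- manual_posterior(matrix(x, ncol = 1, dimnames = list(NULL, "f")),
                          n_chain = 2)
  expect_gt(check_convergence(off)$diagnostics$rhat, 1.1)
  expect_false(check_convergence(off)$pass)
  # diagnostics need chains and mcmc mode
  one <- manual_posterior(matrix(rnorm(100), ncol = 1,
                                 dimnames = list(NULL, "f")))
  expect_error(check_convergence(one), "2 chains")
  mp <- manual_posterior(matrix(1, 1, 1, dimnames = list(NULL, "f")),
                         mode = "map")
  expect_error(check_convergence(mp), "mcmc")
})

test_that("sampler posteriors agree with an independent JAGS fit", {
  skip_if_not_installed("rjags")
  d <- small_dataset()
  cs <- draw_cross_section(d, 80, seed = 29)
  pr <- small_prior()
  mine <- fit_cross_sectional(cs, pr,
                              fit_control("mcmc",
                                          mcmc_control(chains = 4,
                                                       iter = 8000,
                                                       warmup = 4000,
                                                       seed = 37)))
  model_str <- "model {
    for (i in 1:N) {
      mu[i] <- a1 / (1 + exp(-b1 * (age[i] - c1))) +
               (f - a1) / (1 + exp(-b2 * (age[i] - c2)))
      y[i] ~ dnorm(mu[i], 1 / (sigma * sigma))
    }
    f  ~ dnorm(pf, 0.25)
    a1 ~ dnorm(pa, 0.25)
    b1 ~ dnorm(pb1, 25) T(0,)
    c1 ~ dnorm(pc1, 1)
    b2 ~ dnorm(pb2, 25) T(0,)
    c2 ~ dnorm(pc2, 1)
    sigma ~ dexp(0.25)
  }"
  jd <- list(N = nrow(cs), y = cs$value, age = cs$age,
             pf = pr$means$f, pa = pr$means$a1, pb1 = pr$means$b1,
             pc1 = pr$means$c1, pb2 = pr$means$b2, pc2 = pr$means$c2)
  inits <- lapply(1:4, function(k)
    list(f = pr$means$f, a1 = pr$means$a1, b1 = pr$means$b1,
         c1 = pr$means$c1, b2 = pr$means$b2, c2 = pr$means$c2, sigma = 2,
         .RNG.name = "base::Mersenne-Twister", .RNG.seed = 400 + k))
  jm <- rjags::jags.model(textConnection(model_str), data = jd,
                          inits = inits, n.chains = 4, n.adapt = 1000,
                          quiet = TRUE)
  update(jm, 2000, progress.bar = "none")
  js <- rjags::coda.samples(jm, c("f", "a1", "b1", "c1", "b2", "c2",
                                  "sigma"), n.iter = 3000,
                            progress.bar = "none")
  jags_all <- do.call(rbind, lapply(js, as.matrix))
  jags_ess <- coda::effectiveSize(js)
  mine_rep <- check_convergence(mine)
  for (p in c("f", "a1", "b2", "c2", "sigma")) {
    md <- posterior_draws(mine, p)
    mcse <- sqrt(sd(md)^2 /
                   mine_rep$diagnostics$ess[mine_rep$diagnostics$parameter == p] +
                 sd(jags_all[, p])^2 / max(jags_ess[[p]], 10))
    expect_lt(abs(mean(md) - mean(jags_all[, p])), 5 * mcse + 0.02)
    expect_lt(abs(sd(md) / sd(jags_all[, p]) - 1), 0.35)
  }
})
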