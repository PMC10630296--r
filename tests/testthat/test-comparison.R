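test_that("mean absolute difference behaves like a metric on curves", {
  grid <- seq(5, 20, by = 0.25)
  a <- double_logistic(grid, test_truth())
  expect_identical(mean_abs_difference(a, a, grid)$scalar, 0)
  off <- mean_abs_difference(a + 0.5, a, grid)
  expect_true(all(abs(off$curve - 0.5) < 1e-12))
  expect_equal(off$scalar, 0.5)
  # scalar is the grid mean of the MAD curve
  set.seed(3)
  reps <- matrix(rep(a, 4), nrow = 4, byrow = TRUE) + rnorm(4 * length(a))
  m <- mean_abs_difference(reps, a, grid)
  expect_equal(m$scalar, mean(m$curve))
  expect_error(mean_abs_difference(a[-1], a, grid), "identical age grid")
  # pointwise triangle inequality
  b <- a + rnorm(length(a)); c <- a + rnorm(length(a))
  expect_true(all(mean_abs_difference(a, c, grid)$curve <=
                    mean_abs_difference(a, b, grid)$curve +
                    mean_abs_difference(b, c, grid)$curve + 1e-12))
})

test_that("milestone errors vanish for the reference itself", {
  ref <- find_milestones(test_truth(), c(5, 20))
  fake <- structure(list(
    records = data.frame(size = 10, size_label = "10", replicate = 1:3,
                         seed = 1:3, ok = TRUE, reason = "",
                         f = 100, a1 = 85, b1 = 0.8, c1 = 6, b2 = 0.9,
                         c2 = 12, sigma = 1,
                         pgv = ref$pgv, apgv = ref$apgv,
                         converged = TRUE, caution = FALSE),
    curves = matrix(0, 3, 2), draws = list(NULL, NULL, NULL),
    age_grid = c(5, 20), design = list()), class = "experiment_result")
  err <- milestone_errors(fake, ref)
  expect_identical(err$pgv_mae, 0)
  expect_identical(err$apgv_mae, 0)
  expect_identical(err$apgv_bias, 0)
})

test_that("rate RMSD matches a brute-force oracle and scales linearly", {
  grid <- seq(5, 20, by = 0.25)
  gp <- test_truth()
  expect_identical(rate_rmsd(gp, gp, grid), 0)
  set.seed(13)
  for (i in 1:20) {
    pa <- random_valid_params(); pb <- random_valid_params()
    oracle <- sqrt(mean((growth_velocity(grid, pa) -
                           growth_velocity(grid, pb))^2))
    expect_lt(abs(rate_rmsd(pa, pb, grid) - oracle), 1e-10)
  }
  # homogeneity: doubling the adolescent-phase velocity gap doubles the RMSD
  base <- growth_params(f = 100, a1 = 85, b1 = 2, c1 = 1, b2 = 0.8, c2 = 12)
  up1 <- growth_params(f = 102, a1 = 85, b1 = 2, c1 = 1, b2 = 0.8, c2 = 12)
  up2 <- growth_params(f = 104, a1 = 85, b1 = 2, c1 = 1, b2 = 0.8, c2 = 12)
  r1 <- rate_rmsd(base, up1, grid)
  r2 <- rate_rmsd(base, up2, grid)
  expect_lt(abs(r2 / r1 - 2), 0.01)
})

test_that("percentile comparisons detect identical and mismatched bands", {
  b <- posterior_predict(small_mcmc_fit(), seq(5, 20, 0.5),
                         levels = c(50, 98))
  cmp <- percentile_comparison(b, b)
  expect_true(all(cmp$max_abs == 0))
  expect_identical(nrow(cmp), 5L)  # median + 2 endpoints per level
  b2 <- posterior_predict(small_mcmc_fit(), seq(5, 20, 0.5), levels = 80)
  expect_error(percentile_comparison(b, b2), "levels")
  b3 <- posterior_predict(small_mcmc_fit(), seq(5, 19, 0.5),
                          levels = c(50, 98))
  expect_error(percentile_comparison(b, b3), "age grid")
})

test_that("independent refits differ only by Monte-Carlo noise", {
  d <- small_dataset()
  cs <- draw_cross_section(d, 60, seed = 21)
  pr <- small_prior()
  fits <- lapply(c(101, 202), function(s)
    fit_cross_sectional(cs, pr, fit_control("mcmc",
                                            mcmc_control(chains = 2,
                                                         iter = 6000,
                                                         warmup = 3000,
                                                         seed = s))))
  grid <- seq(5, 20, by = 0.5)
  bands <- lapply(fits, posterior_predict, age_grid = grid, levels = 50)
  cmp <- percentile_comparison(bands[[1]], bands[[2]])
  # Monte-Carlo SE of the median curve, from the draws of one fit
  dr <- posterior_draws(fits[[1]])
  mu_sd <- apply(vapply(seq_len(nrow(dr)), function(i)
    double_logistic(grid, suppressWarnings(as_growth_params(
      as.list(dr[i, dlgrowth:::curve_param_names])))),
    numeric(length(grid))), 1, sd)
  ess <- min(check_convergence(fits[[1]])$diagnostics$ess)
  mcse <- 1.25 * max(mu_sd) / sqrt(ess)
  expect_lt(cmp$max_abs[cmp$curve == "median"], 3 * mcse + 0.05)
})

test_that("pooled cross-sectional bands match longitudinal growth standards", {
  d <- med_dataset()
  pr <- med_prior()
  long_fit <- med_mcmc_fit()
  # pool several full-sample cross-sectional posteriors
  pooled <- do.call(rbind, lapply(1:5, function(r) {
    cs <- draw_cross_section(d, "full", seed = 3000 + r)
    fit <- fit_cross_sectional(cs, pr,
                               fit_control("mcmc",
                                           mcmc_control(chains = 2,
                                                        iter = 4000,
                                                        warmup = 2000,
                                                        seed = 3000 + r)))
    posterior_draws(fit)
  }))
  grid <- seq(5, 20, by = 0.5)
  cs_bands <- posterior_predict(manual_posterior(pooled), grid, levels = 98,
                                target = "new-observation", seed = 7)
  long_bands <- posterior_predict(long_fit, grid, levels = 98,
                                  target = "new-observation", seed = 8)
  past_q1 <- grid >= quantile(grid, 0.25)
  expect_lt(max(abs(cs_bands$lower["p98", past_q1] -
                      long_bands$lower["p98", past_q1])), 1)
  expect_lt(max(abs(cs_bands$upper["p98", past_q1] -
                      long_bands$upper["p98", past_q1])), 1)
  expect_lt(max(abs(cs_bands$median[past_q1] -
                      long_bands$median[past_q1])), 1)
})

test_that("agreement with the longitudinal reference improves with size", {
  d <- med_dataset()
  pr <- med_prior()
  ref <- fit_longitudinal(d, pr, mode = "map")
  res <- run_experiment(d, pr, sizes = list(5, 20, 100), reps = 10,
                        master_seed = 31, keep_draws = FALSE)
  rep <- compare_to_longitudinal(res, ref)
  mads <- rep$by_size$mad[match(c(5, 20, 100), rep$by_size$size)]
  expect_true(mads[3] <= mads[2])
  expect_true(mads[2] <= mads[1])
  expect_true(all(rep$by_size$mad >= 0))
  expect_true(all(rep$by_size$pgv_mae >= 0))
  # the MAD scalar equals the grid mean of the stored MAD curve
  expect_equal(rep$by_size$mad,
               unname(rowMeans(rep$mad_curves)[rep$by_size$size_label]))
})
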