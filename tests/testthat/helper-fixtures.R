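# Shared fixtures, built in code. Heavier objects are memoized so several
# test files can reuse one computation.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# truth with both phases well inside the observed age range, so all six
# parameters are identifiable from the data alone
test_truth <- function() {
  growth_params(f = 100, a1 = 85, b1 = 0.8, c1 = 6, b2 = 0.9, c2 = 12)
}

test_config <- function(n_individuals = 80, seed = 42, ...) {
  population_config(params = test_truth(), age_range = c(2, 22),
                    n_individuals = n_individuals, seed = seed, ...)
}

# prior centered at the test truth (what a successful elicitation returns)
truth_prior <- function() {
  tr <- test_truth()
  prior_spec(f = tr$f, a1 = tr$a1, b1 = tr$b1, c1 = tr$c1,
             b2 = tr$b2, c2 = tr$c2)
}

small_dataset <- function() {
  fixture("small_dataset", function() generate_population(test_config()))
}

small_prior <- function() {
  fixture("small_prior", function()
    elicit_prior_means(small_dataset(), ga_control(seed = 9)))
}

# one shared longitudinal MCMC fit (80 individuals) reused across files
small_mcmc_fit <- function() {
  fixture("small_mcmc_fit", function()
    suppressWarnings(fit_longitudinal(small_dataset(), small_prior(),
                                      mcmc_control(chains = 4, iter = 6000,
                                                   warmup = 3000,
                                                   seed = 31))))
}

# a mid-sized population (200 individuals) for recovery and band agreement
med_dataset <- function() {
  fixture("med_dataset", function()
    generate_population(test_config(n_individuals = 200, seed = 15)))
}

med_prior <- function() {
  fixture("med_prior", function()
    elicit_prior_means(med_dataset(), ga_control(seed = 8)))
}

med_mcmc_fit <- function() {
  fixture("med_mcmc_fit", function()
    suppressWarnings(fit_longitudinal(med_dataset(), med_prior(),
                                      mcmc_control(chains = 4, iter = 6000,
                                                   warmup = 3000,
                                                   seed = 23,
                                                   monitor_intercepts = TRUE))))
}

# build a posterior_samples object from an explicit draws matrix
manual_posterior <- function(draws_matrix, mode = "mcmc",
                             model = "cross-sectional", n_chain = 1) {
  n <- nrow(draws_matrix) / n_chain
  arr <- array(NA_real_, dim = c(n, n_chain, ncol(draws_matrix)),
               dimnames = list(NULL, NULL, colnames(draws_matrix)))
  for (k in seq_len(n_chain))
    arr[, k, ] <- draws_matrix[((k - 1) * n + 1):(k * n), ]
  dlgrowth:::new_posterior_samples(arr, mode = mode, model = model,
                                   n_obs = NA_integer_,
                                   n_individuals = NA_integer_)
}

# the scaled replication study shared by several acceptance checks:
# default synthetic population, map-mode longitudinal reference, 20
# cross-sectional replicates at n = 100, 200 and the full sample
acceptance_study <- function() {
  fixture("acceptance_study", function()
    run_study(config = population_config(seed = 101),
              sizes = c(100, 200, "full"), reps = 20, master_seed = 202))
}

random_valid_params <- function() {
  f <- runif(1, 60, 140)
  growth_params(f = f, a1 = f * runif(1, 0.4, 0.9),
                b1 = runif(1, 0.2, 2), c1 = runif(1, 0, 8),
                b2 = runif(1, 0.2, 2), c2 = runif(1, 8, 16))
}
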