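test_that("prior-only posterior reproduces closed-form prior moments", {
  pr <- prior_set(easiness_prior_from_range(1, 23),
                  slope_prior_from_fold(4),
                  prior_spec("theta_sd", "fixed", fixed_value = 1))
  fit <- suppressWarnings(
    fit_mcmc(empty_count_data("I1"), "RPCM", priors = pr, chains = 2,
             iterations = 1000, warmup = 500, seed = 9))
  est <- fit$details$estimates
  conv <- fit$convergence
  # half-normal(0, log 4): mean = scale * sqrt(2/pi)
  target <- log(4) * sqrt(2 / pi)
  hn_sd <- log(4) * sqrt(1 - 2 / pi)
  mcse <- hn_sd / sqrt(conv$ess_bulk[conv$parameter == "slope"])
  expect_lt(abs(est["slope"] - target), 3 * mcse)
  # truncated normal easiness mean
  m <- log(12); s <- log(11)
  tn_mean <- m + s * dnorm(-m / s) / (1 - pnorm(-m / s))
  tn_sd <- sqrt(s^2 * (1 + (-m / s) * dnorm(-m / s) /
                         (1 - pnorm(-m / s)) -
                         (dnorm(-m / s) / (1 - pnorm(-m / s)))^2))
  mcse_e <- tn_sd / sqrt(conv$ess_bulk[conv$parameter == "easiness[I1]"])
  expect_lt(abs(est["easiness[I1]"] - tn_mean), 3 * mcse_e)
  # positivity constraints respected in every draw
  expect_true(all(fit$draws$values > 0))
})

test_that("same seed and config give identical draws", {
  sim <- small_sim()
  args <- list(sim$data, "2PPCM",
               priors = default_priors("variance_standardization",
                                       sim$data),
               chains = 2, iterations = 200, warmup = 100, seed = 123)
  f1 <- suppressWarnings(do.call(fit_mcmc, args))
  f2 <- suppressWarnings(do.call(fit_mcmc, args))
  expect_identical(f1$draws$values, f2$draws$values)
  expect_identical(f1$divergence_count, f2$divergence_count)
})

test_that("fit contract: shapes, posterior means, identification pins", {
  fit <- small_mcmc_fit()
  sim <- small_sim()
  expect_equal(dim(fit$draws$values), c(2L, 350L, 6L + 100L))
  # point estimates are posterior means
  flat <- poisirt:::.flat_draws(fit)
  expect_equal(unname(fit$params$easiness),
               unname(colMeans(flat[, sprintf("easiness[I%d]", 1:3)])))
  # variance standardization: theta_sd exactly 1
  expect_identical(fit$params$theta_sd, 1)
  # convergence table covers every sampled parameter
  expect_setequal(fit$convergence$parameter, fit$draws$parameter_names)
  # estimates land near the generating values (loose sanity bound)
  truth <- c(2.0, 1.7, 2.1)
  for (j in 1:3) {
    nm <- sprintf("easiness[I%d]", j)
    expect_lt(abs(fit$details$estimates[nm] - truth[j]),
              4 * fit$param_errors[nm])
  }
  # pointwise log-likelihood recorded per draw per observation
  expect_equal(dim(fit$pointwise_loglik$values),
               c(700L, nrow(sim$data$records)))
})

test_that("marker identification pins the marker slope at exactly 1", {
  sim <- small_sim()
  fit <- suppressWarnings(
    fit_mcmc(sim$data, "2PPCM", "marker",
             default_priors("marker", sim$data), chains = 2,
             iterations = 300, warmup = 150, seed = 17))
  expect_identical(unname(fit$params$slope[1]), 1)
  expect_true("theta_sd" %in% fit$draws$parameter_names)
  expect_false("slope[I1]" %in% fit$draws$parameter_names)
  comp <- poisirt:::.draw_components(fit)
  expect_true(all(comp$slope[, 1] == 1))
  expect_true(all(comp$theta_sd > 0))
})

test_that("validation errors fire before sampling", {
  sim <- small_sim()
  pr <- default_priors("variance_standardization", sim$data)
  expect_error(fit_mcmc(sim$data, chains = 1, priors = pr), "2 chains")
  expect_error(fit_mcmc(sim$data, priors = pr, iterations = 100,
                        warmup = 100), "exceed")
  expect_error(fit_mcmc(empty_count_data("I1")), "explicit prior_set")
})
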