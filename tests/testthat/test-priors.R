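test_that("easiness prior follows the log-midpoint / log-half-range rule", {
  p <- easiness_prior_from_range(1, 23)
  expect_equal(p$location, log(12))
  expect_equal(p$scale, log(11))
  expect_equal(round(p$location, 2), 2.48)
  expect_equal(round(p$scale, 2), 2.40)
  expect_equal(p$lower_bound, 0)
  expect_equal(p$family, "truncated_normal")

  p2 <- easiness_prior_from_range(0, 10)
  expect_equal(p2$location, log(6))
  expect_equal(p2$scale, log(5))

  expect_error(easiness_prior_from_range(0, 2), "manual")
  expect_error(easiness_prior_from_range(5, 5), "max_score")
})

test_that("slope prior scale is the log of the fold ceiling", {
  expect_equal(slope_prior_from_fold(4)$scale, log(4))
  expect_equal(round(slope_prior_from_fold(4)$scale, 2), 1.39)
  expect_equal(slope_prior_from_fold(exp(1))$scale, 1)
  expect_error(slope_prior_from_fold(1), "max_fold")
})

test_that("default_priors builds the documented prior sets", {
  d <- count_data(c("P1", "P1", "P2"), c("I1", "I2", "I1"),
                  c(1L, 9L, 23L))
  vs <- default_priors("variance_standardization", d)
  expect_equal(vs$easiness_prior$location, log(12))
  expect_equal(vs$easiness_prior$scale, log(11))
  expect_equal(vs$slope_prior$scale, log(4))
  expect_equal(vs$slope_prior$lower_bound, 0)
  expect_equal(vs$theta_sd_prior$family, "fixed")
  expect_equal(vs$theta_sd_prior$fixed_value, 1)

  mk <- default_priors("marker", d)
  expect_equal(mk$marker_item, "I1")
  expect_equal(mk$slope_prior$family, "normal")  # untruncated, as stated
  expect_equal(mk$slope_prior$location, 1)
  expect_equal(mk$slope_prior$scale, 1)
  expect_equal(mk$theta_sd_prior$family, "half_student_t")
  expect_equal(mk$theta_sd_prior$df, 3)
  expect_equal(mk$theta_sd_prior$scale, 2.5)

  # explicit flat easiness is accepted
  ps <- prior_set(prior_spec("easiness", "flat"), vs$slope_prior,
                  vs$theta_sd_prior)
  expect_equal(ps$easiness_prior$family, "flat")
})

test_that("log_prior_density sums free-parameter log densities", {
  d <- count_data(c("P1", "P1"), c("I1", "I2"), c(2L, 3L))
  flat <- prior_set(prior_spec("easiness", "flat"),
                    prior_spec("slope", "flat"),
                    prior_spec("theta_sd", "fixed", fixed_value = 1))
  p <- item_params(c("I1", "I2"), c(1, 2), c(0.3, 0.4))
  expect_equal(log_prior_density(flat, p), 0)

  # half-normal density at its mode: log(2 / (scale * sqrt(2*pi)))
  hp <- prior_set(prior_spec("easiness", "flat"),
                  slope_prior_from_fold(4),
                  prior_spec("theta_sd", "fixed", fixed_value = 1))
  p0 <- item_params("I1", 1, 0, model_kind = "RPCM")
  expect_equal(log_prior_density(hp, p0),
               log(2 / (log(4) * sqrt(2 * pi))))
  # outside truncation support: -Inf, not an error
  pneg <- item_params("I1", 1, -0.1, model_kind = "RPCM")
  expect_identical(log_prior_density(hp, pneg), -Inf)
})

test_that("prior sets round-trip through the JSON config format", {
  f <- withr::local_tempfile(fileext = ".json")
  d <- count_data(c("P1", "P1", "P2"), c("I1", "I2", "I1"),
                  c(1L, 9L, 23L))
  for (method in c("variance_standardization", "marker")) {
    ps <- default_priors(method, d)
    write_prior_config(ps, f)
    back <- read_prior_config(f)
    expect_equal(back, ps)
  }
  expect_error(read_prior_config({
    writeLines('{"easiness": {"family": "flat"}}', f); f
  }), "lacks block")
})

test_that("truncated prior densities integrate to 1 over their support", {
  tn <- prior_spec("slope", "truncated_normal", location = 0.3,
                   scale = 1.39, lower_bound = 0)
  ht <- prior_spec("theta_sd", "half_student_t", location = 0,
                   scale = 2.5, lower_bound = 0, df = 3)
  x <- seq(0, 80, length.out = 400001)
  h <- x[2] - x[1]
  for (spec in list(tn, ht)) {
    dens <- exp(poisirt:::prior_log_density(spec, x))
    expect_equal(sum(dens) * h, 1, tolerance = 1e-3)
  }
  # gradient matches numeric differentiation of the log density
  for (spec in list(tn, ht)) {
    xs <- c(0.2, 1, 3.5)
    num <- (poisirt:::prior_log_density(spec, xs + 1e-6) -
              poisirt:::prior_log_density(spec, xs - 1e-6)) / 2e-6
    expect_equal(poisirt:::prior_log_density_grad(spec, xs), num,
                 tolerance = 1e-5)
  }
})
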