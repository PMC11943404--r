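test_that("fitted values average the rate over draws", {
  d <- count_data(c("P1", "P2"), c("I1", "I1"), c(3L, 5L))
  # two draws with rates {2, 4} for P1 and {1, 1} for P2
  b <- matrix(c(log(2), log(4)), 2, 1)
  a <- matrix(0, 2, 1)
  th <- matrix(c(0.3, -0.5, 0.1, 0.9), 2, 2)
  fit <- manual_fit(b, a, th, d)
  fv <- fitted_values(fit, d)
  expect_equal(fv$fitted, c(3, 3))  # mean of {2, 4} (slope 0)
  expect_equal(attr(fv, "convention"), "posterior_mean_rate")
  # degenerate posterior: fitted equals exp(b + a*theta) exactly
  fit0 <- manual_fit(matrix(1.1, 3, 1), matrix(0.4, 3, 1),
                     matrix(rep(c(0.5, -1), each = 3), 3, 2), d)
  fv0 <- fitted_values(fit0, d)
  expect_equal(fv0$fitted, exp(1.1 + 0.4 * c(0.5, -1)))
})

test_that("posterior-mean rate dominates rate at posterior means (Jensen)", {
  fit <- small_mcmc_fit()
  fv <- fitted_values(fit)
  comp <- poisirt:::.draw_components(fit)
  d <- fit$data
  it <- match(d$records$item, fit$params$item_ids)
  pid <- match(d$records$person, d$persons)
  at_means <- exp(colMeans(comp$easiness)[it] +
                    colMeans(comp$slope)[it] * colMeans(comp$theta)[pid])
  expect_true(all(fv$fitted >= at_means - 1e-10))
  # MML path uses the plugin convention
  fvm <- fitted_values(small_mml_fit(), d)
  expect_equal(attr(fvm, "convention"), "plugin_at_point_estimates")
  expect_true(all(fvm$fitted > 0))
})

test_that("dispersion implements the mean Pearson-contribution formula", {
  d <- count_data(c("P1", "P2", "P1"), c("I1", "I1", "I2"),
                  c(2L, 4L, 6L))
  fv <- structure(data.frame(person = d$records$person,
                             item = d$records$item,
                             observed = d$records$count,
                             fitted = c(1, 4, 6)),
                  class = c("fitted_values", "data.frame"))
  rep_ <- dispersion(d, fv)
  expect_equal(rep_$overall_phi, mean(c((2 - 1)^2 / 1, 0, 0)))
  expect_equal(unname(rep_$per_item_phi),
               c(mean(c(1, 0)), 0))
  expect_equal(rep_$n_observations_used, 3L)
  # overall = record-count-weighted mean of per-item values
  w <- table(factor(d$records$item, levels = d$items))
  expect_equal(rep_$overall_phi,
               sum(rep_$per_item_phi * as.vector(w)) / sum(w))
  # y identical to yhat: zero
  fv0 <- fv; fv0$fitted <- as.numeric(fv0$observed)
  expect_equal(dispersion(d, fv0)$overall_phi, 0)
  # misaligned or non-positive fitted values are rejected
  expect_error(dispersion(d, fv[c(2, 1, 3), ]), "aligned")
  fvz <- fv; fvz$fitted[1] <- 0
  expect_error(dispersion(d, fvz), "positive")
})

test_that("Pearson residuals and the phi identity", {
  d <- count_data(c("P1", "P2"), c("I1", "I1"), c(4L, 3L))
  fv <- structure(data.frame(person = d$records$person,
                             item = d$records$item,
                             observed = c(4L, 3L), fitted = c(1, 3)),
                  class = c("fitted_values", "data.frame"))
  r <- pearson_residuals(d, fv)
  expect_equal(r$residual, c(3, 0))
  expect_equal(mean(r$residual^2), dispersion(d, fv)$overall_phi)
})

test_that("phi calibrates to 1 on equidispersed data, below 1 when thinned", {
  set.seed(81)
  lam <- runif(10000, 2, 12)
  y <- rpois(10000, lam)
  d <- count_data(sprintf("P%d", 1:10000), rep("I1", 10000), y)
  fv <- structure(data.frame(person = d$records$person, item = "I1",
                             observed = y, fitted = lam),
                  class = c("fitted_values", "data.frame"))
  phi <- dispersion(d, fv)$overall_phi
  expect_gt(phi, 0.9); expect_lt(phi, 1.1)
  # binomial thinning of a shifted Poisson gives variance < mean
  y2 <- rbinom(10000, size = 20, prob = lam / 25)
  fv2 <- fv; fv2$observed <- y2; fv2$fitted <- 20 * lam / 25
  d2 <- count_data(d$records$person, d$records$item, y2)
  expect_lt(dispersion(d2, fv2)$overall_phi, 1)
})

test_that("expected frequencies sum the Poisson mass over fitted rates", {
  fv <- structure(data.frame(person = "P1", item = "I1", observed = 2L,
                             fitted = 1),
                  class = c("fitted_values", "data.frame"))
  tab <- expected_frequencies(fv, max_score = 10)
  expect_equal(tab$expected[tab$score == 0], exp(-1))
  expect_equal(sum(tab$observed), 1L)
  # mass conservation at a generous truncation point
  set.seed(82)
  fv2 <- structure(data.frame(person = sprintf("P%d", 1:50), item = "I1",
                              observed = rpois(50, 6),
                              fitted = runif(50, 3, 9)),
                   class = c("fitted_values", "data.frame"))
  mx <- ceiling(max(fv2$fitted) + 10 * sqrt(max(fv2$fitted)))
  tab2 <- expected_frequencies(fv2, max_score = mx)
  expect_gte(sum(tab2$expected), 0.999 * 50)
  expect_equal(sum(tab2$observed), 50L)
  # by_item splits the table
  fv3 <- rbind(fv, fv)
  fv3$item <- c("I1", "I2")
  tab3 <- expected_frequencies(fv3, max_score = 5, by_item = TRUE)
  expect_setequal(unique(tab3$item), c("I1", "I2"))
  expect_error(expected_frequencies(fv, max_score = 1), "at least")
})

test_that("predictive checks: degenerate posterior equals Poisson intervals", {
  d <- count_data(c("P1", "P2"), c("I1", "I1"), c(3L, 50L))
  lam_hat <- 4
  fit <- manual_fit(matrix(log(lam_hat), 2000, 1), matrix(0, 2000, 1),
                    matrix(0, 2000, 2), d)
  ppc <- posterior_predictive_check(fit, d, seed = 5)
  # oracle: the exact smallest integer interval with >= 95% Poisson(4)
  # mass, found by enumeration
  best <- c(0L, 100L)
  for (l in 0:20) for (h in l:30) {
    if (sum(dpois(l:h, lam_hat)) >= 0.95 && h - l < diff(best)) {
      best <- c(l, h)
    }
  }
  for (r in 1:2) {
    expect_lte(abs(ppc$intervals$lo[r] - best[1]), 1)
    expect_lte(abs(ppc$intervals$hi[r] - best[2]), 1)
    covered <- sum(dpois(ppc$intervals$lo[r]:ppc$intervals$hi[r],
                         lam_hat))
    expect_gt(covered, 0.93)
  }
  expect_equal(ppc$outside_count, 1L)  # 50 is far outside Poisson(4)
  expect_equal(ppc$outside_ids$person, "P2")
  # determinism
  ppc2 <- posterior_predictive_check(fit, d, seed = 5)
  expect_identical(ppc$intervals, ppc2$intervals)
  # grouping summaries are consistent with the interval table
  ppc_item <- posterior_predictive_check(fit, d, grouping = "by_item",
                                         seed = 5)
  expect_equal(sum(ppc_item$grouped$outside), ppc$outside_count)
  expect_equal(ppc$outside_count, nrow(ppc$outside_ids))
})

test_that("MML fits are redirected to the parametric bootstrap check", {
  fit <- small_mml_fit()
  expect_error(posterior_predictive_check(fit), "parametric_bootstrap")
  pb <- parametric_bootstrap_check(fit, n_draws = 300, seed = 3)
  expect_s3_class(pb, "ppc_report")
  frac <- pb$outside_count / nrow(pb$intervals)
  expect_lt(frac, 0.15)
})
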