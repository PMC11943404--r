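test_that("item response curves evaluate the model on the grid", {
  p <- item_params(c("I1", "I2"), c(2.06, 1.4), c(0.34, 0.5))
  ct <- item_response_curve(p, seq(-3, 3, 0.5))
  expect_equal(ct$values[ct$theta == 0, ], exp(p$easiness))
  expect_equal(round(ct$values[ct$theta == 0, "I1"], 1), 7.8,
               ignore_attr = TRUE)
  expect_true(all(ct$values >= 0))
  tidy <- as.data.frame(ct)
  expect_named(tidy, c("theta", "item_id", "value", "kind"))
  expect_equal(nrow(tidy), 2L * length(ct$theta))
  expect_error(item_response_curve(p, c(1, 0.5)), "increasing")
})

test_that("equal-slope curves never cross; unequal slopes do", {
  grid <- seq(-3, 3, 0.01)
  eq <- item_params(c("I1", "I2"), c(2, 1.5), 0.4, model_kind = "RPCM")
  vals <- item_response_curve(eq, grid)$values
  expect_true(all(vals[, 1] > vals[, 2]))
  uneq <- item_params(c("I1", "I2"), c(2, 1.5), c(0.1, 0.9))
  dv <- item_response_curve(uneq, grid)$values
  expect_true(any(dv[, 1] > dv[, 2]) && any(dv[, 1] < dv[, 2]))
})

test_that("item information equals the Fisher-information oracle", {
  expect_equal(item_information(1.7, 0, -2), 0)
  expect_equal(item_information(1.7, 0, 2), 0)
  expect_equal(item_information(0, 1, 0), 1)
  set.seed(71)
  for (i in 1:20) {
    b <- runif(1, 0, 2.5); a <- runif(1, 0.05, 0.8)
    th <- runif(1, -2, 2)
    expect_lt(abs(item_information(b, a, th) -
                    oracle_fisher_information(b, a, th)), 1e-4)
  }
})

test_that("test information is additive and ordered as documented", {
  p <- random_params(4)
  th <- 0.3
  expect_equal(test_information(p, th),
               sum(item_information(p$easiness, p$slope, th)))
  # additivity over an arbitrary partition
  p_a <- item_params(p$item_ids[1:2], p$easiness[1:2], p$slope[1:2])
  p_b <- item_params(p$item_ids[3:4], p$easiness[3:4], p$slope[3:4])
  expect_equal(test_information(p_a, th) + test_information(p_b, th),
               test_information(p, th))
  # monotone increasing in theta for positive slopes
  grid <- seq(-3, 3, 0.1)
  expect_true(all(diff(test_information(p, grid)) > 0))
  # RPCM: information ordering follows easiness ordering at any theta
  set.seed(72)
  for (i in 1:10) {
    rp <- random_params(4, model_kind = "RPCM")
    th_i <- runif(1, -2, 2)
    info <- item_information(rp$easiness, rp$slope, th_i)
    expect_equal(order(info), order(rp$easiness))
  }
})

test_that("empirical reliability follows the variance-ratio definition", {
  est <- data.frame(person_id = paste0("P", 1:4),
                    theta = c(-1, 0, 0.5, 1.5), sd = rep(0, 4))
  class(est) <- c("ability_estimates", "data.frame")
  expect_equal(empirical_reliability(est), 1)
  est$sd <- rep(sqrt(var(est$theta)), 4)
  expect_equal(empirical_reliability(est), 0.5)
  # invariant to location shifts of the point estimates
  est2 <- est
  est2$theta <- est$theta + 100
  expect_equal(empirical_reliability(est2), empirical_reliability(est))
  # degenerate case errors
  bad <- data.frame(person_id = c("A", "B"), theta = c(1, 1),
                    sd = c(0, 0))
  expect_error(empirical_reliability(bad), "undefined")
  expect_error(empirical_reliability(est[1, ]), "2 persons")
})

test_that("person reliability decreases with the person's error", {
  est <- data.frame(person_id = paste0("P", 1:3),
                    theta = c(-1, 0, 1), sd = c(0, 0.5, 1))
  class(est) <- c("ability_estimates", "data.frame")
  pr <- person_reliability(est)
  expect_equal(unname(pr[1]), 1)
  expect_true(all(diff(pr) < 0))
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("person reliability increases with ability in the 2PPCM", {
  ip <- item_params(paste0("I", 1:3), c(2, 1.7, 2.1), c(0.3, 0.4, 0.35))
  sim <- simulate_dataset(sim_config(200, ip, seed = 73))
  sc <- eap_scores(sim$data, ip)
  pr <- person_reliability(sc)
  expect_gt(cor(sc$theta, pr, method = "spearman"), 0)
})
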