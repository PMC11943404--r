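test_that("pointwise log-likelihood matches brute-force recomputation", {
  d <- count_data(c("P1", "P2"), c("I1", "I1"), c(3L, 5L))
  b <- matrix(c(1.0, 1.4), 2, 1)
  a <- matrix(c(0.3, 0.5), 2, 1)
  th <- matrix(c(0.2, -0.3, 1.1, 0.4), 2, 2)
  fit <- manual_fit(b, a, th, d)
  ll <- suppressWarnings(pointwise_loglik(fit, d))  # 2 draws: toy case
  manual <- matrix(NA_real_, 2, 2)
  for (s in 1:2) for (r in 1:2) {
    manual[s, r] <- dpois(d$records$count[r],
                          exp(b[s, 1] + a[s, 1] * th[s, r]), log = TRUE)
  }
  expect_equal(ll$values, manual)
  # single draw row equals the joint per-record terms
  expect_equal(sum(ll$values[1, ]),
               joint_log_likelihood(d, item_params("I1", b[1], a[1]),
                                    c(P1 = th[1, 1], P2 = th[1, 2])))
})

test_that("WAIC reproduces hand-computable cases", {
  # constant matrix: no posterior variance
  const <- matrix(log(0.3), 50, 4)
  w <- waic(const)
  expect_equal(w$elpd, 4 * log(0.3))
  expect_equal(w$p_eff, 0)
  expect_equal(w$se, 0)
  # 2-draw single-observation matrix
  ll2 <- matrix(c(log(0.5), log(0.25)), 2, 1)
  w2 <- waic(ll2)
  expect_equal(w2$elpd, log(0.375) - var(c(log(0.5), log(0.25))))
  expect_equal(w2$p_eff, var(c(log(0.5), log(0.25))))
  # penalty is non-negative: elpd_waic <= sum lppd
  set.seed(91)
  llr <- matrix(rnorm(500, -2, 0.5), 100, 5)
  wr <- waic(llr)
  lppd <- apply(llr, 2, function(x) log(mean(exp(x))))
  expect_lte(wr$elpd, sum(lppd))
  expect_error(waic(matrix(-1, 1, 3)), "2 draws")
})

test_that("LOO agrees with WAIC where it must and penalizes elsewhere", {
  const <- matrix(log(0.3), 50, 4)
  expect_equal(loo_is(const)$elpd, waic(const)$elpd)
  expect_equal(loo_is(const, smoothing = "pareto")$elpd,
               waic(const)$elpd)
  set.seed(92)
  llr <- matrix(rnorm(2000, -2, 0.3), 400, 5)
  lr <- loo_is(llr)
  lppd <- apply(llr, 2, function(x) log(mean(exp(x))))
  expect_lte(lr$elpd, sum(lppd))
  expect_length(lr$flagged, 5)
  expect_error(loo_is(matrix(c(-1, NaN), 2, 1)), "non-finite")
})

test_that("LOO and WAIC agree on a well-specified fit", {
  fit <- small_mcmc_fit()
  ll <- fit$pointwise_loglik
  w <- waic(ll); l <- loo_is(ll)
  expect_lt(abs(l$elpd - w$elpd), w$se)
  expect_gt(l$p_eff, 0)
})

test_that("compare_elpd: self-comparison, antisymmetry, mismatch", {
  fit <- small_mcmc_fit()
  ll <- fit$pointwise_loglik
  self <- compare_elpd(ll, ll)
  expect_equal(self$elpd_diff, 0)
  expect_equal(self$se_diff, 0)
  rp <- small_rpcm_fit()$pointwise_loglik
  ab <- compare_elpd(ll, rp, names = c("2ppcm", "rpcm"))
  ba <- compare_elpd(rp, ll, names = c("rpcm", "2ppcm"))
  expect_equal(ab$elpd_diff, -ba$elpd_diff)
  expect_equal(ab$se_diff, ba$se_diff)
  expect_error(compare_elpd(ll$values, ll$values[, 1:10]), "mismatch")
  # se_diff = 0 iff pointwise differences are constant
  shifted <- ll$values + 0.37
  cs <- compare_elpd(shifted, ll$values)
  expect_equal(cs$se_diff, 0, tolerance = 1e-8)
  expect_equal(cs$elpd_diff, ncol(ll$values) * 0.37, tolerance = 1e-6)
})

test_that("slope contrasts are antisymmetric and collapse for the RPCM", {
  fit <- small_mcmc_fit()
  ct <- slope_contrasts(fit)
  expect_equal(nrow(ct), 3L)
  expect_true(all(ct$ci_low <= ct$mean & ct$mean <= ct$ci_high))
  # antisymmetry: recompute a swapped pair directly from the draws
  comp <- poisirt:::.draw_components(fit)
  d12 <- comp$slope[, 1] - comp$slope[, 2]
  row12 <- ct[ct$item_j == "I1" & ct$item_k == "I2", ]
  expect_equal(row12$mean, mean(d12))
  expect_equal(row12$p_gt_0, 1 - mean(-d12 > 0))
  expect_equal(unname(unlist(row12[c("ci_low", "ci_high")])),
               unname(-rev(quantile(-d12, c(0.025, 0.975), type = 7))))
  # RPCM: all differences identically zero, with a note
  ctr <- slope_contrasts(small_rpcm_fit())
  expect_true(all(ctr$mean == 0 & ctr$ci_low == 0 & ctr$ci_high == 0))
  expect_true(all(ctr$zero_in_interval))
  expect_match(attr(ctr, "note"), "RPCM")
})
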