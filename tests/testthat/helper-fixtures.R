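# Shared (lazily computed, memoized) fits so expensive MCMC runs are done
# once per test session.

.fixture_cache <- new.env(parent = emptyenv())

.memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# moderate 2PPCM simulation + MCMC fit used by scoring/diagnostic/
# comparison tests (kept small for speed; recovery-grade runs live in
# test-acceptance.R)
small_sim <- function() {
  .memo("small_sim", {
    ip <- item_params(paste0("I", 1:3), c(2.0, 1.7, 2.1),
                      c(0.3, 0.4, 0.35), model_kind = "2PPCM")
    simulate_dataset(sim_config(100, ip, seed = 301))
  })
}

small_mcmc_fit <- function() {
  .memo("small_mcmc_fit", {
    sim <- small_sim()
    suppressWarnings(fit_mcmc(sim$data, "2PPCM",
                              priors = default_priors(
                                "variance_standardization", sim$data),
                              chains = 2, iterations = 700, warmup = 350,
                              seed = 99))
  })
}

small_rpcm_fit <- function() {
  .memo("small_rpcm_fit", {
    sim <- small_sim()
    suppressWarnings(fit_mcmc(sim$data, "RPCM",
                              priors = default_priors(
                                "variance_standardization", sim$data),
                              chains = 2, iterations = 700, warmup = 350,
                              seed = 99))
  })
}

small_mml_fit <- function() {
  .memo("small_mml_fit", {
    sim <- small_sim()
    fit_mml(sim$data, "2PPCM")
  })
}

# hand-built degenerate MCMC-style fit whose "posterior" is a handful of
# known draws; used to test draw-consuming operations against arithmetic
manual_fit <- function(b_draws, a_draws, th_draws, data) {
  m <- ncol(b_draws); n <- ncol(th_draws); S <- nrow(b_draws)
  items <- data$items
  layout <- poisirt:::par_layout(items, "2PPCM",
                                 "variance_standardization")
  par_names <- c(sprintf("easiness[%s]", items),
                 sprintf("slope[%s]", items),
                 sprintf("theta[%s]", data$persons))
  values <- array(NA_real_, dim = c(1L, S, 2L * m + n),
                  dimnames = list(NULL, NULL, par_names))
  values[1L, , ] <- cbind(b_draws, a_draws, th_draws)
  draws <- structure(list(values = values, parameter_names = par_names,
                          n_warmup_discarded = 0L, seed = 1L),
                     class = "poisirt_draws")
  params <- item_params(items, colMeans(b_draws), colMeans(a_draws),
                        model_kind = "2PPCM")
  flat <- matrix(values, nrow = S, dimnames = list(NULL, par_names))
  poisirt:::new_fit("MCMC", params,
                    apply(flat, 2L, stats::sd),
                    cbind(`2.5%` = apply(flat, 2L, stats::quantile, 0.025),
                          `97.5%` = apply(flat, 2L, stats::quantile,
                                          0.975)),
                    data.frame(parameter = par_names, rhat = NA_real_,
                               ess_bulk = NA_real_, ess_tail = NA_real_),
                    data, draws = draws, divergence_applicable = TRUE,
                    seed = 1L,
                    details = list(layout = layout,
                                   estimates = colMeans(flat),
                                   model_kind = "2PPCM",
                                   identification =
                                     "variance_standardization"))
}
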