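# Independent brute-force oracles used across test files. These never call
# the code paths they check: marginal likelihoods and EAP moments come from
# dense trapezoid integration over a theta grid, information from numeric
# differentiation plus explicit expectation.

# dense-grid marginal log-likelihood: integrate each person's likelihood
# against the N(0, theta_sd^2) density over theta in [-8, 8] * theta_sd
oracle_marginal_ll <- function(data, params, n_grid = 4001) {
  grid <- seq(-8, 8, length.out = n_grid) * params$theta_sd
  dens <- stats::dnorm(grid, 0, params$theta_sd)
  h <- grid[2L] - grid[1L]
  total <- 0
  for (p in data$persons) {
    rows <- which(data$records$person == p)
    f <- dens
    for (r in rows) {
      j <- match(data$records$item[r], params$item_ids)
      lam <- exp(params$easiness[j] + params$slope[j] * grid)
      f <- f * stats::dpois(data$records$count[r], lam)
    }
    # trapezoid rule
    total <- total + log(h * (sum(f) - (f[1L] + f[n_grid]) / 2))
  }
  total
}

# dense-grid posterior moments of theta for one person
oracle_eap <- function(counts, easiness, slope, theta_sd = 1,
                       n_grid = 8001) {
  grid <- seq(-8, 8, length.out = n_grid) * theta_sd
  f <- stats::dnorm(grid, 0, theta_sd)
  for (j in seq_along(counts)) {
    f <- f * stats::dpois(counts[j], exp(easiness[j] + slope[j] * grid))
  }
  w <- f / sum(f)
  mu <- sum(w * grid)
  list(mean = mu, sd = sqrt(sum(w * grid^2) - mu^2), grid = grid, w = w)
}

# grid-based ML estimate of theta for one person (no population prior)
oracle_theta_ml <- function(counts, easiness, slope, n_grid = 8001) {
  grid <- seq(-8, 8, length.out = n_grid)
  ll <- numeric(n_grid)
  for (j in seq_along(counts)) {
    ll <- ll + stats::dpois(counts[j], exp(easiness[j] + slope[j] * grid),
                            log = TRUE)
  }
  grid[which.max(ll)]
}

# Fisher information about theta by numeric second differentiation of the
# Poisson log-likelihood, expectation taken over counts 0..500
oracle_fisher_information <- function(easiness, slope, theta, h = 1e-3) {
  ks <- 0:500
  lam0 <- exp(easiness + slope * theta)
  pk <- stats::dpois(ks, lam0)
  d2 <- vapply(ks, function(k) {
    ll <- function(th) stats::dpois(k, exp(easiness + slope * th),
                                    log = TRUE)
    (ll(theta + h) - 2 * ll(theta) + ll(theta - h)) / h^2
  }, numeric(1))
  -sum(pk * d2)
}

# random small count dataset for property-style checks
random_toy_data <- function(n_persons = 3, n_items = 3, max_count = 12) {
  persons <- rep(sprintf("P%d", seq_len(n_persons)), each = n_items)
  items <- rep(sprintf("I%d", seq_len(n_items)), times = n_persons)
  count_data(persons, items,
             sample.int(max_count + 1L, n_persons * n_items,
                        replace = TRUE) - 1L)
}

# toy dataset whose counts come from the model itself (theta ~ N(0, 1)),
# with parameters in the realistic fluency range; returns data + params
random_toy_case <- function(n_persons = 2, n_items = 3) {
  p <- item_params(sprintf("I%d", seq_len(n_items)),
                   easiness = stats::runif(n_items, 0.5, 2.0),
                   slope = stats::runif(n_items, 0.1, 0.5))
  th <- stats::rnorm(n_persons)
  persons <- rep(sprintf("P%d", seq_len(n_persons)), each = n_items)
  items <- rep(p$item_ids, times = n_persons)
  lam <- exp(p$easiness[items] + p$slope[items] * rep(th, each = n_items))
  list(data = count_data(persons, items, stats::rpois(length(lam), lam)),
       params = p)
}

random_params <- function(n_items = 3, model_kind = "2PPCM") {
  slopes <- stats::runif(n_items, 0.1, 0.8)
  if (model_kind == "RPCM") slopes <- rep(slopes[1L], n_items)
  item_params(sprintf("I%d", seq_len(n_items)),
              easiness = stats::runif(n_items, 0.5, 2.5),
              slope = slopes, model_kind = model_kind)
}
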