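# Bayesian backend: Hamiltonian Monte Carlo with diagonal mass-matrix and
# dual-averaging step-size adaptation (both confined to warmup). The
# sampler targets the joint posterior of the free item parameters and the
# per-person abilities; positivity constraints implied by truncated priors
# (and by theta_sd itself) are handled by log transforms with the
# appropriate Jacobian terms.

#' Empty count-data container for prior-only runs
#'
#' Builds a `count_data` object with the given items but no records and
#' no persons, so that [fit_mcmc] samples the prior (the likelihood term
#' is an empty sum). Useful for prior predictive exploration and for
#' validating the sampler against closed-form prior moments.
#'
#' @param item_ids character vector of item names.
#' @return A degenerate [count_data] with zero records.
#' @export
empty_count_data <- function(item_ids) {
  structure(list(
    records = data.frame(person = character(0), item = character(0),
                         count = integer(0), stringsAsFactors = FALSE),
    persons = character(0),
    items = as.character(item_ids)
  ), class = "count_data")
}

# rowsum guaranteed to produce one row per group level 1..k, in order
.rowsum_full <- function(x, group, k) {
  as.vector(rowsum(c(x, rep(0, k)), c(group, seq_len(k))))
}

# Build the log-posterior-and-gradient closure for one model config.
# Parameter vector v = c(u_item (unconstrained), theta). Returns list
# with lpg(v), dimensions, transform info, and init().
.mcmc_model <- function(data, model_kind, identification, priors,
                        marker_item = NULL) {
  items <- data$items
  m <- length(items)
  n <- length(data$persons)
  layout <- par_layout(items, model_kind, identification,
                       if (!is.null(priors$marker_item))
                         priors$marker_item else marker_item)
  P <- layout$n_free
  it <- item_idx(data)
  pid <- person_idx(data)
  y <- data$records$count
  sum_lgam <- sum(lgamma(y + 1))
  has_sd <- length(layout$idx_sd) > 0L

  # prior spec per free item parameter, aligned with layout$names
  specs <- vector("list", P)
  for (k in layout$idx_easiness) specs[[k]] <- priors$easiness_prior
  for (k in layout$idx_slope) specs[[k]] <- priors$slope_prior
  for (k in layout$idx_sd) specs[[k]] <- priors$theta_sd_prior
  is_log <- vapply(seq_len(P), function(k) {
    if (k %in% layout$idx_sd) return(TRUE)  # sd always positive
    !is.null(specs[[k]]$lower_bound)
  }, logical(1))
  lb <- vapply(seq_len(P), function(k) {
    b <- specs[[k]]$lower_bound
    if (is.null(b)) 0 else b
  }, numeric(1))

  to_x <- function(u) ifelse(is_log, lb + exp(u), u)
  to_u <- function(x) ifelse(is_log, log(pmax(x - lb, 1e-6)), x)

  expand_slopes <- function(x) {
    if (model_kind == "RPCM") {
      rep(if (length(layout$idx_slope)) x[layout$idx_slope] else 1, m)
    } else if (identification == "marker") {
      s <- numeric(m)
      s[match(layout$marker_item, items)] <- 1
      s[match(layout$slope_free_ids, items)] <- x[layout$idx_slope]
      s
    } else x[layout$idx_slope]
  }

  lpg <- function(v) {
    u <- v[seq_len(P)]
    th <- v[P + seq_len(n)]
    x <- to_x(u)
    b <- x[layout$idx_easiness]
    a <- expand_slopes(x)
    sigma <- if (has_sd) x[layout$idx_sd] else 1
    lp <- 0
    g_x <- numeric(P)
    if (length(y)) {
      eta <- b[it] + a[it] * th[pid]
      if (any(eta > 500)) {
        return(list(lp = -Inf, grad = rep(NA_real_, P + n)))
      }
      lam <- exp(eta)
      lp <- lp + sum(y * eta) - sum(lam) - sum_lgam
      resid <- y - lam
      g_x[layout$idx_easiness] <- .rowsum_full(resid, it, m)
      ga_items <- .rowsum_full(th[pid] * resid, it, m)
      if (length(layout$idx_slope)) {
        g_x[layout$idx_slope] <- if (model_kind == "RPCM") {
          sum(ga_items)
        } else if (identification == "marker") {
          ga_items[match(layout$slope_free_ids, items)]
        } else ga_items
      }
      g_th <- .rowsum_full(a[it] * resid, pid, n)
    } else {
      g_th <- numeric(n)
    }
    # population model for theta
    if (n) {
      lp <- lp + sum(stats::dnorm(th, 0, sigma, log = TRUE))
      g_th <- g_th - th / sigma^2
      if (has_sd) {
        g_x[layout$idx_sd] <- g_x[layout$idx_sd] +
          sum(th^2) / sigma^3 - n / sigma
      }
    }
    # priors on free item parameters
    for (k in seq_len(P)) {
      lp <- lp + prior_log_density(specs[[k]], x[k])
      g_x[k] <- g_x[k] + prior_log_density_grad(specs[[k]], x[k])
    }
    # chain rule + Jacobian for log-transformed components
    g_u <- ifelse(is_log, g_x * (x - lb) + 1, g_x)
    lp <- lp + sum(u[is_log])
    list(lp = lp, grad = c(g_u, g_th))
  }

  init <- function() {
    if (length(y)) {
      item_means <- .rowsum_full(y, it, m) / .rowsum_full(rep(1, length(y)),
                                                          it, m)
      b0 <- log(item_means + 0.5) + stats::rnorm(m, 0, 0.1)
    } else {
      b0 <- pmax(1, lb[layout$idx_easiness] + 1) + stats::rnorm(m, 0, 0.1)
    }
    x0 <- numeric(P)
    x0[layout$idx_easiness] <- pmax(b0, lb[layout$idx_easiness] + 0.1)
    if (length(layout$idx_slope)) {
      s0 <- if (identification == "marker") 1 else 0.5
      x0[layout$idx_slope] <- s0 * exp(stats::rnorm(length(layout$idx_slope),
                                                    0, 0.1))
    }
    if (has_sd) x0[layout$idx_sd] <- exp(stats::rnorm(1, 0, 0.1))
    c(to_u(x0), stats::rnorm(n, 0, 0.2))
  }

  list(lpg = lpg, init = init, layout = layout, to_x = to_x, P = P, n = n,
       expand_slopes = expand_slopes, has_sd = has_sd)
}

.find_reasonable_eps <- function(v, lpg, inv_mass) {
  eps <- 0.1
  d <- length(v)
  p0 <- stats::rnorm(d) / sqrt(inv_mass)
  cur <- lpg(v)
  H0 <- cur$lp - 0.5 * sum(p0^2 * inv_mass)
  step_ratio <- function(eps) {
    p <- p0 + 0.5 * eps * cur$grad
    v1 <- v + eps * inv_mass * p
    nxt <- lpg(v1)
    if (!is.finite(nxt$lp) || any(!is.finite(nxt$grad))) return(0)
    p <- p + 0.5 * eps * nxt$grad
    exp(nxt$lp - 0.5 * sum(p^2 * inv_mass) - H0)
  }
  r <- step_ratio(eps)
  dir <- if (r > 0.5) 1 else -1
  for (i in 1:50) {
    eps2 <- eps * 2^dir
    r2 <- step_ratio(eps2)
    if ((dir == 1 && r2 < 0.5) || (dir == -1 && r2 > 0.5) || eps2 < 1e-8 ||
        eps2 > 1e3) break
    eps <- eps2
  }
  eps
}

.run_hmc_chain <- function(model, chain_seed, iterations, warmup,
                           target_accept, l_max, divergence_threshold = 50) {
  set.seed(chain_seed)
  lpg <- model$lpg
  d <- model$P + model$n
  v <- model$init()
  inv_mass <- rep(1, d)
  eps <- .find_reasonable_eps(v, lpg, inv_mass)
  mu <- log(10 * eps)
  log_eps_bar <- 0; h_bar <- 0; da_count <- 0L
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  w1 <- floor(0.25 * warmup); w2 <- floor(0.75 * warmup)
  mass_window <- matrix(NA_real_, max(w2 - w1, 1L), d)
  n_keep <- iterations - warmup
  kept <- matrix(NA_real_, n_keep, d)
  divergences <- 0L
  accept_sum <- 0
  l_min <- max(1L, l_max %/% 2L)
  for (iter in seq_len(iterations)) {
    L <- if (l_max > l_min) sample(l_min:l_max, 1L) else l_max
    p0 <- stats::rnorm(d) / sqrt(inv_mass)
    cur <- lpg(v)
    H0 <- cur$lp - 0.5 * sum(p0^2 * inv_mass)
    p <- p0 + 0.5 * eps * cur$grad
    vn <- v
    ok <- TRUE
    for (l in seq_len(L)) {
      vn <- vn + eps * inv_mass * p
      nxt <- lpg(vn)
      if (!is.finite(nxt$lp) || any(!is.finite(nxt$grad))) {
        ok <- FALSE; break
      }
      p <- p + (if (l < L) eps else 0.5 * eps) * nxt$grad
    }
    if (ok) {
      H1 <- nxt$lp - 0.5 * sum(p^2 * inv_mass)
      dH <- H1 - H0
      alpha <- if (is.finite(dH)) min(1, exp(dH)) else 0
      div <- !is.finite(dH) || dH < -divergence_threshold
    } else {
      alpha <- 0
      div <- TRUE
    }
    if (stats::runif(1) < alpha) v <- vn
    if (iter <= warmup) {
      da_count <- da_count + 1L
      h_bar <- (1 - 1 / (da_count + t0)) * h_bar +
        (target_accept - alpha) / (da_count + t0)
      log_eps <- mu - sqrt(da_count) / gamma * h_bar
      w <- da_count^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      if (iter > w1 && iter <= w2) mass_window[iter - w1, ] <- v
      if (iter == w2 && w2 > w1 + 2L) {
        vv <- apply(mass_window[seq_len(w2 - w1), , drop = FALSE], 2L,
                    stats::var)
        W <- w2 - w1
        inv_mass <- (W / (W + 5)) * vv + 1e-3 * (5 / (W + 5))
        inv_mass[inv_mass <= 0 | !is.finite(inv_mass)] <- 1e-3
        eps <- .find_reasonable_eps(v, lpg, inv_mass)
        mu <- log(10 * eps)
        log_eps_bar <- 0; h_bar <- 0; da_count <- 0L
      }
      if (iter == warmup) eps <- exp(log_eps_bar)
    } else {
      kept[iter - warmup, ] <- v
      if (div) divergences <- divergences + 1L
      accept_sum <- accept_sum + alpha
    }
  }
  list(draws = kept, divergences = divergences,
       mean_accept = accept_sum / n_keep, step_size = eps)
}

#' Fit a count IRT model by MCMC
#'
#' Samples the joint posterior of the free item parameters and the
#' per-person abilities theta_i (with theta_i ~ Normal(0, theta_sd) as
#' part of the model) under the supplied priors, using Hamiltonian Monte
#' Carlo with dual-averaging step-size and diagonal mass-matrix
#' adaptation confined to the warmup phase. Draws are reproducible from
#' `seed`; chains run sequentially with seeds derived from it.
#'
#' Point estimates are posterior means. The pointwise log-likelihood
#' (one Poisson log-pmf per post-warmup draw per observation,
#' conditional on that draw's theta) is recorded for WAIC/LOO, and
#' rank-normalized split R-hat plus bulk/tail ESS are computed for every
#' sampled parameter. R-hat above 1.01 or ESS below 400 triggers a
#' warning, not a failure. Divergent transitions (energy error beyond 50
#' on the log scale) are counted post warmup.
#'
#' @param data a [count_data] object (possibly [empty_count_data] for a
#'   prior-only run).
#' @param model_kind `"RPCM"` or `"2PPCM"`.
#' @param identification `"variance_standardization"` or `"marker"`.
#' @param priors a [prior_set]; defaults to [default_priors] for the
#'   chosen identification method.
#' @param chains number of chains (>= 2, default 4).
#' @param iterations iterations per chain including warmup (default 2000).
#' @param warmup warmup iterations per chain (default 1000), discarded.
#' @param seed integer seed (required for reproducibility).
#' @param step_control list of sampler knobs: `target_accept` (default
#'   0.9; raise towards 0.99 to take smaller steps, the analogue of a
#'   stricter step-size control), `max_leapfrog` (default 16).
#' @return A `poisirt_fit` with `method = "MCMC"`: posterior-mean
#'   item parameters, posterior SDs, 2.5%/97.5% intervals, the draws
#'   array, pointwise log-likelihood, per-parameter convergence table
#'   and divergence count.
#' @export
fit_mcmc <- function(data, model_kind = c("2PPCM", "RPCM"),
                     identification = c("variance_standardization",
                                        "marker"),
                     priors = NULL, chains = 4, iterations = 2000,
                     warmup = 1000, seed = 1, step_control = list()) {
  model_kind <- match.arg(model_kind)
  identification <- match.arg(identification)
  stopifnot(inherits(data, "count_data"))
  if (chains < 2) stop("need at least 2 chains")
  if (iterations <= warmup) stop("iterations must exceed warmup")
  if (is.null(priors)) {
    priors <- if (nrow(data$records)) {
      default_priors(identification, data)
    } else stop("prior-only runs require an explicit prior_set")
  }
  if (identification == "marker" && is.null(priors$marker_item)) {
    priors$marker_item <- data$items[1L]
  }
  target_accept <- if (is.null(step_control$target_accept)) 0.9 else
    step_control$target_accept
  l_max <- if (is.null(step_control$max_leapfrog)) 16L else
    as.integer(step_control$max_leapfrog)

  model <- .mcmc_model(data, model_kind, identification, priors)
  layout <- model$layout
  n <- model$n
  P <- model$P
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  n_keep <- iterations - warmup
  par_names <- c(layout$names,
                 if (n) sprintf("theta[%s]", data$persons))
  values <- array(NA_real_, dim = c(chains, n_keep, P + n),
                  dimnames = list(NULL, NULL, par_names))
  divergences <- 0L
  accept <- numeric(chains)
  for (c in seq_len(chains)) {
    res <- .run_hmc_chain(model, chain_seeds[c], iterations, warmup,
                          target_accept, l_max)
    # store on the constrained (reporting) scale
    con <- res$draws
    if (P) con[, seq_len(P)] <- t(apply(res$draws[, seq_len(P),
                                                  drop = FALSE], 1L,
                                        model$to_x))
    values[c, , ] <- con
    divergences <- divergences + res$divergences
    accept[c] <- res$mean_accept
  }
  draws <- structure(list(values = values, parameter_names = par_names,
                          n_warmup_discarded = as.integer(warmup),
                          seed = as.integer(seed)),
                     class = "poisirt_draws")
  flat <- matrix(values, nrow = chains * n_keep, ncol = P + n,
                 dimnames = list(NULL, par_names))
  post_mean <- colMeans(flat)
  post_sd <- apply(flat, 2L, stats::sd)
  ci <- t(apply(flat, 2L, stats::quantile, probs = c(0.025, 0.975),
                type = 7))
  colnames(ci) <- c("2.5%", "97.5%")
  # posterior-mean item parameters
  mean_x <- post_mean[seq_len(P)]
  params <- .params_from_free(layout, mean_x)
  conv <- .convergence_table(values, par_names)
  bad <- conv[!is.na(conv$rhat) &
                (conv$rhat > 1.01 | conv$ess_bulk < 400 |
                   conv$ess_tail < 400), "parameter"]
  if (length(bad)) {
    warning(sprintf(
      "convergence caution for %d parameter(s) (R-hat > 1.01 or ESS < 400): %s",
      length(bad), paste(utils::head(bad, 5L), collapse = ", ")))
  }
  fit <- new_fit("MCMC", params, post_sd, ci, conv, data, draws = draws,
                 logLik = NA_real_, divergence_count = divergences,
                 divergence_applicable = TRUE, priors = priors, seed = seed,
                 details = list(mean_accept = accept, layout = layout,
                                estimates = post_mean,
                                model_kind = model_kind,
                                identification = identification))
  if (nrow(data$records)) {
    fit$pointwise_loglik <- pointwise_loglik(fit, data)
  }
  fit
}

# rebuild item_params from posterior means of the free parameters
.params_from_free <- function(layout, mean_x) {
  v <- mean_x
  if (length(layout$idx_sd)) v[layout$idx_sd] <- log(v[layout$idx_sd])
  layout$unpack(unname(v))
}

#' Export posterior draws as a flat table
#'
#' @param draws a `poisirt_draws` object (or a `poisirt_fit` with draws).
#' @return A data.frame with columns chain, iteration, parameter, value.
#' @export
draws_table <- function(draws) {
  if (inherits(draws, "poisirt_fit")) draws <- draws$draws
  stopifnot(inherits(draws, "poisirt_draws"))
  dm <- dim(draws$values)
  data.frame(
    chain = rep(seq_len(dm[1L]), times = dm[2L] * dm[3L]),
    iteration = rep(rep(seq_len(dm[2L]), each = dm[1L]), times = dm[3L]),
    parameter = rep(draws$parameter_names, each = dm[1L] * dm[2L]),
    value = as.vector(draws$values),
    stringsAsFactors = FALSE)
}

# S x P matrix of all post-warmup draws (chains stacked)
.flat_draws <- function(fit) {
  v <- fit$draws$values
  matrix(v, nrow = dim(v)[1L] * dim(v)[2L], ncol = dim(v)[3L],
         dimnames = list(NULL, fit$draws$parameter_names))
}

# per-draw matrices of easiness (S x m), slope (S x m), theta (S x n),
# theta_sd (S)
.draw_components <- function(fit) {
  layout <- fit$details$layout
  flat <- .flat_draws(fit)
  items <- layout$item_ids
  m <- length(items)
  S <- nrow(flat)
  b <- flat[, sprintf("easiness[%s]", items), drop = FALSE]
  if (layout$model_kind == "RPCM") {
    a_shared <- if ("slope" %in% colnames(flat)) flat[, "slope"] else
      rep(1, S)
    a <- matrix(a_shared, S, m)
  } else if (layout$identification == "marker") {
    a <- matrix(1, S, m)
    if (length(layout$slope_free_ids)) {
      a[, match(layout$slope_free_ids, items)] <-
        flat[, sprintf("slope[%s]", layout$slope_free_ids), drop = FALSE]
    }
  } else {
    a <- flat[, sprintf("slope[%s]", items), drop = FALSE]
  }
  sd <- if ("theta_sd" %in% colnames(flat)) flat[, "theta_sd"] else
    rep(1, S)
  th_names <- sprintf("theta[%s]", fit$data$persons)
  th <- flat[, th_names, drop = FALSE]
  list(easiness = b, slope = a, theta = th, theta_sd = sd, items = items)
}
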