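#' Fitted (expected) counts per observation
#'
#' For MCMC fits, the posterior mean of the rate lambda_ij across all
#' post-warmup draws (`convention = "posterior_mean_rate"`). For MML
#' fits, the rate at the point estimates with theta set to the person's
#' EAP score (`convention = "plugin_at_point_estimates"`). By Jensen's
#' inequality the posterior mean of the rate is at least the rate at the
#' posterior means.
#'
#' @param fit a `poisirt_fit`.
#' @param data a [count_data] whose persons and items are all covered by
#'   the fit.
#' @return A `fitted_values` data.frame: person, item, observed, fitted;
#'   the convention is stored as an attribute.
#' @export
fitted_values <- function(fit, data = fit$data) {
  stopifnot(inherits(fit, "poisirt_fit"), inherits(data, "count_data"))
  if (!all(data$items %in% fit$params$item_ids)) {
    stop("data contains items absent from the fit")
  }
  it <- match(data$records$item, fit$params$item_ids)
  if (fit$method == "MCMC") {
    if (!all(data$persons %in% fit$data$persons)) {
      stop("data contains persons absent from the fit")
    }
    comp <- .draw_components(fit)
    pid <- match(data$records$person, fit$data$persons)
    lam <- exp(comp$easiness[, it, drop = FALSE] +
                 comp$slope[, it, drop = FALSE] *
                   comp$theta[, pid, drop = FALSE])
    fitted <- colMeans(lam)
    convention <- "posterior_mean_rate"
  } else {
    sc <- eap_scores(data, fit$params)
    th <- sc$theta[match(data$records$person, sc$person_id)]
    fitted <- rate(fit$params$easiness[it], fit$params$slope[it], th)
    convention <- "plugin_at_point_estimates"
  }
  out <- data.frame(person = data$records$person,
                    item = data$records$item,
                    observed = data$records$count,
                    fitted = unname(fitted), stringsAsFactors = FALSE)
  class(out) <- c("fitted_values", "data.frame")
  attr(out, "convention") <- convention
  out
}

.check_alignment <- function(data, fitted) {
  stopifnot(inherits(data, "count_data"))
  if (!is.data.frame(fitted) ||
      !all(c("person", "item", "observed", "fitted") %in% names(fitted))) {
    stop("fitted must be a fitted_values data.frame")
  }
  if (nrow(fitted) != nrow(data$records) ||
      !all(fitted$person == data$records$person &
             fitted$item == data$records$item)) {
    stop("fitted values are not aligned with the data records")
  }
  if (any(fitted$fitted <= 0)) stop("fitted values must be strictly positive")
}

#' Dispersion statistics
#'
#' Overall dispersion `phi = mean((y - yhat)^2 / yhat)` over the observed
#' records, and the same restricted to each item's records. Under missing
#' data the divisor is the observed-record count, keeping phi a mean of
#' per-record terms. Equidispersion implies phi = 1; phi < 1 indicates
#' underdispersion, phi > 1 overdispersion. The overall value equals both
#' the mean of squared Pearson residuals and the observation-count-
#' weighted mean of the per-item values.
#'
#' @param data a [count_data].
#' @param fitted aligned `fitted_values` (see [fitted_values]).
#' @return A `dispersion_report`: list with `overall_phi`,
#'   `per_item_phi` (named), `n_observations_used`.
#' @export
dispersion <- function(data, fitted) {
  .check_alignment(data, fitted)
  contrib <- (fitted$observed - fitted$fitted)^2 / fitted$fitted
  per_item <- tapply(contrib, factor(fitted$item, levels = data$items),
                     mean)
  structure(list(overall_phi = mean(contrib),
                 per_item_phi = stats::setNames(as.vector(per_item),
                                                data$items),
                 n_observations_used = nrow(fitted)),
            class = "dispersion_report")
}

#' @export
print.dispersion_report <- function(x, ...) {
  cat(sprintf("dispersion: overall phi = %.3f (%d observations)\n",
              x$overall_phi, x$n_observations_used))
  for (nm in names(x$per_item_phi)) {
    cat(sprintf("  phi[%s] = %.3f\n", nm, x$per_item_phi[[nm]]))
  }
  cat(if (x$overall_phi < 1) "  (underdispersion)\n" else
    if (x$overall_phi > 1) "  (overdispersion)\n" else "")
  invisible(x)
}

#' Pearson residuals
#'
#' `(y - yhat) / sqrt(yhat)` per observed record, exported together with
#' the fitted values for residual-vs-fitted inspection. The mean of the
#' squared residuals equals the overall dispersion parameter exactly.
#'
#' @inheritParams dispersion
#' @return data.frame: person, item, observed, fitted, residual.
#' @export
pearson_residuals <- function(data, fitted) {
  .check_alignment(data, fitted)
  data.frame(person = fitted$person, item = fitted$item,
             observed = fitted$observed, fitted = fitted$fitted,
             residual = (fitted$observed - fitted$fitted) /
               sqrt(fitted$fitted),
             stringsAsFactors = FALSE)
}

#' Expected and observed score frequencies
#'
#' Covariate-adjusted frequencies: for each possible score k the
#' expected frequency is the Poisson probability mass at k summed over
#' the fitted rates of all records, `sum_r dpois(k, yhat_r)`; the
#' observed frequency is the count of records scoring k. As max_score
#' grows the expected frequencies sum to the number of records.
#'
#' @param fitted a `fitted_values` data.frame.
#' @param max_score largest score tabulated (>= the observed maximum;
#'   default: observed maximum plus ten SDs of the largest rate).
#' @param by_item tabulate separately per item.
#' @return data.frame with columns score, expected, observed (and item
#'   when `by_item`).
#' @export
expected_frequencies <- function(fitted, max_score = NULL,
                                 by_item = FALSE) {
  if (!is.data.frame(fitted) ||
      !all(c("observed", "fitted") %in% names(fitted))) {
    stop("fitted must be a fitted_values data.frame")
  }
  if (is.null(max_score)) {
    mx <- max(fitted$fitted)
    max_score <- max(max(fitted$observed), ceiling(mx + 10 * sqrt(mx)))
  }
  if (max_score < max(fitted$observed)) {
    stop("max_score must be at least the observed maximum")
  }
  tab_one <- function(df) {
    k <- 0:max_score
    expected <- vapply(k, function(kk) sum(stats::dpois(kk, df$fitted)),
                       numeric(1))
    observed <- as.vector(table(factor(df$observed, levels = k)))
    data.frame(score = k, expected = expected, observed = observed)
  }
  if (!by_item) return(tab_one(fitted))
  parts <- lapply(split(fitted, fitted$item), tab_one)
  out <- do.call(rbind, Map(function(nm, df) {
    cbind(item = nm, df, stringsAsFactors = FALSE)
  }, names(parts), parts))
  rownames(out) <- NULL
  out
}

# shared predictive-check core: lambda_draws is an S x N matrix of rates
# aligned with data records
.predictive_check <- function(lambda_draws, data, grouping, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  S <- nrow(lambda_draws)
  N <- ncol(lambda_draws)
  yrep <- matrix(stats::rpois(S * N, lambda_draws), S, N)
  h <- ceiling(0.95 * S)
  lo <- integer(N); hi <- integer(N)
  for (r in seq_len(N)) {
    srt <- sort.int(yrep[, r], method = "quick")
    widths <- srt[h:S] - srt[seq_len(S - h + 1L)]
    i <- which.min(widths)
    lo[r] <- srt[i]; hi[r] <- srt[i + h - 1L]
  }
  y <- data$records$count
  outside <- y < lo | y > hi
  ids <- data$records[outside, c("person", "item")]
  max_k <- max(y, yrep)
  k <- 0:max_k
  rep_freq <- tabulate(as.vector(yrep) + 1L, nbins = max_k + 1L) / S
  obs_freq <- tabulate(y + 1L, nbins = max_k + 1L)
  group_tab <- switch(grouping,
    overall = data.frame(group = "overall", n = N,
                         outside = sum(outside)),
    by_item = {
      f <- factor(data$records$item, levels = data$items)
      data.frame(group = data$items,
                 n = as.vector(table(f)),
                 outside = as.vector(tapply(outside, f, sum,
                                            default = 0L)))
    },
    by_person = {
      f <- factor(data$records$person, levels = data$persons)
      data.frame(group = data$persons,
                 n = as.vector(table(f)),
                 outside = as.vector(tapply(outside, f, sum,
                                            default = 0L)))
    })
  structure(list(
    intervals = data.frame(person = data$records$person,
                           item = data$records$item, observed = y,
                           lo = lo, hi = hi, outside = outside,
                           stringsAsFactors = FALSE),
    outside_count = sum(outside),
    outside_ids = ids,
    grouping = grouping,
    grouped = group_tab,
    score_distribution = data.frame(score = k, observed = obs_freq,
                                    expected_replicate = rep_freq),
    n_draws_used = S, seed = seed), class = "ppc_report")
}

#' Posterior predictive check
#'
#' Simulates replicated counts from Poisson(lambda_ij) at each retained
#' posterior draw's parameters and abilities, forms for each observation
#' the smallest integer interval holding at least 95% of the replicate
#' mass (discreteness makes exact 95% unattainable), and counts/lists
#' the observations falling outside. Grouped summaries by item or person
#' are available, and the pooled replicate score distribution is
#' returned for density-overlay plotting.
#'
#' @param fit an MCMC `poisirt_fit` (for MML fits use
#'   [parametric_bootstrap_check]).
#' @param data a [count_data] aligned with the fit.
#' @param grouping `"overall"`, `"by_item"` or `"by_person"`.
#' @param n_draws_used number of posterior draws to use (default: all;
#'   subsampling is seeded).
#' @param seed seed for the replicate simulation (default: the fit's).
#' @return A `ppc_report`.
#' @export
posterior_predictive_check <- function(fit, data = fit$data,
                                       grouping = c("overall", "by_item",
                                                    "by_person"),
                                       n_draws_used = NULL,
                                       seed = fit$seed) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(fit, "poisirt_fit"))
  if (fit$method != "MCMC" || is.null(fit$draws)) {
    stop("fit has no posterior draws; use parametric_bootstrap_check() for MML fits")
  }
  comp <- .draw_components(fit)
  it <- match(data$records$item, fit$params$item_ids)
  pid <- match(data$records$person, fit$data$persons)
  if (anyNA(it) || anyNA(pid)) {
    stop("data contains persons or items absent from the fit")
  }
  lam <- exp(comp$easiness[, it, drop = FALSE] +
               comp$slope[, it, drop = FALSE] *
                 comp$theta[, pid, drop = FALSE])
  if (!is.null(n_draws_used) && n_draws_used < nrow(lam)) {
    old <- .Random.seed_save(); set.seed(seed)
    keep <- sample.int(nrow(lam), n_draws_used)
    .Random.seed_restore(old)
    lam <- lam[keep, , drop = FALSE]
  }
  .predictive_check(lam, data, grouping, seed)
}

#' Parametric bootstrap predictive check for MML fits
#'
#' Same contract as [posterior_predictive_check], with parameter draws
#' taken from the asymptotic normal distribution of the MML estimates
#' (mean = estimates, covariance = inverse observed information) and
#' abilities drawn from each person's EAP posterior approximated as
#' N(EAP, EAP-SD^2).
#'
#' @param fit an MML `poisirt_fit` with an invertible information matrix.
#' @param data a [count_data] aligned with the fit.
#' @param grouping `"overall"`, `"by_item"` or `"by_person"`.
#' @param n_draws number of parameter draws (default 1000).
#' @param seed simulation seed.
#' @return A `ppc_report`.
#' @export
parametric_bootstrap_check <- function(fit, data = fit$data,
                                       grouping = c("overall", "by_item",
                                                    "by_person"),
                                       n_draws = 1000, seed = 1) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(fit, "poisirt_fit"))
  if (fit$method != "MML") stop("parametric bootstrap applies to MML fits")
  if (is.null(fit$vcov)) stop("fit has no covariance matrix (singular information)")
  layout <- fit$details$layout
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  est <- layout$pack(fit$params)
  R <- chol(fit$vcov)
  par_draws <- matrix(stats::rnorm(n_draws * length(est)), n_draws) %*% R
  par_draws <- sweep(par_draws, 2L, est, "+")
  sc <- eap_scores(data, fit$params)
  pid <- match(data$records$person, sc$person_id)
  it_names <- data$records$item
  S <- n_draws
  lam <- matrix(NA_real_, S, nrow(data$records))
  th_draws <- matrix(stats::rnorm(S * nrow(sc)), S) *
    rep(sc$sd, each = S) + rep(sc$theta, each = S)
  for (s in seq_len(S)) {
    p_s <- layout$unpack(par_draws[s, ])
    lam[s, ] <- rate(p_s$easiness[it_names], p_s$slope[it_names],
                     th_draws[s, pid])
  }
  .predictive_check(lam, data, grouping, seed)
}

#' @export
print.ppc_report <- function(x, ...) {
  cat(sprintf(
    "predictive check (%s): %d of %d observations outside the >=95%% intervals (%d draws)\n",
    x$grouping, x$outside_count, nrow(x$intervals), x$n_draws_used))
  if (x$outside_count > 0 && x$outside_count <= 20) {
    for (r in seq_len(nrow(x$outside_ids))) {
      cat(sprintf("  outside: person %s, item %s\n",
                  x$outside_ids$person[r], x$outside_ids$item[r]))
    }
  }
  invisible(x)
}
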