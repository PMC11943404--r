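#' Pointwise log-likelihood matrix from posterior draws
#'
#' For each post-warmup draw s and observed record r, the Poisson
#' log-pmf of the observed count at that draw's rate (conditional on the
#' draw's theta). This conditional formulation is what WAIC and LOO
#' consume; a marginal (theta-integrated, person-level) alternative is
#' available via `type = "marginal"`, which integrates each person's
#' likelihood over the population distribution of theta by quadrature
#' and returns one column per person.
#'
#' @param fit an MCMC `poisirt_fit`.
#' @param data a [count_data] aligned with the fit.
#' @param type `"conditional"` (default, per record) or `"marginal"`
#'   (per person).
#' @param n_nodes quadrature nodes for the marginal variant.
#' @return A `pointwise_loglik` object: list with `values` (S x N
#'   matrix) and `obs` (data.frame of observation ids).
#' @export
pointwise_loglik <- function(fit, data = fit$data,
                             type = c("conditional", "marginal"),
                             n_nodes = 21) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "poisirt_fit"))
  if (fit$method != "MCMC" || is.null(fit$draws)) {
    stop("pointwise log-likelihood requires an MCMC fit with draws")
  }
  comp <- .draw_components(fit)
  if (type == "conditional") {
    it <- match(data$records$item, fit$params$item_ids)
    pid <- match(data$records$person, fit$data$persons)
    if (anyNA(it) || anyNA(pid)) {
      stop("data contains persons or items absent from the fit")
    }
    eta <- comp$easiness[, it, drop = FALSE] +
      comp$slope[, it, drop = FALSE] * comp$theta[, pid, drop = FALSE]
    y <- data$records$count
    ll <- sweep(eta, 2L, y, "*") - exp(eta) -
      rep(lgamma(y + 1), each = nrow(eta))
    dimnames(ll) <- NULL
    obs <- data.frame(person = data$records$person,
                      item = data$records$item, stringsAsFactors = FALSE)
  } else {
    rule <- gauss_hermite_rule(n_nodes)
    S <- nrow(comp$easiness)
    persons <- data$persons
    ll <- matrix(NA_real_, S, length(persons))
    pid <- person_idx(data)
    itn <- match(data$records$item, fit$params$item_ids)
    y <- data$records$count
    lg <- lgamma(y + 1)
    for (s in seq_len(S)) {
      node_ll <- matrix(0, length(persons), n_nodes)
      for (q in seq_len(n_nodes)) {
        eta <- comp$easiness[s, itn] + comp$slope[s, itn] *
          comp$theta_sd[s] * rule$nodes[q]
        node_ll[, q] <- .rowsum_full(y * eta - exp(eta) - lg, pid,
                                     length(persons))
      }
      ll[s, ] <- logsumexp_rows(sweep(node_ll, 2L, log(rule$weights),
                                      "+"))
    }
    obs <- data.frame(person = persons, item = NA_character_,
                      stringsAsFactors = FALSE)
  }
  if (nrow(ll) < 100L) {
    warning("fewer than 100 draws: WAIC/LOO estimates may be unstable")
  }
  structure(list(values = ll, obs = obs, type = type),
            class = "pointwise_loglik")
}

.check_ll <- function(ll) {
  if (inherits(ll, "pointwise_loglik")) ll <- ll$values
  ll <- as.matrix(ll)
  if (any(!is.finite(ll))) stop("non-finite pointwise log-likelihood entries")
  ll
}

# column-wise log(mean(exp(x))) in log space
.col_log_mean_exp <- function(m) {
  mx <- apply(m, 2L, max)
  mx + log(colMeans(exp(sweep(m, 2L, mx))))
}

#' Widely applicable information criterion
#'
#' `lppd_i = log mean_s exp(ll_si)` (computed via log-sum-exp),
#' `p_i = var_s(ll_si)` (n-1 denominator), `elpd = sum(lppd_i - p_i)`,
#' `se = sqrt(N * var_i(lppd_i - p_i))`.
#'
#' @param ll a `pointwise_loglik` or an S x N matrix (draws x
#'   observations), S >= 2.
#' @return List with `elpd`, `p_eff`, `se`, and the `pointwise`
#'   elpd contributions.
#' @export
waic <- function(ll) {
  ll <- .check_ll(ll)
  if (nrow(ll) < 2L) stop("WAIC requires at least 2 draws")
  lppd <- .col_log_mean_exp(ll)
  p <- apply(ll, 2L, stats::var)
  pointwise <- lppd - p
  list(elpd = sum(pointwise), p_eff = sum(p),
       se = sqrt(ncol(ll) * stats::var(pointwise)), pointwise = pointwise,
       criterion = "waic")
}

# maximum-likelihood-flavoured fit of a generalized Pareto distribution
# to tail excesses (Zhang & Stephens 2009 profile posterior mean)
.gpd_fit <- function(x) {
  n <- length(x)
  x <- sort(x)
  prior_bs <- 3
  m <- 30L + floor(sqrt(n))
  bs <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) /
    (prior_bs * x[max(1L, floor(n / 4 + 0.5))])
  lx <- vapply(bs, function(b) {
    k <- -mean(log1p(-b * x))
    n * (log(b / k) + k - 1)
  }, numeric(1))
  w <- 1 / vapply(seq_len(m), function(i) sum(exp(lx - lx[i])), numeric(1))
  b <- sum(bs * w)
  k <- -mean(log1p(-b * x))
  list(k = k, sigma = k / b)
}

#' Importance-sampling leave-one-out cross-validation
#'
#' Per observation the importance ratios are `r_s` proportional to
#' `exp(-ll_si)`. With `smoothing = "truncated"` (default) ratios are
#' truncated at `mean(r) * S^(3/4)`; with `"pareto"` the largest ratios
#' are replaced by expected order statistics of a generalized Pareto
#' distribution fitted to the tail. `elpd_i = log(sum(r_s exp(ll_si)) /
#' sum(r_s))`, evaluated in log space. A per-observation diagnostic flag
#' marks heavy-tailed ratio distributions (fitted Pareto k > 0.7).
#'
#' @inheritParams waic
#' @param smoothing `"truncated"` or `"pareto"`.
#' @return List with `elpd`, `p_eff`, `se`, `pointwise`, and
#'   `flagged` (logical per observation).
#' @export
loo_is <- function(ll, smoothing = c("truncated", "pareto")) {
  smoothing <- match.arg(smoothing)
  ll <- .check_ll(ll)
  S <- nrow(ll)
  if (S < 2L) stop("LOO requires at least 2 draws")
  lppd <- .col_log_mean_exp(ll)
  N <- ncol(ll)
  pointwise <- numeric(N)
  flagged <- logical(N)
  for (i in seq_len(N)) {
    lw <- -ll[, i]
    lw <- lw - max(lw)
    r <- exp(lw)
    # tail diagnostic on the raw ratios
    n_tail <- min(ceiling(0.2 * S), max(5L, ceiling(3 * sqrt(S))))
    if (S >= 10L) {
      srt <- sort(r)
      cut <- srt[S - n_tail]
      exc <- srt[srt > cut] - cut
      if (length(exc) >= 5L && stats::sd(exc) > 0) {
        k_hat <- tryCatch(.gpd_fit(exc)$k, error = function(e) NA_real_)
        flagged[i] <- is.na(k_hat) || k_hat > 0.7
        if (smoothing == "pareto" && !is.na(k_hat) && k_hat > -1) {
          fitg <- .gpd_fit(exc)
          ord <- order(r, decreasing = TRUE)[seq_along(exc)]
          p <- (seq_along(exc) - 0.5) / length(exc)
          q <- cut + fitg$sigma / fitg$k * ((1 - p)^(-fitg$k) - 1)
          r[ord] <- pmin(sort(q, decreasing = TRUE), max(r))
        }
      }
    }
    if (smoothing == "truncated") {
      r <- pmin(r, mean(r) * S^0.75)
    }
    pointwise[i] <- log(sum(r * exp(ll[, i]))) - log(sum(r))
  }
  list(elpd = sum(pointwise), p_eff = sum(lppd - pointwise),
       se = sqrt(N * stats::var(pointwise)), pointwise = pointwise,
       flagged = flagged, criterion = "loo")
}

#' Compare two models by ELPD
#'
#' Computes the chosen criterion for both pointwise log-likelihood
#' matrices (which must cover the same observations in the same order),
#' the ELPD difference (model A minus model B), and its standard error
#' from the pointwise differences. The model with the higher ELPD is
#' preferred.
#'
#' @param ll_a,ll_b `pointwise_loglik` objects or S x N matrices for
#'   models A and B.
#' @param criterion `"waic"` or `"loo"`.
#' @param names length-2 character vector of model labels.
#' @return A `comparison_result`: per-model elpd/p_eff/se, `elpd_diff`
#'   (A - B), `se_diff`, `preferred_model`.
#' @export
compare_elpd <- function(ll_a, ll_b, criterion = c("waic", "loo"),
                         names = c("model_a", "model_b")) {
  criterion <- match.arg(criterion)
  obs_a <- if (inherits(ll_a, "pointwise_loglik")) ll_a$obs else NULL
  obs_b <- if (inherits(ll_b, "pointwise_loglik")) ll_b$obs else NULL
  if (!is.null(obs_a) && !is.null(obs_b)) {
    if (nrow(obs_a) != nrow(obs_b) ||
        !all(obs_a$person == obs_b$person & obs_a$item == obs_b$item)) {
      stop("the two models cover different observation sets")
    }
  }
  ma <- .check_ll(ll_a); mb <- .check_ll(ll_b)
  if (ncol(ma) != ncol(mb)) stop("mismatched observation counts")
  f <- if (criterion == "waic") waic else loo_is
  ra <- f(ma); rb <- f(mb)
  d <- ra$pointwise - rb$pointwise
  structure(list(models = stats::setNames(list(ra, rb), names),
                 elpd_diff = ra$elpd - rb$elpd,
                 se_diff = sqrt(length(d) * stats::var(d)),
                 preferred_model = names[which.max(c(ra$elpd, rb$elpd))],
                 criterion = criterion),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("model comparison (%s)\n", x$criterion))
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("  %-12s elpd %9.2f  p_eff %7.2f  se %6.2f\n",
                nm, m$elpd, m$p_eff, m$se))
  }
  cat(sprintf("  elpd diff (%s - %s): %.2f (SE %.2f); preferred: %s\n",
              names(x$models)[1L], names(x$models)[2L], x$elpd_diff,
              x$se_diff, x$preferred_model))
  cat("  (Bayes factors are not computed; use dedicated bridge-sampling tooling)\n")
  invisible(x)
}

#' Machine-readable export of a comparison
#'
#' @param x a `comparison_result`.
#' @param path output JSON path.
#' @export
write_comparison <- function(x, path) {
  stopifnot(inherits(x, "comparison_result"))
  out <- list(criterion = x$criterion,
              models = lapply(x$models, function(m) {
                list(elpd = m$elpd, p_eff = m$p_eff, se = m$se)
              }),
              elpd_diff = x$elpd_diff, se_diff = x$se_diff,
              preferred_model = x$preferred_model)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pairwise slope contrasts
#'
#' For every item pair the per-draw slope difference, its posterior mean,
#' 2.5%/97.5% quantiles, the posterior probability that the difference
#' is positive, and whether the 95% interval includes 0. For an RPCM
#' fit all differences are identically 0 (shared slope) and a note is
#' attached.
#'
#' @param fit an MCMC `poisirt_fit`.
#' @return A `contrast_report` data.frame: item_j, item_k, mean, ci_low,
#'   ci_high, p_gt_0, zero_in_interval.
#' @export
slope_contrasts <- function(fit) {
  stopifnot(inherits(fit, "poisirt_fit"))
  if (fit$method != "MCMC" || is.null(fit$draws)) {
    stop("slope contrasts require an MCMC fit with draws")
  }
  comp <- .draw_components(fit)
  items <- comp$items
  m <- length(items)
  if (m < 2L) stop("need at least 2 items")
  pairs <- utils::combn(m, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    j <- pairs[1L, p]; k <- pairs[2L, p]
    d <- comp$slope[, j] - comp$slope[, k]
    q <- stats::quantile(d, c(0.025, 0.975), type = 7, names = FALSE)
    data.frame(item_j = items[j], item_k = items[k], mean = mean(d),
               ci_low = q[1L], ci_high = q[2L], p_gt_0 = mean(d > 0),
               zero_in_interval = q[1L] <= 0 && 0 <= q[2L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("contrast_report", "data.frame")
  if (fit$params$model_kind == "RPCM") {
    attr(out, "note") <- "RPCM: shared slope, all differences identically 0"
  }
  out
}
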