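#' EAP ability estimates via quadrature
#'
#' For each person the posterior over theta is proportional to the
#' N(0, theta_sd^2) population density times the product of Poisson
#' likelihood terms over that person's observed items, evaluated on the
#' Gauss-Hermite grid. The point estimate is the normalized weighted
#' mean (EAP), the error the weighted SD, and the 95% interval comes
#' from inverting the discretized CDF with linear interpolation between
#' nodes. Persons absent from the training data can be scored post hoc
#' against fixed item parameters.
#'
#' @param data a [count_data] object.
#' @param params fitted [item_params].
#' @param rule a [gauss_hermite_rule] (default 61 nodes).
#' @return An `ability_estimates` data.frame: person_id, theta, sd,
#'   ci_low, ci_high, n_items_observed.
#' @export
eap_scores <- function(data, params, rule = gauss_hermite_rule(61)) {
  stopifnot(inherits(data, "count_data"), inherits(params, "item_params"),
            inherits(rule, "quadrature_rule"))
  if (!nrow(data$records)) stop("no records to score")
  ll <- .person_node_loglik(data, params, rule$nodes)  # persons x nodes
  logw <- sweep(ll, 2L, log(rule$weights), "+")
  logw <- logw - apply(logw, 1L, max)
  w <- exp(logw)
  w <- w / rowSums(w)
  theta_nodes <- params$theta_sd * rule$nodes
  point <- as.vector(w %*% theta_nodes)
  second <- as.vector(w %*% theta_nodes^2)
  sd <- sqrt(pmax(second - point^2, 0))
  qs <- t(apply(w, 1L, function(wi) {
    .discrete_cdf_quantile(theta_nodes, wi, c(0.025, 0.975))
  }))
  n_obs <- as.vector(table(factor(data$records$person,
                                  levels = data$persons)))
  out <- data.frame(person_id = data$persons, theta = point, sd = sd,
                    ci_low = qs[, 1L], ci_high = qs[, 2L],
                    n_items_observed = n_obs, stringsAsFactors = FALSE)
  class(out) <- c("ability_estimates", "data.frame")
  out
}

# quantiles by linear interpolation of the discretized CDF over nodes;
# the midpoint convention F(x_i) = cumsum(w)_i - w_i/2 keeps the node
# atoms from biasing the inversion outward
.discrete_cdf_quantile <- function(x, w, probs) {
  cdf <- cumsum(w) - w / 2
  vapply(probs, function(p) {
    i <- which(cdf >= p)[1L]
    if (is.na(i)) return(x[length(x)])
    if (i == 1L) return(x[1L])
    p0 <- cdf[i - 1L]
    x[i - 1L] + (x[i] - x[i - 1L]) * (p - p0) / (cdf[i] - p0)
  }, numeric(1))
}

#' Extract ability estimates from MCMC draws
#'
#' Per-person posterior mean, SD and 2.5%/97.5% quantiles of theta across
#' all chains and post-warmup iterations. Quantiles use linear
#' interpolation of the empirical CDF (type 7). For MML fits use
#' [eap_scores] instead.
#'
#' @param fit an MCMC `poisirt_fit`.
#' @param keep_draws logical; attach the per-person draw matrix as the
#'   `"draws"` attribute.
#' @return An `ability_estimates` data.frame as in [eap_scores].
#' @export
extract_theta <- function(fit, keep_draws = FALSE) {
  stopifnot(inherits(fit, "poisirt_fit"))
  if (fit$method != "MCMC" || is.null(fit$draws)) {
    stop("fit has no posterior draws; use eap_scores() for MML fits")
  }
  comp <- .draw_components(fit)
  th <- comp$theta
  point <- colMeans(th)
  sd <- apply(th, 2L, stats::sd)
  if (any(sd == 0)) {
    warning("degenerate posterior (zero SD) for at least one person")
  }
  qs <- t(apply(th, 2L, stats::quantile, probs = c(0.025, 0.975),
                type = 7))
  n_obs <- as.vector(table(factor(fit$data$records$person,
                                  levels = fit$data$persons)))
  out <- data.frame(person_id = fit$data$persons, theta = unname(point),
                    sd = unname(sd), ci_low = unname(qs[, 1L]),
                    ci_high = unname(qs[, 2L]), n_items_observed = n_obs,
                    stringsAsFactors = FALSE)
  class(out) <- c("ability_estimates", "data.frame")
  if (keep_draws) attr(out, "draws") <- th
  out
}

#' Write ability estimates to CSV
#'
#' @param estimates an `ability_estimates` data.frame.
#' @param path output path.
#' @export
write_scores <- function(estimates, path) {
  utils::write.csv(as.data.frame(estimates), path, row.names = FALSE)
  invisible(path)
}
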