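#' Gauss-Hermite quadrature rule for standard-normal expectations
#'
#' Nodes and weights for approximating E[f(Z)], Z ~ N(0, 1), as
#' `sum(w * f(z))`. Computed by the Golub-Welsch eigenvalue method on the
#' Jacobi matrix of the (physicists') Hermite polynomials and then
#' rescaled to the probabilists' convention, so the weights sum to 1 and
#' the nodes are symmetric about 0.
#'
#' @param n number of nodes (>= 2).
#' @return An object of class `quadrature_rule`: list with `nodes` and
#'   `weights`.
#' @export
#' @examples
#' r <- gauss_hermite_rule(21)
#' sum(r$weights * r$nodes^2)  # E[Z^2] = 1
gauss_hermite_rule <- function(n) {
  if (!is.numeric(n) || n < 2) stop("need at least 2 quadrature nodes")
  n <- as.integer(n)
  # Jacobi matrix for Hermite polynomials orthogonal w.r.t. exp(-x^2)
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- e$vectors[1L, ]^2  # already normalized: sum(w) = 1 relative to sqrt(pi)
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  # symmetrize against rounding; map to N(0,1): z = sqrt(2) x
  x <- (x - rev(x)) / 2
  w <- (w + rev(w)) / 2
  w <- w / sum(w)
  structure(list(nodes = sqrt(2) * x, weights = w),
            class = "quadrature_rule")
}

# per-person log integrand matrix: rows persons, cols nodes, entry =
# sum over the person's observed records of the Poisson log-pmf at
# theta = theta_sd * node
.person_node_loglik <- function(data, params, nodes) {
  pid <- person_idx(data)
  b <- params$easiness[data$records$item]
  a <- params$slope[data$records$item]
  y <- data$records$count
  lg <- lgamma(y + 1)
  n <- length(data$persons)
  out <- matrix(0, n, length(nodes))
  for (q in seq_along(nodes)) {
    eta <- b + a * params$theta_sd * nodes[q]
    ll <- y * eta - exp(eta) - lg
    out[, q] <- rowsum(ll, pid, reorder = FALSE)[, 1L]
  }
  out
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Marginal log-likelihood of a Poisson count IRT model
#'
#' Integrates the latent ability out of the joint likelihood person by
#' person: `sum_i log sum_q w_q prod_j Poisson(x_ij | exp(b_j + a_j *
#' theta_sd * z_q))`, evaluated in log space via log-sum-exp.
#'
#' @param data a [count_data] object.
#' @param params an [item_params] object.
#' @param rule a [gauss_hermite_rule] (default 61 nodes).
#' @return A single numeric value.
#' @export
marginal_log_likelihood <- function(data, params,
                                    rule = gauss_hermite_rule(61)) {
  stopifnot(inherits(data, "count_data"), inherits(params, "item_params"),
            inherits(rule, "quadrature_rule"))
  if (!all(data$items %in% params$item_ids)) {
    stop("params do not cover all items in data")
  }
  ll <- .person_node_loglik(data, params, rule$nodes)
  sum(logsumexp_rows(sweep(ll, 2L, log(rule$weights), "+")))
}
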