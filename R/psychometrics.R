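#' Item response curves
#'
#' Evaluates the expected count `exp(b_j + a_j * theta)` for every item
#' over a grid of ability values. The default grid spans the plausible
#' range -3 to 3 in steps of 0.01.
#'
#' @param params an [item_params] object.
#' @param theta_grid strictly increasing numeric grid.
#' @return A `curve_table`: list with `theta` (grid), `values` (grid x
#'   item matrix) and `kind = "response"`.
#' @export
item_response_curve <- function(params, theta_grid = seq(-3, 3, 0.01)) {
  stopifnot(inherits(params, "item_params"))
  if (!length(theta_grid)) stop("theta_grid must be nonempty")
  if (is.unsorted(theta_grid, strictly = TRUE)) {
    stop("theta_grid must be strictly increasing")
  }
  vals <- outer(theta_grid, seq_along(params$item_ids),
                function(th, j) rate(params$easiness[j], params$slope[j],
                                     th))
  colnames(vals) <- params$item_ids
  structure(list(theta = theta_grid, values = vals, kind = "response"),
            class = "curve_table")
}

#' Item information curves
#'
#' Fisher information of each item about theta over a grid:
#' `a_j^2 * exp(b_j + a_j * theta)`.
#'
#' @inheritParams item_response_curve
#' @return A `curve_table` with `kind = "information"`.
#' @export
item_information_curve <- function(params, theta_grid = seq(-3, 3, 0.01)) {
  out <- item_response_curve(params, theta_grid)
  out$values <- sweep(out$values, 2L, params$slope^2, "*")
  out$kind <- "information"
  out
}

#' @export
print.curve_table <- function(x, ...) {
  cat(sprintf("curve_table (%s): %d grid points x %d items, theta in [%g, %g]\n",
              x$kind, length(x$theta), ncol(x$values), min(x$theta),
              max(x$theta)))
  invisible(x)
}

#' Tidy export of a curve table
#'
#' @param x a `curve_table`.
#' @param ... unused.
#' @return data.frame with columns theta, item_id, value, kind.
#' @export
as.data.frame.curve_table <- function(x, ...) {
  data.frame(theta = rep(x$theta, times = ncol(x$values)),
             item_id = rep(colnames(x$values), each = length(x$theta)),
             value = as.vector(x$values), kind = x$kind,
             stringsAsFactors = FALSE)
}

#' Item information at a single ability value
#'
#' Fisher information of one item about theta: `slope^2 * exp(easiness +
#' slope * theta)`, the negative expected second derivative of the
#' Poisson log-likelihood with respect to theta. Vectorized.
#'
#' @param easiness item easiness b.
#' @param slope item slope a.
#' @param theta ability value.
#' @return Non-negative information value(s).
#' @export
#' @examples
#' item_information(0, 1, 0)  # 1
item_information <- function(easiness, slope, theta) {
  slope^2 * rate(easiness, slope, theta)
}

#' Test information at an ability value
#'
#' Sum of [item_information] over all items of the test; additive over
#' arbitrary item partitions.
#'
#' @param params an [item_params] object.
#' @param theta ability value (vectorized).
#' @return Non-negative information value(s).
#' @export
test_information <- function(params, theta) {
  stopifnot(inherits(params, "item_params"))
  vapply(theta, function(th) {
    sum(item_information(params$easiness, params$slope, th))
  }, numeric(1))
}

#' Group-level empirical reliability
#'
#' Classical-test-theory style ratio of true-score variance to total
#' variance: `VAR(point estimates) / (VAR(point estimates) +
#' mean(sd^2))`, with the n-1 variance denominator. Depends on the
#' point-estimate convention (posterior means with posterior SDs for
#' MCMC, EAP with EAP-SD for MML); invariant to adding a constant to all
#' point estimates.
#'
#' @param estimates an `ability_estimates` data.frame ([eap_scores] or
#'   [extract_theta]).
#' @return A value in [0, 1].
#' @export
empirical_reliability <- function(estimates) {
  .check_estimates(estimates)
  v <- stats::var(estimates$theta)
  err <- mean(estimates$sd^2)
  if (v == 0 && err == 0) {
    stop("reliability undefined: no score variance and no error variance")
  }
  v / (v + err)
}

#' Person-level empirical reliability
#'
#' As [empirical_reliability] but with the person's own squared error in
#' the denominator: `VAR(points) / (VAR(points) + sd_i^2)`.
#'
#' @inheritParams empirical_reliability
#' @return Named numeric vector, one value in [0, 1] per person.
#' @export
person_reliability <- function(estimates) {
  .check_estimates(estimates)
  v <- stats::var(estimates$theta)
  if (v == 0 && all(estimates$sd == 0)) {
    stop("reliability undefined: no score variance and no error variance")
  }
  stats::setNames(v / (v + estimates$sd^2), estimates$person_id)
}

.check_estimates <- function(estimates) {
  if (!is.data.frame(estimates) ||
      !all(c("person_id", "theta", "sd") %in% names(estimates))) {
    stop("estimates must be an ability_estimates data.frame")
  }
  if (nrow(estimates) < 2L) stop("need at least 2 persons")
}
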