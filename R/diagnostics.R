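# Rank-normalized split-R-hat and effective sample size, following the
# modern (split, rank-normalized, Geyer-truncated) definitions used by
# current MCMC tooling.

# biased autocovariance estimate (lag 0..n-1, divided by n) via FFT
.acov_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  M <- stats::nextn(2L * n)
  f <- stats::fft(c(x, rep(0, M - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / M
  ac / n
}

# split each column (chain) of an iter x chain matrix in half
.split_chains <- function(x) {
  n <- nrow(x)
  h <- n %/% 2L
  cbind(x[seq_len(h), , drop = FALSE],
        x[seq_len(h) + (n - h), , drop = FALSE])
}

.rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  array(z, dim = dim(x))
}

# core R-hat on an iter x chain matrix (no splitting/normalization here)
.rhat_core <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  s2 <- apply(x, 2L, stats::var)
  W <- mean(s2)
  B <- n * stats::var(mu)
  if (!is.finite(W) || (W == 0 && B == 0)) return(NaN)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# core ESS (Geyer initial monotone sequence) on an iter x chain matrix
.ess_core <- function(x) {
  n <- nrow(x)
  C <- ncol(x)
  S <- n * C
  if (n < 3L || any(!is.finite(x))) return(NaN)
  acov <- apply(x, 2L, .acov_fft)
  mean_var <- mean(acov[1L, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n
  if (C > 1) var_plus <- var_plus + stats::var(colMeans(x))
  if (!is.finite(var_plus) || var_plus == 0) return(NaN)
  rho <- rep.int(0, n)
  t <- 0L
  rho_even <- 1
  rho[1L] <- 1
  rho_odd <- 1 - (mean_var - mean(acov[2L, ])) / var_plus
  rho[2L] <- rho_odd
  while (t < n - 5L && !is.nan(rho_even + rho_odd) &&
         rho_even + rho_odd > 0) {
    t <- t + 2L
    rho_even <- 1 - (mean_var - mean(acov[t + 1L, ])) / var_plus
    rho_odd <- 1 - (mean_var - mean(acov[t + 2L, ])) / var_plus
    if (rho_even + rho_odd >= 0) {
      rho[t + 1L] <- rho_even
      rho[t + 2L] <- rho_odd
    }
  }
  max_t <- t
  if (rho_even > 0) rho[max_t + 1L] <- rho_even
  # enforce monotone non-increasing pair sums
  t <- 0L
  while (t <= max_t - 4L) {
    t <- t + 2L
    if (rho[t + 1L] + rho[t + 2L] > rho[t - 1L] + rho[t]) {
      rho[t + 1L] <- (rho[t - 1L] + rho[t]) / 2
      rho[t + 2L] <- rho[t + 1L]
    }
  }
  tau <- -1 + 2 * sum(rho[seq_len(max_t)]) + rho[max_t + 1L]
  tau <- max(tau, 1 / log10(S))
  S / tau
}

.check_draw_matrix <- function(draws) {
  draws <- as.matrix(draws)
  if (nrow(draws) < 2L) stop("need at least 2 chains")
  if (ncol(draws) < 4L) stop("need at least 4 iterations per chain")
  t(draws)  # internal orientation: iterations x chains
}

#' Rank-normalized split R-hat
#'
#' Potential scale reduction factor computed on rank-normalized split
#' chains: each chain is split in half, all draws are jointly
#' rank-normalized through the inverse normal CDF, and
#' `sqrt(((n-1)/n * W + B/n) / W)` is evaluated over the resulting
#' half-chains. Values close to 1.00 (below 1.01) indicate good mixing.
#'
#' @param draws numeric matrix with one row per chain and one column per
#'   iteration.
#' @return A single numeric value; `NaN` (with a warning) when all draws
#'   are identical, `Inf` when chains are internally constant but
#'   disagree.
#' @export
#' @examples
#' set.seed(1)
#' split_rhat(matrix(rnorm(4000), nrow = 4))
split_rhat <- function(draws) {
  x <- .check_draw_matrix(draws)
  if (stats::sd(x) == 0) {
    warning("all draws identical: R-hat undefined")
    return(NaN)
  }
  z <- .rank_normalize(.split_chains(x))
  .rhat_core(z)
}

#' Effective sample size (bulk or tail)
#'
#' Bulk ESS is computed on rank-normalized split chains via summed
#' autocorrelations truncated by Geyer's initial monotone sequence; tail
#' ESS is the minimum of the ESS of the 5% and 95% quantile-indicator
#' sequences. Both should exceed roughly 400 for trustworthy posterior
#' summaries.
#'
#' @inheritParams split_rhat
#' @param tail logical; if `TRUE` return tail ESS, else bulk ESS.
#' @return A single numeric value; `NaN` with a warning for constant
#'   draws.
#' @export
ess <- function(draws, tail = FALSE) {
  x <- .check_draw_matrix(draws)
  if (stats::sd(x) == 0) {
    warning("all draws identical: ESS undefined")
    return(NaN)
  }
  xs <- .split_chains(x)
  if (!tail) {
    return(.ess_core(.rank_normalize(xs)))
  }
  q05 <- stats::quantile(xs, 0.05, names = FALSE)
  q95 <- stats::quantile(xs, 0.95, names = FALSE)
  e1 <- .ess_core(array(as.numeric(xs <= q05), dim = dim(xs)))
  e2 <- .ess_core(array(as.numeric(xs <= q95), dim = dim(xs)))
  min(e1, e2)
}

# convergence table for a chains x iter x param draws array
.convergence_table <- function(values, parameter_names) {
  out <- data.frame(parameter = parameter_names,
                    rhat = NA_real_, ess_bulk = NA_real_,
                    ess_tail = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(parameter_names)) {
    dk <- values[, , k, drop = FALSE]
    dk <- matrix(dk, nrow = dim(values)[1L])
    if (stats::sd(dk) == 0) next
    out$rhat[k] <- split_rhat(dk)
    out$ess_bulk[k] <- ess(dk, tail = FALSE)
    out$ess_tail[k] <- ess(dk, tail = TRUE)
  }
  out
}
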