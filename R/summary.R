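# Human-readable fit summaries: a parameter table mirroring the usual
# Bayesian regression output (Estimate, Est.Error, l-95% CI, u-95% CI,
# Rhat, Bulk_ESS, Tail_ESS) plus an exponentiated-estimates table, since
# exp(easiness) is the expected count at theta = 0 and exp(slope) the
# fold change per SD of theta.

.item_param_names <- function(fit) {
  layout <- fit$details$layout
  layout$names
}

#' Summarize a fitted count IRT model
#'
#' @param object a `poisirt_fit`.
#' @param ... unused.
#' @return A `summary.poisirt_fit` list with the parameter table, the
#'   exponentiated table and convergence metadata.
#' @export
summary.poisirt_fit <- function(object, ...) {
  nms <- .item_param_names(object)
  est <- object$details$estimates[nms]
  se <- object$param_errors[nms]
  ci <- object$credible_intervals[nms, , drop = FALSE]
  tab <- data.frame(Estimate = unname(est), Est.Error = unname(se),
                    `l-95% CI` = unname(ci[, 1L]),
                    `u-95% CI` = unname(ci[, 2L]), check.names = FALSE,
                    row.names = nms)
  if (object$method == "MCMC") {
    conv <- object$convergence
    idx <- match(nms, conv$parameter)
    tab$Rhat <- conv$rhat[idx]
    tab$Bulk_ESS <- round(conv$ess_bulk[idx])
    tab$Tail_ESS <- round(conv$ess_tail[idx])
  }
  exp_rows <- grep("^(easiness|slope)", nms)
  exp_tab <- data.frame(Estimate = exp(unname(est[exp_rows])),
                        `l-95% CI` = exp(unname(ci[exp_rows, 1L])),
                        `u-95% CI` = exp(unname(ci[exp_rows, 2L])),
                        check.names = FALSE, row.names = nms[exp_rows])
  structure(list(method = object$method,
                 model_kind = object$params$model_kind,
                 identification = object$params$identification,
                 theta_sd = object$params$theta_sd,
                 theta_sd_fixed = object$params$identification ==
                   "variance_standardization",
                 table = tab, exponentiated = exp_tab,
                 divergence_count = object$divergence_count,
                 divergence_applicable = object$divergence_applicable,
                 logLik = object$logLik,
                 gradient_norm = if (object$method == "MML")
                   attr(object$convergence, "gradient_norm") else NA_real_,
                 n_persons = length(object$data$persons),
                 n_items = length(object$data$items),
                 n_records = nrow(object$data$records)),
            class = "summary.poisirt_fit")
}

#' @export
print.summary.poisirt_fit <- function(x, digits = 2, ...) {
  cat(sprintf("%s fit (%s, %s identification)\n", x$model_kind, x$method,
              gsub("_", " ", x$identification)))
  cat(sprintf("data: %d persons, %d items, %d observations\n\n",
              x$n_persons, x$n_items, x$n_records))
  if (x$theta_sd_fixed) {
    cat("Latent SD (fixed for identification):\n")
    cat(sprintf("  sd(theta) = %g (Est.Error 0, diagnostics NA)\n\n",
                x$theta_sd))
  }
  cat("Parameters:\n")
  print(round(x$table, digits))
  cat("\nExponentiated estimates (expected count at theta = 0 /",
      "fold change per SD):\n")
  print(round(x$exponentiated, digits))
  if (x$method == "MCMC") {
    if (x$divergence_applicable) {
      cat(sprintf("\nDivergent transitions: %d\n", x$divergence_count))
    } else {
      cat("\nDivergent transitions: not applicable to this sampler\n")
    }
  } else {
    cat(sprintf("\nMarginal log-likelihood: %.3f (gradient norm %.2e)\n",
                x$logLik, x$gradient_norm))
  }
  invisible(x)
}

#' @export
print.poisirt_fit <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' Write a structured text summary of a fit
#'
#' @param fit a `poisirt_fit`.
#' @param path output path.
#' @export
write_fit_summary <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sink(con)
  print(summary(fit))
  sink()
  invisible(path)
}
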