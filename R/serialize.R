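# Text-only persistence of fit results, so the command-line workflow can
# hand fits between subcommands: meta.json for scalars/estimates,
# draws.csv (chain, iteration, parameter, value) for posterior draws.

#' Write a fit to a directory of plain-text files
#'
#' @param fit a `poisirt_fit`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "poisirt_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- fit$params
  meta <- list(
    method = fit$method, model_kind = p$model_kind,
    identification = p$identification, item_ids = p$item_ids,
    easiness = unname(p$easiness), slope = unname(p$slope),
    theta_sd = p$theta_sd,
    marker_item = if (is.null(p$marker_item)) NULL else p$marker_item,
    estimates = as.list(fit$details$estimates[.item_param_names(fit)]),
    param_errors = as.list(fit$param_errors),
    seed = fit$seed, logLik = fit$logLik,
    divergence_count = fit$divergence_count,
    divergence_applicable = fit$divergence_applicable,
    n_warmup = if (!is.null(fit$draws)) fit$draws$n_warmup_discarded else
      NULL,
    persons = fit$data$persons,
    vcov = if (!is.null(fit$vcov)) as.vector(fit$vcov) else NULL,
    n_nodes = fit$details$n_nodes)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(
    data.frame(parameter = rownames(fit$credible_intervals),
               estimate = unname(fit$details$estimates[
                 rownames(fit$credible_intervals)]),
               se = unname(fit$param_errors),
               ci_low = unname(fit$credible_intervals[, 1L]),
               ci_high = unname(fit$credible_intervals[, 2L])),
    file.path(dir, "estimates.csv"), row.names = FALSE)
  utils::write.csv(fit$convergence, file.path(dir, "convergence.csv"),
                   row.names = FALSE)
  if (!is.null(fit$draws)) {
    utils::write.csv(draws_table(fit$draws), file.path(dir, "draws.csv"),
                     row.names = FALSE)
  }
  write_item_params(p, file.path(dir, "item_params.txt"))
  write_fit_summary(fit, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' Read a fit written by [write_fit]
#'
#' @param dir fit directory.
#' @param data the [count_data] the fit was estimated on (persons must
#'   match the stored registry).
#' @return A reconstructed `poisirt_fit`.
#' @export
read_fit <- function(dir, data) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  stopifnot(inherits(data, "count_data"))
  if (!identical(as.character(meta$persons), data$persons)) {
    stop("data does not match the fit's person registry")
  }
  params <- item_params(meta$item_ids, meta$easiness, meta$slope,
                        model_kind = meta$model_kind,
                        identification = meta$identification,
                        theta_sd = meta$theta_sd,
                        marker_item = meta$marker_item)
  layout <- par_layout(meta$item_ids, meta$model_kind,
                       meta$identification, meta$marker_item)
  est_tab <- utils::read.csv(file.path(dir, "estimates.csv"),
                             stringsAsFactors = FALSE)
  conv <- utils::read.csv(file.path(dir, "convergence.csv"),
                          stringsAsFactors = FALSE)
  est <- stats::setNames(est_tab$estimate, est_tab$parameter)
  se <- stats::setNames(est_tab$se, est_tab$parameter)
  ci <- cbind(`2.5%` = est_tab$ci_low, `97.5%` = est_tab$ci_high)
  rownames(ci) <- est_tab$parameter
  draws <- NULL
  if (file.exists(file.path(dir, "draws.csv"))) {
    dt <- utils::read.csv(file.path(dir, "draws.csv"),
                          stringsAsFactors = FALSE)
    chains <- max(dt$chain)
    iters <- max(dt$iteration)
    pnames <- unique(dt$parameter)
    values <- array(NA_real_, dim = c(chains, iters, length(pnames)),
                    dimnames = list(NULL, NULL, pnames))
    values[cbind(dt$chain, dt$iteration,
                 match(dt$parameter, pnames))] <- dt$value
    draws <- structure(list(values = values, parameter_names = pnames,
                            n_warmup_discarded =
                              as.integer(meta$n_warmup),
                            seed = as.integer(meta$seed)),
                       class = "poisirt_draws")
  }
  vcov <- if (!is.null(meta$vcov)) {
    k <- as.integer(sqrt(length(meta$vcov)))
    matrix(meta$vcov, k, k)
  } else NULL
  fit <- new_fit(meta$method, params, se, ci, conv, data, draws = draws,
                 vcov = vcov, logLik = if (is.null(meta$logLik))
                   NA_real_ else meta$logLik,
                 divergence_count = meta$divergence_count,
                 divergence_applicable = meta$divergence_applicable,
                 seed = meta$seed,
                 details = list(layout = layout, estimates = est,
                                n_nodes = meta$n_nodes,
                                model_kind = meta$model_kind,
                                identification = meta$identification))
  if (fit$method == "MCMC" && nrow(data$records)) {
    fit$pointwise_loglik <- pointwise_loglik(fit, data)
  }
  fit
}
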