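# Shared machinery for the two estimation backends: the free-parameter
# layout implied by (model kind, identification) and the fit-result
# container.

# Describes the free parameters of a model configuration and how to map
# between a flat numeric vector and an item_params object. theta_sd is
# carried on the log scale in the flat vector (marker identification only).
par_layout <- function(item_ids, model_kind, identification,
                       marker_item = NULL) {
  m <- length(item_ids)
  if (identification == "marker" && is.null(marker_item)) {
    marker_item <- item_ids[1L]
  }
  easiness_names <- sprintf("easiness[%s]", item_ids)
  slope_free_ids <- switch(model_kind,
    RPCM = if (identification == "marker") character(0) else "",
    `2PPCM` = if (identification == "marker")
      setdiff(item_ids, marker_item) else item_ids)
  slope_names <- if (model_kind == "RPCM") {
    if (length(slope_free_ids)) "slope" else character(0)
  } else sprintf("slope[%s]", slope_free_ids)
  sd_names <- if (identification == "marker") "theta_sd" else character(0)
  names <- c(easiness_names, slope_names, sd_names)
  i_e <- seq_len(m)
  i_s <- m + seq_along(slope_names)
  i_sd <- m + length(slope_names) + seq_along(sd_names)

  unpack <- function(par) {
    easiness <- par[i_e]
    theta_sd <- if (length(i_sd)) exp(par[i_sd]) else 1
    slope <- if (model_kind == "RPCM") {
      rep(if (length(i_s)) par[i_s] else 1, m)
    } else if (identification == "marker") {
      s <- numeric(m)
      s[match(marker_item, item_ids)] <- 1
      s[match(slope_free_ids, item_ids)] <- par[i_s]
      s
    } else par[i_s]
    item_params(item_ids, easiness, slope, model_kind = model_kind,
                identification = identification, theta_sd = theta_sd,
                marker_item = marker_item)
  }
  pack <- function(params) {
    v <- params$easiness
    if (model_kind == "RPCM") {
      if (length(i_s)) v <- c(v, params$slope[1L])
    } else {
      v <- c(v, params$slope[slope_free_ids])
    }
    if (length(i_sd)) v <- c(v, log(params$theta_sd))
    stats::setNames(unname(v), names)
  }
  list(names = names, n_free = length(names), unpack = unpack, pack = pack,
       idx_easiness = i_e, idx_slope = i_s, idx_sd = i_sd,
       slope_free_ids = slope_free_ids, marker_item = marker_item,
       item_ids = item_ids, model_kind = model_kind,
       identification = identification)
}

new_fit <- function(method, params, param_errors, credible_intervals,
                    convergence, data, draws = NULL,
                    pointwise_loglik = NULL, vcov = NULL, logLik = NA_real_,
                    divergence_count = 0L, divergence_applicable = FALSE,
                    priors = NULL, seed = NA_integer_, details = list()) {
  structure(list(method = method, params = params,
                 param_errors = param_errors,
                 credible_intervals = credible_intervals,
                 convergence = convergence, data = data, draws = draws,
                 pointwise_loglik = pointwise_loglik, vcov = vcov,
                 logLik = logLik, divergence_count = divergence_count,
                 divergence_applicable = divergence_applicable,
                 priors = priors, seed = seed, details = details),
            class = "poisirt_fit")
}

#' @export
logLik.poisirt_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$param_errors),
            class = "logLik")
}

#' Extract item parameter point estimates from a fit
#'
#' @param fit a `poisirt_fit` object.
#' @return The [item_params] object holding the point estimates
#'   (posterior means for MCMC, maximizers for MML).
#' @export
coef_items <- function(fit) {
  stopifnot(inherits(fit, "poisirt_fit"))
  fit$params
}
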