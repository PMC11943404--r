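#' Item parameters for Poisson count IRT models
#'
#' Holds per-item easiness `b_j` (log-count scale) and slope `a_j`
#' (log-count change per SD of theta) together with the model kind and
#' identification scheme. Under the RPCM all slopes are constrained equal;
#' under marker identification the designated marker item's slope is fixed
#' at exactly 1 and the latent SD is free.
#'
#' @param item_ids character vector of item names.
#' @param easiness numeric vector of easiness parameters, one per item.
#' @param slope numeric: either one shared value (RPCM) or one per item.
#' @param model_kind `"RPCM"` or `"2PPCM"`.
#' @param identification `"variance_standardization"` (theta SD fixed at 1)
#'   or `"marker"` (first/designated slope fixed at 1, theta SD free).
#' @param theta_sd latent standard deviation; must be 1 under variance
#'   standardization.
#' @param marker_item item id whose slope is fixed under marker
#'   identification (default: first item).
#' @return An object of class `item_params`.
#' @export
#' @examples
#' item_params(c("rope", "paperclip", "bag"), easiness = c(2.06, 1.89, 2.12),
#'             slope = c(0.34, 0.38, 0.36), model_kind = "2PPCM")
item_params <- function(item_ids, easiness, slope,
                        model_kind = c("2PPCM", "RPCM"),
                        identification = c("variance_standardization",
                                           "marker"),
                        theta_sd = 1, marker_item = NULL) {
  model_kind <- match.arg(model_kind)
  identification <- match.arg(identification)
  item_ids <- as.character(item_ids)
  m <- length(item_ids)
  if (anyDuplicated(item_ids)) stop("duplicate item ids")
  if (length(easiness) != m) stop("easiness must have one value per item")
  if (model_kind == "RPCM") {
    if (length(slope) == 1L) slope <- rep(slope, m)
    if (length(unique(slope)) != 1L) {
      stop("RPCM requires a single shared slope")
    }
  }
  if (length(slope) != m) stop("slope must have one value per item (or one shared value for RPCM)")
  if (!is.numeric(theta_sd) || theta_sd <= 0) stop("theta_sd must be > 0")
  if (identification == "variance_standardization" && theta_sd != 1) {
    stop("variance standardization fixes theta_sd at 1")
  }
  if (identification == "marker") {
    if (is.null(marker_item)) marker_item <- item_ids[1L]
    if (!marker_item %in% item_ids) stop("marker_item not among item_ids")
    if (abs(slope[match(marker_item, item_ids)] - 1) > 1e-12) {
      stop("marker identification requires the marker item's slope to be exactly 1")
    }
  } else {
    marker_item <- NULL
  }
  structure(list(item_ids = item_ids,
                 easiness = stats::setNames(as.numeric(easiness), item_ids),
                 slope = stats::setNames(as.numeric(slope), item_ids),
                 model_kind = model_kind, identification = identification,
                 theta_sd = as.numeric(theta_sd), marker_item = marker_item),
            class = "item_params")
}

#' @export
print.item_params <- function(x, ...) {
  cat(sprintf("%s item parameters (%s identification, theta_sd = %g)\n",
              x$model_kind, gsub("_", " ", x$identification), x$theta_sd))
  print(data.frame(item = x$item_ids, easiness = unname(x$easiness),
                   slope = unname(x$slope)), row.names = FALSE)
  invisible(x)
}

#' Expected count (rate) of the log-linear Poisson response model
#'
#' The model's item response function: `exp(easiness + slope * theta)`.
#' Evaluated in log space; strictly positive. Vectorized over all
#' arguments.
#'
#' @param easiness item easiness b (log-count scale).
#' @param slope item slope a.
#' @param theta person ability.
#' @return Expected count, `exp(easiness + slope * theta)`.
#' @export
#' @examples
#' rate(2.06, 0.34, 0)   # about 7.8 ideas for a person of average ability
#' rate(2.06, 0.34, 1) / rate(2.06, 0.34, 0)  # exp(0.34), about 1.4-fold
rate <- function(easiness, slope, theta) {
  exp(easiness + slope * theta)
}

#' Poisson log-likelihood of one observation
#'
#' `count * log(rate) - rate - log(count!)`, with the factorial computed
#' through the log-gamma function so large counts do not overflow.
#'
#' @param count observed non-negative integer score.
#' @param rate Poisson rate, must be > 0.
#' @return Log-likelihood value(s).
#' @export
log_likelihood_point <- function(count, rate) {
  if (any(rate <= 0)) stop("rate must be strictly positive")
  if (any(count < 0) || any(abs(count - round(count)) > 1e-8)) {
    stop("count must be a non-negative integer")
  }
  count * log(rate) - rate - lgamma(count + 1)
}

#' Joint log-likelihood of a dataset given abilities
#'
#' Local independence makes the joint log-likelihood the sum of pointwise
#' Poisson terms over the observed records only; unobserved (missing)
#' pairs contribute nothing.
#'
#' @param data a [count_data] object.
#' @param params an [item_params] object covering all items in `data`.
#' @param thetas named numeric vector of abilities covering every person
#'   appearing in `data`.
#' @return A single numeric value (0 for empty data).
#' @export
joint_log_likelihood <- function(data, params, thetas) {
  stopifnot(inherits(data, "count_data"), inherits(params, "item_params"))
  if (nrow(data$records) == 0L) return(0)
  if (!all(data$items %in% params$item_ids)) {
    stop("params do not cover all items in data")
  }
  if (is.null(names(thetas)) || !all(data$persons %in% names(thetas))) {
    stop("thetas must be named and cover every person in data")
  }
  b <- params$easiness[data$records$item]
  a <- params$slope[data$records$item]
  th <- thetas[data$records$person]
  sum(log_likelihood_point(data$records$count, rate(b, a, th)))
}

#' Convert slope-intercept parameters to the IRT parametrization
#'
#' The discrimination/difficulty form writes the rate as
#' `exp(alpha_j * (theta_i - delta_j))`, i.e. `alpha_j = a_j` and
#' `delta_j = -b_j / a_j`. The sign convention is chosen so that higher
#' ability implies a higher expected count, consistent with the
#' slope-intercept form; see the methods vignette for discussion.
#'
#' @param params an [item_params] object with all slopes nonzero.
#' @return An object of class `irt_params` with fields `item_ids`,
#'   `discrimination` and `difficulty`.
#' @export
to_irt_parametrization <- function(params) {
  stopifnot(inherits(params, "item_params"))
  if (any(params$slope == 0)) {
    stop("IRT parametrization undefined for zero slopes")
  }
  structure(list(item_ids = params$item_ids,
                 discrimination = params$slope,
                 difficulty = -params$easiness / params$slope),
            class = "irt_params")
}

#' Convert IRT-parametrized items back to slope-intercept form
#'
#' Inverse of [to_irt_parametrization]: `a_j = alpha_j`,
#' `b_j = -alpha_j * delta_j`. Round-trip is the identity.
#'
#' @param irt an `irt_params` object.
#' @param model_kind,identification,theta_sd,marker_item passed to
#'   [item_params].
#' @return An [item_params] object.
#' @export
from_irt_parametrization <- function(irt, model_kind = "2PPCM",
                                     identification =
                                       "variance_standardization",
                                     theta_sd = 1, marker_item = NULL) {
  stopifnot(inherits(irt, "irt_params"))
  item_params(irt$item_ids,
              easiness = -irt$discrimination * irt$difficulty,
              slope = irt$discrimination, model_kind = model_kind,
              identification = identification, theta_sd = theta_sd,
              marker_item = marker_item)
}

#' Write item parameters to a plain-text file
#'
#' Serializes to a small CSV with a `#`-prefixed header block carrying the
#' model kind, identification scheme, theta SD and marker item, followed
#' by one row per item (item_id, easiness, slope).
#'
#' @param params an [item_params] object.
#' @param path output path.
#' @export
write_item_params <- function(params, path) {
  stopifnot(inherits(params, "item_params"))
  hdr <- c(sprintf("# model_kind: %s", params$model_kind),
           sprintf("# identification: %s", params$identification),
           sprintf("# theta_sd: %.17g", params$theta_sd),
           sprintf("# marker_item: %s",
                   if (is.null(params$marker_item)) "" else
                     params$marker_item))
  body <- sprintf("%s,%.17g,%.17g", params$item_ids, params$easiness,
                  params$slope)
  writeLines(c(hdr, "item_id,easiness,slope", body), path)
  invisible(path)
}

#' Read item parameters written by [write_item_params]
#'
#' @param path file path.
#' @return An [item_params] object.
#' @export
read_item_params <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    ln <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(ln)) stop(sprintf("header field '%s' missing", key))
    trimws(sub(sprintf("^# %s:", key), "", ln[1L]))
  }
  body <- utils::read.csv(text = lines[!grepl("^#", lines)],
                          stringsAsFactors = FALSE)
  marker <- get_field("marker_item")
  item_params(body$item_id, body$easiness, body$slope,
              model_kind = get_field("model_kind"),
              identification = get_field("identification"),
              theta_sd = as.numeric(get_field("theta_sd")),
              marker_item = if (nzchar(marker)) marker else NULL)
}
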