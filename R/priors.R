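#' Prior specification for one parameter block
#'
#' @param block one of `"easiness"`, `"slope"`, `"theta_sd"`.
#' @param family one of `"flat"`, `"normal"`, `"truncated_normal"`,
#'   `"half_student_t"`, `"fixed"`.
#' @param location location parameter (mean of the untruncated normal).
#' @param scale scale parameter (> 0 for non-flat, non-fixed families).
#' @param lower_bound truncation bound; required for truncated families.
#' @param fixed_value required when `family == "fixed"`.
#' @param df degrees of freedom (half-Student-t only, default 3).
#' @return An object of class `prior_spec`.
#' @export
#' @examples
#' prior_spec("slope", "truncated_normal", location = 0,
#'            scale = log(4), lower_bound = 0)
prior_spec <- function(block = c("easiness", "slope", "theta_sd"),
                       family = c("flat", "normal", "truncated_normal",
                                  "half_student_t", "fixed"),
                       location = 0, scale = 1, lower_bound = NULL,
                       fixed_value = NULL, df = 3) {
  block <- match.arg(block)
  family <- match.arg(family)
  if (family == "fixed" && is.null(fixed_value)) {
    stop("fixed priors require fixed_value")
  }
  if (family %in% c("truncated_normal", "half_student_t") &&
      is.null(lower_bound)) {
    stop(sprintf("%s priors require lower_bound", family))
  }
  if (!family %in% c("flat", "fixed") && (!is.numeric(scale) || scale <= 0)) {
    stop("scale must be > 0")
  }
  structure(list(block = block, family = family, location = location,
                 scale = scale, lower_bound = lower_bound,
                 fixed_value = fixed_value, df = df),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  desc <- switch(x$family,
    flat = "flat",
    fixed = sprintf("fixed at %g", x$fixed_value),
    normal = sprintf("normal(%g, %g)", x$location, x$scale),
    truncated_normal = sprintf("normal(%g, %g) truncated at %g",
                               x$location, x$scale, x$lower_bound),
    half_student_t = sprintf("student_t(%g, %g, %g) truncated at %g",
                             x$df, x$location, x$scale, x$lower_bound))
  cat(sprintf("prior[%s]: %s\n", x$block, desc))
  invisible(x)
}

#' Weakly informative easiness prior from a score range
#'
#' Builds the log-midpoint / log-half-range rule: a normal distribution
#' truncated at 0 whose mean is the log of the midpoint count,
#' `log(1 + (max - min)/2)`, and whose SD is the log of half the range,
#' `log((max - min)/2)`. For scores spanning 1 to 23 this gives location
#' `log(12)` (about 2.48) and scale `log(11)` (about 2.40).
#'
#' @param min_score,max_score observed or hypothesized score range
#'   (`max_score > min_score >= 0`).
#' @return A `prior_spec` for the easiness block.
#' @export
easiness_prior_from_range <- function(min_score, max_score) {
  if (max_score <= min_score || min_score < 0) {
    stop("need max_score > min_score >= 0")
  }
  half_range <- (max_score - min_score) / 2
  if (half_range <= 1) {
    stop("score range too narrow: log of half the range would be <= 0; specify a prior manually")
  }
  prior_spec("easiness", "truncated_normal",
             location = log(1 + half_range), scale = log(half_range),
             lower_bound = 0)
}

#' Weakly informative slope prior from a maximum fold change
#'
#' A one-SD increase in theta multiplies the expected count by
#' `exp(a_j)`; if it is judged to at most multiply the count `max_fold`
#' times, a positive-truncated normal with location 0 and scale
#' `log(max_fold)` is weakly informative. `max_fold = 4` gives scale
#' `log(4)` (about 1.39).
#'
#' @param max_fold hypothesized maximum multiplicative effect (> 1).
#' @return A `prior_spec` for the slope block.
#' @export
slope_prior_from_fold <- function(max_fold) {
  if (!is.numeric(max_fold) || max_fold <= 1) {
    stop("max_fold must be > 1")
  }
  prior_spec("slope", "truncated_normal", location = 0,
             scale = log(max_fold), lower_bound = 0)
}

#' Prior set for a model fit
#'
#' Bundles the three block priors and (for marker identification) the
#' marker item. Invariants: under variance standardization the theta-SD
#' prior must be fixed at 1; under marker identification a marker item
#' must be named (its slope is fixed at 1 by the model, not by a prior).
#'
#' @param easiness_prior,slope_prior,theta_sd_prior `prior_spec` objects.
#' @param marker_item optional item id (marker identification only).
#' @return An object of class `prior_set`.
#' @export
prior_set <- function(easiness_prior, slope_prior, theta_sd_prior,
                      marker_item = NULL) {
  for (p in list(easiness_prior, slope_prior, theta_sd_prior)) {
    stopifnot(inherits(p, "prior_spec"))
  }
  structure(list(easiness_prior = easiness_prior,
                 slope_prior = slope_prior,
                 theta_sd_prior = theta_sd_prior,
                 marker_item = marker_item),
            class = "prior_set")
}

#' @export
print.prior_set <- function(x, ...) {
  print(x$easiness_prior); print(x$slope_prior); print(x$theta_sd_prior)
  if (!is.null(x$marker_item)) {
    cat(sprintf("marker item: %s (slope fixed at 1)\n", x$marker_item))
  }
  invisible(x)
}

#' Default weakly informative priors
#'
#' Under variance standardization: theta SD fixed at 1, easiness from the
#' observed score range ([easiness_prior_from_range]), slope from a
#' hypothesized maximum fold change ([slope_prior_from_fold]). Under
#' marker identification: the first item's slope is fixed at 1 by the
#' model, the remaining slopes get an untruncated normal(1, 1) prior,
#' easiness as above, and the free theta SD gets a half-Student-t(3, 2.5)
#' prior bounded below at 0.
#'
#' @param method `"variance_standardization"` or `"marker"`.
#' @param data a [count_data] object (supplies the observed score range).
#' @param max_fold slope-prior fold ceiling (default 4).
#' @param marker_item marker item id (default: first item in the data).
#' @return A `prior_set`.
#' @export
#' @examples
#' d <- count_data(c("P1", "P1", "P2"), c("I1", "I2", "I1"), c(1L, 9L, 23L))
#' default_priors("variance_standardization", d)
default_priors <- function(method = c("variance_standardization", "marker"),
                           data, max_fold = 4, marker_item = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(data, "count_data"))
  easiness <- easiness_prior_from_range(min(data$records$count),
                                        max(data$records$count))
  if (method == "variance_standardization") {
    prior_set(easiness,
              slope_prior_from_fold(max_fold),
              prior_spec("theta_sd", "fixed", fixed_value = 1))
  } else {
    if (is.null(marker_item)) marker_item <- data$items[1L]
    prior_set(easiness,
              prior_spec("slope", "normal", location = 1, scale = 1),
              prior_spec("theta_sd", "half_student_t", location = 0,
                         scale = 2.5, lower_bound = 0, df = 3),
              marker_item = marker_item)
  }
}

#' Read a prior set from a JSON config file
#'
#' The file holds one object per block (`easiness`, `slope`,
#' `theta_sd`), each accepting `family`, `location`, `scale`,
#' `lower_bound`, `fixed_value` and `df` keys, plus an optional
#' top-level `marker_item`. Mirrors [write_prior_config].
#'
#' @param path path to the JSON file.
#' @return A [prior_set].
#' @export
read_prior_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(block) {
    b <- cfg[[block]]
    if (is.null(b)) stop(sprintf("prior config lacks block '%s'", block))
    prior_spec(block, b$family,
               location = if (is.null(b$location)) 0 else b$location,
               scale = if (is.null(b$scale)) 1 else b$scale,
               lower_bound = b$lower_bound,
               fixed_value = b$fixed_value,
               df = if (is.null(b$df)) 3 else b$df)
  }
  prior_set(mk("easiness"), mk("slope"), mk("theta_sd"),
            marker_item = cfg$marker_item)
}

#' Write a prior set to a JSON config file
#'
#' @param priors a [prior_set].
#' @param path output path.
#' @export
write_prior_config <- function(priors, path) {
  stopifnot(inherits(priors, "prior_set"))
  blk <- function(p) {
    Filter(Negate(is.null),
           list(family = p$family, location = p$location, scale = p$scale,
                lower_bound = p$lower_bound, fixed_value = p$fixed_value,
                df = if (p$family == "half_student_t") p$df else NULL))
  }
  jsonlite::write_json(
    Filter(Negate(is.null),
           list(easiness = blk(priors$easiness_prior),
                slope = blk(priors$slope_prior),
                theta_sd = blk(priors$theta_sd_prior),
                marker_item = priors$marker_item)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# log density of one prior_spec at x (vectorized); truncated families are
# renormalized over their support; outside support -> -Inf
prior_log_density <- function(spec, x) {
  out <- switch(spec$family,
    flat = rep(0, length(x)),
    fixed = rep(0, length(x)),
    normal = stats::dnorm(x, spec$location, spec$scale, log = TRUE),
    truncated_normal = {
      lognorm <- stats::pnorm(spec$lower_bound, spec$location, spec$scale,
                              lower.tail = FALSE, log.p = TRUE)
      stats::dnorm(x, spec$location, spec$scale, log = TRUE) - lognorm
    },
    half_student_t = {
      z <- (x - spec$location) / spec$scale
      zb <- (spec$lower_bound - spec$location) / spec$scale
      lognorm <- stats::pt(zb, spec$df, lower.tail = FALSE, log.p = TRUE)
      stats::dt(z, spec$df, log = TRUE) - log(spec$scale) - lognorm
    })
  if (!is.null(spec$lower_bound)) out[x < spec$lower_bound] <- -Inf
  out
}

# derivative of prior_log_density w.r.t. x (inside the support);
# truncation constants do not depend on x
prior_log_density_grad <- function(spec, x) {
  switch(spec$family,
    flat = rep(0, length(x)),
    fixed = rep(0, length(x)),
    normal = -(x - spec$location) / spec$scale^2,
    truncated_normal = -(x - spec$location) / spec$scale^2,
    half_student_t = {
      z <- (x - spec$location) / spec$scale
      -(spec$df + 1) * z / ((spec$df + z^2) * spec$scale)
    })
}

#' Joint log prior density of a parameter set
#'
#' Sums the log prior densities over the free parameters of `params`
#' under `priors`. Truncated families are renormalized over their
#' support; flat and fixed blocks contribute 0; a parameter outside a
#' truncation support yields `-Inf` (a rejected state, not an error).
#'
#' @param priors a [prior_set].
#' @param params an [item_params] object consistent with the priors'
#'   identification scheme.
#' @return A single numeric value (possibly `-Inf`).
#' @export
log_prior_density <- function(priors, params) {
  stopifnot(inherits(priors, "prior_set"), inherits(params, "item_params"))
  total <- sum(prior_log_density(priors$easiness_prior, params$easiness))
  if (params$identification == "marker") {
    if (is.null(priors$marker_item) ||
        priors$marker_item != params$marker_item) {
      stop("priors' marker item does not match params")
    }
    free_slopes <- params$slope[params$item_ids != params$marker_item]
    if (length(free_slopes)) {
      total <- total + sum(prior_log_density(priors$slope_prior,
                                             free_slopes))
    }
    total <- total + sum(prior_log_density(priors$theta_sd_prior,
                                           params$theta_sd))
  } else {
    if (priors$theta_sd_prior$family != "fixed") {
      stop("variance standardization requires a fixed theta_sd prior")
    }
    slopes <- if (params$model_kind == "RPCM") params$slope[1L] else
      params$slope
    total <- total + sum(prior_log_density(priors$slope_prior, slopes))
  }
  total
}
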