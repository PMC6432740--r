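#' Recall bias (mean signed error)
#'
#' Bounded spaces use the arithmetic mean. Circular errors are doubled onto
#' the full circle, averaged as unit vectors, and the mean direction is
#' halved back to the stimulus scale, wrapped into `(-period/2, period/2]`.
#'
#' @param errors Signed errors from [signed_error()] (degrees for circular
#'   spaces, stimulus units for bounded), non-empty.
#' @param space The feature space the errors live in.
#' @return Mean error on the stimulus scale.
#' @export
error_bias <- function(errors, space) {
  if (length(errors) == 0) stop("empty error set", call. = FALSE)
  if (!is_circular(space)) return(mean(errors))
  a <- errors * (2 * pi / space$period) # doubled-angle radians
  mu <- atan2(mean(sin(a)), mean(cos(a)))
  signed_error(space, 0, mu * space$period / (2 * pi))
}

#' Recall variability (standard deviation of errors)
#'
#' Bounded spaces use the sample standard deviation (n - 1 denominator).
#' Circular errors use Fisher's circular standard deviation
#' `sqrt(-2 ln Rbar)` on the doubled-angle circle, with `Rbar` the mean
#' resultant length; `Rbar = 0` yields `Inf`, not an error. The result is
#' reported on the stimulus scale by default (doubled-angle radians times
#' `period / (2 pi)`); `scale = "doubled_radians"` returns the raw circular
#' SD.
#'
#' @inheritParams error_bias
#' @param scale For circular spaces, `"stimulus"` (default) or
#'   `"doubled_radians"`.
#' @return Dispersion (>= 0, possibly `Inf` for circular data).
#' @export
error_dispersion <- function(errors, space,
                             scale = c("stimulus", "doubled_radians")) {
  scale <- match.arg(scale)
  if (length(errors) == 0) stop("empty error set", call. = FALSE)
  if (!is_circular(space)) return(stats::sd(errors))
  a <- errors * (2 * pi / space$period)
  rbar <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  sd_rad <- if (rbar < 1e-12) Inf else sqrt(-2 * log(rbar))
  if (scale == "doubled_radians") sd_rad else sd_rad * space$period / (2 * pi)
}

#' Summary table of recall bias and variability
#'
#' One row per combination of the grouping keys, with the mean signed
#' error (`bias`), its dispersion (`sd`, stimulus scale; plus
#' `sd_doubled_rad` for circular spaces) and the trial count `n`. An empty
#' grouping gives a single grand-summary row. Errors are computed with the
#' circular or Euclidean convention appropriate to `space`.
#'
#' @param trials Data frame with `target` and `response` columns plus any
#'   grouping keys (e.g. `participant`, `set_size`, `emotion`, `target`).
#' @param grouping Character vector of column names to group by (may be
#'   empty).
#' @param space The feature space of `target` and `response`.
#' @return A tibble, one row per group.
#' @export
summarize_trials <- function(trials, grouping = character(), space) {
  stopifnot(inherits(space, "feature_space"))
  unknown <- setdiff(grouping, names(trials))
  if (length(unknown) > 0)
    stop(sprintf("unknown grouping key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  miss <- setdiff(c("target", "response"), names(trials))
  if (length(miss) > 0)
    stop(sprintf("trial table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (nrow(trials) == 0) stop("empty trial set", call. = FALSE)
  check_in_space(space, trials$target, "target")
  check_in_space(space, trials$response, "response")
  trials <- dplyr::mutate(
    tibble::as_tibble(trials),
    .error = signed_error(space, .data$target, .data$response))
  out <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      bias = error_bias(.data$.error, space),
      sd = error_dispersion(.data$.error, space),
      n = dplyr::n(),
      .groups = "drop")
  if (is_circular(space)) {
    out$sd_doubled_rad <- out$sd * (2 * pi / space$period)
  }
  out
}
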