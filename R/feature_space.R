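#' Circular feature space
#'
#' Geometry of a periodic stimulus dimension such as grating orientation.
#' Orientation repeats every 180 degrees; internally all angles are doubled
#' onto the full 360-degree circle (the standard directional-statistics
#' treatment of axial data) and halved again on output.
#'
#' @param period Angular extent in degrees over which stimuli repeat
#'   (180 for grating orientation).
#' @return An object of class `c("circular_space", "feature_space")`.
#' @examples
#' sp <- circular_space(180)
#' signed_error(sp, 170, 10) # +20: wraps across the 180/0 seam
#' @export
circular_space <- function(period = 180) {
  stopifnot(is.numeric(period), length(period) == 1, period > 0)
  structure(list(period = as.numeric(period)),
            class = c("circular_space", "feature_space"))
}

#' Bounded linear feature space
#'
#' Geometry of a stimulus dimension confined to an interval, such as the
#' morph intensity of a facial expression between a neutral face (0%) and
#' the full expression (100%). Values outside the interval are rejected,
#' never silently clamped.
#'
#' @param lower,upper Interval endpoints (default 0 and 100, % intensity).
#' @return An object of class `c("bounded_space", "feature_space")`.
#' @export
bounded_space <- function(lower = 0, upper = 100) {
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == 1, length(upper) == 1, lower < upper)
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper)),
            class = c("bounded_space", "feature_space"))
}

is_circular <- function(space) inherits(space, "circular_space")

#' @export
print.feature_space <- function(x, ...) {
  if (is_circular(x)) {
    cat(sprintf("<circular feature space, period %g degrees>\n", x$period))
  } else {
    cat(sprintf("<bounded feature space [%g, %g]>\n", x$lower, x$upper))
  }
  invisible(x)
}

#' Canonical wrapping of stimulus values
#'
#' Maps circular values into `[0, period)`; validates bounded values.
#' Wrapping is idempotent.
#'
#' @param space A [circular_space()] or [bounded_space()].
#' @param x Numeric vector of stimulus values.
#' @return Numeric vector of canonical values.
#' @export
wrap_value <- function(space, x) {
  if (is_circular(space)) {
    x %% space$period
  } else {
    check_in_space(space, x, "value")
    x
  }
}

check_in_space <- function(space, x, what = "value") {
  if (is_circular(space)) return(invisible(x))
  bad <- which(!is.na(x) & (x < space$lower | x > space$upper))
  if (length(bad) > 0) {
    stop(sprintf("%s out of range [%g, %g] at position %d (got %g)",
                 what, space$lower, space$upper, bad[1], x[bad[1]]),
         call. = FALSE)
  }
  invisible(x)
}

#' Signed reproduction error
#'
#' Deviation of a response from its target. On a circular space the
#' deviation is wrapped into `(-period/2, period/2]` (the antipodal tie
#' wraps to `+period/2`); on a bounded space it is the plain difference
#' `response - target`, after range validation.
#'
#' @inheritParams wrap_value
#' @param target,response Stimulus values (vectorized, recycled).
#' @return Numeric vector of signed errors.
#' @examples
#' signed_error(circular_space(180), 10, 170) # -20
#' signed_error(bounded_space(0, 100), 91, 75) # -16
#' @export
signed_error <- function(space, target, response) {
  if (is_circular(space)) {
    p <- space$period
    e <- (response - target) %% p      # [0, p)
    ifelse(e > p / 2, e - p, e)        # (-p/2, p/2]
  } else {
    check_in_space(space, target, "target")
    check_in_space(space, response, "response")
    response - target
  }
}

#' Histogram bin edges over a response space
#'
#' Equal-width, half-open bins tiling the full response space exactly once
#' (the last bounded bin is closed at the upper limit; circular bins wrap).
#' The model-fitting pipeline uses 40 bins for orientation and 20 for
#' expression intensity by default.
#'
#' @inheritParams wrap_value
#' @param n_bins Number of bins, at least 2.
#' @return Numeric vector of `n_bins + 1` ordered bin edges.
#' @export
response_bins <- function(space, n_bins) {
  if (!is.numeric(n_bins) || length(n_bins) != 1 || n_bins < 2 ||
      n_bins != round(n_bins)) {
    stop("n_bins must be an integer >= 2", call. = FALSE)
  }
  if (is_circular(space)) {
    seq(0, space$period, length.out = n_bins + 1)
  } else {
    seq(space$lower, space$upper, length.out = n_bins + 1)
  }
}

#' Map responses to bins
#'
#' Assigns each response to the unique half-open bin containing it.
#' Circular responses are wrapped first, so every valid value maps to
#' exactly one of the `n_bins` bins.
#'
#' @inheritParams wrap_value
#' @param edges Bin edges from [response_bins()].
#' @param x Responses to bin.
#' @return Integer bin indices in `1..n_bins`.
#' @export
bin_index <- function(space, edges, x) {
  n_bins <- length(edges) - 1
  if (is_circular(space)) {
    x <- wrap_value(space, x)
    idx <- findInterval(x, edges)
    idx[idx > n_bins] <- n_bins # guard fp rounding at the seam
  } else {
    check_in_space(space, x, "response")
    idx <- findInterval(x, edges, rightmost.closed = TRUE)
  }
  idx
}

# internal unit conversion: circular stimuli live on the doubled circle in
# radians; bounded stimuli are used as-is
to_internal <- function(space, x) {
  if (is_circular(space)) (x %% space$period) * (2 * pi / space$period) else x
}

from_internal <- function(space, x) {
  if (is_circular(space)) x * (space$period / (2 * pi)) else x
}
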