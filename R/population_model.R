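#' Population-code parameters
#'
#' The neural resource model has two free parameters: the gain constant
#' `gain` (expected total spike count of the whole population, shared across
#' all memorized items) and the tuning width `width` of each neuron's tuning
#' function. On a circular space the tuning kernel is the von Mises-shaped
#' `exp((cos(d) - 1) / width^2)` with `d` the distance on the doubled-angle
#' circle, so `width` is in doubled-angle radians (concentration
#' `kappa = 1/width^2`); on a bounded space the kernel is the Gaussian
#' `exp(-d^2 / (2 width^2))` with `width` in stimulus units (% intensity).
#' Preferred values are evenly spaced: around the full circle, or over the
#' bounded interval inclusive of both ends.
#'
#' @param space A [circular_space()] or [bounded_space()].
#' @param gain Gain constant, > 0.
#' @param width Tuning width, > 0 (see Details above for units).
#' @param n_neurons Population size, >= 2 (default 1000).
#' @return An object of class `"population_params"` with fields `space`,
#'   `gain`, `width`, `n_neurons` and `preferred_values` (user-facing
#'   stimulus units).
#' @export
population_params <- function(space, gain, width, n_neurons = 1000) {
  stopifnot(inherits(space, "feature_space"))
  if (!is.numeric(gain) || length(gain) != 1 || gain <= 0)
    stop("gain must be a positive scalar", call. = FALSE)
  if (!is.numeric(width) || length(width) != 1 || width <= 0)
    stop("width must be a positive scalar", call. = FALSE)
  if (!is.numeric(n_neurons) || length(n_neurons) != 1 || n_neurons < 2)
    stop("n_neurons must be at least 2", call. = FALSE)
  n_neurons <- as.integer(n_neurons)
  pref <- if (is_circular(space)) {
    seq(0, space$period, length.out = n_neurons + 1)[-(n_neurons + 1)]
  } else {
    seq(space$lower, space$upper, length.out = n_neurons)
  }
  structure(list(space = space, gain = gain, width = width,
                 n_neurons = n_neurons, preferred_values = pref),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf("<population code: gain %g, tuning width %g, %d neurons>\n",
              x$gain, x$width, x$n_neurons))
  print(x$space)
  invisible(x)
}

# log tuning kernel values, one row per neuron, one column per stimulus value
# (all in internal units); underflow-safe because it never leaves log space
log_tuning <- function(params, x_internal) {
  sp <- params$space
  pref <- to_internal(sp, params$preferred_values)
  w <- params$width
  if (is_circular(sp)) {
    (cos(outer(pref, x_internal, "-")) - 1) / w^2
  } else {
    -outer(pref, x_internal, "-")^2 / (2 * w^2)
  }
}

#' Expected spike counts for one memorized item
#'
#' Mean count of neuron `i` is `(gain/set_size) * g_i(theta) / sum_j
#' g_j(theta)`: divisive normalization holds the summed expected count at
#' exactly `gain/set_size` for every stimulus value, including near the
#' edges of a bounded space. This is the model's resource limit: total
#' population activity is constant across memory load, so the activity
#' devoted to any one item is inversely proportional to set size.
#'
#' @param params A [population_params()].
#' @param stimulus A single stimulus value, valid in the parameter space.
#' @param set_size Number of memorized items, >= 1.
#' @return Numeric vector of `n_neurons` mean spike counts.
#' @export
expected_rates <- function(params, stimulus, set_size) {
  stopifnot(inherits(params, "population_params"))
  if (!is.numeric(set_size) || length(set_size) != 1 || set_size < 1)
    stop("set_size must be a positive count", call. = FALSE)
  check_in_space(params$space, stimulus, "stimulus")
  lg <- drop(log_tuning(params, to_internal(params$space, stimulus)))
  g <- exp(lg - max(lg))
  s <- sum(g)
  if (s == 0) stop("tuning kernel sums to zero", call. = FALSE)
  (params$gain / set_size) * g / s
}

#' Poisson spiking
#'
#' One simulated encoding: independent Poisson draws, one per neuron,
#' reproducible under `set.seed()`.
#'
#' @param rates Non-negative mean spike counts, e.g. from [expected_rates()].
#' @return Integer vector of spike counts (a spike pattern).
#' @export
sample_spikes <- function(rates) {
  if (any(rates < 0)) stop("negative rate", call. = FALSE)
  stats::rpois(length(rates), rates)
}

#' Default decoding grid
#'
#' Dense grid of candidate stimulus values used by the decoders:
#' 1 degree resolution for orientation (before angle doubling) and 0.5%
#' for expression intensity by default. The circular grid tiles
#' `[0, period)`; the bounded grid spans the closed interval, so decoded
#' responses never need clamping.
#'
#' @param space A feature space.
#' @param resolution Grid step in stimulus units; `NULL` for the default.
#' @return Numeric vector of grid values.
#' @export
decoding_grid <- function(space, resolution = NULL) {
  if (is_circular(space)) {
    if (is.null(resolution)) resolution <- space$period / 180
    seq(0, space$period - resolution / 2, by = resolution)
  } else {
    if (is.null(resolution)) resolution <- 0.5
    seq(space$lower, space$upper, by = resolution)
  }
}

#' Log likelihood of a spike pattern over candidate stimuli
#'
#' For each grid value `theta` returns `sum_i [n_i log f_i(theta) -
#' f_i(theta)]` up to an additive constant independent of `theta`
#' (factorial terms dropped), where `f_i` are the normalized expected
#' rates. Because divisive normalization fixes `sum_i f_i(theta)` at
#' `gain/set_size`, a zero-spike pattern yields a likelihood that is
#' constant across the grid.
#'
#' @param spikes Integer spike counts, length `n_neurons`.
#' @param params A [population_params()].
#' @param set_size Memory load.
#' @param grid Candidate stimulus values (default [decoding_grid()]).
#' @return Numeric vector of log likelihoods, one per grid value.
#' @export
log_likelihood_grid <- function(spikes, params, set_size,
                                grid = decoding_grid(params$space)) {
  stopifnot(inherits(params, "population_params"))
  if (length(spikes) != params$n_neurons)
    stop("spike pattern length must equal n_neurons", call. = FALSE)
  if (any(spikes < 0)) stop("negative spike count", call. = FALSE)
  gi <- to_internal(params$space, grid)
  lg <- log_tuning(params, gi)                      # M x L
  logS <- apply(lg, 2, logsumexp)
  gain_eff <- params$gain / set_size
  # log f_i(theta) = log(gain_eff) + lg - logS; n . log f  minus  sum f
  nz <- spikes > 0
  ll <- log(gain_eff) * sum(spikes) - sum(spikes) * logS - gain_eff
  if (any(nz)) {
    contrib <- colSums(lg[nz, , drop = FALSE] * spikes[nz])
    ll <- ll + contrib
  }
  # f_i(theta) = 0 with n_i > 0 would give -Inf; with width > 0 the log
  # kernel is finite everywhere, so this arises only from degenerate input
  ll[is.nan(ll)] <- -Inf
  ll
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Maximum-likelihood decoder
#'
#' Returns the grid point with maximal log likelihood; ties are broken by
#' the lowest grid index, so a zero-spike (flat-likelihood) pattern decodes
#' to the first grid point.
#'
#' @inheritParams log_likelihood_grid
#' @return A single decoded stimulus value.
#' @export
decode_ml <- function(spikes, params, set_size,
                      grid = decoding_grid(params$space)) {
  ll <- log_likelihood_grid(spikes, params, set_size, grid)
  grid[which.max(ll)]
}

#' Prior distributions over the decoding grid
#'
#' `uniform_prior()` puts equal weight on every grid point (the default in
#' the model: uniform over the full response range); `point_prior()` is the
#' degenerate prior concentrated at the grid point nearest `at`.
#'
#' @param space A feature space.
#' @param grid Decoding grid the prior is defined over.
#' @param at Location of the point mass.
#' @return A list with fields `space`, `grid` and `weights` (summing to 1).
#' @export
uniform_prior <- function(space, grid = decoding_grid(space)) {
  structure(list(space = space, grid = grid,
                 weights = rep(1 / length(grid), length(grid))),
            class = "prior_distribution")
}

#' @rdname uniform_prior
#' @export
point_prior <- function(space, at, grid = decoding_grid(space)) {
  w <- numeric(length(grid))
  d <- if (is_circular(space)) abs(signed_error(space, at, grid)) else abs(grid - at)
  w[which.min(d)] <- 1
  structure(list(space = space, grid = grid, weights = w),
            class = "prior_distribution")
}

#' Posterior over the decoding grid
#'
#' Discrete posterior proportional to `exp(log likelihood) * prior`,
#' normalized with a log-sum-exp-stable computation. With a uniform prior
#' its argmax coincides with [decode_ml()] on every spike pattern, and a
#' zero-spike pattern returns the prior exactly.
#'
#' @inheritParams log_likelihood_grid
#' @param prior A prior from [uniform_prior()] or [point_prior()]; its grid
#'   is used as the decoding grid.
#' @return Numeric vector of posterior probabilities over the prior's grid.
#' @export
posterior_over_grid <- function(spikes, params, set_size,
                                prior = uniform_prior(params$space)) {
  ll <- log_likelihood_grid(spikes, params, set_size, prior$grid)
  lw <- ll + log(prior$weights)
  m <- max(lw)
  if (!is.finite(m)) stop("posterior has no mass on the grid", call. = FALSE)
  p <- exp(lw - m)
  p / sum(p)
}

#' Posterior-sampling decoder
#'
#' Generates a response by drawing once from the posterior distribution
#' over the decoding grid instead of maximizing it. Reproducible under
#' `set.seed()`.
#'
#' @inheritParams posterior_over_grid
#' @return A single decoded stimulus value.
#' @export
decode_posterior_sample <- function(spikes, params, set_size,
                                    prior = uniform_prior(params$space)) {
  p <- posterior_over_grid(spikes, params, set_size, prior)
  prior$grid[sample.int(length(p), 1, prob = p)]
}

# Vectorized Monte-Carlo encode-decode via the C++ engine.
#
# targets / gain_eff are parallel vectors (recycled); fixed_k = -1 draws the
# total spike count from Poisson(gain_eff), a non-negative value conditions
# on that exact count (used by the stratified fitter). Returns responses in
# user-facing units, grouped by target (n_per_target consecutive responses
# per target). Uses the R RNG, so it is reproducible under set.seed().
simulate_responses <- function(params, targets, set_size = 1,
                               decoder = c("ml", "posterior_sampling"),
                               n_per_target = 1,
                               grid = decoding_grid(params$space),
                               prior = NULL, gain_eff = NULL,
                               fixed_k = NULL) {
  decoder <- match.arg(decoder)
  sp <- params$space
  nt <- length(targets)
  if (is.null(gain_eff)) gain_eff <- params$gain / set_size
  gain_eff <- rep_len(gain_eff, nt)
  fixed_k <- if (is.null(fixed_k)) rep(-1L, nt) else rep_len(as.integer(fixed_k), nt)
  log_prior <- if (decoder == "posterior_sampling") {
    if (is.null(prior)) prior <- uniform_prior(sp, grid)
    if (length(prior$weights) != length(grid))
      stop("prior grid must match the decoding grid", call. = FALSE)
    log(prior$weights)
  } else numeric(length(grid))
  res <- pc_simulate_cpp(
    space_type = if (is_circular(sp)) 0L else 1L,
    targets = to_internal(sp, targets),
    gain_eff = gain_eff,
    fixed_k = fixed_k,
    omega = params$width,
    prefs = to_internal(sp, params$preferred_values),
    grid = to_internal(sp, grid),
    decoder = if (decoder == "ml") 0L else 1L,
    log_prior = log_prior,
    n_per_target = as.integer(n_per_target))
  from_internal(sp, res)
}
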