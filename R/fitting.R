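#' Standard parameter grids for the fitting tasks
#'
#' Grid-search parameter lattices for the three fitting tasks:
#' \describe{
#'   \item{`orientation_ml`}{60 log-spaced values in `[1, 100]` for both the
#'     gain and the width axis. The width axis of this grid is on the
#'     concentration scale (`kappa = 1/omega^2`): its image under
#'     `omega = kappa^(-1/2)` is `[0.1, 1]`, the same tuning-width range the
#'     posterior-sampling orientation grid spans, which is what makes fitted
#'     widths comparable across the two decoders. The fitter converts
#'     internally; `width_scale` records the convention.}
#'   \item{`orientation_sampling`}{50 log-spaced gains in `[0.1, 1000]` by
#'     20 log-spaced widths in `[0.1, 1]` (doubled-angle radians).}
#'   \item{`expression_sampling`}{50 log-spaced gains in `[0.1, 1000]` by
#'     50 log-spaced widths in `[0.01, 10]` (% intensity).}
#' }
#'
#' @param task One of `"orientation_ml"`, `"orientation_sampling"`,
#'   `"expression_sampling"`.
#' @return A list with `gain`, `width`, `width_scale` (`"width"` or
#'   `"concentration"`) and `task`.
#' @export
default_grids <- function(task) {
  grids <- switch(task,
    orientation_ml = list(
      gain = 10^seq(0, 2, length.out = 60),
      width = 10^seq(0, 2, length.out = 60),
      width_scale = "concentration"),
    orientation_sampling = list(
      gain = 10^seq(-1, 3, length.out = 50),
      width = 10^seq(-1, 0, length.out = 20),
      width_scale = "width"),
    expression_sampling = list(
      gain = 10^seq(-1, 3, length.out = 50),
      width = 10^seq(-2, 1, length.out = 50),
      width_scale = "width"),
    stop(sprintf("unknown task '%s'", task), call. = FALSE))
  grids$task <- task
  grids
}

task_space <- function(task) {
  if (startsWith(task, "orientation")) circular_space(180)
  else if (startsWith(task, "expression")) bounded_space(0, 100)
  else stop(sprintf("unknown task '%s'", task), call. = FALSE)
}

task_decoder <- function(task) {
  if (endsWith(task, "_ml")) "ml" else "posterior_sampling"
}

task_n_bins <- function(space) if (is_circular(space)) 40L else 20L
task_n_sim <- function(space) if (is_circular(space)) 1e4 else 1e5

# widths on the concentration scale are kappa = 1/omega^2
grid_width_to_omega <- function(w, width_scale) {
  if (identical(width_scale, "concentration")) 1 / sqrt(w) else w
}

# deterministic per-stratum seed derivation from a master seed (kept < 2^31)
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) + as.numeric(k) * 1299721) %% 2147483629) + 1L
}

#' Akaike information criterion
#'
#' `2 * n_params - 2 * log_likelihood`.
#'
#' @param log_likelihood Maximized log likelihood.
#' @param n_params Number of free parameters, >= 0.
#' @return AIC value.
#' @export
aic <- function(log_likelihood, n_params) {
  stopifnot(is.numeric(n_params), n_params >= 0)
  2 * n_params - 2 * log_likelihood
}

#' Monte-Carlo prediction of a binned response distribution
#'
#' Simulates `n_sim` encode-decode cycles at one target and set size and
#' returns a histogram estimate of the response distribution over the bins
#' of [response_bins()]. Each bin receives a pseudo-count of one before
#' renormalization (add-one smoothing), so every probability is at least
#' `1/(n_sim + n_bins)` and no observed response can have zero likelihood.
#' Defaults follow the model-fitting pipeline: 10^4 simulated responses in
#' 40 bins for orientation, 10^5 responses in 20 bins for expression
#' intensity. Reproducible under `set.seed()`.
#'
#' @param params A [population_params()].
#' @param target Target stimulus value.
#' @param set_size Memory load.
#' @param decoder `"ml"` or `"posterior_sampling"`.
#' @param n_sim Number of simulated responses.
#' @param n_bins Number of histogram bins.
#' @param prior Prior for the posterior-sampling decoder (default uniform).
#' @param grid Decoding grid (default [decoding_grid()]).
#' @return An object of class `"error_distribution"` with fields `space`,
#'   `target`, `set_size`, `decoder`, `bin_edges`, `probabilities`, `n_sim`.
#' @export
predict_distribution <- function(params, target, set_size,
                                 decoder = c("ml", "posterior_sampling"),
                                 n_sim = task_n_sim(params$space),
                                 n_bins = task_n_bins(params$space),
                                 prior = NULL,
                                 grid = decoding_grid(params$space)) {
  decoder <- match.arg(decoder)
  stopifnot(n_sim >= 1)
  sp <- params$space
  check_in_space(sp, target, "target")
  edges <- response_bins(sp, n_bins)
  res <- simulate_responses(params, targets = target, set_size = set_size,
                            decoder = decoder, n_per_target = n_sim,
                            grid = grid, prior = prior)
  counts <- tabulate(bin_index(sp, edges, res), nbins = n_bins)
  structure(list(space = sp, target = target, set_size = set_size,
                 decoder = decoder, bin_edges = edges,
                 probabilities = (counts + 1) / (n_sim + n_bins),
                 n_sim = n_sim),
            class = "error_distribution")
}

#' @export
print.error_distribution <- function(x, ...) {
  cat(sprintf(
    "<predicted response distribution: target %g, set size %d, %s decoder, %d bins>\n",
    x$target, as.integer(x$set_size), x$decoder,
    length(x$probabilities)))
  invisible(x)
}

check_trials <- function(trials, space, need_response = TRUE) {
  need <- c("target", "set_size", if (need_response) "response")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0)
    stop(sprintf("trial table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (nrow(trials) == 0) stop("empty trial set", call. = FALSE)
  check_in_space(space, trials$target, "target")
  if (need_response) check_in_space(space, trials$response, "response")
  invisible(trials)
}

# unique (target, set_size) cells in a fixed, documented order, with the
# binned response counts of the trials falling in each cell
trial_cells <- function(trials, space, edges) {
  key <- paste(format(trials$target, digits = 12), trials$set_size)
  uk <- sort(unique(key))
  lapply(uk, function(k) {
    rows <- which(key == k)
    list(target = trials$target[rows[1]],
         set_size = as.integer(trials$set_size[rows[1]]),
         counts = tabulate(bin_index(space, edges, trials$response[rows]),
                           nbins = length(edges) - 1),
         rows = rows)
  })
}

#' Log likelihood of trial data under the population model
#'
#' Sum over trials of the log probability of the histogram bin containing
#' the observed response, under the Monte-Carlo predicted distribution for
#' that trial's target and set size. Distributions are computed once per
#' unique (target, set size) cell; with `cache = FALSE` they are naively
#' recomputed per trial (same per-cell derived seeds, so the result is
#' identical — useful as a cross-check).
#'
#' @param trials Data frame with columns `target`, `set_size`, `response`.
#' @param params A [population_params()].
#' @inheritParams predict_distribution
#' @param seed Master seed; per-cell seeds are derived deterministically
#'   from it in cell order (cells sorted by target then set size). `NULL`
#'   uses the ambient RNG stream.
#' @param cache Compute one distribution per unique cell (default) or per
#'   trial.
#' @param per_trial Return the vector of per-trial log probabilities
#'   instead of their sum.
#' @return Total log likelihood (or per-trial vector).
#' @export
trial_log_likelihood <- function(trials, params,
                                 decoder = c("ml", "posterior_sampling"),
                                 n_sim = task_n_sim(params$space),
                                 n_bins = task_n_bins(params$space),
                                 seed = NULL, cache = TRUE,
                                 per_trial = FALSE) {
  decoder <- match.arg(decoder)
  sp <- params$space
  check_trials(trials, sp)
  edges <- response_bins(sp, n_bins)
  cells <- trial_cells(trials, sp, edges)
  ll <- numeric(nrow(trials))
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    idx <- bin_index(sp, edges, trials$response[cell$rows])
    if (cache) {
      if (!is.null(seed)) set.seed(derive_seed(seed, ci))
      d <- predict_distribution(params, cell$target, cell$set_size,
                                decoder = decoder, n_sim = n_sim,
                                n_bins = n_bins)
      ll[cell$rows] <- log(d$probabilities[idx])
    } else {
      for (j in seq_along(cell$rows)) {
        if (!is.null(seed)) set.seed(derive_seed(seed, ci))
        d <- predict_distribution(params, cell$target, cell$set_size,
                                  decoder = decoder, n_sim = n_sim,
                                  n_bins = n_bins)
        ll[cell$rows[j]] <- log(d$probabilities[idx[j]])
      }
    }
  }
  if (per_trial) ll else sum(ll)
}

#' Grid-search maximum-likelihood fit of the population model
#'
#' Evaluates the trial log likelihood at every (gain, width) grid point and
#' returns the maximizer, fitting jointly across all set sizes present:
#' divisive normalization alone carries the memory-load effect, so no
#' per-set-size parameter exists. Two evaluation methods:
#' \describe{
#'   \item{`"stratified"` (default)}{Exploits the fact that, conditional on
#'     the total spike count K, the decoded response distribution does not
#'     depend on the gain (normalization makes both the Poisson total and
#'     the per-spike tuning draw gain-free). Response histograms are
#'     simulated once per (width, target, K) stratum for K = 0..`k_cap`
#'     (Poisson tail mass lumped into the cap stratum, where decoding
#'     precision has saturated below one bin width) and assembled into
#'     every gain's predicted distribution with Poisson weights. Common
#'     random numbers across widths keep the likelihood surface smooth.
#'     On a circular space the distribution is additionally computed at a
#'     single canonical target and translated, using rotational symmetry.}
#'   \item{`"direct"`}{Calls [trial_log_likelihood()] independently at every
#'     grid point. Exact reference implementation; practical only for small
#'     grids.}
#' }
#'
#' @param trials Data frame with columns `target`, `set_size`, `response`.
#' @param task Fitting task, see [default_grids()]; sets the space, grids,
#'   default decoder and histogram bins.
#' @param decoder `"ml"` or `"posterior_sampling"`; default follows the
#'   task.
#' @param grids Parameter grids (default [default_grids()] for the task).
#' @param n_sim Nominal simulated responses per predicted distribution
#'   (default 2000); sets the smoothing floor and the per-stratum count
#'   (`n_sim / 10`).
#' @param n_bins Histogram bins (default 40 orientation / 20 expression).
#' @param seed Master seed for the simulation streams.
#' @param method `"stratified"` or `"direct"`.
#' @param k_cap Largest explicitly simulated spike-count stratum.
#' @param strata_sims Simulated responses per spike-count stratum
#'   (default `min(500, n_sim/10)`); raise for lower-noise likelihood
#'   surfaces at extra cost.
#' @param refine Two-stage search (stratified method only): after the
#'   first pass, width columns whose best cell lies within 4 log units of
#'   the optimum (at most 16 columns) are re-evaluated at 4x the stratum
#'   precision and their entries replaced, then the argmax is taken over
#'   the updated surface. Suppresses rare long slides along the flat
#'   gain-width likelihood ridge caused by simulation noise.
#' @param n_neurons Population size (default 1000).
#' @return An object of class `"fit_result"`: `best_gain`, `best_width`
#'   (tuning width omega, whatever the grid scale), `log_likelihood`,
#'   `aic`, `grid_loglik` (gain x width matrix), `gain_grid`, `width_grid`,
#'   `width_scale`, `decoder`, `task`, `n_trials`, `seed`.
#' @export
grid_search_fit <- function(trials, task, decoder = NULL,
                            grids = default_grids(task),
                            n_sim = 2000, n_bins = NULL, seed = 1,
                            method = c("stratified", "direct"),
                            k_cap = 256L, n_neurons = 1000,
                            strata_sims = NULL, refine = TRUE) {
  method <- match.arg(method)
  sp <- task_space(task)
  if (is.null(decoder)) decoder <- task_decoder(task)
  if (is.null(n_bins)) n_bins <- task_n_bins(sp)
  check_trials(trials, sp)
  gains <- grids$gain
  widths <- grids$width
  omegas <- grid_width_to_omega(widths, grids$width_scale)
  edges <- response_bins(sp, n_bins)
  grid <- decoding_grid(sp)

  if (method == "direct") {
    ll <- matrix(NA_real_, length(gains), length(widths))
    for (wi in seq_along(widths)) {
      for (gi in seq_along(gains)) {
        p <- population_params(sp, gains[gi], omegas[wi], n_neurons)
        ll[gi, wi] <- trial_log_likelihood(
          trials, p, decoder = decoder, n_sim = n_sim, n_bins = n_bins,
          seed = derive_seed(seed, (wi - 1) * length(gains) + gi))
      }
    }
  } else {
    ll <- fit_stratified(trials, sp, gains, omegas, decoder, n_sim, n_bins,
                         edges, grid, seed, as.integer(k_cap), n_neurons,
                         strata_sims)
    if (refine) {
      m1 <- if (is.null(strata_sims)) {
        min(500L, max(50L, as.integer(ceiling(n_sim / 10))))
      } else as.integer(strata_sims)
      colmax <- apply(ll, 2, max)
      cand <- which(colmax >= max(colmax) - 4)
      if (length(cand) > 16)
        cand <- cand[order(colmax[cand], decreasing = TRUE)[1:16]]
      ll2 <- fit_stratified(trials, sp, gains, omegas[cand], decoder, n_sim,
                            n_bins, edges, grid, seed,
                            as.integer(k_cap), n_neurons, 4L * m1)
      ll[, cand] <- ll2
    }
  }

  best <- arrayInd(which.max(ll), dim(ll))
  logl <- ll[best[1], best[2]]
  structure(list(
    best_gain = gains[best[1]],
    best_width = omegas[best[2]],
    best_index = c(gain = best[1], width = best[2]),
    log_likelihood = logl,
    aic = aic(logl, 2),
    grid_loglik = ll,
    gain_grid = gains,
    width_grid = widths,
    width_scale = grids$width_scale,
    decoder = decoder,
    task = task,
    n_trials = nrow(trials),
    seed = seed,
    method = method), class = "fit_result")
}

fit_stratified <- function(trials, sp, gains, omegas, decoder, n_sim,
                           n_bins, edges, grid, seed, k_cap, n_neurons,
                           strata_sims = NULL) {
  # per-stratum simulation count: the stratified estimator's effective
  # sample size per cell is m / sum(w_K^2), roughly 5-25x m, so m well
  # below n_sim already matches the precision of n_sim direct draws
  m <- if (is.null(strata_sims)) {
    min(500L, max(50L, as.integer(ceiling(n_sim / 10))))
  } else as.integer(strata_sims)

  if (is_circular(sp)) {
    # rotational symmetry: one canonical-target distribution per
    # (width, set size); trials enter via their error mapped to target 0.
    # Targets in the data are continuous while simulated responses snap to
    # the decoding grid, so the canonical target is jittered over J
    # sub-grid offsets to reproduce the continuous error lattice.
    canon <- wrap_value(sp, signed_error(sp, trials$target, trials$response))
    tt <- data.frame(target = 0, set_size = trials$set_size, response = canon)
    n_jitter <- 8L
    offs <- (seq_len(n_jitter) - 1) / n_jitter * (grid[2] - grid[1])
  } else {
    tt <- trials[, c("target", "set_size", "response")]
    n_jitter <- 1L
    offs <- 0
  }
  cells <- trial_cells(tt, sp, edges)
  utar <- sort(unique(vapply(cells, `[[`, numeric(1), "target")))
  Ns <- sort(unique(vapply(cells, `[[`, integer(1), "set_size")))

  # strata beyond any plausible total spike count carry no Poisson mass
  k_cap <- min(k_cap, max(10L, stats::qpois(1 - 1e-9, max(gains) / min(Ns))))
  ks <- 0:k_cap
  n_strata <- k_cap + 1L
  mj <- max(25L, as.integer(ceiling(m / n_jitter)))

  # Poisson stratum weights per set size; tail mass lumped into the cap
  Wg <- lapply(Ns, function(N) {
    lam <- gains / N
    W <- outer(lam, ks, function(l, k) stats::dpois(k, l))
    W[, n_strata] <- stats::ppois(k_cap - 1, lam, lower.tail = FALSE)
    W
  })

  ll <- matrix(0, length(gains), length(omegas))
  for (wi in seq_along(omegas)) {
    params <- population_params(sp, 1, omegas[wi], n_neurons)
    for (ti in seq_along(utar)) {
      # same derived seed for every width: common random numbers
      set.seed(derive_seed(seed, ti))
      tvec <- rep(utar[ti] + offs, each = n_strata) # constant runs: kernel reuse
      res <- simulate_responses(params, targets = tvec,
                                decoder = decoder, n_per_target = mj,
                                grid = grid, fixed_k = rep(ks, n_jitter))
      if (is_circular(sp)) {
        res <- wrap_value(sp, res - rep(tvec, each = mj) + utar[ti])
      }
      idx <- bin_index(sp, edges, res)
      # pool the jitter offsets within each spike-count stratum
      stratum <- rep(rep(ks, n_jitter), each = mj)
      H <- vapply(ks, function(k)
        tabulate(idx[stratum == k], nbins = n_bins), integer(n_bins))
      Hn <- t(H) / (mj * n_jitter)  # strata x n_bins, rows sum to 1
      if (is_circular(sp)) {
        # a zero-spike pattern has a flat likelihood, so its decoded
        # response is fixed by the tie-break rule, not the target: over
        # the uniformly distributed targets of the design its ERROR is
        # exactly uniform. The canonical-target translation cannot see
        # this (it is the one stratum that is not shift-equivariant), so
        # the row is set analytically.
        Hn[1, ] <- 1 / n_bins
      }
      for (cell in cells) {
        if (cell$target != utar[ti]) next
        P <- Wg[[match(cell$set_size, Ns)]] %*% Hn  # gains x bins
        P <- (P * n_sim + 1) / (n_sim + n_bins)
        ll[, wi] <- ll[, wi] + drop(log(P) %*% cell$counts)
      }
    }
  }
  ll
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<population-model fit (%s decoder, %s, %s grid)>\n",
              x$decoder, x$task, x$method))
  cat(sprintf("  gain constant: %.4g   tuning width: %.4g\n",
              x$best_gain, x$best_width))
  cat(sprintf("  log likelihood: %.2f over %d trials   AIC: %.2f\n",
              x$log_likelihood, x$n_trials, x$aic))
  invisible(x)
}

#' Compare the ML and posterior-sampling decoders on the same trials
#'
#' Fits both model variants to one set of orientation trials (the
#' standard default grids for each) and reports the AIC difference. Only
#' defined for circular-space data: the ML decoder variant was applied to
#' orientation only.
#'
#' @param trials Orientation trial data frame (`target`, `set_size`,
#'   `response`, degrees on the 180-degree circle).
#' @param seed Master seed, shared by both fits.
#' @param n_sim,k_cap,strata_sims Passed to [grid_search_fit()].
#' @return An object of class `"decoder_comparison"`: fields `ml` and
#'   `posterior_sampling` (both [grid_search_fit()] results) and
#'   `delta_aic = AIC(ml) - AIC(posterior sampling)` (negative values
#'   favor the ML variant).
#' @export
compare_decoders <- function(trials, seed = 1, n_sim = 2000, k_cap = 256L,
                             strata_sims = NULL) {
  if (("item_kind" %in% names(trials) && any(trials$item_kind == "face")) ||
      any(trials$target < 0 | trials$target >= 180))
    stop("decoder comparison is only supported for orientation data",
         call. = FALSE)
  fit_ml <- grid_search_fit(trials, "orientation_ml", seed = seed,
                            n_sim = n_sim, k_cap = k_cap,
                            strata_sims = strata_sims)
  fit_ps <- grid_search_fit(trials, "orientation_sampling", seed = seed,
                            n_sim = n_sim, k_cap = k_cap,
                            strata_sims = strata_sims)
  structure(list(ml = fit_ml, posterior_sampling = fit_ps,
                 delta_aic = fit_ml$aic - fit_ps$aic),
            class = "decoder_comparison")
}

#' @export
print.decoder_comparison <- function(x, ...) {
  cat("<decoder comparison on shared orientation trials>\n")
  cat(sprintf("  ML:                gain %.4g, width %.4g, AIC %.2f\n",
              x$ml$best_gain, x$ml$best_width, x$ml$aic))
  cat(sprintf("  posterior sampling: gain %.4g, width %.4g, AIC %.2f\n",
              x$posterior_sampling$best_gain, x$posterior_sampling$best_width,
              x$posterior_sampling$aic))
  cat(sprintf("  delta AIC (ML - sampling): %.3f\n", x$delta_aic))
  invisible(x)
}
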