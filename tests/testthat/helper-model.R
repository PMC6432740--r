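# small fixtures shared across test files; everything is generated in code

orientation_space <- function() circular_space(180)
intensity_space <- function() bounded_space(0, 100)

small_params <- function(space = orientation_space(), gain = 30,
                         width = if (is_circular(space)) 0.3 else 8,
                         n_neurons = 200) {
  population_params(space, gain, width, n_neurons)
}

# independent brute-force log likelihood: per-neuron Poisson densities
# summed with dpois, no shared code with log_likelihood_grid
oracle_loglik <- function(spikes, params, set_size, grid) {
  vapply(grid, function(theta) {
    f <- expected_rates(params, theta, set_size)
    sum(stats::dpois(spikes, f, log = TRUE))
  }, numeric(1))
}

# a tiny balanced bounded-space trial table with known responses
tiny_trials <- function(n = 12) {
  tibble::tibble(
    participant = 1L,
    set_size = rep(c(1L, 2L), length.out = n),
    target = rep(c(28, 73), length.out = n),
    response = seq(20, 80, length.out = n))
}
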