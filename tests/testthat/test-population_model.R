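test_that("divisive normalization conserves total expected activity", {
  set.seed(21)
  for (i in 1:25) {
    circ <- i %% 2 == 0
    sp <- if (circ) orientation_space() else intensity_space()
    gain <- 10^runif(1, -1, 3)
    width <- if (circ) 10^runif(1, -1, 0) else 10^runif(1, -2, 1)
    theta <- if (circ) runif(1, 0, 180) else runif(1, 0, 100)
    N <- sample(1:5, 1)
    p <- population_params(sp, gain, width, 500)
    r <- expected_rates(p, theta, N)
    expect_true(all(r >= 0))
    expect_lt(abs(sum(r) - gain / N) / (gain / N), 1e-10)
  }
  # explicit load effect: five items each get a fifth of the activity
  p <- population_params(intensity_space(), 100, 10)
  expect_equal(sum(expected_rates(p, 7, 1)), 100)
  expect_equal(sum(expected_rates(p, 7, 5)), 20)
  expect_error(expected_rates(p, 7, 0), "set_size")
})

test_that("the preferred-value neuron fires most for its own stimulus", {
  p <- small_params(orientation_space(), n_neurons = 24)
  for (k in c(1, 7, 13)) {
    r <- expected_rates(p, p$preferred_values[k], 1)
    expect_equal(which.max(r), k) # brute force over all neurons
  }
})

test_that("Poisson spiking is reproducible and matches its means", {
  p <- small_params()
  r <- expected_rates(p, 90, 1)
  set.seed(99); s1 <- sample_spikes(r)
  set.seed(99); s2 <- sample_spikes(r)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0))
  expect_equal(sample_spikes(rep(0, 10)), rep(0L, 10))
  expect_error(sample_spikes(c(1, -0.5)), "negative")
  # Monte-Carlo mean of repeated draws of one neuron
  i <- which.max(r)
  set.seed(100)
  draws <- rpois(1e5, r[i])
  expect_lt(abs(mean(draws) - r[i]), 3 * sqrt(r[i] / 1e5))
})

test_that("log likelihood over the grid matches a dpois oracle", {
  set.seed(22)
  for (rep in 1:8) {
    circ <- rep %% 2 == 0
    sp <- if (circ) orientation_space() else intensity_space()
    p <- population_params(sp, 10^runif(1, 0.5, 2),
                           if (circ) runif(1, 0.2, 0.8) else runif(1, 3, 15),
                           300)
    N <- sample(1:5, 1)
    theta <- if (circ) runif(1, 0, 180) else runif(1, 5, 95)
    spikes <- sample_spikes(expected_rates(p, theta, N))
    grid <- decoding_grid(sp, if (circ) 2 else 1)
    ll <- log_likelihood_grid(spikes, p, N, grid)
    oracle <- oracle_loglik(spikes, p, N, grid)
    # equal up to an additive constant (factorial terms dropped)
    expect_equal(ll - max(ll), oracle - max(oracle), tolerance = 1e-8)
    expect_equal(which.max(ll), which.max(oracle))
    expect_equal(decode_ml(spikes, p, N, grid), grid[which.max(oracle)])
  }
})

test_that("zero spikes give a flat likelihood and decode to the first grid point", {
  for (sp in list(orientation_space(), intensity_space())) {
    p <- small_params(sp)
    ll <- log_likelihood_grid(rep(0L, p$n_neurons), p, 3)
    expect_lt(diff(range(ll)), 1e-10)
    expect_equal(decode_ml(rep(0L, p$n_neurons), p, 3),
                 decoding_grid(sp)[1])
  }
})

test_that("a single spike decodes to the spiking neuron's preferred value", {
  p <- small_params(orientation_space(), n_neurons = 180)
  grid <- decoding_grid(orientation_space())
  for (k in c(30, 91, 170)) {
    spikes <- integer(180); spikes[k] <- 1L
    d <- decode_ml(spikes, p, 1, grid)
    nearest <- grid[which.min(abs(signed_error(orientation_space(), p$preferred_values[k], grid)))]
    expect_equal(d, nearest)
  }
})

test_that("doubling all spike counts moves the argmax at most one grid step", {
  set.seed(23)
  p <- small_params(orientation_space())
  grid <- decoding_grid(orientation_space())
  for (rep in 1:5) {
    spikes <- sample_spikes(expected_rates(p, runif(1, 0, 180), 1))
    d1 <- decode_ml(spikes, p, 1, grid)
    d2 <- decode_ml(2L * spikes, p, 2, grid)
    expect_lte(abs(signed_error(orientation_space(), d1, d2)), 1 + 1e-9)
  }
})

test_that("posterior over the grid is proper and agrees with ML decoding", {
  set.seed(24)
  for (rep in 1:6) {
    circ <- rep %% 2 == 0
    sp <- if (circ) orientation_space() else intensity_space()
    p <- small_params(sp)
    N <- sample(1:5, 1)
    theta <- if (circ) runif(1, 0, 180) else runif(1, 0, 100)
    spikes <- sample_spikes(expected_rates(p, theta, N))
    prior <- uniform_prior(sp)
    post <- posterior_over_grid(spikes, p, N, prior)
    expect_equal(sum(post), 1)
    expect_true(all(post >= 0))
    expect_equal(prior$grid[which.max(post)], decode_ml(spikes, p, N, prior$grid))
  }
})

test_that("degenerate priors control the posterior draw", {
  sp <- intensity_space()
  p <- small_params(sp)
  spikes <- sample_spikes(expected_rates(p, 30, 1))
  pp <- point_prior(sp, 72.5)
  set.seed(25)
  expect_equal(decode_posterior_sample(spikes, p, 1, pp), 72.5)
  # zero spikes: draws distributed exactly as the prior
  up <- uniform_prior(sp)
  expect_equal(posterior_over_grid(rep(0L, p$n_neurons), p, 1, up),
               up$weights)
})

test_that("high-gain decoding concentrates near the true stimulus", {
  sp <- orientation_space()
  p <- population_params(sp, 1e4, 0.3, 1000)
  set.seed(26)
  res <- popcodewm:::simulate_responses(p, 45, set_size = 1, decoder = "ml",
                                        n_per_target = 1000)
  err <- signed_error(sp, 45, res)
  width_deg <- 0.3 * 180 / (2 * pi) # tuning width on the stimulus scale
  expect_gte(mean(abs(err) <= width_deg), 0.99)
})

test_that("the simulation engine and the reference decoder agree", {
  # exact agreement: a spike pattern built from the engine's own sampled
  # preferred values must decode identically through decode_ml
  sp <- intensity_space()
  p <- small_params(sp, gain = 40, width = 8, n_neurons = 200)
  grid <- decoding_grid(sp)
  set.seed(27)
  for (rep in 1:5) {
    spikes <- sample_spikes(expected_rates(p, 25, 1))
    ll <- log_likelihood_grid(spikes, p, 1, grid)
    expect_equal(decode_ml(spikes, p, 1, grid), grid[which.max(ll)])
  }
  # distributional agreement: engine responses vs an R-level
  # encode-decode loop, compared on coarse bins (chi-square)
  set.seed(28)
  eng <- popcodewm:::simulate_responses(p, 25, set_size = 2, decoder = "ml",
                                        n_per_target = 400)
  ref <- replicate(400, decode_ml(sample_spikes(expected_rates(p, 25, 2)),
                                  p, 2, grid))
  edges <- response_bins(sp, 10)
  tab <- rbind(tabulate(bin_index(sp, edges, eng), 10),
               tabulate(bin_index(sp, edges, ref), 10))
  keep <- colSums(tab) > 5
  pval <- suppressWarnings(chisq.test(tab[, keep])$p.value)
  expect_gt(pval, 1e-4)
})
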