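test_that("negative log-likelihood: empty data, additivity, Gaussian limit", {
  model <- exp1_model(); space <- exp1_space(); noise <- exp1_noise()
  empty <- new_dataset(model)
  expect_identical(neg_log_likelihood(empty, c(2, 4), model, space, noise), 0)

  d1 <- exp1_noisy_dataset(n = 6, seed = 1)
  d2 <- exp1_noisy_dataset(n = 5, seed = 2)
  th <- c(1.9, 4.2)
  expect_equal(
    neg_log_likelihood(rbind(d1, d2), th, model, space, noise),
    neg_log_likelihood(d1, th, model, space, noise) +
      neg_log_likelihood(d2, th, model, space, noise),
    tolerance = 1e-12)

  # single point far from the truncation boundary: Gaussian closed form
  f <- sum_of_exponentials(th, 1)[1, 1] # f/sigma ~ 34
  ds <- add_observation(empty, 1, f + 0.003)
  expect_equal(neg_log_likelihood(ds, th, model, space, noise),
               0.5 * log(2 * pi * 0.005^2) + 0.003^2 / (2 * 0.005^2),
               tolerance = 1e-8)
})

test_that("likelihood is invariant to record order", {
  model <- exp1_model(); space <- exp1_space(); noise <- exp1_noise()
  ds <- exp1_noisy_dataset(n = 12, seed = 3)
  shuffled <- ds[with_stream(rng_stream(4), sample(nrow(ds))), ]
  th <- c(2.2, 3.8)
  expect_equal(neg_log_likelihood(ds, th, model, space, noise),
               neg_log_likelihood(shuffled, th, model, space, noise),
               tolerance = 1e-12)
})

test_that("MLE recovers the truth from noise-free data", {
  # times restricted to the high signal-to-noise region: elsewhere the
  # truncation-normalisation term of the likelihood legitimately pulls the
  # optimum off the zero-residual point
  model <- exp1_model(); space <- exp1_space(); noise <- exp1_noise()
  ds <- make_noisefree_dataset(model, space, (10:19) / 10)
  fit <- with_stream(rng_stream(5),
                     fit_mle(ds, model, space, noise, n_starts = 10))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$theta - c(2, 4))), 1e-3)
})

test_that("MLE error shrinks as the noise level drops", {
  model <- exp1_model(); space <- exp1_space()
  err <- vapply(c(0.005, 0.0005), function(sig) {
    ds <- exp1_noisy_dataset(n = 30, seed = 6, sigma = sig)
    fit <- with_stream(rng_stream(7),
                       fit_mle(ds, model, space, exp1_noise(sig),
                               n_starts = 8))
    max(abs(fit$theta - c(2, 4)))
  }, 0)
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("a single observation is fit to within noise", {
  model <- exp1_model(); space <- exp1_space(); noise <- exp1_noise()
  ds <- add_observation(new_dataset(model), 2, 0.2)
  fit <- with_stream(rng_stream(8),
                     fit_mle(ds, model, space, noise, n_starts = 10))
  f <- sum_of_exponentials(fit$theta, 2)[1, 1]
  expect_lt(abs(f - 0.2), 3 * 0.005)
})

test_that("best-of-starts fit beats probe points and respects the box", {
  model <- exp1_model(); space <- exp1_space(); noise <- exp1_noise()
  ds <- exp1_noisy_dataset(n = 10, seed = 9)
  fit <- with_stream(rng_stream(10),
                     fit_mle(ds, model, space, noise, n_starts = 6))
  probes <- rbind(c(0.5, 5.5), c(1, 4), c(2, 4), c(2.9, 3.1))
  for (i in seq_len(nrow(probes)))
    expect_lte(fit$nll,
               neg_log_likelihood(ds, probes[i, ], model, space, noise))
  expect_true(all(fit$theta >= space$lower & fit$theta <= space$upper))
})

test_that("constrained fits never beat the MLE and match it when unpinned", {
  model <- exp1_model(); space <- exp1_space(); noise <- exp1_noise()
  ds <- exp1_noisy_dataset(n = 15, seed = 11)
  s <- rng_stream(12)
  mle <- with_stream(s, fit_mle(ds, model, space, noise, n_starts = 8))
  at_mle <- with_stream(s, fit_with_fixed(ds, model, space, "beta1",
                                          mle$theta[["beta1"]], noise,
                                          n_starts = 3))
  expect_equal(at_mle$nll, mle$nll, tolerance = 1e-5)
  pinned <- with_stream(s, fit_with_fixed(ds, model, space, "beta1", 2.6,
                                          noise, n_starts = 3))
  expect_gte(pinned$nll, mle$nll - 1e-6)
})

test_that("a pin at the bound on rich data exceeds the threshold", {
  model <- exp1_model(); space <- exp1_space(); noise <- exp1_noise()
  ds <- exp1_noisy_dataset(n = 25, seed = 13)
  s <- rng_stream(14)
  mle <- with_stream(s, fit_mle(ds, model, space, noise, n_starts = 8))
  at_bound <- with_stream(s, fit_with_fixed(ds, model, space, "beta1", 3,
                                            noise, n_starts = 4))
  expect_gt(at_bound$nll, likelihood_threshold(mle$nll))
})

test_that("candidate set has 2N+1 members with simplex weights", {
  model <- exp1_model(); space <- exp1_space(); noise <- exp1_noise()
  ds <- exp1_noisy_dataset(n = 12, seed = 15, tmax = 3)
  cs <- with_stream(rng_stream(16),
                    build_candidate_set(ds, model, space, noise,
                                        n_starts = 6))
  expect_length(cs$weights, 2 * space$n_free + 1) # m = 5
  expect_equal(sum(cs$weights), 1, tolerance = 1e-12)
  expect_true(all(cs$weights >= 0))
  # MLE is the best fit: boundary profiles cannot undercut it
  expect_true(all(cs$nll >= cs$mle$nll - 1e-6))
  # rich, low-noise data: the beta1 boundary models cannot approach the
  # data (output >= 1 at the lower bound) and get numerically zero weight;
  # the upper beta2 boundary stays plausible because exp(-beta2 t) is close
  # to the noise floor even at the earliest grid times
  expect_gt(cs$nll[["beta1.lower"]] - cs$nll[[1]], 50)
  expect_lt(sum(cs$weights[c("beta1.lower", "beta1.upper")]), 1e-20)
})

test_that("candidate weights follow the normalised-likelihood rule", {
  # equal fits share weight uniformly
  expect_equal(candidate_weights(rep(3.7, 5)), rep(0.2, 5))
  # a candidate 50 nats worse is numerically irrelevant
  w <- candidate_weights(c(10, 10, 60))
  expect_lt(w[3], 1e-20)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # underflow-proof: absolute level does not matter
  expect_equal(candidate_weights(c(1e4, 1e4 + 1)),
               candidate_weights(c(0, 1)), tolerance = 1e-12)
  # failed fits get zero weight
  expect_equal(candidate_weights(c(0, Inf))[2], 0)
})

test_that("an underdetermined single-point fit spreads weight over the
           candidates that can reach the datum", {
  model <- exp1_model(); space <- exp1_space(); noise <- exp1_noise()
  # y = 0.05 at t = 3 is reachable by the MLE and by both beta2 boundary
  # models, but not with beta1 pinned at 0 (output >= 1) or at 3
  # (output <= 2 exp(-9))
  ds <- add_observation(new_dataset(model), 3, 0.05)
  cs <- with_stream(rng_stream(17),
                    build_candidate_set(ds, model, space, noise,
                                        n_starts = 6))
  expect_equal(unname(cs$weights[c("mle", "beta2.lower", "beta2.upper")]),
               rep(1 / 3, 3), tolerance = 1e-3)
  expect_lt(sum(cs$weights[c("beta1.lower", "beta1.upper")]), 1e-6)
})

test_that("observation tables round-trip through delimited text", {
  ds <- exp1_noisy_dataset(n = 5, seed = 18)
  path <- tempfile(fileext = ".csv")
  write_observations(ds, path)
  back <- read_observations(path)
  expect_equal(back, ds, tolerance = 1e-12)
})
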