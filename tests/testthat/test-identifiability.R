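test_that("threshold is nll plus half the chi-squared quantile", {
  # chi^2(0.95, 1) = 3.841459 from standard tables
  expect_equal(likelihood_threshold(0), 1.9207, tolerance = 1e-4)
  expect_equal(likelihood_threshold(0, confidence = 0), 0)
  expect_equal(likelihood_threshold(10) - likelihood_threshold(0), 10)
  expect_error(likelihood_threshold(0, confidence = 1))
})

test_that("verdicts follow the boundary-profile rule, equality excluded", {
  space <- exp1_space()
  mk <- function(nll_lo1, nll_hi1, nll_lo2, nll_hi2, conv = TRUE) {
    fake_candidates(
      thetas = NULL, weights = rep(0.2, 5),
      nll = c(mle = 0, beta1.lower = nll_lo1, beta1.upper = nll_hi1,
              beta2.lower = nll_lo2, beta2.upper = nll_hi2),
      space = space) -> cs
    cs$boundary <- list(
      beta1.lower = list(nll = nll_lo1, converged = conv),
      beta1.upper = list(nll = nll_hi1, converged = conv),
      beta2.lower = list(nll = nll_lo2, converged = TRUE),
      beta2.upper = list(nll = nll_hi2, converged = TRUE))
    cs
  }
  thr <- 1.9207
  rep1 <- check_identifiability(mk(5, 5, 5, 5), thr)
  expect_true(all(rep1$identifiable))
  # profile exactly at the threshold: not identifiable (the <= rule)
  rep2 <- check_identifiability(mk(thr, 5, 5, 5), thr)
  expect_equal(rep2$identifiable, c(FALSE, TRUE))
  # a non-converged boundary fit is conservatively not identifiable
  rep3 <- check_identifiability(mk(5, 5, 5, 5, conv = FALSE), thr)
  expect_equal(rep3$identifiable, c(FALSE, TRUE))
})

test_that("one fresh observation leaves both decay rates unidentifiable", {
  model <- exp1_model(); space <- exp1_space(); noise <- exp1_noise()
  # a typical first draw at t = 3 (true output 0.0028): near-flat profiles
  ds <- add_observation(new_dataset(model), 3, 0.003)
  cs <- with_stream(rng_stream(21),
                    build_candidate_set(ds, model, space, noise,
                                        n_starts = 6))
  thr <- likelihood_threshold(cs$mle$nll)
  rep <- check_identifiability(cs, thr)
  expect_false(any(rep$identifiable))
})

test_that("bisection matches closed-form crossings of a quadratic profile", {
  sur <- quadratic_profile_surrogate(center = 2, curvature = 1, box = c(0, 4))
  off <- 1.9207
  exact <- sur$crossings(off)           # 2 -+ sqrt(1.9207) = 2 -+ 1.38589...
  expect_equal(unname(exact), c(2 - sqrt(off), 2 + sqrt(off)))
  expect_equal(exact[["lower"]], 0.61410, tolerance = 1e-4)
  eps <- 1e-4
  got <- bisect_profile(sur$profile, 2, sur$box, threshold = off,
                        epsilon = eps)
  expect_lt(abs(got$lower - exact[["lower"]]), eps)
  expect_lt(abs(got$upper - exact[["upper"]]), eps)
  # bisection bound on probe count per side
  expect_lte(got$n_probes[["lower"]], ceiling(log2(2 / eps)))
  expect_lte(got$n_probes[["upper"]], ceiling(log2(2 / eps)))
  # interval contains the center
  expect_true(got$lower <= 2 && 2 <= got$upper)
})

test_that("quadratic surrogate edge cases: no crossing, stiff curvature", {
  sur <- quadratic_profile_surrogate(2, 1, c(0, 3))
  expect_null(sur$crossings(-0.5)) # threshold below the minimum
  # a profile flat below the threshold at the bounds: not identifiable
  flat <- function(v) 0.1 * (v - 2)^2
  expect_null(bisect_profile(flat, 2, c(0, 3), threshold = 1.9207))
  stiff <- quadratic_profile_surrogate(2, 1e8, c(0, 3))
  got <- bisect_profile(stiff$profile, 2, c(0, 3), 1.9207, epsilon = 1e-6)
  expect_lt(got$width, 1e-3) # curvature -> Inf: width -> 0
})

test_that("model-based bisection agrees with a dense-grid profile scan", {
  model <- exp1_model(); space <- exp1_space(); noise <- exp1_noise()
  ds <- exp1_noisy_dataset(n = 20, seed = 22, tmax = 3)
  s <- rng_stream(23)
  mle <- with_stream(s, fit_mle(ds, model, space, noise, n_starts = 8))
  thr <- likelihood_threshold(mle$nll)
  eps <- 1e-3 * 3
  ci <- with_stream(s, bisection_ci(ds, model, space, noise, "beta1", mle,
                                    thr, epsilon = eps))
  expect_true(ci$lower <= mle$theta[["beta1"]],
              ci$upper >= mle$theta[["beta1"]])
  expect_lte(ci$n_probes[["lower"]], ceiling(log2(3 / eps)))
  expect_lte(ci$n_probes[["upper"]], ceiling(log2(3 / eps)))

  # independent dense-grid profile scan as the oracle
  grid_v <- seq(space$lower[["beta1"]], space$upper[["beta1"]],
                length.out = 201)
  prof <- vapply(grid_v, function(v) {
    f <- with_stream(s, fit_with_fixed(ds, model, space, "beta1", v, noise,
                                       n_starts = 3,
                                       warm = matrix(mle$theta["beta2"], 1)))
    f$nll
  }, 0)
  spacing <- diff(grid_v)[1]
  below <- grid_v[prof <= thr]
  expect_lt(abs(ci$lower - min(below)), eps + spacing + 1e-9)
  expect_lt(abs(ci$upper - max(below)), eps + spacing + 1e-9)
})

test_that("replicating an observation does not widen the interval on average", {
  model <- exp1_model(); space <- exp1_space(); noise <- exp1_noise()
  deltas <- vapply(1:20, function(seed) {
    ds <- exp1_noisy_dataset(n = 15, seed = 100 + seed, tmax = 3)
    s <- rng_stream(200 + seed)
    mle <- with_stream(s, fit_mle(ds, model, space, noise, n_starts = 6))
    thr <- likelihood_threshold(mle$nll)
    ci1 <- with_stream(s, bisection_ci(ds, model, space, noise, "beta1",
                                       mle, thr, epsilon = 3e-3))
    # replicate an existing record (new truncated-normal draw at its time)
    t_rep <- ds$time[1]
    f <- sum_of_exponentials(space$truth, t_rep)[1, 1]
    y_rep <- with_stream(s, sample_truncated_obs(f, 0.005))
    ds2 <- add_observation(ds, t_rep, y_rep)
    mle2 <- with_stream(s, fit_mle(ds2, model, space, noise, n_starts = 6,
                                   warm = matrix(mle$theta_free, 1)))
    thr2 <- likelihood_threshold(mle2$nll)
    ci2 <- with_stream(s, bisection_ci(ds2, model, space, noise, "beta1",
                                       mle2, thr2, epsilon = 3e-3))
    ci2$width - ci1$width
  }, 0)
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(mean(deltas), 3 * se) # no widening in expectation (3-SE slack)
})
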