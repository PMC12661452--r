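# Shared fixtures: all generated in code from stated seeds.

exp1_space <- function() {
  parameter_space(c("beta1", "beta2"), lower = c(0, 3), upper = c(3, 6),
                  truth = c(2, 4))
}

exp1_model <- function() get_model("sum_of_exponentials")

exp1_noise <- function(sigma = 0.005) noise_spec(c(y = sigma))

# A small noisy Experiment-1 dataset with a stated seed. `tmax` restricts
# the sampled grid times to the informative early region where the signal
# is well above the noise floor.
exp1_noisy_dataset <- function(n = 20, seed = 42, sigma = 0.005, tmax = 10) {
  model <- exp1_model()
  space <- exp1_space()
  noise <- exp1_noise(sigma)
  s <- rng_stream(seed)
  grid <- (10:100) / 10
  grid <- grid[grid <= tmax]
  times <- with_stream(s, sample(grid, n, replace = TRUE))
  ds <- make_noisefree_dataset(model, space, sort(times))
  ds$y <- with_stream(s, sample_truncated_obs(ds$y, sigma))
  ds
}

# A tiny constant-output fake model: forward values set by hand per
# "candidate" theta. theta[1] indexes a row of `values` (|thetas| x M).
constant_model <- function(values, output_names = paste0("o", seq_len(ncol(values)))) {
  model_spec(
    id = "constant_fake",
    forward = function(theta, times) {
      v <- values[theta[[1]], , drop = FALSE]
      matrix(rep(v, each = length(times)), nrow = length(times),
             dimnames = list(NULL, output_names))
    },
    output_names = output_names,
    initial_conditions = c(x = 0))
}

# Hand-built candidate-set object (bypasses fitting) for score tests.
fake_candidates <- function(thetas, weights, nll = NULL, space = NULL) {
  structure(
    list(thetas = thetas, weights = weights,
         nll = if (is.null(nll)) rep(0, length(weights)) else nll,
         space = space),
    class = "al_candidates")
}

# Stub trace for evaluation arithmetic tests.
stub_trace <- function(reliable, max_points = 50, method = "stub",
                       mode = "stop_on_id", final = NULL) {
  structure(
    list(method = method, replication = 1, mode = mode,
         reliable_iteration = reliable, termination = "x",
         iterations = list(), dataset = data.frame(time = numeric(0)),
         final = final, max_points = max_points, seed = 1),
    class = "al_trace")
}
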