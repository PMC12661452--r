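# Acquisition strategies: where to measure next.
#
# All strategies score every time point on the candidate grid and the next
# measurement is the argmax (random sampling ignores scores). Scores are
# non-negative and vanish wherever the model ensemble's trajectories
# coincide.

# Full-grid trajectories for a set of parameter vectors; list of
# |grid| x M matrices (NULL where integration failed).
.ensemble_trajectories <- function(thetas, model, grid) {
  lapply(seq_len(nrow(thetas)), function(i) {
    tr <- model$forward(thetas[i, ], grid)
    if (anyNA(tr)) NULL else tr
  })
}

# Predicted per-output observation variance along the grid, from the MLE
# trajectory and the known truncated-normal noise model: |grid| x M matrix.
.predicted_variance_grid <- function(f_mle, model, noise) {
  sig <- noise$sigma[model$output_names]
  v <- vapply(seq_along(sig),
              function(j) trunc_obs_variance(pmax(f_mle[, j], 0), sig[[j]]),
              numeric(nrow(f_mle)))
  matrix(v, nrow = nrow(f_mle))
}

#' E-ALPIPE acquisition scores: scaled weighted disagreement
#'
#' For every candidate time `x` the score is the likelihood-weighted squared
#' disagreement between the candidate-set models and the MLE model, scaled by
#' the predicted observation-noise variance and summed over outputs:
#' `sum_j (1/sigma_hat_j^2(x)) sum_i w_i (f_j(x|theta_i) - f_j(x|theta_MLE))^2`,
#' where `sigma_hat_j^2(x)` is the truncated-normal variance predicted at the
#' MLE trajectory. High scores flag times where plausible boundary models
#' disagree with the MLE by more than measurement noise can explain.
#'
#' @param candidates An `al_candidates`.
#' @param model An `al_model`.
#' @param grid Candidate measurement times (sorted, hours).
#' @param noise An `al_noise`.
#' @return An object of class `al_scores`: list with `score` (length
#'   `|grid|`), `grid`, `noise_variance` (`|grid| x M`), `strategy`.
#' @export
ealpipe_scores <- function(candidates, model, grid, noise) {
  trajs <- .ensemble_trajectories(candidates$thetas, model, grid)
  if (is.null(trajs[[1]]))
    stop("MLE trajectory failed to integrate on the candidate grid")
  f_mle <- trajs[[1]]
  v_hat <- .predicted_variance_grid(f_mle, model, noise)
  w <- candidates$weights
  acc <- matrix(0, nrow(f_mle), ncol(f_mle))
  for (i in seq_along(trajs)[-1]) {
    if (is.null(trajs[[i]]) || w[i] <= 0) next
    acc <- acc + w[i] * (trajs[[i]] - f_mle)^2
  }
  structure(
    list(score = rowSums(acc / v_hat), grid = grid, noise_variance = v_hat,
         strategy = "ealpipe"),
    class = "al_scores")
}

#' Profile-likelihood model ensemble for the benchmark strategies
#'
#' For each free parameter, 10 evenly spaced pin values across its bounds
#' (endpoints included); while a parameter is practically identifiable, only
#' pin values inside its most recent profile-likelihood confidence interval
#' are kept, falling back to the interval midpoint when none fall inside.
#' Each retained pin value yields one constrained fit, for at most `10 * N`
#' profile models. Failed constrained fits are dropped with a warning.
#'
#' @inheritParams fit_mle
#' @param cis Named list (by parameter) of current confidence intervals
#'   (`list(lower=, upper=)`), or `NULL` entries where not identifiable.
#' @param mle Optional `al_fit` used to warm-start the constrained fits.
#' @param n_per_param Pin values per parameter (10 in the reference
#'   protocol).
#' @return List with `thetas` (ensemble matrix of full parameter vectors) and
#'   `fits`.
#' @export
benchmark_ensemble <- function(dataset, model, space, noise, cis = NULL,
                               mle = NULL, n_starts = 2, n_per_param = 10) {
  thetas <- NULL
  fits <- list()
  for (param in space$free) {
    pins <- seq(space$lower[[param]], space$upper[[param]],
                length.out = n_per_param)
    ci <- cis[[param]]
    if (!is.null(ci)) {
      inside <- pins[pins >= ci$lower & pins <= ci$upper]
      pins <- if (length(inside)) inside else (ci$lower + ci$upper) / 2
    }
    keep <- setdiff(space$free, param)
    for (v in pins) {
      warm <- if (!is.null(mle)) matrix(mle$theta[keep], nrow = 1) else NULL
      fit <- fit_with_fixed(dataset, model, space, param, v, noise,
                            n_starts = n_starts, warm = warm)
      if (!is.finite(fit$nll)) {
        warning("dropping failed profile fit at ", param, " = ", signif(v, 4))
        next
      }
      fits[[length(fits) + 1L]] <- fit
      thetas <- rbind(thetas, fit$theta)
    }
  }
  list(thetas = thetas, fits = fits)
}

#' Benchmark acquisition scores: (scaled) generalized variance
#'
#' Single output: the variance of the ensemble's predicted values at each
#' candidate time. Multiple outputs: the generalized variance, i.e. the
#' determinant of the across-ensemble covariance of the output vector.
#' The scaled variant divides by the predicted noise variance (product of the
#' per-output predicted variances for multiple outputs), giving the relative
#' variance criterion. The ensemble is an exhaustive model set rather than a
#' sample, so population (denominator `m`) moments are used; near-singular
#' covariances are regularised by adding `1e-12 * trace` to the diagonal
#' before the determinant.
#'
#' @param ensemble Result of [benchmark_ensemble()] (or any list with a
#'   `thetas` matrix, ensemble size >= 2).
#' @param model,grid,noise As in [ealpipe_scores()].
#' @param scaled Divide by the predicted noise variance(s)?
#' @param f_mle Optional precomputed MLE trajectory on `grid` used for the
#'   noise-variance prediction; defaults to the ensemble mean trajectory
#'   source, i.e. must be supplied when `scaled = TRUE`.
#' @return An `al_scores`.
#' @export
benchmark_scores <- function(ensemble, model, grid, noise, scaled = FALSE,
                             f_mle = NULL) {
  thetas <- ensemble$thetas
  stopifnot(nrow(thetas) >= 2)
  trajs <- .ensemble_trajectories(thetas, model, grid)
  trajs <- Filter(Negate(is.null), trajs)
  m <- length(trajs)
  if (m < 2) stop("fewer than two ensemble trajectories integrated")
  M <- model$n_outputs
  arr <- array(unlist(trajs), dim = c(length(grid), M, m))
  mu <- apply(arr, c(1, 2), mean)
  dev <- sweep(arr, c(1, 2), mu)
  if (M == 1L) {
    score <- rowMeans(dev[, 1, , drop = FALSE]^2) # population variance
  } else {
    # population covariance per grid point, guarded determinant
    score <- vapply(seq_along(grid), function(t) {
      d <- matrix(dev[t, , ], nrow = M)
      cv <- tcrossprod(d) / m
      tr <- sum(diag(cv))
      if (tr > 0) cv <- cv + diag(1e-12 * tr, M)
      det(cv)
    }, 0)
  }
  v_hat <- NULL
  if (scaled) {
    if (is.null(f_mle)) stop("scaled benchmark needs the MLE trajectory")
    v_hat <- .predicted_variance_grid(f_mle, model, noise)
    score <- score / apply(v_hat, 1, prod)
  }
  structure(
    list(score = score, grid = grid, noise_variance = v_hat,
         strategy = if (scaled) "scaled_benchmark" else "benchmark"),
    class = "al_scores")
}

#' @export
print.al_scores <- function(x, ...) {
  cat("<al_scores> ", x$strategy, ": ", length(x$grid), " grid points, max ",
      format(max(x$score), digits = 4), " at t = ",
      x$grid[which.max(x$score)], "\n", sep = "")
  invisible(x)
}

#' Select the next measurement time
#'
#' Argmax of the scores with ties broken by the earliest time (the grid is
#' sorted). The random strategy ignores scores and draws uniformly from the
#' grid, with replacement across iterations: already-sampled times remain
#' selectable for every strategy, since replicate measurements are
#' informative under noise.
#'
#' @param scores An `al_scores`, or `NULL` for the random strategy.
#' @param grid Candidate times.
#' @param strategy One of `"ealpipe"`, `"benchmark"`, `"scaled_benchmark"`,
#'   `"random"`.
#' @return The chosen time (a member of `grid`).
#' @export
select_next <- function(scores, grid, strategy = "ealpipe") {
  if (strategy == "random") return(grid[sample.int(length(grid), 1)])
  stopifnot(inherits(scores, "al_scores"), length(scores$score) == length(grid))
  grid[which.max(scores$score)]
}
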