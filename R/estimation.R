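#' Negative log-likelihood of a dataset under the truncated-normal noise model
#'
#' Sums the truncated-normal negative log-densities over all records and
#' outputs, assuming independent errors. The empty dataset scores 0; a failed
#' forward integration scores `+Inf` (an infinitely bad fit), making the
#' objective total.
#'
#' @param dataset Observation `data.frame` (`time` + outputs).
#' @param theta_free Free-parameter values in `space$free` order.
#' @param model An `al_model`.
#' @param space An `al_space`.
#' @param noise An `al_noise`.
#' @return Scalar negative log-likelihood (nats).
#' @export
neg_log_likelihood <- function(dataset, theta_free, model, space, noise) {
  .nll_fun(dataset, model, space, noise)(theta_free)
}

# Closure over the dataset-dependent quantities (sorted unique times,
# record index, observation and sigma matrices): the optimiser calls the
# objective hundreds of times per fit and these never change within one.
.nll_fun <- function(dataset, model, space, noise) {
  n <- nrow(dataset)
  if (n == 0L) return(function(theta_free) 0)
  ut <- sort(unique(dataset$time))
  idx <- match(dataset$time, ut)
  y <- as.matrix(dataset[, model$output_names, drop = FALSE])
  sig <- matrix(noise$sigma[model$output_names], n, model$n_outputs,
                byrow = TRUE)
  template <- space$truth
  fixed <- space$fixed
  free <- space$free
  forward <- model$forward
  function(theta_free) {
    th <- template
    th[free] <- theta_free
    if (length(fixed)) th[names(fixed)] <- fixed
    f <- forward(th, ut)[idx, , drop = FALSE]
    if (anyNA(f)) return(Inf)
    v <- -sum(trunc_obs_log_density(y, f, sig))
    if (is.nan(v)) Inf else v
  }
}

# Box-constrained quasi-Newton minimisation from a set of start points.
# Non-finite objective values are replaced by a large finite penalty so
# L-BFGS-B can recover from infeasible regions.
.multistart_optim <- function(obj, lower, upper, starts) {
  big <- 1e10
  safe <- function(p) {
    v <- obj(p)
    if (!is.finite(v)) big else v
  }
  width <- upper - lower
  best <- NULL
  any_ok <- FALSE
  for (i in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(starts[i, ], lower), upper)
    fit <- tryCatch(
      optim(p0, safe, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(factr = 1e7, maxit = 300, parscale = width,
                           ndeps = rep(1e-4, length(p0)))),
      error = function(e) NULL)
    if (is.null(fit)) next
    ok <- fit$convergence == 0 && fit$value < big
    any_ok <- any_ok || ok
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    best <- list(par = pmin(pmax(starts[1, ], lower), upper), value = big)
  list(par = best$par, value = best$value, converged = any_ok)
}

# Latin-hypercube start points over the free box (consumes the caller's RNG).
.lhs_starts <- function(k, lower, upper) {
  p <- length(lower)
  if (k <= 0) return(matrix(numeric(0), 0, p))
  u <- lhs::randomLHS(k, p)
  sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
}

.as_fit <- function(space, par, value, converged, n_starts) {
  structure(
    list(theta = full_theta(space, par), theta_free = par, nll = value,
         converged = converged, n_starts = n_starts, free = space$free),
    class = "al_fit")
}

#' @export
print.al_fit <- function(x, ...) {
  cat("<al_fit> nll =", format(x$nll, digits = 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(round(x$theta, 6))
  invisible(x)
}

#' Multi-start maximum-likelihood fit
#'
#' Minimises [neg_log_likelihood()] over the free-parameter box with L-BFGS-B
#' from `n_starts` start points: any supplied warm starts first (e.g. the
#' previous iteration's optimum), topped up with Latin-hypercube draws over
#' the box. Deterministic given the caller's RNG state.
#'
#' @param dataset Observation `data.frame`.
#' @param model,space,noise Model, parameter space and noise specification.
#' @param n_starts Total number of start points (>= 1).
#' @param warm Optional matrix (rows = start points, columns in `space$free`
#'   order) of warm starts.
#' @return An `al_fit`: full `theta`, `nll`, `converged` flag, `n_starts`.
#' @export
fit_mle <- function(dataset, model, space, noise, n_starts = 10, warm = NULL) {
  lower <- space$lower[space$free]
  upper <- space$upper[space$free]
  wm <- if (is.null(warm)) matrix(numeric(0), 0, space$n_free)
        else matrix(warm, ncol = space$n_free)
  k <- max(0L, n_starts - nrow(wm))
  starts <- rbind(wm, .lhs_starts(k, lower, upper))
  if (nrow(starts) == 0) stop("n_starts must be >= 1")
  obj <- .nll_fun(dataset, model, space, noise)
  res <- .multistart_optim(obj, lower, upper, starts)
  .as_fit(space, res$par, res$value, res$converged, nrow(starts))
}

#' Profile (constrained) maximum-likelihood fit with one parameter pinned
#'
#' Fixes `param = value` and maximises the likelihood over the remaining free
#' parameters -- the building block of the simplified profile-likelihood
#' analysis (boundary models) and of the bisection confidence-interval
#' search.
#'
#' @inheritParams fit_mle
#' @param param Name of the free parameter to pin.
#' @param value Pin value inside the parameter's bounds.
#' @param warm Optional matrix of warm starts in the *reduced* free space, or
#'   full-length named vectors from which the pinned coordinate is dropped.
#' @return An `al_fit` on the full parameter vector (pinned entry included).
#' @export
fit_with_fixed <- function(dataset, model, space, param, value, noise,
                           n_starts = 3, warm = NULL) {
  sp <- pin_parameter(space, param, value)
  if (sp$n_free == 0L) { # nothing left to optimise
    nll <- neg_log_likelihood(dataset, numeric(0), model, sp, noise)
    return(.as_fit(sp, numeric(0), nll, TRUE, 0L))
  }
  fit <- fit_mle(dataset, model, sp, noise, n_starts = n_starts, warm = warm)
  fit
}

#' Build the candidate set: MLE plus boundary models, with likelihood weights
#'
#' The candidate set of the simplified profile-likelihood analysis: the MLE
#' model plus, for each of the `N` free parameters, the two boundary models
#' obtained by pinning it at its lower and at its upper bound and re-fitting
#' the rest -- `m = 2N + 1` models in total. Normalised likelihood weights
#' `w_i = exp(-nll_i) / sum_k exp(-nll_k)` are computed in the log domain
#' (shift by the minimum before exponentiating) to avoid underflow.
#'
#' Boundary fits start from the MLE projected into the constrained space
#' (profile continuity) topped up with Latin-hypercube draws; the depth of
#' convergence of these profile fits directly shapes the identifiability
#' verdicts, see the methods vignette.
#'
#' @inheritParams fit_mle
#' @param n_starts_profile Start points per boundary fit.
#' @param warm Optional list with element `mle` (free-parameter vector from
#'   a previous iteration) used to warm-start the MLE re-fit.
#' @return An object of class `al_candidates`: list with `mle` (`al_fit`),
#'   `boundary` (named list of `al_fit`s, names `<param>.lower` /
#'   `<param>.upper`), `weights` (simplex, MLE first), `thetas` (m x p matrix
#'   of full parameter vectors) and `nll` (length-m vector).
#' @export
build_candidate_set <- function(dataset, model, space, noise, n_starts = 10,
                                n_starts_profile = 2, warm = NULL) {
  if (nrow(dataset) == 0L) stop("candidate set needs a nonempty dataset")
  wm_mle <- if (!is.null(warm$mle)) matrix(warm$mle, nrow = 1) else NULL
  mle <- fit_mle(dataset, model, space, noise, n_starts = n_starts,
                 warm = wm_mle)
  boundary <- list()
  for (param in space$free) {
    for (side in c("lower", "upper")) {
      value <- space[[side]][[param]]
      key <- paste(param, side, sep = ".")
      keep <- setdiff(space$free, param)
      starts <- matrix(mle$theta[keep], nrow = 1)
      boundary[[key]] <- fit_with_fixed(
        dataset, model, space, param, value, noise,
        n_starts = n_starts_profile, warm = starts)
    }
  }
  nll <- c(mle = mle$nll, vapply(boundary, function(f) f$nll, 0))
  w <- candidate_weights(nll)
  thetas <- rbind(mle$theta,
                  t(vapply(boundary, function(f) f$theta,
                           numeric(length(space$names)))))
  rownames(thetas) <- names(nll)
  structure(
    list(mle = mle, boundary = boundary, weights = w, thetas = thetas,
         nll = nll, space = space),
    class = "al_candidates")
}

#' Normalised likelihood weights from negative log-likelihoods
#'
#' `w_i = exp(-nll_i) / sum_k exp(-nll_k)`, evaluated by shifting by the
#' minimum before exponentiating: the raw likelihoods underflow once a few
#' dozen observations accumulate. Members with infinite `nll` (failed fits)
#' get weight 0.
#'
#' @param nll Vector of negative log-likelihoods (nats).
#' @return Weights on the simplex, same length as `nll`.
#' @export
#' @examples
#' candidate_weights(c(0, 0, 0))        # uniform
#' candidate_weights(c(0, 50))          # second weight ~ 2e-22
candidate_weights <- function(nll) {
  w <- exp(-(nll - min(nll[is.finite(nll)])))
  w[!is.finite(nll)] <- 0
  w / sum(w)
}

#' @export
print.al_candidates <- function(x, ...) {
  cat("<al_candidates> m =", length(x$nll), "models\n")
  print(data.frame(nll = round(x$nll, 4), weight = signif(x$weights, 4)))
  invisible(x)
}
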