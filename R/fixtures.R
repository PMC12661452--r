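# Deterministic toy generators used by the test-suite and the examples:
# noise-free datasets (the sigma -> 0 pathway) and analytic profile
# surrogates with closed-form threshold crossings.

#' Noise-free dataset from the true trajectory
#'
#' @param model An `al_model`.
#' @param space An `al_space` (its `truth` generates the data) or a full
#'   parameter vector.
#' @param times Measurement times (subset of the candidate grid).
#' @return Dataset `data.frame` whose observations equal the true
#'   trajectory exactly.
#' @export
make_noisefree_dataset <- function(model, space, times) {
  theta <- if (inherits(space, "al_space")) space$truth else space
  f <- .model_at_times(model, theta, times)
  d <- data.frame(time = times)
  for (j in seq_len(model$n_outputs)) d[[model$output_names[j]]] <- f[, j]
  d
}

#' Quadratic profile-likelihood surrogate
#'
#' An analytic stand-in for a profile negative log-likelihood,
#' `nll(v) = curvature * (v - center)^2`, whose threshold crossings are
#' closed-form: `center +/- sqrt(offset / curvature)` for a threshold
#' `offset` above the minimum. Used as an independent oracle for the
#' bisection confidence-interval search.
#'
#' @param center Location of the minimum.
#' @param curvature Positive curvature.
#' @param box Length-2 bounds of the search interval.
#' @return List with `profile` (function of v), `crossings(offset)` giving
#'   the exact interval, and `box`.
#' @export
quadratic_profile_surrogate <- function(center, curvature, box) {
  stopifnot(curvature > 0, length(box) == 2, box[1] < center, center < box[2])
  list(
    profile = function(v) curvature * (v - center)^2,
    crossings = function(offset) {
      if (offset < 0) return(NULL) # threshold below the minimum: no crossing
      h <- sqrt(offset / curvature)
      c(lower = center - h, upper = center + h)
    },
    box = box, center = center, curvature = curvature)
}

# Bisection on an arbitrary profile function over [box, center]; mirrors the
# model-based search so the quadratic surrogate can exercise the same
# bracketing logic without any fitting. Shared by tests.
#' Bisection threshold crossings of an analytic profile function
#'
#' Same bracketing scheme as [bisection_ci()] but for a plain function
#' `profile(v)` instead of constrained model fits: used with
#' [quadratic_profile_surrogate()] to validate the search against
#' closed-form crossings.
#'
#' @param profile Function of the scalar parameter returning profile nll.
#' @param center Parameter value at the profile minimum.
#' @param box Length-2 search bounds.
#' @param threshold Crossing level (absolute, same units as `profile`).
#' @param epsilon Bracket tolerance.
#' @return List with `lower`, `upper`, `width`, `n_probes`, or `NULL` when
#'   the profile fails to exceed the threshold at a bound (not
#'   identifiable).
#' @export
bisect_profile <- function(profile, center, box, threshold, epsilon = 1e-3) {
  if (profile(box[1]) <= threshold || profile(box[2]) <= threshold)
    return(NULL)
  side <- function(outside, inside) {
    n <- 0L
    while (abs(inside - outside) > epsilon) {
      mid <- (outside + inside) / 2
      n <- n + 1L
      if (profile(mid) > threshold) outside <- mid else inside <- mid
    }
    list(cross = (outside + inside) / 2, n = n)
  }
  l <- side(box[1], center)
  u <- side(box[2], center)
  list(lower = l$cross, upper = u$cross, width = u$cross - l$cross,
       n_probes = c(lower = l$n, upper = u$n))
}
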