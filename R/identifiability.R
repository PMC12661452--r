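#' Profile-likelihood threshold for practical identifiability
#'
#' `threshold = nLL(theta_MLE) + chi^2(confidence, df = 1) / 2`. Profile
#' negative log-likelihood values above this level on both sides of the MLE
#' mark a parameter practically identifiable; the crossings bound the
#' pointwise confidence interval (df = 1: one parameter profiled at a time).
#'
#' @param nll_mle Negative log-likelihood at the MLE (nats).
#' @param confidence Confidence level in `[0, 1)`.
#' @return Threshold in nats.
#' @export
#' @examples
#' likelihood_threshold(0)        # 1.9207...
likelihood_threshold <- function(nll_mle, confidence = 0.95) {
  stopifnot(confidence >= 0, confidence < 1)
  nll_mle + qchisq(confidence, df = 1) / 2
}

#' Practical-identifiability verdicts from the candidate set
#'
#' The boundary models of the candidate set are the profile-likelihood values
#' at the box bounds: `pl_min` (lower bound) and `pl_max` (upper bound) per
#' free parameter. A parameter is practically identifiable iff both exceed
#' the threshold; `pl <= threshold` on either side (equality included) means
#' the profile has not risen above the confidence level before the search
#' bound, so the parameter is not (yet) identifiable. A non-converged
#' boundary fit is treated conservatively as not identifiable.
#'
#' @param candidates An `al_candidates` from [build_candidate_set()].
#' @param threshold Threshold from [likelihood_threshold()].
#' @return An object of class `al_idreport`: data.frame with one row per free
#'   parameter (`pl_min`, `pl_max`, `identifiable`) plus attribute
#'   `threshold`.
#' @export
check_identifiability <- function(candidates, threshold) {
  space <- candidates$space
  rows <- lapply(space$free, function(param) {
    lo <- candidates$boundary[[paste0(param, ".lower")]]
    hi <- candidates$boundary[[paste0(param, ".upper")]]
    ok <- lo$converged && hi$converged &&
      lo$nll > threshold && hi$nll > threshold
    data.frame(parameter = param, pl_min = lo$nll, pl_max = hi$nll,
               identifiable = ok)
  })
  rep <- do.call(rbind, rows)
  attr(rep, "threshold") <- threshold
  class(rep) <- c("al_idreport", "data.frame")
  rep
}

#' @export
print.al_idreport <- function(x, ...) {
  cat("<al_idreport> threshold =", format(attr(x, "threshold"), digits = 6),
      "nats\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Bisection search for a profile-likelihood confidence interval
#'
#' Assumes a unimodal profile. For each side of the MLE the search brackets
#' the threshold crossing between an "outside" point (profile above the
#' threshold; initially the box bound, where the parameter was already found
#' identifiable) and an "inside" point (profile at or below the threshold;
#' initially the MLE). Each probe re-optimises the nuisance parameters with
#' [fit_with_fixed()], warm-started from the nearest previously accepted
#' profile point; a failed probe fit counts as above-threshold (conservative
#' widening). Bisection stops when the bracket is narrower than `epsilon`, so
#' each side uses at most `ceiling(log2(bracket / epsilon))` probes.
#'
#' @inheritParams fit_with_fixed
#' @param param Free parameter whose interval is sought.
#' @param mle_fit The `al_fit` at the MLE.
#' @param threshold Profile-likelihood threshold (nats).
#' @param epsilon Absolute tolerance on the crossing location (parameter
#'   units). Default: 1e-3 of the parameter's box width.
#' @return List with `lower`, `upper`, `width`, and per-side probe counts
#'   `n_probes`. The interval contains the MLE value.
#' @export
bisection_ci <- function(dataset, model, space, noise, param, mle_fit,
                         threshold, epsilon = NULL, n_starts = 2) {
  lo_b <- space$lower[[param]]
  up_b <- space$upper[[param]]
  if (is.null(epsilon)) epsilon <- 1e-3 * (up_b - lo_b)
  stopifnot(epsilon > 0)
  mle_v <- mle_fit$theta[[param]]
  keep <- setdiff(space$free, param)
  # profile-point cache for warm starts: pin values -> nuisance vectors
  cache_v <- mle_v
  cache_th <- matrix(mle_fit$theta[keep], nrow = 1)
  profile_at <- function(value) {
    if (length(keep) == 0L) {
      sp <- pin_parameter(space, param, value)
      return(neg_log_likelihood(dataset, numeric(0), model, sp, noise))
    }
    i <- which.min(abs(cache_v - value))
    warm <- cache_th[i, , drop = FALSE]
    fit <- fit_with_fixed(dataset, model, space, param, value, noise,
                          n_starts = n_starts, warm = warm)
    if (!fit$converged || !is.finite(fit$nll)) return(Inf)
    cache_v <<- c(cache_v, value)
    cache_th <<- rbind(cache_th, fit$theta[keep])
    fit$nll
  }
  side <- function(outside, inside) {
    n <- 0L
    while (abs(inside - outside) > epsilon) {
      mid <- (outside + inside) / 2
      n <- n + 1L
      if (profile_at(mid) > threshold) outside <- mid else inside <- mid
    }
    list(cross = (outside + inside) / 2, n = n)
  }
  l <- side(lo_b, mle_v)
  u <- side(up_b, mle_v)
  list(lower = l$cross, upper = u$cross, width = u$cross - l$cross,
       n_probes = c(lower = l$n, upper = u$n),
       epsilon = epsilon, parameter = param)
}
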