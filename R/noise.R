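#' Lower-truncated normal observation-noise model
#'
#' Observations are the noise-free model output plus additive Gaussian error
#' truncated below so the observed value stays non-negative: with mean
#' `f >= 0` and standard deviation `sigma`, the error `e ~ N(0, sigma^2)` is
#' conditioned on `e >= -f`. As `f/sigma` grows the model reduces to ordinary
#' Gaussian noise; near `f = 0` it is half-normal-like and its variance drops
#' below `sigma^2`.
#'
#' @param sigma Named numeric vector of per-output noise standard deviations
#'   (output units); all strictly positive.
#' @return An object of class `al_noise`.
#' @export
#' @examples
#' noise_spec(c(BG = 0.5, SC = 1.6))
noise_spec <- function(sigma) {
  sigma <- unlist(sigma)
  stopifnot(is.numeric(sigma), all(sigma > 0))
  if (is.null(names(sigma)) && length(sigma) == 1) names(sigma) <- "y"
  structure(list(sigma = sigma), class = "al_noise")
}

#' @export
print.al_noise <- function(x, ...) {
  cat("<al_noise> lower-truncated normal, sigma:",
      paste(sprintf("%s=%g", names(x$sigma), x$sigma), collapse = ", "), "\n")
  invisible(x)
}

#' Sample lower-truncated normal observations
#'
#' Draws `y = f + e` with `e ~ N(0, sigma^2)` conditioned on `e >= -f`, via
#' the inverse-CDF method so that each observation consumes exactly one
#' uniform variate (this keeps noise streams aligned across acquisition
#' strategies that visit the same design points).
#'
#' @param f Non-negative noise-free means (vectorised).
#' @param sigma Noise standard deviation(s), recycled against `f`.
#' @return Non-negative observations, same length as `f`.
#' @export
sample_truncated_obs <- function(f, sigma) {
  if (any(f < -1e-9)) stop("negative noise-free mean")
  f <- pmax(f, 0)
  p_lo <- pnorm(-f / sigma)
  u <- runif(length(f))
  y <- f + sigma * qnorm(p_lo + u * (1 - p_lo))
  pmax(y, 0) # guard against -0.0 / rounding at the boundary
}

#' Log-density of a lower-truncated normal observation
#'
#' `log[ phi((y - f)/sigma) / (sigma * Phi(f/sigma)) ]` for `y >= 0`, `-Inf`
#' for `y < 0`. The normalising term uses `pnorm(..., log.p = TRUE)` so the
#' evaluation stays accurate for signal-to-noise ratios `f/sigma` in the
#' hundreds.
#'
#' @param y Observed values.
#' @param f Non-negative noise-free means.
#' @param sigma Noise standard deviation(s).
#' @return Log-density values (vectorised).
#' @export
trunc_obs_log_density <- function(y, f, sigma) {
  f <- pmax(f, 0)
  ld <- dnorm((y - f) / sigma, log = TRUE) - log(sigma) -
    pnorm(f / sigma, log.p = TRUE)
  ld[y < 0] <- -Inf
  ld
}

#' Predicted variance of a lower-truncated normal observation
#'
#' Closed form for the variance of `N(f, sigma^2)` truncated below at 0, i.e.
#' at `alpha = -f/sigma` standard units:
#' `sigma^2 * (1 + alpha * lambda - lambda^2)` with hazard
#' `lambda = phi(alpha) / (1 - Phi(alpha))`. Equals `sigma^2 (1 - 2/pi)` at
#' `f = 0` (half-normal) and tends to `sigma^2` as `f/sigma -> Inf`. This is
#' the noise-variance estimate used to scale acquisition scores.
#'
#' @param f Non-negative predicted means (vectorised).
#' @param sigma Noise standard deviation(s).
#' @return Predicted observation variances.
#' @export
trunc_obs_variance <- function(f, sigma) {
  f <- pmax(f, 0)
  a <- -f / sigma
  lam <- exp(dnorm(a, log = TRUE) -
               pnorm(a, lower.tail = FALSE, log.p = TRUE))
  v <- sigma^2 * (1 + a * lam - lam^2)
  pmax(v, sigma^2 * (1 - 2 / pi)) # numerical floor: minimum is at f = 0
}
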