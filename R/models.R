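#' Parameter space of a dynamic model
#'
#' Describes the box over which parameters are estimated: ordered parameter
#' names, per-parameter lower/upper bounds, a subset of parameters pinned to
#' fixed values, and the ground-truth vector used by the simulator.
#'
#' @param names Character vector of all parameter names, in the order the
#'   model's forward map expects them.
#' @param lower,upper Named (or positionally matched) numeric bounds for every
#'   parameter. Free parameters must satisfy `lower < upper`.
#' @param truth Named or positional numeric vector of ground-truth values used
#'   to simulate observations; must lie strictly inside the box for free
#'   parameters.
#' @param fixed Named numeric vector of parameters pinned at a single value
#'   (removed from estimation). May be empty.
#' @return An object of class `al_space` with elements `names`, `lower`,
#'   `upper`, `truth`, `fixed`, `free` (names of free parameters) and `n_free`.
#' @export
#' @examples
#' parameter_space(c("beta1", "beta2"), lower = c(0, 3), upper = c(3, 6),
#'                 truth = c(2, 4))
parameter_space <- function(names, lower, upper, truth, fixed = numeric(0)) {
  p <- length(names)
  named <- function(x) {
    x <- as.numeric(x)
    stopifnot(length(x) == p)
    stats::setNames(x, names)
  }
  lower <- named(lower); upper <- named(upper); truth <- named(truth)
  if (length(fixed)) {
    stopifnot(!is.null(names(fixed)), all(names(fixed) %in% names))
    fixed <- stats::setNames(as.numeric(fixed), names(fixed))
  } else {
    fixed <- stats::setNames(numeric(0), character(0))
  }
  free <- setdiff(names, names(fixed))
  if (any(lower[free] >= upper[free]))
    stop("free parameters need lower < upper")
  inside <- truth[free] > lower[free] & truth[free] < upper[free]
  if (!all(inside))
    stop("truth must lie strictly inside the box for free parameters: ",
         paste(free[!inside], collapse = ", "))
  structure(
    list(names = names, lower = lower, upper = upper, truth = truth,
         fixed = fixed, free = free, n_free = length(free)),
    class = "al_space")
}

#' @export
print.al_space <- function(x, ...) {
  cat("<al_space> ", length(x$names), " parameters (", x$n_free, " free)\n",
      sep = "")
  for (nm in x$names) {
    if (nm %in% names(x$fixed)) {
      cat(sprintf("  %-8s fixed at %g\n", nm, x$fixed[[nm]]))
    } else {
      cat(sprintf("  %-8s in [%g, %g], truth %g\n", nm,
                  x$lower[[nm]], x$upper[[nm]], x$truth[[nm]]))
    }
  }
  invisible(x)
}

#' Pin one further parameter of a space at a fixed value
#'
#' Used by profile-likelihood (constrained) fits: the pinned parameter leaves
#' the free set and its value is carried in `fixed`.
#'
#' @param space An [parameter_space()].
#' @param param Name of a free parameter.
#' @param value Value inside that parameter's bounds.
#' @return A new `al_space` with `param` fixed.
#' @export
pin_parameter <- function(space, param, value) {
  stopifnot(param %in% space$free)
  if (value < space$lower[[param]] || value > space$upper[[param]])
    stop("pin value outside bounds for ", param)
  space$fixed <- c(space$fixed, stats::setNames(value, param))
  space$free <- setdiff(space$free, param)
  space$n_free <- length(space$free)
  space
}

#' Assemble a full parameter vector from free values
#'
#' @param space An `al_space`.
#' @param theta_free Numeric vector of free-parameter values, in `space$free`
#'   order.
#' @return Named full-length parameter vector with fixed entries filled in.
#' @export
full_theta <- function(space, theta_free) {
  th <- space$truth # template: right names/order
  th[space$free] <- theta_free
  if (length(space$fixed)) th[names(space$fixed)] <- space$fixed
  th
}

#' Forward-model specification
#'
#' A model is a deterministic map from a full parameter vector and a sorted
#' time grid to a `length(times) x M` matrix of noise-free outputs.
#'
#' @param id Character identifier (used by [get_model()] and the experiment
#'   presets).
#' @param forward Function `(theta, times) -> matrix` returning one column per
#'   output; rows follow `times`. On integration failure it must return a
#'   matrix of `NA`s (treated by the likelihood as an infinitely bad fit).
#' @param output_names Character vector of output (observable) names.
#' @param initial_conditions Named numeric state vector at time 0.
#' @return An object of class `al_model`.
#' @export
model_spec <- function(id, forward, output_names, initial_conditions) {
  stopifnot(is.function(forward))
  structure(
    list(id = id, forward = forward, output_names = output_names,
         n_outputs = length(output_names),
         initial_conditions = initial_conditions),
    class = "al_model")
}

#' @export
print.al_model <- function(x, ...) {
  cat("<al_model> ", x$id, ": ", x$n_outputs, " output(s) [",
      paste(x$output_names, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

.model_registry <- new.env(parent = emptyenv())

#' Register a forward model under its string id
#'
#' User-supplied models registered here can be addressed from
#' [experiment_config()] exactly like the built-in ones.
#'
#' @param model An [model_spec()].
#' @return The model, invisibly.
#' @export
register_model <- function(model) {
  stopifnot(inherits(model, "al_model"))
  assign(model$id, model, envir = .model_registry)
  invisible(model)
}

#' Look up a registered model by id
#' @param id Model identifier string.
#' @return The `al_model`.
#' @export
get_model <- function(id) {
  if (!exists(id, envir = .model_registry))
    stop("unknown model id: ", id, " (see register_model())")
  get(id, envir = .model_registry)
}

#' Sum of two exponential decays
#'
#' Two first-order decay processes, both starting at 1, of which only the sum
#' `y(t) = exp(-beta1 t) + exp(-beta2 t)` is observed. Linear in the states,
#' with an analytic solution, so the forward map needs no ODE solver.
#'
#' @param theta `(beta1, beta2)` decay rates in 1/h.
#' @param times Sorted numeric time vector (hours).
#' @return `length(times) x 1` matrix of the observed total.
#' @export
#' @examples
#' sum_of_exponentials(c(2, 4), c(0, 1))
sum_of_exponentials <- function(theta, times) {
  y <- exp(-theta[[1]] * times) + exp(-theta[[2]] * times)
  matrix(y, ncol = 1, dimnames = list(NULL, "y"))
}

#' Monod microbial-growth bioreactor trajectories
#'
#' Integrates bacterial biomass `BG` growing on substrate `SC` with Monod
#' kinetics, first-order decay and a yield coefficient:
#' `d(BG)/dt = muMax SC/(KS+SC) BG - KD BG`,
#' `d(SC)/dt = -(1/YieldC) muMax SC/(KS+SC) BG`,
#' from `BG(0) = 1`, `SC(0) = 30` g/L by default. Integration uses an
#' adaptive embedded Runge-Kutta 5(4) pair at relative tolerance 1e-8 and
#' absolute tolerance 1e-10 (bounds admit growth rates up to 50/h, where the
#' dynamics are fast).
#'
#' @param theta `(muMax, KS, KD, YieldC)`: maximum growth rate (1/h), substrate
#'   half-saturation constant (g/L), decay rate (1/h), and yield coefficient
#'   (dimensionless).
#' @param times Sorted time vector (hours).
#' @param init Initial state `(BG, SC)` in g/L.
#' @param outputs Which states are observed: `c("BG", "SC")` or just `"BG"`.
#' @param rtol,atol Integrator tolerances.
#' @return `length(times) x length(outputs)` matrix; all `NA` on integration
#'   failure (step-size collapse), which callers treat as an infinitely bad
#'   fit.
#' @export
#' @examples
#' microbial_growth(c(0.5, 30, 0.05, 0.6), c(0, 10, 20))
microbial_growth <- function(theta, times, init = c(BG = 1, SC = 30),
                             outputs = c("BG", "SC"),
                             rtol = 1e-8, atol = 1e-10) {
  out <- .growth_traj_cpp(as.numeric(theta), as.numeric(times),
                          as.numeric(init), rtol, atol)
  colnames(out) <- c("BG", "SC")
  out[, outputs, drop = FALSE]
}

.register_builtin_models <- function() {
  register_model(model_spec(
    id = "sum_of_exponentials",
    forward = function(theta, times) sum_of_exponentials(theta, times),
    output_names = "y",
    initial_conditions = c(x1 = 1, x2 = 1)))
  register_model(model_spec(
    id = "microbial_growth_1out",
    forward = function(theta, times)
      microbial_growth(theta, times, outputs = "BG"),
    output_names = "BG",
    initial_conditions = c(BG = 1, SC = 30)))
  register_model(model_spec(
    id = "microbial_growth_2out",
    forward = function(theta, times)
      microbial_growth(theta, times, outputs = c("BG", "SC")),
    output_names = c("BG", "SC"),
    initial_conditions = c(BG = 1, SC = 30)))
}

.onLoad <- function(libname, pkgname) {
  .register_builtin_models()
}
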