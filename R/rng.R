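#' Independent reproducible random-number streams
#'
#' The simulation harness draws observation noise, optimiser start points and
#' random design points from separate streams so that, e.g., two acquisition
#' strategies run on the same replication see identical noise realisations
#' wherever their datasets coincide. A stream is a saved Mersenne-Twister
#' state that is swapped into `.Random.seed` for the duration of
#' [with_stream()] and captured back afterwards.
#'
#' @param seed Integer seed (< 2^31) initialising the stream.
#' @return An environment of class `al_rng_stream` holding the generator
#'   state.
#' @seealso [with_stream()], [child_seed()]
#' @export
#' @examples
#' s <- rng_stream(1)
#' a <- with_stream(s, runif(2))
#' b <- with_stream(s, runif(2))  # continues the stream, a != b
rng_stream <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  st <- new.env(parent = emptyenv())
  st$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(st) <- "al_rng_stream"
  st
}

#' Evaluate an expression using a given random stream
#'
#' @param stream An [rng_stream()].
#' @param expr Expression to evaluate; random draws inside it consume the
#'   stream and advance its saved state.
#' @return The value of `expr`.
#' @export
with_stream <- function(stream, expr) {
  stopifnot(inherits(stream, "al_rng_stream"))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

#' Derive a child seed from a base seed
#'
#' Deterministic integer mixing used to give every (replication, purpose)
#' pair its own stream; all results stay below 2^31 - 1.
#'
#' @param base Base seed (integer).
#' @param ... Further non-negative integer indices (replication number,
#'   stream id, ...).
#' @return A single integer seed.
#' @export
child_seed <- function(base, ...) {
  idx <- c(...)
  s <- as.double(base %% 1000003L)
  for (k in idx) s <- (s * 10007 + as.double(k) * 101 + 7919) %% 2147483647
  as.integer(s + 1)
}
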