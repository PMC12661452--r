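#' Observation datasets
#'
#' A dataset is a plain `data.frame` with a `time` column (hours) followed by
#' one column per observed output, in model output order. Repeated times
#' (replicate measurements) are permitted; observations are non-negative.
#'
#' @param model An `al_model`; its `output_names` become the columns.
#' @return An empty dataset with the right columns.
#' @export
new_dataset <- function(model) {
  cols <- c(list(time = numeric(0)),
            stats::setNames(rep(list(numeric(0)), model$n_outputs),
                            model$output_names))
  as.data.frame(cols)
}

#' Append one observation record
#'
#' @param dataset A dataset (`data.frame` with `time` first).
#' @param time Measurement time (hours).
#' @param y Numeric vector of observed outputs (length = number of outputs).
#' @return The extended dataset.
#' @export
add_observation <- function(dataset, time, y) {
  if (any(y < 0)) stop("observations must be non-negative")
  dataset[nrow(dataset) + 1L, ] <- c(time, y)
  dataset
}

#' Read / write observation tables
#'
#' Delimited text with a header row: `time`, then one column per output.
#'
#' @param path File path.
#' @return `read_observations()` returns the dataset `data.frame`.
#' @export
read_observations <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (names(d)[1] != "time") stop("first column must be 'time'")
  d
}

#' @param dataset Dataset to write.
#' @rdname read_observations
#' @export
write_observations <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE)
  invisible(path)
}

# Noise-free model outputs at the dataset's times, handling duplicates and
# unsorted records through one forward solve over the sorted unique times.
.model_at_times <- function(model, theta, times) {
  ut <- sort(unique(times))
  tr <- model$forward(theta, ut)
  tr[match(times, ut), , drop = FALSE]
}
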