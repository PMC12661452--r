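# Evaluation of replicated design runs: the three performance metrics
# (speed to reliable identifiability, confidence-interval width at a fixed
# budget, trajectory error of the budget-time MLE), failure-assignment
# rules, paired significance testing and delimited-text reports.

#' Mean observations-to-reliable-identifiability, failures scored at the cap
#'
#' Averages each trace's `reliable_iteration`; replications that never
#' became reliably identifiable are scored at `max_points`.
#'
#' @param traces List of `al_trace` (one method).
#' @param max_points Cap used when a replication failed.
#' @return Scalar mean.
#' @export
mean_iterations_to_identifiability <- function(traces,
                                               max_points = traces[[1]]$max_points) {
  if (!length(traces)) stop("no traces")
  it <- vapply(traces, function(tr) {
    r <- tr$reliable_iteration
    if (is.na(r)) max_points else r
  }, 0)
  mean(it)
}

#' Per-parameter confidence-interval widths at the observation budget
#'
#' For a fixed-budget trace: the bisection confidence-interval width for
#' every parameter identifiable at the budget, and the full box width (the
#' failure assignment) otherwise. Widths are capped at the box width.
#'
#' @param trace An `al_trace` run in `"fixed_budget"` mode.
#' @param space The experiment's `al_space`.
#' @return Named vector of widths, one per free parameter.
#' @export
ci_width_at_budget <- function(trace, space) {
  box <- space$upper[space$free] - space$lower[space$free]
  w <- box
  for (param in space$free) {
    ci <- trace$final$cis[[param]]
    if (!is.null(ci)) w[[param]] <- min(ci$width, box[[param]])
  }
  w
}

#' Mean absolute trajectory deviation of an estimate from the truth
#'
#' For each observed output, `mean_t |f(t, theta_hat) - f(t, theta_true)|`
#' over the candidate time grid: the point-estimate quality metric.
#'
#' @param theta_hat Full parameter vector (e.g. `trace$final$mle$theta`).
#' @param space An `al_space` (supplies the truth).
#' @param model An `al_model`.
#' @param grid The experiment's candidate times.
#' @return Named vector, one mean absolute deviation per output.
#' @export
diff_metric <- function(theta_hat, space, model, grid) {
  fh <- model$forward(theta_hat, grid)
  ft <- model$forward(space$truth, grid)
  stats::setNames(colMeans(abs(fh - ft)), model$output_names)
}

#' Cumulative probability of reliable identifiability per iteration
#'
#' At observation count `k`, the fraction of replications whose reliable
#' identifiability occurred at or before `k`. Nondecreasing in `k` by
#' construction.
#'
#' @param traces List of `al_trace`.
#' @param max_k Largest observation count to report (default: the cap).
#' @return Data frame with `n_obs` and `probability`.
#' @export
identifiability_probability <- function(traces,
                                        max_k = traces[[1]]$max_points) {
  rel <- vapply(traces, function(tr) {
    r <- tr$reliable_iteration
    if (is.na(r)) Inf else r
  }, 0)
  k <- seq_len(max_k)
  data.frame(n_obs = k,
             probability = vapply(k, function(x) mean(rel <= x), 0))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired per-replication values (methods are
#' paired through shared noise seeds). Zero differences are dropped; the
#' exact distribution is used for n <= 25 without ties, otherwise the normal
#' approximation with continuity correction.
#'
#' @param values_a,values_b Equal-length paired vectors.
#' @return Two-sided p-value (1 when every difference is zero).
#' @export
paired_rank_test <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b))
  d <- values_a - values_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  exact <- n <= 25 && !anyDuplicated(abs(d))
  suppressWarnings(
    wilcox.test(d, exact = exact, correct = TRUE)$p.value)
}

#' Summarise one method's traces
#'
#' @param traces List of `al_trace` for one method (either mode).
#' @param space,model,grid Experiment ingredients (for widths and
#'   trajectory deviations, used when traces are fixed-budget).
#' @return List with `method`, `mean_iterations`, `id_probability`, and --
#'   for fixed-budget traces -- matrices `ci_widths` (reps x parameters) and
#'   `diffs` (reps x outputs) plus their `mean`/`se` summaries
#'   (standard errors are across-replication sd / sqrt(reps)).
#' @export
summarise_method <- function(traces, space = NULL, model = NULL,
                             grid = NULL) {
  out <- list(method = traces[[1]]$method,
              reps = length(traces),
              mean_iterations = mean_iterations_to_identifiability(traces),
              id_probability = identifiability_probability(traces))
  fixed <- traces[[1]]$mode == "fixed_budget"
  if (fixed && !is.null(space)) {
    cw <- t(vapply(traces, ci_width_at_budget, space = space,
                   numeric(space$n_free)))
    colnames(cw) <- space$free
    out$ci_widths <- cw
    out$ci_mean <- colMeans(cw)
    out$ci_se <- apply(cw, 2, sd) / sqrt(nrow(cw))
    if (!is.null(model)) {
      df <- t(vapply(traces, function(tr)
        diff_metric(tr$final$mle$theta, space, model, grid),
        numeric(model$n_outputs)))
      colnames(df) <- model$output_names
      out$diffs <- df
      out$diff_mean <- colMeans(df)
      out$diff_se <- apply(df, 2, sd) / sqrt(nrow(df))
    }
  }
  out
}

#' Write delimited-text report tables for a set of method summaries
#'
#' Produces the standard comparison artefacts: an iterations table (mean
#' observations to reliable identifiability per method), per-parameter CI
#' width and per-output trajectory-deviation tables (mean and SE columns),
#' identifiability-probability curves, and one JSON-lines trace file per
#' method.
#'
#' @param summaries List of [summarise_method()] results.
#' @param out_dir Output directory (created if missing).
#' @param traces Optional named list (by method) of trace lists to dump as
#'   JSON lines.
#' @param prefix File-name prefix (e.g. `"exp1"`).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(summaries, out_dir, traces = NULL,
                         prefix = "experiment") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(out_dir, paste0(prefix, "_iterations.csv"))
  utils::write.csv(data.frame(
    method = vapply(summaries, `[[`, "", "method"),
    mean_iterations = vapply(summaries, `[[`, 0, "mean_iterations"),
    reps = vapply(summaries, `[[`, 0L, "reps")), p, row.names = FALSE)
  paths <- c(paths, p)

  has_ci <- vapply(summaries, function(s) !is.null(s$ci_mean), TRUE)
  if (any(has_ci)) {
    tab <- do.call(rbind, lapply(summaries[has_ci], function(s) {
      d <- data.frame(method = s$method, parameter = names(s$ci_mean),
                      mean = unname(s$ci_mean), se = unname(s$ci_se))
      d
    }))
    p <- file.path(out_dir, paste0(prefix, "_ci_width.csv"))
    utils::write.csv(tab, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  has_diff <- vapply(summaries, function(s) !is.null(s$diff_mean), TRUE)
  if (any(has_diff)) {
    tab <- do.call(rbind, lapply(summaries[has_diff], function(s)
      data.frame(method = s$method, output = names(s$diff_mean),
                 mean = unname(s$diff_mean), se = unname(s$diff_se))))
    p <- file.path(out_dir, paste0(prefix, "_diff.csv"))
    utils::write.csv(tab, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  curves <- do.call(rbind, lapply(summaries, function(s) {
    d <- s$id_probability
    d$method <- s$method
    d
  }))
  if (is.null(curves))
    curves <- data.frame(n_obs = numeric(0), probability = numeric(0),
                         method = character(0))
  p <- file.path(out_dir, paste0(prefix, "_id_probability.csv"))
  utils::write.csv(curves, p, row.names = FALSE)
  paths <- c(paths, p)

  if (!is.null(traces)) {
    dir.create(file.path(out_dir, "traces"), showWarnings = FALSE)
    for (m in names(traces)) {
      p <- file.path(out_dir, "traces",
                     paste0(prefix, "_", m, ".jsonl"))
      con <- file(p, "w")
      for (tr in traces[[m]]) {
        rec <- list(method = tr$method, replication = tr$replication,
                    mode = tr$mode,
                    reliable_iteration = tr$reliable_iteration,
                    termination = tr$termination,
                    n_obs = nrow(tr$dataset),
                    times = tr$dataset$time)
        writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                    na = "null"), con)
      }
      close(con)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
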