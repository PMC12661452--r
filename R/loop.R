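#' Experiment configuration
#'
#' Bundles everything one replication of the sequential design needs: the
#' forward model, parameter space, noise model, candidate time grid, initial
#' design, acquisition method, stopping rule and seeds.
#'
#' @param model_id Registered model id (see [register_model()]).
#' @param space An [parameter_space()].
#' @param noise An [noise_spec()]; one sigma per model output.
#' @param grid Sorted candidate measurement times (hours).
#' @param first_time Time of the initial observation (must lie on the grid).
#' @param method Acquisition strategy: `"ealpipe"`, `"benchmark"`,
#'   `"scaled_benchmark"` or `"random"`.
#' @param max_points Maximum number of observations (cap for the
#'   stop-on-identifiability mode).
#' @param budget Observation count for the fixed-budget evaluation mode.
#' @param confidence Confidence level of the profile-likelihood threshold.
#' @param n_starts Multi-start count for cold maximum-likelihood fits (the
#'   first fit of a replication and the fresh budget-time fit).
#' @param n_starts_refit Start count for warm sequential MLE re-fits.
#' @param n_starts_profile Start count for constrained (profile) fits.
#' @param n_starts_ensemble Start count per pin-value fit of the benchmark
#'   profile ensemble (these fits feed only the prediction-variance score,
#'   so a single warm-started optimisation is the standard depth).
#' @param epsilon_frac Bisection tolerance as a fraction of each parameter's
#'   box width.
#' @param seed Base seed; replication `r` derives independent noise,
#'   optimiser and selection streams from it via [child_seed()].
#' @param reps Default replication count for [run_experiment()].
#' @return An object of class `al_config`.
#' @export
experiment_config <- function(model_id, space, noise, grid, first_time,
                              method = "ealpipe", max_points = 50,
                              budget = 20, confidence = 0.95,
                              n_starts = 10, n_starts_refit = 4,
                              n_starts_profile = 2, n_starts_ensemble = 1,
                              epsilon_frac = 1e-3,
                              seed = 1, reps = 100) {
  model <- get_model(model_id)
  stopifnot(inherits(space, "al_space"), inherits(noise, "al_noise"),
            all(model$output_names %in% names(noise$sigma)),
            max_points >= 1, budget >= 2,
            method %in% c("ealpipe", "benchmark", "scaled_benchmark",
                          "random"))
  if (!any(abs(grid - first_time) < 1e-9))
    stop("first_time must be a member of the candidate grid")
  structure(
    list(model_id = model_id, space = space, noise = noise, grid = grid,
         first_time = first_time, method = method, max_points = max_points,
         budget = budget, confidence = confidence, n_starts = n_starts,
         n_starts_refit = n_starts_refit,
         n_starts_profile = n_starts_profile,
         n_starts_ensemble = n_starts_ensemble,
         epsilon_frac = epsilon_frac,
         seed = seed, reps = reps),
    class = "al_config")
}

#' @export
print.al_config <- function(x, ...) {
  cat("<al_config> model ", x$model_id, ", method ", x$method,
      ", grid [", min(x$grid), ", ", max(x$grid), "] (",
      length(x$grid), " pts), first obs at t = ", x$first_time,
      ", cap ", x$max_points, "\n", sep = "")
  invisible(x)
}

#' Built-in case-study configurations
#'
#' Three synthetic studies:
#' * **1** -- sum of two exponential decays, `beta1 in [0, 3]`,
#'   `beta2 in [3, 6]` (non-overlapping because the output is symmetric in
#'   the two rates), truth `(2, 4)` 1/h, noise sd 0.005, grid 1--10 h in 0.1 h
#'   steps, first observation at t = 3 h.
#' * **2** -- Monod bioreactor with only biomass `BG` observed; free
#'   parameters `muMax in [0.1, 50]`, `KD in [1e-4, 1]`,
#'   `YieldC in [0.01, 10]` with `KS` fixed at 30 g/L, truth
#'   `(1, 0.1, 0.5)`, noise sd 2 g/L, grid 1--60 h in 0.5 h steps, first
#'   observation at t = 10 h.
#' * **3** -- the same bioreactor with both `BG` and `SC` observed and all
#'   four parameters free (`KS in [0.1, 50]`), truth
#'   `(0.5, 30, 0.05, 0.6)`, noise sds 0.5 (BG) and 1.6 (SC) g/L.
#'
#' @param experiment 1, 2 or 3.
#' @param ... Overrides passed on to [experiment_config()] (e.g. `method`,
#'   `seed`, `reps`).
#' @return An `al_config`.
#' @export
#' @examples
#' experiment_preset(1, method = "random", seed = 7)
experiment_preset <- function(experiment, ...) {
  args <- switch(as.character(experiment),
    "1" = list(
      model_id = "sum_of_exponentials",
      space = parameter_space(c("beta1", "beta2"), lower = c(0, 3),
                              upper = c(3, 6), truth = c(2, 4)),
      noise = noise_spec(c(y = 0.005)),
      grid = (10:100) / 10,
      first_time = 3),
    "2" = list(
      model_id = "microbial_growth_1out",
      space = parameter_space(
        c("muMax", "KS", "KD", "YieldC"),
        lower = c(0.1, 0.1, 1e-4, 0.01), upper = c(50, 50, 1, 10),
        truth = c(1, 30, 0.1, 0.5), fixed = c(KS = 30)),
      noise = noise_spec(c(BG = 2)),
      grid = (2:120) / 2,
      first_time = 10),
    "3" = list(
      model_id = "microbial_growth_2out",
      space = parameter_space(
        c("muMax", "KS", "KD", "YieldC"),
        lower = c(0.1, 0.1, 1e-4, 0.01), upper = c(50, 50, 1, 10),
        truth = c(0.5, 30, 0.05, 0.6)),
      noise = noise_spec(c(BG = 0.5, SC = 1.6)),
      grid = (2:120) / 2,
      first_time = 10),
    stop("experiment must be 1, 2 or 3"))
  over <- list(...)
  do.call(experiment_config, utils::modifyList(args, over))
}

#' Simulate one observation at a design point
#'
#' Draws one noisy measurement of every observed output at `time` from the
#' ground-truth trajectory, under the lower-truncated normal noise model
#' (truncated at minus the true noise-free value, so observations stay
#' non-negative).
#'
#' @param model An `al_model`.
#' @param space An `al_space` (supplies the ground truth).
#' @param time Measurement time (hours).
#' @param noise An `al_noise`.
#' @return Named vector, one entry per observed output.
#' @export
collect_observation <- function(model, space, time, noise) {
  f <- .model_at_times(model, space$truth, time)[1, ]
  y <- vapply(seq_along(f), function(j)
    sample_truncated_obs(f[[j]], noise$sigma[[model$output_names[j]]]), 0)
  stats::setNames(y, model$output_names)
}

#' Run one replication of the sequential design
#'
#' Implements the active-learning loop: collect the initial observation,
#' then alternate an estimation phase (MLE + boundary models) with an
#' exploration phase (score the candidate grid with the configured strategy
#' and measure at the argmax). Identifiability is assessed from the second
#' observation onwards; the run is *reliably identifiable* at the second of
#' two consecutive assessments in which every free parameter is practically
#' identifiable.
#'
#' Modes: `"stop_on_id"` stops at reliable identifiability (then computes
#' bisection confidence intervals) or at `max_points`; `"fixed_budget"`
#' ignores early stopping, always collects exactly `budget` observations,
#' and finishes with a fresh multi-start MLE plus confidence intervals for
#' the parameters identifiable at the budget (used by the evaluation
#' metrics).
#'
#' @param config An `al_config`.
#' @param replication Replication index (>= 1); combined with `config$seed`
#'   to derive independent noise / optimiser / selection streams, so the
#'   same replication of two methods sees identical noise wherever the
#'   designs coincide.
#' @param mode `"stop_on_id"` or `"fixed_budget"`.
#' @return An object of class `al_trace`; see Details. Fields: `iterations`
#'   (per-assessment records: observation count, identifiability flags,
#'   MLE, nll, threshold, chosen next time), `reliable_iteration`
#'   (observation count at reliable identifiability, `NA` if never),
#'   `termination`, `dataset`, `final` (list: `mle`, `cis`, `report`).
#' @export
run_replication <- function(config, replication = 1,
                            mode = c("stop_on_id", "fixed_budget")) {
  mode <- match.arg(mode)
  model <- get_model(config$model_id)
  space <- config$space
  noise <- config$noise
  grid <- config$grid
  method <- config$method
  cap <- if (mode == "fixed_budget") config$budget else config$max_points

  noise_s <- rng_stream(child_seed(config$seed, replication, 1))
  opt_s <- rng_stream(child_seed(config$seed, replication, 2))
  sel_s <- rng_stream(child_seed(config$seed, replication, 3))

  take <- function(time) {
    y <- with_stream(noise_s, collect_observation(model, space, time, noise))
    add_observation(ds, time, y)
  }
  epsilons <- config$epsilon_frac *
    (space$upper[space$free] - space$lower[space$free])
  all_cis <- function(dataset, mle_fit, report, threshold) {
    cis <- list()
    for (param in space$free) {
      if (!report$identifiable[report$parameter == param]) next
      cis[[param]] <- with_stream(opt_s, bisection_ci(
        dataset, model, space, noise, param, mle_fit, threshold,
        epsilon = epsilons[[param]],
        n_starts = config$n_starts_profile))
    }
    cis
  }

  ds <- new_dataset(model)
  ds <- take(config$first_time)
  warm <- NULL
  last_cis <- list()
  prev_ok <- FALSE
  reliable <- NA_integer_
  iterations <- list()
  termination <- NULL
  final <- list(mle = NULL, cis = NULL, report = NULL)
  first_fit <- TRUE

  repeat {
    k <- nrow(ds)
    cand <- NULL
    report <- NULL
    threshold <- NA_real_
    if (method != "random" || k >= 2) {
      ns <- if (first_fit) config$n_starts else config$n_starts_refit
      cand <- with_stream(opt_s, build_candidate_set(
        ds, model, space, noise, n_starts = ns,
        n_starts_profile = config$n_starts_profile, warm = warm))
      first_fit <- FALSE
      warm <- list(mle = cand$mle$theta_free)
    }
    ok <- FALSE
    if (k >= 2 && !is.null(cand)) {
      threshold <- likelihood_threshold(cand$mle$nll, config$confidence)
      report <- check_identifiability(cand, threshold)
      ok <- all(report$identifiable)
      if (ok && prev_ok && is.na(reliable)) reliable <- k
    }
    rec <- list(n_obs = k, identifiable = ok,
                flags = if (!is.null(report))
                  stats::setNames(report$identifiable, report$parameter)
                else NULL,
                mle = if (!is.null(cand)) cand$mle$theta else NULL,
                nll = if (!is.null(cand)) cand$mle$nll else NA_real_,
                threshold = threshold, chosen = NA_real_)

    if (mode == "stop_on_id" && !is.na(reliable)) {
      final$report <- report
      final$mle <- cand$mle
      final$cis <- all_cis(ds, cand$mle, report, threshold)
      iterations[[length(iterations) + 1L]] <- rec
      termination <- "identifiable"
      break
    }
    if (k >= cap) {
      iterations[[length(iterations) + 1L]] <- rec
      termination <- if (mode == "fixed_budget") "budget" else "max_points"
      if (mode == "fixed_budget") {
        # fresh multi-start MLE at the budget anchors both the trajectory
        # error metric and the confidence intervals (its lower nLL gives
        # the sharper threshold)
        final$mle <- with_stream(opt_s, fit_mle(
          ds, model, space, noise, n_starts = config$n_starts,
          warm = if (!is.null(cand)) matrix(cand$mle$theta_free, 1)
                 else NULL))
        final$report <- report
        if (!is.null(report)) {
          thr_final <- likelihood_threshold(final$mle$nll,
                                            config$confidence)
          final$cis <- all_cis(ds, final$mle, report, thr_final)
        }
      } else {
        final$report <- report
        final$mle <- if (!is.null(cand)) cand$mle else NULL
      }
      break
    }

    # exploration phase: score the grid and choose the next design point
    chosen <- if (method == "random") {
      with_stream(sel_s, select_next(NULL, grid, "random"))
    } else if (method == "ealpipe") {
      sc <- ealpipe_scores(cand, model, grid, noise)
      select_next(sc, grid, method)
    } else {
      if (!is.null(report)) {
        for (param in space$free) {
          idp <- report$identifiable[report$parameter == param]
          if (idp) {
            last_cis[[param]] <- with_stream(opt_s, bisection_ci(
              ds, model, space, noise, param, cand$mle, threshold,
              epsilon = epsilons[[param]],
              n_starts = config$n_starts_profile))
          } else {
            last_cis[param] <- list(NULL)
          }
        }
      }
      ens <- with_stream(opt_s, benchmark_ensemble(
        ds, model, space, noise, cis = last_cis, mle = cand$mle,
        n_starts = config$n_starts_ensemble))
      f_mle <- model$forward(cand$mle$theta, grid)
      sc <- benchmark_scores(ens, model, grid, noise,
                             scaled = (method == "scaled_benchmark"),
                             f_mle = f_mle)
      select_next(sc, grid, method)
    }
    rec$chosen <- chosen
    iterations[[length(iterations) + 1L]] <- rec
    ds <- take(chosen)
    prev_ok <- ok
  }

  structure(
    list(method = method, replication = replication, mode = mode,
         reliable_iteration = reliable, termination = termination,
         iterations = iterations, dataset = ds, final = final,
         max_points = cap, seed = config$seed),
    class = "al_trace")
}

#' @export
print.al_trace <- function(x, ...) {
  cat("<al_trace> ", x$method, " rep ", x$replication, " (", x$mode, "): ",
      nrow(x$dataset), " observations, ",
      if (is.na(x$reliable_iteration)) "never reliably identifiable"
      else paste0("reliably identifiable at n = ", x$reliable_iteration),
      ", terminated: ", x$termination, "\n", sep = "")
  invisible(x)
}

#' Run replicated experiments for one or more acquisition methods
#'
#' Replication `r` of every method shares the same derived noise stream, so
#' methods are compared on identical noise realisations wherever their
#' designs coincide (the pairing assumed by the signed-rank comparisons).
#'
#' @param config An `al_config` (its `method` field is overridden).
#' @param methods Character vector of strategies to run.
#' @param reps Number of replications per method.
#' @param mode Passed to [run_replication()].
#' @param verbose Print one line per completed replication?
#' @return Named list (by method) of lists of `al_trace`.
#' @export
run_experiment <- function(config, methods = config$method,
                           reps = config$reps,
                           mode = "stop_on_id", verbose = FALSE) {
  out <- list()
  for (m in methods) {
    cfg <- config
    cfg$method <- m
    out[[m]] <- lapply(seq_len(reps), function(r) {
      tr <- run_replication(cfg, replication = r, mode = mode)
      if (verbose)
        message(sprintf("%s rep %d: n=%d, reliable=%s", m, r,
                        nrow(tr$dataset), tr$reliable_iteration))
      tr
    })
  }
  out
}
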